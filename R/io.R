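# Configuration, provenance and the three pipeline commands
# (simulate -> estimate -> stats). All tabular I/O is CSV (comma, ".",
# UTF-8, mandatory header, "#" provenance comments); networks use the
# package JSON dialect.

#' Run configuration
#'
#' Bundles paths, physical defaults and seeds for the pipeline commands.
#' Defaults carry the standard constants: rho = 1060 kg/m^3,
#' mu = 3.45 mPa s, ICP 11.6 mmHg, 5 mm cut planes, 5% per-cross-section
#' noise averaged over 15 cross-sections.
#'
#' @param output_dir directory for pipeline outputs.
#' @param n_subjects cohort size for `cmd_simulate`.
#' @param seed integer master seed; every stochastic step derives from it.
#' @param density,viscosity fluid properties (SI).
#' @param icp default intracranial pressure, mmHg.
#' @param cut_distance cut-plane distance, m.
#' @param noise_sd_fraction,n_cross_sections measurement noise settings.
#' @param n_tests Bonferroni correction count for `cmd_stats`.
#' @param alpha family-wise significance level.
#' @param cohort_params distribution table, see [default_cohort_params()].
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir = "cowcvr-out", n_subjects = 10L,
                       seed = 1L, density = 1060, viscosity = 3.45e-3,
                       icp = 11.6, cut_distance = 0.005,
                       noise_sd_fraction = 0.05, n_cross_sections = 15L,
                       n_tests = 18L, alpha = 0.05,
                       cohort_params = default_cohort_params()) {
  structure(list(output_dir = output_dir, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), density = density,
                 viscosity = viscosity, icp = icp,
                 cut_distance = cut_distance,
                 noise_sd_fraction = noise_sd_fraction,
                 n_cross_sections = as.integer(n_cross_sections),
                 n_tests = as.integer(n_tests), alpha = alpha,
                 cohort_params = cohort_params),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Fields present in the file override the [run_config()] defaults.
#'
#' @param path a `.json`, `.yml` or `.yaml` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  known <- names(formals(run_config))
  do.call(run_config, raw[intersect(names(raw), known)])
}

# polynomial rolling hash of the serialized config, for provenance
# headers; output paths are excluded so the hash identifies the
# scientific settings, not where they were written
.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  bytes <- utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                      digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.provenance <- function(config) {
  sprintf("cowcvr %s; seed=%d; config=%s",
          as.character(utils::packageVersion("cowcvr")), config$seed,
          .config_hash(config))
}

.write_table <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write / read a subject table
#'
#' @param subjects list of [subject_record()]s (writer) or CSV path
#'   (reader).
#' @param path CSV path.
#' @param header provenance comment line.
#' @return The reader returns a list of `subject_record`s.
#' @export
write_subjects <- function(subjects, path, header = "cowcvr subjects") {
  df <- do.call(rbind, lapply(subjects, function(s) data.frame(
    subject_id = s$id, group = s$group, map_mmHg = s$map_value,
    icp_mmHg = s$icp_value, ipsi_side = ifelse(is.na(s$ipsi_side), "", s$ipsi_side),
    stenosis_degree_ipsi = s$stenosis_degree_ipsi,
    stenosis_degree_contra = s$stenosis_degree_contra,
    total_volume_ml = s$total_volume, stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(subject_id = character(), group = character(),
                     map_mmHg = numeric(), icp_mmHg = numeric(),
                     ipsi_side = character(),
                     stenosis_degree_ipsi = numeric(),
                     stenosis_degree_contra = numeric(),
                     total_volume_ml = numeric())
  .write_table(df, path, header)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    subject_record(id = r$subject_id, group = r$group,
                   map_value = r$map_mmHg, icp_value = r$icp_mmHg,
                   ipsi_side = if (is.na(r$ipsi_side) || r$ipsi_side == "")
                     NA_character_ else r$ipsi_side,
                   stenosis_degree_ipsi = r$stenosis_degree_ipsi,
                   stenosis_degree_contra = r$stenosis_degree_contra,
                   total_volume = r$total_volume_ml)
  })
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic cohort and writes, under the configured output
#' directory: one network JSON and one measurement CSV per subject, the
#' subject table, and the ground-truth territorial resistance table.
#' Every file carries a provenance header (package version, seed, config
#' hash); identical config and seed give byte-identical payloads.
#'
#' @param config a [run_config()].
#' @return Invisibly, the output directory.
#' @export
cmd_simulate <- function(config = run_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$output_dir))
    stop("cannot create output directory ", config$output_dir)
  prov <- .provenance(config)
  cohort <- if (config$n_subjects > 0)
    simulate_cohort(config$n_subjects, config$cohort_params,
                    seed = config$seed,
                    noise_sd_fraction = config$noise_sd_fraction,
                    n_cross_sections = config$n_cross_sections)
  else list()
  gt <- list()
  for (s in cohort) {
    id <- s$subject$id
    write_cow_network(s$network,
                      file.path(config$output_dir, sprintf("network_%s.json", id)))
    write_measurements(s$measurements,
                       file.path(config$output_dir,
                                 sprintf("measurements_%s.csv", id)),
                       header = prov)
    gtd <- ground_truth_downstream_resistance(s$network, s$resistances,
                                              config$cut_distance)
    gtd$subject_id <- id
    gtd$r_lumped <- unname(s$resistances[gtd$segment_id])
    gt[[length(gt) + 1L]] <- gtd
  }
  gt_df <- if (length(gt)) do.call(rbind, gt) else
    data.frame(territory = character(), side = character(), dup = integer(),
               segment_id = character(), cut_segment = character(),
               r_downstream = numeric(), subject_id = character(),
               r_lumped = numeric())
  .write_table(gt_df, file.path(config$output_dir, "ground_truth.csv"), prov)
  write_subjects(lapply(cohort, `[[`, "subject"),
                 file.path(config$output_dir, "subjects.csv"), prov)
  vols <- generate_synthetic_volumes(config$n_subjects,
                                     config$cohort_params$volumes,
                                     seed = config$seed)
  if (config$n_subjects == 0)
    vols <- data.frame(subject_id = character(), territory = character(),
                       side = character(), volume_ml = numeric())
  .write_table(vols, file.path(config$output_dir, "volumes.csv"), prov)
  message(sprintf("simulated %d subjects into %s (seed %d)",
                  length(cohort), config$output_dir, config$seed))
  invisible(config$output_dir)
}

#' Estimate CVR for every simulated subject on disk
#'
#' Reads the cohort written by [cmd_simulate()], runs [cvr_estimate()]
#' per subject, and writes the territorial table (`cvr.csv`: subject,
#' territory, hemisphere, perfusion pressure, flow, CVR, conductance,
#' flag) and the global table (`cvr_global.csv`: tCVR, total inflow).
#' Per-subject failures are logged and skipped with an exit summary.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the two tables and the failure count.
#' @export
cmd_estimate <- function(config = run_config()) {
  fluid <- fluid_properties(config$density, config$viscosity)
  subjects <- read_subjects(file.path(config$output_dir, "subjects.csv"))
  prov <- .provenance(config)
  terr <- list(); glob <- list(); failed <- 0L
  for (s in subjects) {
    res <- tryCatch({
      net <- read_cow_network(file.path(config$output_dir,
                                        sprintf("network_%s.json", s$id)))
      meas <- read_measurements(file.path(config$output_dir,
                                          sprintf("measurements_%s.csv", s$id)))
      cvr_estimate(net, meas, s, fluid, cut_distance = config$cut_distance)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      message(sprintf("subject %s skipped: %s", s$id, conditionMessage(res)))
      next
    }
    t <- res$territorial
    t <- data.frame(subject_id = s$id, territory = t$territory,
                    hemisphere = t$side, P_terr_mmHg = t$p_terr_mmHg,
                    Q_terr_ml_s = t$q_terr_ml_s,
                    CVR_mmHg_s_ml = t$cvr_mmHg_s_ml,
                    conductance_ml_mmHg_s = t$conductance_ml_mmHg_s,
                    flags = t$flag, stringsAsFactors = FALSE)
    terr[[length(terr) + 1L]] <- t
    glob[[length(glob) + 1L]] <- data.frame(
      subject_id = s$id, group = s$group, tCVR_mmHg_s_ml = res$global$tcvr,
      Q_total_ml_s = res$global$q_total, MAP_mmHg = res$global$map_value,
      ICP_mmHg = res$global$icp_value, stringsAsFactors = FALSE)
  }
  terr_df <- do.call(rbind, terr)
  glob_df <- do.call(rbind, glob)
  .write_table(terr_df, file.path(config$output_dir, "cvr.csv"), prov)
  .write_table(glob_df, file.path(config$output_dir, "cvr_global.csv"), prov)
  message(sprintf("estimated %d subjects (%d skipped)", length(glob), failed))
  invisible(list(territorial = terr_df, global = glob_df, failed = failed))
}

#' Cohort statistics report
#'
#' From the tables written by [cmd_estimate()]: group comparison of tCVR
#' (stenotic vs non-stenotic), per-territory comparisons between
#' hemisphere classes, Bonferroni-thresholded significance flags, the
#' conductance-volume mixed model when volumes are available, and
#' ICC(2,1) when a duplicate-rating table is supplied.
#'
#' @param config a [run_config()].
#' @param ratings optional subjects x raters matrix for the inter-rater
#'   ICC.
#' @return Invisibly, a list with the comparison table, the summary
#'   table, the LMM (or NULL) and the ICC (or NULL). Also writes
#'   `stats_comparisons.csv`, `stats_summary.csv` and `stats_report.txt`.
#' @export
cmd_stats <- function(config = run_config(), ratings = NULL) {
  prov <- .provenance(config)
  terr <- utils::read.csv(file.path(config$output_dir, "cvr.csv"),
                          comment.char = "#", stringsAsFactors = FALSE)
  glob <- utils::read.csv(file.path(config$output_dir, "cvr_global.csv"),
                          comment.char = "#", stringsAsFactors = FALSE)
  thr <- bonferroni_threshold(config$alpha, config$n_tests)

  # hemisphere class per row
  subjects <- read_subjects(file.path(config$output_dir, "subjects.csv"))
  ipsi <- stats::setNames(vapply(subjects, function(s)
    ifelse(is.na(s$ipsi_side), "", s$ipsi_side), character(1)),
    vapply(subjects, `[[`, character(1), "id"))
  terr$hemisphere_class <- ifelse(ipsi[terr$subject_id] == "", "non_stenotic",
                                  ifelse(terr$hemisphere == ipsi[terr$subject_id],
                                         "ipsilateral", "contralateral"))

  comparisons <- list()
  addc <- function(name, a, b, paired = FALSE) {
    res <- tryCatch(compare_groups(a, b, paired), error = function(e) NULL)
    comparisons[[length(comparisons) + 1L]] <<- data.frame(
      comparison = name,
      t = if (is.null(res)) NA_real_ else res$statistic,
      p = if (is.null(res)) NA_real_ else res$p_value,
      significant = if (is.null(res)) NA else res$p_value < thr,
      performed = !is.null(res), stringsAsFactors = FALSE)
  }
  a <- glob$tCVR_mmHg_s_ml[glob$group == "stenotic"]
  b <- glob$tCVR_mmHg_s_ml[glob$group == "non_stenotic"]
  if (length(a) >= 2 && length(b) >= 2)
    addc("tCVR stenotic vs non-stenotic", a, b)
  for (t in unique(terr$territory)) {
    sel <- terr$territory == t & !is.na(terr$CVR_mmHg_s_ml)
    ip <- terr$CVR_mmHg_s_ml[sel & terr$hemisphere_class == "ipsilateral"]
    co <- terr$CVR_mmHg_s_ml[sel & terr$hemisphere_class == "contralateral"]
    if (length(ip) >= 2 && length(co) >= 2)
      addc(sprintf("%s ipsilateral vs contralateral", t), ip, co)
  }
  comp_df <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame(comparison = character(), t = numeric(), p = numeric(),
               significant = logical(), performed = logical())

  cells <- stats::aggregate(CVR_mmHg_s_ml ~ territory + hemisphere_class,
                            data = terr[!is.na(terr$CVR_mmHg_s_ml), ],
                            function(x) c(mean = mean(x), sd = stats::sd(x),
                                          n = length(x)))
  summary_df <- data.frame(territory = cells$territory,
                           hemisphere_class = cells$hemisphere_class,
                           mean = cells$CVR_mmHg_s_ml[, "mean"],
                           sd = cells$CVR_mmHg_s_ml[, "sd"],
                           n = cells$CVR_mmHg_s_ml[, "n"])

  lmm <- NULL
  vol_path <- file.path(config$output_dir, "volumes.csv")
  if (file.exists(vol_path)) {
    vols <- utils::read.csv(vol_path, comment.char = "#",
                            stringsAsFactors = FALSE)
    rec <- merge(terr, vols,
                 by.x = c("subject_id", "territory", "hemisphere"),
                 by.y = c("subject_id", "territory", "side"))
    rec <- rec[!is.na(rec$conductance_ml_mmHg_s) & rec$volume_ml > 0, ]
    rec$conductance <- rec$conductance_ml_mmHg_s
    if (nrow(rec) >= 12 && length(unique(rec$subject_id)) >= 2)
      lmm <- tryCatch(fit_conductance_volume_lmm(rec),
                      error = function(e) NULL)
  }

  icc <- if (!is.null(ratings)) icc_two_way_random(ratings) else NULL

  .write_table(comp_df, file.path(config$output_dir, "stats_comparisons.csv"),
               prov)
  .write_table(summary_df, file.path(config$output_dir, "stats_summary.csv"),
               prov)
  rpt <- c(prov,
           sprintf("Bonferroni: alpha %.3g over %d tests -> p < %s",
                   config$alpha, config$n_tests,
                   format_significance_threshold(thr)),
           utils::capture.output(print(comp_df)),
           utils::capture.output(print(summary_df)),
           if (!is.null(lmm)) utils::capture.output(print(lmm)),
           if (!is.null(icc)) utils::capture.output(print(icc)))
  writeLines(rpt, file.path(config$output_dir, "stats_report.txt"))
  invisible(list(comparisons = comp_df, summary = summary_df, lmm = lmm,
                 icc = icc, threshold = thr))
}
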
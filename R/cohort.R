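# Synthetic cohort generation. The defaults ARE the study conditions: the
# printed cohort statistics (territorial CVR means/SDs, MAP by group,
# ICP 11.6 mmHg, stenosis degrees, total brain volume 1065 +/- 108 ml) are
# the generating distributions, truncated at +/- 4 SD and at zero to keep
# draws physical.

#' Default cohort distribution parameters
#'
#' Means and SDs used by the synthetic cohort generator:
#' territorial CVR (MCA 33.8 +/- 10.5, ACA 59.0 +/- 30.6, PCA
#' 77.8 +/- 21.3 mmHg s/ml), MAP (patients 93 +/- 12, controls
#' 102 +/- 12 mmHg), ICP fixed at 11.6 mmHg, ipsilateral stenosis degree
#' 75 +/- 12% with a 9/29 chance of a contralateral stenosis of
#' 67 +/- 10%, territorial brain volumes summing to about 1065 ml, and the
#' conductance-volume linkage (intercept 0.0224 ml/(mmHg s), slope
#' 1.84e-4 1/(mmHg s) on grand-mean-centred volume).
#'
#' @return A nested list of distribution parameters; edit and pass to the
#'   generators to change the emulated cohort.
#' @export
default_cohort_params <- function() {
  list(
    resistance = data.frame(
      territory = c("MCA", "ACA", "PCA"),
      mean = c(33.8, 59.0, 77.8),
      sd = c(10.5, 30.6, 21.3), stringsAsFactors = FALSE),
    map = list(patient = c(mean = 93, sd = 12),
               control = c(mean = 102, sd = 12)),
    icp = 11.6,
    stenosis = list(ipsi = c(mean = 75, sd = 12),
                    contra = c(mean = 67, sd = 10),
                    contra_prob = 9 / 29, min_degree = 50, max_degree = 95),
    volumes = list(
      territory = data.frame(territory = c("MCA", "ACA", "PCA"),
                             mean = c(240, 160, 130),
                             sd = c(28, 22, 18), stringsAsFactors = FALSE),
      subject_scale_sd = 0.09),
    linkage = list(intercept = 0.0224, slope = 1.84e-4,
                   subject_sd = 0.003, residual_sd = 0.005),
    noise = list(sd_fraction = 0.05, n_cross_sections = 15L),
    variants = list(pcoa = 0.7, acoa = 0.95, fetal_given_pcoa = 0.05,
                    dup_aca2 = 4 / 48, dup_mca1 = 1 / 48)
  )
}

# truncated-normal draw: within mean +/- 4 sd and > lower
.rtnorm <- function(n, mean, sd, lower = 0) {
  if (sd < 0) stop("non-positive SD in distribution table")
  if (sd == 0) return(rep(mean, n))
  lo <- max(mean - 4 * sd, lower)
  hi <- mean + 4 * sd
  if (lo >= hi) stop("truncation bounds do not keep draws positive")
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lo & draw < hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Draw one synthetic subject with ground-truth resistances
#'
#' Samples a subject record (MAP by group, ICP fixed, stenosis degrees for
#' the stenotic group) together with ground-truth territorial resistances,
#' one per territory per hemisphere, from the configured truncated-normal
#' distributions. Deterministic given `seed`.
#'
#' @param params cohort parameters, see [default_cohort_params()].
#' @param seed integer seed.
#' @param id subject identifier.
#' @param group `"stenotic"`, `"non_stenotic"` or `"control"`.
#' @return list(subject, resistances): the [subject_record()] and a named
#'   vector of per-territory per-hemisphere lumped resistances
#'   (`MCA_L`, `MCA_R`, ..., mmHg s/ml).
#' @export
sample_subject <- function(params = default_cohort_params(), seed = NULL,
                           id = "S1",
                           group = c("stenotic", "non_stenotic", "control")) {
  group <- match.arg(group)
  if (any(params$resistance$sd < 0))
    stop("non-positive SD in distribution table")
  draw <- function() {
    res <- c()
    for (i in seq_len(nrow(params$resistance))) {
      t <- params$resistance$territory[i]
      v <- .rtnorm(2, params$resistance$mean[i], params$resistance$sd[i])
      res[sprintf("%s_L", t)] <- v[1]
      res[sprintf("%s_R", t)] <- v[2]
    }
    mp <- if (group == "control") params$map$control else params$map$patient
    map <- .rtnorm(1, mp[["mean"]], mp[["sd"]], lower = params$icp + 20)
    ipsi <- NA_character_; d_ipsi <- NA_real_; d_contra <- NA_real_
    if (group == "stenotic") {
      ipsi <- sample(c("L", "R"), 1)
      st <- params$stenosis
      clamp <- function(x) min(max(x, st$min_degree), st$max_degree)
      d_ipsi <- clamp(.rtnorm(1, st$ipsi[["mean"]], st$ipsi[["sd"]]))
      if (stats::runif(1) < st$contra_prob)
        d_contra <- clamp(.rtnorm(1, st$contra[["mean"]], st$contra[["sd"]]))
    }
    subject <- subject_record(id = id, group = group, map_value = map,
                              icp_value = params$icp, ipsi_side = ipsi,
                              stenosis_degree_ipsi = d_ipsi,
                              stenosis_degree_contra = d_contra)
    list(subject = subject, resistances = res)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Synthetic territorial brain volumes
#'
#' Draws per-subject, per-territory, per-hemisphere grey+white-matter
#' volumes: a subject-level scale factor (truncated normal around 1)
#' times truncated-normal territory draws, so that total brain volume has
#' a realistic mean (about 1065 ml) and between-subject SD (about 108 ml).
#'
#' @param cohort_size number of subjects.
#' @param params the `volumes` element of [default_cohort_params()].
#' @param seed integer seed.
#' @return data.frame(subject_id, territory, side, volume_ml) plus a
#'   `total_ml` attribute-free summary obtainable by aggregation.
#' @export
generate_synthetic_volumes <- function(cohort_size,
                                       params = default_cohort_params()$volumes,
                                       seed = NULL) {
  stopifnot(all(params$territory$mean > 0), all(params$territory$sd >= 0),
            params$subject_scale_sd >= 0)
  gen <- function() {
    rows <- list()
    for (i in seq_len(cohort_size)) {
      scale <- .rtnorm(1, 1, params$subject_scale_sd, lower = 0.5)
      for (j in seq_len(nrow(params$territory))) {
        t <- params$territory$territory[j]
        v <- scale * .rtnorm(2, params$territory$mean[j], params$territory$sd[j])
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%03d", i),
          territory = t, side = c("L", "R"), volume_ml = v,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Linked conductance-volume records for mixed-model recovery
#'
#' Generates the territory-level records the conductance-volume mixed
#' model is fitted to, with a known generating truth:
#' `conductance = intercept + slope * (volume - mean(volume)) + b_subject
#' + residual`, hemisphere classes assigned as in a stenosis cohort (half
#' the subjects stenotic with ipsilateral left, the rest non-stenotic).
#'
#' @param n_subjects number of subjects (6 records each).
#' @param params a [default_cohort_params()] list (uses `volumes` and
#'   `linkage`).
#' @param seed integer seed.
#' @return data.frame(subject_id, hemisphere_class, territory, side,
#'   volume_ml, conductance).
#' @export
generate_conductance_volume_cohort <- function(n_subjects = 46,
                                               params = default_cohort_params(),
                                               seed = NULL) {
  gen <- function() {
    vols <- generate_synthetic_volumes(n_subjects, params$volumes)
    lk <- params$linkage
    vbar <- mean(vols$volume_ml)
    ids <- unique(vols$subject_id)
    b <- stats::setNames(stats::rnorm(length(ids), 0, lk$subject_sd), ids)
    sten <- stats::setNames(seq_along(ids) <= length(ids) / 2, ids)
    vols$hemisphere_class <- ifelse(!sten[vols$subject_id], "non_stenotic",
                                    ifelse(vols$side == "L", "ipsilateral",
                                           "contralateral"))
    vols$conductance <- lk$intercept + lk$slope * (vols$volume_ml - vbar) +
      b[vols$subject_id] + stats::rnorm(nrow(vols), 0, lk$residual_sd)
    vols[c("subject_id", "hemisphere_class", "territory", "side",
           "volume_ml", "conductance")]
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# random variant draw for a cohort anatomy
.sample_variants <- function(pv) {
  pcoa_l <- stats::runif(1) < pv$pcoa
  pcoa_r <- stats::runif(1) < pv$pcoa
  cow_variants(
    pcoa_l = pcoa_l, pcoa_r = pcoa_r,
    acoa = stats::runif(1) < pv$acoa,
    fetal_pca_l = pcoa_l && stats::runif(1) < pv$fetal_given_pcoa,
    fetal_pca_r = pcoa_r && stats::runif(1) < pv$fetal_given_pcoa,
    dup_aca2_l = stats::runif(1) < pv$dup_aca2 / 2,
    dup_aca2_r = stats::runif(1) < pv$dup_aca2 / 2,
    dup_mca1_l = stats::runif(1) < pv$dup_mca1 / 2,
    dup_mca1_r = stats::runif(1) < pv$dup_mca1 / 2)
}

#' Expand territorial resistances to per-branch lumped elements
#'
#' Maps per-territory per-hemisphere resistances (`MCA_L`, `ACA_R`, ...)
#' onto the network's outflow segments. Duplicated branches share the
#' territory element as a parallel pair: each of `n` duplicates receives
#' `n` times the territory resistance, so the parallel combination equals
#' the territorial value.
#'
#' @param network a `cow_network`.
#' @param territorial named vector of territorial resistances
#'   (mmHg s/ml) keyed `"<territory>_<side>"`.
#' @return Named vector of lumped resistances keyed by outflow segment id,
#'   as consumed by [forward_solve()].
#' @export
expand_territorial_resistances <- function(network, territorial) {
  outs <- .outflow_segments(network)
  key <- sprintf("%s_%s", outs$territory, outs$side)
  ndup <- stats::ave(rep(1, nrow(outs)), key, FUN = sum)
  stats::setNames(territorial[key] * ndup, outs$segment_id)
}

#' Simulate a synthetic cohort
#'
#' For each subject: draw an anatomy (anatomical variants and jittered
#' geometry), clinical covariates and ground-truth territorial
#' resistances; solve the forward problem; emulate noisy 4D-flow-style
#' measurements. Stenotic subjects receive a carotid stenosis element on
#' the ipsilateral (and possibly contralateral) ICA.
#'
#' @param n_subjects number of patients (stenotic/non-stenotic mix about
#'   29:19 as in a stroke/TIA cohort).
#' @param params cohort parameters, see [default_cohort_params()].
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param noise_sd_fraction,n_cross_sections measurement noise settings
#'   (defaults from `params$noise`).
#' @param jitter fractional geometric jitter per subject anatomy.
#' @return list of per-subject lists: `subject`, `network`,
#'   `resistances` (per-segment lumped), `territorial` (per-territory),
#'   `truth` (forward solution), `measurements`.
#' @export
simulate_cohort <- function(n_subjects, params = default_cohort_params(),
                            seed = 1L,
                            noise_sd_fraction = params$noise$sd_fraction,
                            n_cross_sections = params$noise$n_cross_sections,
                            jitter = 0.05) {
  withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      group <- if (stats::runif(1) < 29 / 48) "stenotic" else "non_stenotic"
      sub <- sample_subject(params, seed = NULL, id = sprintf("S%03d", i),
                            group = group)
      variants <- .sample_variants(params$variants)
      stenoses <- list()
      if (group == "stenotic") {
        r_ica <- default_cow_geometry()$radius_mm[1] * 1e-3
        stenoses[[sprintf("ICA_%s", sub$subject$ipsi_side)]] <-
          stenosis_from_degree(sub$subject$stenosis_degree_ipsi, r_ica)
        if (is.finite(sub$subject$stenosis_degree_contra)) {
          contra <- if (sub$subject$ipsi_side == "L") "R" else "L"
          stenoses[[sprintf("ICA_%s", contra)]] <-
            stenosis_from_degree(sub$subject$stenosis_degree_contra, r_ica)
        }
      }
      net <- build_synthetic_cow(variants, jitter = jitter,
                                 seed = sample.int(2^31 - 1, 1),
                                 stenoses = stenoses)
      res <- expand_territorial_resistances(net, sub$resistances)
      truth <- forward_solve(net, sub$subject, res)
      meas <- emulate_measurements(truth, noise_sd_fraction,
                                   n_cross_sections, seed = NULL)
      list(subject = sub$subject, network = net, resistances = res,
           territorial = sub$resistances, truth = truth,
           measurements = meas)
    })
  })
}
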
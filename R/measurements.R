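# Per-artery mean flow-rate container, emulating what a 4D-flow-MRI
# post-processing pipeline reports: one cycle-averaged flow per artery,
# signed for the PCoA (positive = anterior -> posterior). Missing arteries
# are simply absent rows.

#' Construct a flow measurement set
#'
#' @param df data.frame with columns `artery` (ICA, MCA1, ACA1, ACA2, BA,
#'   PCA1, PCA2, PCoA), `side` ("L", "R" or "" for the BA), `dup`
#'   (duplicate index, 1 for singleton arteries) and `flow_ml_s`.
#' @param n_cross_sections number of cross-sections averaged per artery
#'   (metadata; default 15).
#' @return An object of class `flow_measurements`.
#' @export
flow_measurements <- function(df, n_cross_sections = 15L) {
  need <- c("artery", "side", "flow_ml_s")
  if (!all(need %in% names(df)))
    stop("measurement table must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$dup)) df$dup <- 1L
  df$dup <- as.integer(df$dup)
  if (any(!is.finite(df$flow_ml_s)))
    stop("non-finite flow value in measurement table")
  if (anyDuplicated(df[c("artery", "side", "dup")]))
    stop("duplicate (artery, side, dup) rows in measurement table")
  structure(list(table = df[c("artery", "side", "dup", "flow_ml_s")],
                 n_cross_sections = as.integer(n_cross_sections)),
            class = "flow_measurements")
}

#' @export
print.flow_measurements <- function(x, ...) {
  cat(sprintf("Flow measurement set: %d arteries (%d cross-sections averaged)\n",
              nrow(x$table), x$n_cross_sections))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# all flows for (artery, side) summed over duplicates; NA when absent
.meas_flow <- function(m, artery, side = "") {
  t <- m$table
  sel <- t$artery == artery & t$side == side
  if (!any(sel)) return(NA_real_)
  sum(t$flow_ml_s[sel])
}

.meas_rows <- function(m, artery, side = "") {
  t <- m$table
  t[t$artery == artery & t$side == side, , drop = FALSE]
}

#' Read / write measurement tables as CSV
#'
#' CSV dialect: comma separated, header mandatory, `#` comment lines
#' allowed, columns `artery_label, side, dup, flow_ml_per_s,
#' n_cross_sections`.
#'
#' @param path CSV file path.
#' @return For the reader, a `flow_measurements`; the writer returns
#'   `path` invisibly.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("artery_label", "side", "flow_ml_per_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed measurement CSV, missing column(s): ",
         paste(miss, collapse = ", "))
  df$side[is.na(df$side)] <- ""
  ncs <- if ("n_cross_sections" %in% names(df)) df$n_cross_sections[1] else 15L
  flow_measurements(data.frame(artery = df$artery_label, side = df$side,
                               dup = if (is.null(df$dup)) 1L else df$dup,
                               flow_ml_s = df$flow_ml_per_s,
                               stringsAsFactors = FALSE),
                    n_cross_sections = ncs)
}

#' @param measurements a `flow_measurements` object.
#' @param header optional provenance comment lines (written prefixed `#`).
#' @rdname read_measurements
#' @export
write_measurements <- function(measurements, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(artery_label = measurements$table$artery,
                   side = measurements$table$side,
                   dup = measurements$table$dup,
                   flow_ml_per_s = measurements$table$flow_ml_s,
                   n_cross_sections = measurements$n_cross_sections)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Subject record
#'
#' Clinical covariates of one subject: group, mean arterial pressure,
#' intracranial pressure, stenosis degrees with the symptomatic side, and
#' (optionally) territorial brain volumes.
#'
#' @param id subject identifier.
#' @param group one of `"stenotic"`, `"non_stenotic"`, `"control"`.
#' @param map_value mean arterial pressure, mmHg.
#' @param icp_value intracranial pressure, mmHg (default 11.6, a healthy
#'   elderly reference value).
#' @param ipsi_side side of the symptomatic stenosis ("L"/"R"), or `NA`.
#' @param stenosis_degree_ipsi,stenosis_degree_contra NASCET percent, or
#'   `NA` when absent.
#' @param territorial_volumes optional data.frame(territory, side,
#'   volume_ml).
#' @param total_volume total brain volume, ml, or `NA`.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(id, group = c("stenotic", "non_stenotic", "control"),
                           map_value, icp_value = 11.6,
                           ipsi_side = NA_character_,
                           stenosis_degree_ipsi = NA_real_,
                           stenosis_degree_contra = NA_real_,
                           territorial_volumes = NULL,
                           total_volume = NA_real_) {
  group <- match.arg(group)
  if (!is.finite(map_value) || map_value <= icp_value)
    stop("require map_value > icp_value >= 0")
  if (icp_value < 0) stop("require icp_value >= 0")
  if (!is.null(territorial_volumes) && any(territorial_volumes$volume_ml <= 0))
    stop("territorial volumes must be positive")
  structure(list(id = id, group = group, map_value = map_value,
                 icp_value = icp_value, ipsi_side = ipsi_side,
                 stenosis_degree_ipsi = stenosis_degree_ipsi,
                 stenosis_degree_contra = stenosis_degree_contra,
                 territorial_volumes = territorial_volumes,
                 total_volume = total_volume),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s (%s): MAP %.1f mmHg, ICP %.1f mmHg", x$id, x$group,
              x$map_value, x$icp_value))
  if (!is.na(x$ipsi_side))
    cat(sprintf(", stenosis %s%% (%s)", x$stenosis_degree_ipsi, x$ipsi_side))
  cat("\n")
  invisible(x)
}
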
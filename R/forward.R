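# Forward problem: given a network, MAP/ICP and known (ground-truth)
# territorial resistances attached behind the outflow arteries, solve the
# full unsplit circle of Willis for true flows and pressures, then emulate
# 4D-flow-style measurements. This is the forward counterpart of the
# inverse estimation pipeline and supplies ground truth for
# parameter-recovery tests.

# Outflow segments (those carrying a territorial lumped element).
.outflow_segments <- function(network) {
  s <- network$segments
  sel <- s$label %in% c("MCA1", "ACA2", "PCA2")
  data.frame(segment_id = s$id[sel],
             territory = sub("1|2", "", s$label[sel]),
             side = s$side[sel], dup = s$dup[sel],
             terminal = s$dist[sel], stringsAsFactors = FALSE)
}

#' Solve the full network forward with known territorial resistances
#'
#' All root nodes are held at the subject's MAP (behind any stenosis
#' element on a root-feeding ICA, resolved by damped iteration since the
#' stenosis law is quadratic in flow), and every territorial lumped
#' resistance drains to a single venous/parenchymal sink node held at ICP.
#' Returns the exact nodal pressures and per-segment flows.
#'
#' @param network a validated, unsplit `cow_network`.
#' @param subject a [subject_record()] (supplies MAP and ICP).
#' @param resistances named numeric vector of territorial lumped
#'   resistances in mmHg s/ml, keyed by outflow segment id (`"MCA1_L"`,
#'   `"ACA2_R_d2"`, ...); all strictly positive.
#' @param fluid a [fluid_properties()] object.
#' @param tol relative residual for the stenosis iteration.
#' @return An object of class `forward_truth`: nodal pressures (mmHg),
#'   segment flows (ml/s), terminal (territory) flows, the inputs, and the
#'   achieved conservation residual.
#' @export
forward_solve <- function(network, subject, resistances,
                          fluid = fluid_properties(), tol = 1e-12) {
  outs <- .outflow_segments(network)
  missing_r <- setdiff(outs$segment_id, names(resistances))
  if (length(missing_r))
    stop("no territorial resistance supplied for: ",
         paste(missing_r, collapse = ", "))
  if (any(resistances <= 0)) stop("territorial resistances must be > 0")

  segs <- network$segments
  resist <- data.frame(id = segs$id, prox = segs$prox, dist = segs$dist,
                       R = segment_resistance(segs, fluid),
                       stringsAsFactors = FALSE)
  # territorial lumped elements: terminal -> SINK
  lump <- data.frame(id = paste0("LUMP_", outs$segment_id),
                     prox = outs$terminal, dist = "SINK",
                     R = unname(resistances[outs$segment_id]),
                     stringsAsFactors = FALSE)
  resist <- rbind(resist, lump)

  roots <- intersect(.cow_root_nodes, network$nodes$id)
  fixed <- stats::setNames(rep(subject$map_value, length(roots)), roots)
  fixed["SINK"] <- subject$icp_value

  # stenosis elements sit between the MAP source and the ICA root
  sten_ids <- names(network$stenoses)
  sten_rows <- NULL
  if (length(sten_ids)) {
    side <- sub("ICA_", "", sten_ids)
    root <- sprintf("ICA_%s_root", side)
    src <- sprintf("SRC_%s", side)
    sten_rows <- data.frame(id = paste0("STEN_", sten_ids), prox = src,
                            dist = root, R = NA_real_,
                            stringsAsFactors = FALSE)
    fixed <- fixed[setdiff(names(fixed), root)]
    fixed[src] <- subject$map_value
  }

  solve_once <- function(sten_R) {
    r <- resist
    if (!is.null(sten_rows)) {
      sr <- sten_rows; sr$R <- sten_R
      r <- rbind(r, sr)
    }
    .solve_nodal(r, fixed = fixed)
  }

  if (is.null(sten_rows)) {
    sol <- solve_once(NULL)
  } else {
    sten_R <- vapply(sten_ids, function(id)
      .stenosis_effective_resistance(network$stenoses[[id]], 0, fluid),
      numeric(1))
    sol <- NULL
    for (it in 1:200) {
      sol <- solve_once(sten_R)
      q <- abs(sol$flows[paste0("STEN_", sten_ids)])
      new_R <- vapply(seq_along(sten_ids), function(i)
        .stenosis_effective_resistance(network$stenoses[[sten_ids[i]]],
                                       q[i], fluid), numeric(1))
      upd <- 0.5 * sten_R + 0.5 * new_R
      if (max(abs(upd - sten_R) / pmax(sten_R, 1e-12)) < tol) {
        sten_R <- upd
        sol <- solve_once(sten_R)
        break
      }
      sten_R <- upd
    }
  }

  seg_flows <- sol$flows[segs$id]
  terminal_flows <- stats::setNames(sol$flows[paste0("LUMP_", outs$segment_id)],
                                    outs$segment_id)

  # conservation residual over all non-pinned nodes
  rtab <- sol$resist
  bal <- stats::setNames(numeric(length(sol$pressures)), names(sol$pressures))
  for (i in seq_len(nrow(rtab))) {
    bal[rtab$prox[i]] <- bal[rtab$prox[i]] - sol$flows[i]
    bal[rtab$dist[i]] <- bal[rtab$dist[i]] + sol$flows[i]
  }
  free <- setdiff(names(bal), names(sol$fixed))
  residual <- if (length(free)) max(abs(bal[free])) else 0

  structure(list(
    network = network, subject = subject, resistances = resistances,
    nodal_pressures = sol$pressures, segment_flows = seg_flows,
    terminal_flows = terminal_flows, outflows = outs,
    max_conservation_residual = residual, fluid = fluid
  ), class = "forward_truth")
}

#' @export
print.forward_truth <- function(x, ...) {
  cat(sprintf("Forward solution: MAP %.1f mmHg, total inflow %.3f ml/s\n",
              x$subject$map_value, sum(x$terminal_flows)))
  invisible(x)
}

#' Ground-truth downstream resistance seen from the cut planes
#'
#' The inverse pipeline reads perfusion pressure at a cut plane 5 mm from
#' each outflow bifurcation, so the resistance it estimates is the lumped
#' territorial element plus the Poiseuille resistance of everything distal
#' to the plane. With a PCoA present the PCA plane sits on the PCA2 (5 mm
#' from the PCoA junction); with no PCoA it sits on the PCA path 5 mm from
#' the BA bifurcation, so the full PCA2 is also downstream.
#'
#' @param network a `cow_network`.
#' @param resistances territorial lumped resistances as in
#'   [forward_solve()].
#' @param cut_distance cut-plane distance in m (default 5 mm); must be
#'   less than the carrying segment's length.
#' @param fluid a [fluid_properties()] object.
#' @return data.frame(territory, side, dup, segment_id, cut_segment,
#'   r_downstream) in mmHg s/ml.
#' @export
ground_truth_downstream_resistance <- function(network, resistances,
                                               cut_distance = 0.005,
                                               fluid = fluid_properties()) {
  plan <- .cut_plan(network)
  segs <- network$segments
  out <- plan
  out$r_downstream <- NA_real_
  for (i in seq_len(nrow(plan))) {
    ci <- match(plan$cut_segment[i], segs$id)
    if (cut_distance >= segs$length_m[ci])
      stop(sprintf("cut distance %.4g m >= length of segment %s",
                   cut_distance, plan$cut_segment[i]))
    rem <- poiseuille_resistance(segs$length_m[ci], segs$r_prox_m[ci],
                                 segs$r_dist_m[ci], fluid,
                                 from = cut_distance, to = segs$length_m[ci])
    extra <- 0
    if (plan$cut_segment[i] != plan$segment_id[i]) {
      # PCA plane on the PCA1: the whole PCA2 is downstream of the plane
      si <- match(plan$segment_id[i], segs$id)
      extra <- poiseuille_resistance(segs$length_m[si], segs$r_prox_m[si],
                                     segs$r_dist_m[si], fluid)
    }
    out$r_downstream[i] <- rem + extra +
      unname(resistances[[plan$segment_id[i]]])
  }
  out
}

# Cut-plane plan: which segment carries each territory's cut plane.
.cut_plan <- function(network) {
  outs <- .outflow_segments(network)
  outs$cut_segment <- outs$segment_id
  has_pcoa <- function(s) sprintf("PCoA_%s", s) %in% network$segments$id
  for (i in which(outs$territory == "PCA")) {
    if (!has_pcoa(outs$side[i]))
      outs$cut_segment[i] <- sprintf("PCA1_%s", outs$side[i])
  }
  outs
}

#' Emulate 4D-flow-style measurements from a forward solution
#'
#' Each measured artery reports the mean of `n_cross_sections` independent
#' normal draws centred on its true flow with SD
#' `noise_sd_fraction * |true flow|`, mimicking cross-section averaging of
#' a velocity field. Zero noise returns the true flows exactly.
#'
#' @param truth a `forward_truth` from [forward_solve()].
#' @param noise_sd_fraction per-cross-section relative noise SD (>= 0).
#' @param n_cross_sections number of averaged cross-sections (>= 1).
#' @param seed integer seed (reproducible measurement set).
#' @return A [flow_measurements()] set covering ICA, MCA1, ACA1, ACA2, BA,
#'   PCA1, PCA2 per side and the signed PCoA flows.
#' @export
emulate_measurements <- function(truth, noise_sd_fraction = 0.05,
                                 n_cross_sections = 15L, seed = NULL) {
  stopifnot(noise_sd_fraction >= 0, n_cross_sections >= 1)
  s <- truth$network$segments
  meas_labels <- c("ICA", "MCA1", "ACA1", "ACA2", "BA", "PCA1", "PCA2", "PCoA")
  sel <- s$label %in% meas_labels
  df <- data.frame(artery = s$label[sel], side = s$side[sel], dup = s$dup[sel],
                   flow_ml_s = unname(truth$segment_flows[s$id[sel]]),
                   stringsAsFactors = FALSE)
  noisy <- function() {
    df$flow_ml_s <- vapply(df$flow_ml_s, function(q) {
      if (noise_sd_fraction == 0) return(q)
      mean(stats::rnorm(n_cross_sections, q, noise_sd_fraction * abs(q)))
    }, numeric(1))
    df
  }
  df <- if (is.null(seed)) noisy() else withr::with_seed(seed, noisy())
  flow_measurements(df, n_cross_sections = n_cross_sections)
}
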
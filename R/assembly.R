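# Boundary-condition assembly: turns a measurement set and subject record
# into balanced anterior/posterior domain models following the
# measurement-driven rules: ICA and BA boundaries are inlets; MCA1, ACA2
# and PCA2 boundaries are outlets; a PCoA boundary is an outlet or inlet
# depending on its flow direction; inlet flows are sums of the measured
# downstream flows so that mass is conserved exactly; the ACA2 outlets are
# rescaled so the ACA1 flows are honoured; MAP is the reference pressure
# at the contralateral ICA (stenotic subjects, minus the stenosis drop
# when the contralateral stenosis is >= 50%), at the largest-inflow ICA
# (non-stenotic subjects) and at the BA.

#' Resolve PCoA boundary roles from the measured flow sign
#'
#' Positive PCoA flow (anterior -> posterior) makes the PCoA an outlet of
#' the anterior model and an inlet of the posterior model; negative flow
#' the opposite; zero flow an outlet of both with zero flow; a missing
#' PCoA contributes no boundary.
#'
#' @param measurements a [flow_measurements()] set.
#' @return data.frame(side, present, flow_ml_s, anterior_role,
#'   posterior_role).
#' @export
resolve_pcoa_roles <- function(measurements) {
  out <- lapply(c("L", "R"), function(s) {
    q <- .meas_flow(measurements, "PCoA", s)
    if (is.na(q)) {
      data.frame(side = s, present = FALSE, flow_ml_s = NA_real_,
                 anterior_role = NA_character_, posterior_role = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(side = s, present = TRUE, flow_ml_s = q,
                 anterior_role = if (q >= 0) "outlet" else "inlet",
                 posterior_role = if (q > 0) "inlet" else "outlet",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Anterior ICA inlet flows from measured branch flows
#'
#' Each ICA inlet is set to the sum of its side's MCA1, ACA1 and (signed)
#' PCoA flows, so the inlet carries exactly what the measured branches
#' drain plus what leaves through the PCoA.
#'
#' @param measurements a [flow_measurements()] set.
#' @return Named numeric `c(L = ..., R = ...)` in ml/s.
#' @export
anterior_inlet_flows <- function(measurements) {
  res <- vapply(c("L", "R"), function(s) {
    mca <- .meas_flow(measurements, "MCA1", s)
    aca <- .meas_flow(measurements, "ACA1", s)
    if (is.na(mca) || is.na(aca))
      stop("missing MCA1 or ACA1 measurement on side ", s)
    pcoa <- .meas_flow(measurements, "PCoA", s)
    mca + aca + if (is.na(pcoa)) 0 else pcoa
  }, numeric(1))
  stats::setNames(res, c("L", "R"))
}

#' Posterior BA inlet flow from measured branch flows
#'
#' The BA inlet is the signed sum that balances the posterior domain:
#' all PCA2 outflows minus the PCoA inflow received from the anterior
#' circulation (plus any PCoA outflow back to it).
#'
#' @param measurements a [flow_measurements()] set.
#' @return BA inlet flow in ml/s (error if non-positive: nonphysical
#'   measurement set).
#' @export
posterior_inlet_flow <- function(measurements) {
  pca <- sum(.meas_flow(measurements, "PCA2", "L"),
             .meas_flow(measurements, "PCA2", "R"), na.rm = TRUE)
  pcoa <- sum(.meas_flow(measurements, "PCoA", "L"),
              .meas_flow(measurements, "PCoA", "R"), na.rm = TRUE)
  q <- pca - pcoa
  if (q <= 0) {
    warning("computed BA inflow is non-positive (", signif(q, 4),
            " ml/s): nonphysical measurement set")
    stop("cannot assemble posterior model with non-positive BA inflow")
  }
  q
}

#' Rescale ACA2 outlet flows to honour the measured ACA1 flows
#'
#' Multiplies the measured ACA2 flows by the common factor
#' `s = (Q_ACA1_L + Q_ACA1_R) / sum(Q_ACA2)` so that the total ACA2
#' outflow equals the total measured ACA1 inflow. Duplicated ACA2
#' branches keep their measured proportions (zeros stay zero). With
#' `per_side = TRUE` (used when no ACoA connects the two sides) the factor
#' is computed per side so each disconnected half balances on its own.
#'
#' @param measurements a [flow_measurements()] set.
#' @param per_side logical; rescale per side instead of globally.
#' @return data.frame(side, dup, measured, adjusted, factor).
#' @export
adjust_aca2_outlets <- function(measurements, per_side = FALSE) {
  rows <- rbind(.meas_rows(measurements, "ACA2", "L"),
                .meas_rows(measurements, "ACA2", "R"))
  if (!nrow(rows)) stop("no ACA2 measurements to adjust")
  aca1 <- c(L = .meas_flow(measurements, "ACA1", "L"),
            R = .meas_flow(measurements, "ACA1", "R"))
  if (per_side) {
    fac <- vapply(rows$side, function(s) {
      tot <- sum(rows$flow_ml_s[rows$side == s])
      if (!is.finite(aca1[[s]]) || tot <= 0)
        stop("cannot adjust ACA2 on side ", s, ": non-positive total")
      aca1[[s]] / tot
    }, numeric(1))
  } else {
    tot <- sum(rows$flow_ml_s)
    if (tot <= 0) stop("cannot adjust ACA2: non-positive total ACA2 flow")
    fac <- rep(sum(aca1, na.rm = TRUE) / tot, nrow(rows))
  }
  data.frame(side = rows$side, dup = rows$dup, measured = rows$flow_ml_s,
             adjusted = rows$flow_ml_s * fac, factor = unname(fac),
             stringsAsFactors = FALSE)
}

#' Reference-pressure placement
#'
#' Posterior models take MAP at the BA root. Anterior models of stenotic
#' subjects take the contralateral ICA root at MAP, reduced by the
#' computed stenosis pressure drop when the contralateral stenosis is
#' >= 50%; non-stenotic subjects take the ICA root with the larger
#' measured inlet flow at MAP (ties broken toward the left).
#'
#' @param subject a [subject_record()].
#' @param part `"anterior"` or `"posterior"`.
#' @param inlet_flows named `c(L=, R=)` inlet flows from
#'   [anterior_inlet_flows()] (anterior only).
#' @param stenosis_drop pressure drop (mmHg) across the contralateral
#'   stenosis at its inlet flow; only subtracted when the contralateral
#'   degree is >= 50.
#' @return list(node, pressure_mmhg, side, note).
#' @export
assign_reference_pressure <- function(subject, part, inlet_flows = NULL,
                                      stenosis_drop = 0) {
  if (!is.finite(subject$map_value)) stop("subject has no MAP")
  if (part == "posterior")
    return(list(node = "BA_root", pressure_mmhg = subject$map_value,
                side = "", note = "MAP at BA"))
  stopifnot(part == "anterior")
  if (identical(subject$group, "stenotic") && !is.na(subject$ipsi_side)) {
    contra <- if (subject$ipsi_side == "L") "R" else "L"
    drop <- 0
    note <- sprintf("MAP at contralateral ICA (%s)", contra)
    if (is.finite(subject$stenosis_degree_contra) &&
        subject$stenosis_degree_contra >= 50) {
      drop <- stenosis_drop
      note <- sprintf("%s minus %.2f mmHg stenosis drop", note, drop)
    }
    list(node = sprintf("ICA_%s_root", contra),
         pressure_mmhg = subject$map_value - drop, side = contra, note = note)
  } else {
    if (is.null(inlet_flows)) stop("inlet flows required for anterior reference")
    side <- if (inlet_flows[["R"]] > inlet_flows[["L"]]) "R" else "L"
    list(node = sprintf("ICA_%s_root", side),
         pressure_mmhg = subject$map_value, side = side,
         note = sprintf("MAP at largest-inflow ICA (%s)", side))
  }
}

# Outflow boundary node of a segment terminal (terminal node id).
.terminal_node <- function(network, segment_id) {
  s <- network$segments
  s$dist[match(segment_id, s$id)]
}

#' Assemble anterior and posterior domain models
#'
#' Applies the full boundary-condition rule set to a network split and a
#' measurement set, producing one balanced `domain_model` per part
#' (sum of inlets equals sum of outlets exactly, by construction) with the
#' reference pressure placed per [assign_reference_pressure()]. When the
#' anterior sub-network is internally disconnected (no ACoA), the ACA2
#' adjustment and the MAP reference are applied per connected component,
#' each component's ICA root receiving MAP minus its own stenosis drop
#' where applicable. Every rule fired is recorded in the `log`.
#'
#' @param network a validated `cow_network` (full, unsplit).
#' @param measurements a [flow_measurements()] set.
#' @param subject a [subject_record()].
#' @param fluid a [fluid_properties()] object.
#' @return list(anterior, posterior, inlet_flows, ba_inflow, aca2, log);
#'   each domain is a list(part, network, boundaries, reference) of class
#'   `domain_model`.
#' @export
assemble_domains <- function(network, measurements, subject,
                             fluid = fluid_properties()) {
  parts <- split_anterior_posterior(network)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  pcoa <- resolve_pcoa_roles(measurements)
  ica_in <- anterior_inlet_flows(measurements)
  say("ICA inlet sums: L = %.4f, R = %.4f ml/s", ica_in[["L"]], ica_in[["R"]])

  ant_net <- parts$anterior
  comps <- .components(ant_net$segments)
  per_side <- length(comps) > 1L
  aca2 <- adjust_aca2_outlets(measurements, per_side = per_side)
  say("ACA2 adjustment factor(s): %s%s",
      paste(signif(unique(aca2$factor), 6), collapse = ", "),
      if (per_side) " (per side: anterior domain disconnected)" else "")

  # ---- anterior boundaries ----
  bounds <- list()
  bnd <- function(node, role, flow, artery)
    bounds[[length(bounds) + 1L]] <<- data.frame(
      node = node, role = role, flow_ml_s = flow, artery = artery,
      stringsAsFactors = FALSE)
  for (s in c("L", "R")) {
    root <- sprintf("ICA_%s_root", s)
    if (!root %in% ant_net$nodes$id) next
    if (ica_in[[s]] >= 0) bnd(root, "inlet", ica_in[[s]], sprintf("ICA_%s", s))
    else bnd(root, "outlet", -ica_in[[s]], sprintf("ICA_%s", s))
    for (i in seq_len(nrow(.meas_rows(measurements, "MCA1", s)))) {
      row <- .meas_rows(measurements, "MCA1", s)[i, ]
      seg_id <- sprintf("MCA1_%s%s", s, if (row$dup > 1) sprintf("_d%d", row$dup) else "")
      bnd(.terminal_node(ant_net, seg_id), "outlet", row$flow_ml_s, seg_id)
    }
    asel <- aca2[aca2$side == s, , drop = FALSE]
    for (i in seq_len(nrow(asel))) {
      seg_id <- sprintf("ACA2_%s%s", s, if (asel$dup[i] > 1) sprintf("_d%d", asel$dup[i]) else "")
      bnd(.terminal_node(ant_net, seg_id), "outlet", asel$adjusted[i], seg_id)
    }
    prow <- pcoa[pcoa$side == s, ]
    if (isTRUE(prow$present)) {
      cut_node <- sprintf("PCoA_%s_cut", s)
      if (cut_node %in% ant_net$nodes$id) {
        bnd(cut_node, prow$anterior_role, abs(prow$flow_ml_s),
            sprintf("PCoA_%s", s))
        say("PCoA_%s: %.4f ml/s -> anterior %s / posterior %s", s,
            prow$flow_ml_s, prow$anterior_role, prow$posterior_role)
      }
    }
  }
  ant_bounds <- do.call(rbind, bounds)

  # ---- anterior reference(s), one per connected component ----
  refs <- list()
  stent <- function(side) {
    seg_id <- sprintf("ICA_%s", side)
    st <- network$stenoses[[seg_id]]
    if (is.null(st)) return(0)
    stenosis_pressure_drop(st, max(ica_in[[side]], 0), fluid)
  }
  main_drop <- 0
  if (identical(subject$group, "stenotic") && !is.na(subject$ipsi_side)) {
    contra <- if (subject$ipsi_side == "L") "R" else "L"
    if (is.finite(subject$stenosis_degree_contra) &&
        subject$stenosis_degree_contra >= 50)
      main_drop <- stent(contra)
  }
  main_ref <- assign_reference_pressure(subject, "anterior", ica_in, main_drop)
  say("anterior reference: %s", main_ref$note)
  for (cmp in comps) {
    roots_in <- intersect(c("ICA_L_root", "ICA_R_root"), cmp)
    if (main_ref$node %in% cmp) {
      refs[[length(refs) + 1L]] <- data.frame(node = main_ref$node,
                                              pressure_mmhg = main_ref$pressure_mmhg)
    } else if (length(roots_in)) {
      side <- sub("ICA_(.)_root", "\\1", roots_in[1])
      drop <- 0
      deg <- if (!is.na(subject$ipsi_side) && side == subject$ipsi_side)
        subject$stenosis_degree_ipsi else subject$stenosis_degree_contra
      if (is.finite(deg) && deg >= 50) drop <- stent(side)
      refs[[length(refs) + 1L]] <- data.frame(
        node = roots_in[1], pressure_mmhg = subject$map_value - drop)
      say("disconnected anterior component: MAP%s at %s",
          if (drop > 0) sprintf(" - %.2f mmHg", drop) else "", roots_in[1])
    }
  }
  ant_ref <- do.call(rbind, refs)

  anterior <- structure(list(part = "anterior", network = ant_net,
                             boundaries = ant_bounds, reference = ant_ref),
                        class = "domain_model")

  # ---- posterior ----
  post_net <- parts$posterior
  ba_in <- posterior_inlet_flow(measurements)
  say("BA inlet sum: %.4f ml/s", ba_in)
  bounds <- list()
  bnd(sprintf("BA_root"), "inlet", ba_in, "BA")
  for (s in c("L", "R")) {
    rows <- .meas_rows(measurements, "PCA2", s)
    for (i in seq_len(nrow(rows))) {
      seg_id <- sprintf("PCA2_%s%s", s, if (rows$dup[i] > 1) sprintf("_d%d", rows$dup[i]) else "")
      if (seg_id %in% post_net$segments$id)
        bnd(.terminal_node(post_net, seg_id), "outlet", rows$flow_ml_s[i], seg_id)
    }
    prow <- pcoa[pcoa$side == s, ]
    if (isTRUE(prow$present)) {
      cut_node <- sprintf("PCoA_%s_cut", s)
      if (cut_node %in% post_net$nodes$id)
        bnd(cut_node, prow$posterior_role, abs(prow$flow_ml_s),
            sprintf("PCoA_%s", s))
    }
  }
  post_ref <- assign_reference_pressure(subject, "posterior")
  say("posterior reference: %s", post_ref$note)
  posterior <- structure(list(part = "posterior", network = post_net,
                              boundaries = do.call(rbind, bounds),
                              reference = data.frame(node = post_ref$node,
                                                     pressure_mmhg = post_ref$pressure_mmhg)),
                         class = "domain_model")

  list(anterior = anterior, posterior = posterior, inlet_flows = ica_in,
       ba_inflow = ba_in, aca2 = aca2, pcoa = pcoa, log = log)
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf("%s domain: %d segments, %d boundaries, reference %s\n",
              x$part, nrow(x$network$segments), nrow(x$boundaries),
              paste(sprintf("%s @ %.2f mmHg", x$reference$node,
                            x$reference$pressure_mmhg), collapse = ", ")))
  invisible(x)
}
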
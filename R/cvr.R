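# Territorial and total cerebrovascular resistance.
#
#   R_terr = (P_terr - ICP) / Q_terr      (per outflow artery)
#   tCVR   = (MAP - ICP) / Q_total        (Q_total = ICA_L + ICA_R + BA)
#
# P_terr is the perfusion pressure read at a cut plane 5 mm from the
# bifurcation of each outflow artery; ICP is the parenchymal
# counter-pressure (default 11.6 mmHg). Duplicated arteries are combined
# as parallel resistances.

#' Territorial CVR from perfusion pressure and flow
#'
#' @param p_terr perfusion pressure at the territory's cut plane, mmHg.
#' @param icp intracranial pressure, mmHg.
#' @param q_terr flow into the territory, ml/s.
#' @return `(p_terr - icp) / q_terr` in mmHg s/ml; `NA` (with a
#'   `"undefined"` attribute-free flag via `NA`) when `q_terr <= 0`, the
#'   excluded-territory case.
#' @export
territorial_cvr <- function(p_terr, icp, q_terr) {
  ifelse(q_terr > 0, (p_terr - icp) / q_terr, NA_real_)
}

#' Total CVR
#'
#' @param map_value mean arterial pressure, mmHg.
#' @param icp intracranial pressure, mmHg.
#' @param q_total total cerebral inflow (sum of both ICA and the BA flow
#'   rates), ml/s; must be positive.
#' @return `(MAP - ICP) / Q_total` in mmHg s/ml.
#' @export
total_cvr <- function(map_value, icp, q_total) {
  if (any(q_total <= 0)) stop("`q_total` must be > 0")
  (map_value - icp) / q_total
}

#' Parallel combination of resistances
#'
#' @param resistances non-empty vector of positive resistances.
#' @return Reciprocal of the summed reciprocals; at most `min(resistances)`.
#' @export
parallel_resistance <- function(resistances) {
  if (!length(resistances)) stop("empty resistance list")
  if (any(resistances <= 0)) stop("resistances must be > 0")
  1 / sum(1 / resistances)
}

#' Vascular conductance
#'
#' @param resistance resistance in mmHg s/ml; `NA` (undefined) propagates.
#' @return `1 / resistance` in ml/(mmHg s).
#' @export
conductance <- function(resistance) {
  ok <- !is.na(resistance)
  if (any(resistance[ok] <= 0)) stop("resistance must be > 0")
  out <- rep(NA_real_, length(resistance))
  out[ok] <- 1 / resistance[ok]
  out
}

#' Classify hemodynamic disturbance from ICA flow
#'
#' @param ica_flow_ml_min ICA flow rate in ml/min (>= 0).
#' @return `TRUE` iff the flow is strictly below 160 ml/min.
#' @export
classify_hemodynamic_disturbance <- function(ica_flow_ml_min) {
  if (any(ica_flow_ml_min < 0)) stop("flow must be >= 0")
  ica_flow_ml_min < 160
}

#' Estimate territorial and total CVR for one subject
#'
#' The full inverse pipeline: validate and split the network, assemble
#' balanced anterior/posterior domain models from the measured flows
#' (signed PCoA roles, inlet-flow summation, ACA2 adjustment, MAP
#' reference with stenosis correction), solve both domains by nodal
#' analysis, read perfusion pressures at cut planes 5 mm from the outflow
#' bifurcations, and apply the Ohm's-law relations. Duplicated arteries
#' are estimated per branch and combined as parallel resistances;
#' territories with non-positive flow are flagged undefined and excluded,
#' not silently valued.
#'
#' @param network a validated, unsplit `cow_network`.
#' @param measurements a [flow_measurements()] set.
#' @param subject a [subject_record()].
#' @param fluid a [fluid_properties()] object.
#' @param icp intracranial pressure override, mmHg (default: the
#'   subject's, itself defaulting to 11.6).
#' @param cut_distance cut-plane distance in m (default 5 mm).
#' @return An object of class `cvr_fit` with components `territorial`
#'   (per territory x hemisphere: perfusion pressure, flow, resistance,
#'   conductance, flag), `branches` (per duplicate branch), `global`
#'   (tCVR, total inflow, MAP, ICP), the domain solutions and the
#'   assembly log. Methods: `print`, `summary`, `coef`, `plot`,
#'   `residuals`, `simulate`.
#' @examples
#' net <- build_synthetic_cow()
#' sub <- subject_record("S1", "non_stenotic", map_value = 93)
#' truth <- forward_solve(net, sub, expand_territorial_resistances(net,
#'   c(MCA_L = 33.8, MCA_R = 33.8, ACA_L = 59, ACA_R = 59,
#'     PCA_L = 77.8, PCA_R = 77.8)))
#' fit <- cvr_estimate(net, emulate_measurements(truth, 0), sub)
#' coef(fit)
#' @export
cvr_estimate <- function(network, measurements, subject,
                         fluid = fluid_properties(), icp = NULL,
                         cut_distance = 0.005) {
  v <- validate_network(network)
  if (length(v)) stop("invalid network: ", paste(v, collapse = "; "))
  if (is.null(icp)) icp <- subject$icp_value
  if (!is.finite(icp)) icp <- 11.6

  asm <- assemble_domains(network, measurements, subject, fluid)
  sol_ant <- solve_domain(asm$anterior, fluid)
  sol_post <- solve_domain(asm$posterior, fluid)

  plan <- .cut_plan(network)
  plan$solution_part <- ifelse(plan$territory == "PCA", "posterior", "anterior")
  branches <- plan
  branches$p_terr <- NA_real_
  branches$q_terr <- NA_real_
  for (i in seq_len(nrow(branches))) {
    sol <- if (branches$solution_part[i] == "anterior") sol_ant else sol_post
    branches$p_terr[i] <- cut_plane_pressure(sol, branches$cut_segment[i],
                                             cut_distance, fluid)
    branches$q_terr[i] <- sol$segment_flows[[branches$cut_segment[i]]]
  }
  branches$cvr <- territorial_cvr(branches$p_terr, icp, branches$q_terr)
  # excluded territories: non-positive flow, or perfusion pressure at or
  # below the counter-pressure (non-positive resistance is nonphysical)
  branches$flag <- ifelse(is.na(branches$cvr) | branches$cvr <= 0,
                          "undefined", "ok")
  branches$cvr[branches$flag == "undefined"] <- NA_real_

  # combine duplicates per territory x hemisphere by parallel resistance
  keys <- unique(branches[c("territory", "side")])
  terr <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- branches$territory == keys$territory[i] &
      branches$side == keys$side[i]
    b <- branches[sel, , drop = FALSE]
    ok <- b$flag == "ok"
    r <- if (any(ok)) parallel_resistance(b$cvr[ok]) else NA_real_
    data.frame(territory = keys$territory[i], side = keys$side[i],
               n_branches = nrow(b),
               p_terr_mmHg = stats::weighted.mean(b$p_terr, pmax(b$q_terr, 0)),
               q_terr_ml_s = sum(b$q_terr),
               cvr_mmHg_s_ml = r,
               conductance_ml_mmHg_s = if (is.na(r)) NA_real_ else 1 / r,
               flag = if (all(ok)) "ok" else if (any(ok)) "partial" else "undefined",
               stringsAsFactors = FALSE)
  }))

  q_total <- sum(asm$inlet_flows) + asm$ba_inflow
  glob <- list(tcvr = total_cvr(subject$map_value, icp, q_total),
               q_total = q_total, map_value = subject$map_value,
               icp_value = icp)

  structure(list(
    territorial = terr[order(terr$territory, terr$side), ],
    branches = branches,
    global = glob,
    solutions = list(anterior = sol_ant, posterior = sol_post),
    assembly = asm,
    subject = subject, network = network, measurements = measurements,
    fluid = fluid, cut_distance = cut_distance
  ), class = "cvr_fit")
}

#' @export
print.cvr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Territorial CVR estimate, subject %s (%s)\n",
              x$subject$id, x$subject$group))
  t <- x$territorial
  cat(sprintf("  %s %s: %s mmHg s/ml (P %s mmHg, Q %s ml/s)%s\n",
              t$territory, t$side, signif(t$cvr_mmHg_s_ml, digits),
              signif(t$p_terr_mmHg, digits), signif(t$q_terr_ml_s, digits),
              ifelse(t$flag == "ok", "", paste0(" [", t$flag, "]"))),
      sep = "")
  cat(sprintf("  tCVR: %s mmHg s/ml (MAP %.1f, ICP %.1f, inflow %.3f ml/s)\n",
              signif(x$global$tcvr, digits), x$global$map_value,
              x$global$icp_value, x$global$q_total))
  invisible(x)
}

#' @export
coef.cvr_fit <- function(object, ...) {
  t <- object$territorial
  c(stats::setNames(t$cvr_mmHg_s_ml, sprintf("%s_%s", t$territory, t$side)),
    tCVR = object$global$tcvr)
}

#' @export
residuals.cvr_fit <- function(object, ...) {
  c(anterior = object$solutions$anterior$max_conservation_residual,
    posterior = object$solutions$posterior$max_conservation_residual)
}

#' @export
summary.cvr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cvr_fit")
}

#' @export
print.summary.cvr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nConservation residuals (ml/s):\n")
  print(residuals(x$fit))
  cat("\nAssembly rules fired:\n")
  cat(paste0("  ", x$fit$assembly$log, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
plot.cvr_fit <- function(x, ...) {
  t <- x$territorial
  h <- matrix(t$cvr_mmHg_s_ml, nrow = 2,
              dimnames = list(unique(t$side), unique(t$territory)))
  graphics::barplot(h, beside = TRUE, legend.text = rownames(h),
                    ylab = "CVR (mmHg s/ml)",
                    main = sprintf("Territorial CVR, subject %s", x$subject$id),
                    ...)
  invisible(x)
}

#' Simulate measurement sets from a fitted CVR model
#'
#' Converts the fitted cut-plane resistances back to lumped territorial
#' elements (subtracting the known Poiseuille remainders), runs the
#' forward model at the subject's MAP/ICP and emulates noisy measurement
#' sets. Closing the loop: at zero noise the simulated measurements
#' reproduce the fitted flows.
#'
#' @param object a `cvr_fit`.
#' @param nsim number of measurement sets.
#' @param seed integer seed.
#' @param noise_sd_fraction,n_cross_sections see [emulate_measurements()].
#' @param ... unused.
#' @return list of [flow_measurements()] sets (length `nsim`).
#' @export
simulate.cvr_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd_fraction = 0.05,
                             n_cross_sections = 15L, ...) {
  zero_r <- ground_truth_downstream_resistance(
    object$network,
    stats::setNames(rep(1e-12, nrow(object$branches)), object$branches$segment_id),
    object$cut_distance, object$fluid)
  remainder <- stats::setNames(zero_r$r_downstream - 1e-12, zero_r$segment_id)
  lumped <- stats::setNames(object$branches$cvr - remainder[object$branches$segment_id],
                            object$branches$segment_id)
  if (any(is.na(lumped) | lumped <= 0))
    stop("cannot simulate: undefined or non-positive lumped resistance")
  truth <- forward_solve(object$network, object$subject, lumped, object$fluid)
  sim <- function() lapply(seq_len(nsim), function(i)
    emulate_measurements(truth, noise_sd_fraction, n_cross_sections))
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}
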
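# Reduced-order steady laminar solver: Kirchhoff nodal analysis with
# Hagen-Poiseuille constitutive laws on every segment. This replaces a 3D
# finite-element Navier-Stokes solve for the cycle-averaged quantities of
# interest; junction and inertial losses are neglected (see the methods
# vignette for the fidelity discussion).

# Core linear solve.
#   resist : data.frame(id, prox, dist, R) with R in mmHg.s/ml
#   injections : named numeric, ml/s, positive = into the network
#   fixed : named numeric, mmHg, pressures pinned at these nodes
# Every connected component must contain at least one fixed node.
.solve_nodal <- function(resist, injections = numeric(0),
                         fixed = numeric(0)) {
  nodes <- unique(c(resist$prox, resist$dist))
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  if (!all(names(fixed) %in% nodes))
    stop("fixed-pressure node(s) not in network: ",
         paste(setdiff(names(fixed), nodes), collapse = ", "))
  comps <- .components(resist, nodes)
  for (cmp in comps) {
    if (!any(names(fixed) %in% cmp))
      stop("singular system: component {", paste(cmp, collapse = ", "),
           "} has no pressure reference")
  }
  g <- 1 / resist$R
  L <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(resist))) {
    a <- idx[[resist$prox[i]]]; b <- idx[[resist$dist[i]]]
    L[a, a] <- L[a, a] + g[i]; L[b, b] <- L[b, b] + g[i]
    L[a, b] <- L[a, b] - g[i]; L[b, a] <- L[b, a] - g[i]
  }
  q <- stats::setNames(numeric(n), nodes)
  if (length(injections)) {
    if (!all(names(injections) %in% nodes))
      stop("boundary flow at unknown node: ",
           paste(setdiff(names(injections), nodes), collapse = ", "))
    q[names(injections)] <- q[names(injections)] + injections
  }
  p <- stats::setNames(numeric(n), nodes)
  fixed_ids <- names(fixed)
  free_ids <- setdiff(nodes, fixed_ids)
  p[fixed_ids] <- fixed
  if (length(free_ids)) {
    A <- L[free_ids, free_ids, drop = FALSE]
    rhs <- q[free_ids]
    if (length(fixed_ids))
      rhs <- rhs - L[free_ids, fixed_ids, drop = FALSE] %*% fixed
    p[free_ids] <- drop(solve(A, rhs))
  }
  flows <- stats::setNames(g * (p[resist$prox] - p[resist$dist]), resist$id)
  list(pressures = p, flows = flows, resist = resist, injections = q,
       fixed = fixed)
}

#' Solve a domain model for nodal pressures and segment flows
#'
#' Linear nodal analysis on an assembled anterior or posterior domain:
#' conservation of mass at every junction, a Hagen-Poiseuille pressure-flow
#' law on every segment (rigid walls, no-slip, parabolic profiles implied),
#' boundary flows as sources/sinks and the reference node(s) pinned at the
#' assigned pressure. Loops such as the ACoA circuit are resolved by the
#' solve itself, not by assumption.
#'
#' @param model a `domain_model` from [assemble_domains()].
#' @param fluid a [fluid_properties()] object.
#' @return An object of class `pressure_solution` with named
#'   `nodal_pressures` (mmHg), `segment_flows` (ml/s, proximal->distal
#'   positive), the boundaries and references used, and
#'   `max_conservation_residual` (ml/s).
#' @export
solve_domain <- function(model, fluid = fluid_properties()) {
  net <- model$network
  segs <- net$segments
  resist <- data.frame(id = segs$id, prox = segs$prox, dist = segs$dist,
                       R = segment_resistance(segs, fluid),
                       stringsAsFactors = FALSE)
  inj <- stats::setNames(
    ifelse(model$boundaries$role == "inlet", 1, -1) * model$boundaries$flow_ml_s,
    model$boundaries$node)
  inj <- tapply(inj, names(inj), sum)  # collapse multiple boundaries per node
  inj <- stats::setNames(as.numeric(inj), names(inj))
  fixed <- stats::setNames(model$reference$pressure_mmhg, model$reference$node)
  sol <- .solve_nodal(resist, inj, fixed)
  out <- structure(list(
    part = model$part,
    nodal_pressures = sol$pressures,
    segment_flows = sol$flows,
    network = net,
    boundaries = model$boundaries,
    reference = model$reference,
    max_conservation_residual = NA_real_
  ), class = "pressure_solution")
  out$max_conservation_residual <- conservation_residual(out)
  out
}

#' @export
print.pressure_solution <- function(x, ...) {
  cat(sprintf("%s domain solution: %d nodes, %d segments, max residual %.2e ml/s\n",
              x$part, length(x$nodal_pressures), length(x$segment_flows),
              x$max_conservation_residual))
  invisible(x)
}

#' Maximum conservation residual of a solution
#'
#' Recomputes, from the stored segment flows and boundary flows, the net
#' mass imbalance at every node that is not a pressure reference, and
#' returns the maximum absolute value. A converged solve is below the
#' solver tolerance; a corrupted flow shows up as exactly the injected
#' imbalance.
#'
#' @param solution a `pressure_solution`.
#' @return Maximum absolute junction imbalance in ml/s (0 for an empty
#'   network).
#' @export
conservation_residual <- function(solution) {
  segs <- solution$network$segments
  if (!nrow(segs)) return(0)
  nodes <- unique(c(segs$prox, segs$dist))
  bal <- stats::setNames(numeric(length(nodes)), nodes)
  fl <- solution$segment_flows[segs$id]
  for (i in seq_len(nrow(segs))) {
    bal[segs$prox[i]] <- bal[segs$prox[i]] - fl[i]
    bal[segs$dist[i]] <- bal[segs$dist[i]] + fl[i]
  }
  if (nrow(solution$boundaries)) {
    b <- solution$boundaries
    s <- ifelse(b$role == "inlet", 1, -1) * b$flow_ml_s
    for (i in seq_len(nrow(b))) bal[b$node[i]] <- bal[b$node[i]] + s[i]
  }
  free <- setdiff(nodes, solution$reference$node)
  if (!length(free)) return(0)
  max(abs(bal[free]))
}

#' Pressure at a cut plane along a segment
#'
#' Pressure a given distance into a segment from its proximal junction:
#' the junction pressure minus the analytically integrated Poiseuille drop
#' of the traversed portion at the segment's (signed) flow.
#'
#' @param solution a `pressure_solution`.
#' @param segment_id id of the segment carrying the cut plane.
#' @param distance distance from the proximal junction in m (default 5 mm);
#'   must be strictly less than the segment length.
#' @param fluid a [fluid_properties()] object.
#' @return Pressure in mmHg.
#' @export
cut_plane_pressure <- function(solution, segment_id, distance = 0.005,
                               fluid = fluid_properties()) {
  segs <- solution$network$segments
  i <- match(segment_id, segs$id)
  if (is.na(i)) stop("no segment with id ", segment_id)
  if (distance >= segs$length_m[i])
    stop(sprintf("cut distance %.4g m is not inside segment %s (length %.4g m)",
                 distance, segment_id, segs$length_m[i]))
  r_part <- poiseuille_resistance(segs$length_m[i], segs$r_prox_m[i],
                                  segs$r_dist_m[i], fluid,
                                  from = 0, to = distance)
  p_prox <- solution$nodal_pressures[[segs$prox[i]]]
  q <- solution$segment_flows[[segment_id]]
  p_prox - q * r_part
}

#' Export a pressure solution to CSV
#'
#' Writes two tables: nodal pressures (`node, pressure_mmHg`) and segment
#' flows (`segment, flow_ml_per_s`).
#'
#' @param solution a `pressure_solution`.
#' @param pressures_path,flows_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_pressure_solution <- function(solution, pressures_path, flows_path) {
  utils::write.csv(data.frame(node = names(solution$nodal_pressures),
                              pressure_mmHg = unname(solution$nodal_pressures)),
                   pressures_path, row.names = FALSE)
  utils::write.csv(data.frame(segment = names(solution$segment_flows),
                              flow_ml_per_s = unname(solution$segment_flows)),
                   flows_path, row.names = FALSE)
  invisible(c(pressures_path, flows_path))
}
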
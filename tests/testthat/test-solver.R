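# Nodal-analysis solver: hand-reducible circuits, conservation, cut
# planes.

# hand nodal analysis of the two-resistor divider: feed R to a junction,
# two branches R1/R2 to a sink; root at p_in, sink at p_out
.divider_oracle <- function(p_in, p_out, r_feed, r1, r2) {
  r_par <- 1 / (1 / r1 + 1 / r2)
  q <- (p_in - p_out) / (r_feed + r_par)
  p_j <- p_in - q * r_feed
  list(q_total = q, p_junction = p_j,
       q1 = (p_j - p_out) / r1, q2 = (p_j - p_out) / r2)
}

# build a solvable domain for an arbitrary resistor list
.make_domain <- function(segs, boundaries, reference) {
  nodes <- unique(c(segs$prox, segs$dist))
  net <- structure(list(segments = segs,
                        nodes = data.frame(id = nodes, role = "junction"),
                        variants = cow_variants(), stenoses = list()),
                   class = "cow_network")
  structure(list(part = "test", network = net, boundaries = boundaries,
                 reference = reference), class = "domain_model")
}

.seg <- function(id, prox, dist, R, r = 1.5e-3) {
  data.frame(id = id, label = "ICA", side = "", dup = 1L, prox = prox,
             dist = dist, length_m = R / poiseuille_resistance(1, r),
             r_prox_m = r, r_dist_m = r, stump = FALSE,
             stringsAsFactors = FALSE)
}

test_that("solver reproduces the hand-solved two-resistor divider", {
  o <- .divider_oracle(93, 11.6, 0.13, 40, 60)
  # printed-precision sanity of the oracle itself
  expect_equal(o$q_total, 3.3734, tolerance = 1e-4)
  expect_equal(o$p_junction, 92.5615, tolerance = 1e-5)

  segs <- rbind(.seg("FEED", "ICA_L_root", "J", 0.13),
                .seg("BR1", "J", "T1", 40), .seg("BR2", "J", "T2", 60))
  bounds <- data.frame(node = c("T1", "T2"), role = "outlet",
                       flow_ml_s = c(o$q1, o$q2),
                       artery = c("BR1", "BR2"), stringsAsFactors = FALSE)
  ref <- data.frame(node = "ICA_L_root", pressure_mmhg = 93)
  sol <- solve_domain(.make_domain(segs, bounds, ref))
  expect_equal(sol$nodal_pressures[["J"]], o$p_junction, tolerance = 1e-10)
  expect_equal(sol$segment_flows[["FEED"]], o$q_total, tolerance = 1e-10)
  expect_equal(sol$segment_flows[["BR1"]], o$q1, tolerance = 1e-10)
  expect_lt(sol$max_conservation_residual, 1e-9)
})

test_that("single segment with prescribed flow matches Poiseuille to 1e-10", {
  R <- poiseuille_resistance(0.02, 1.2e-3)
  segs <- .seg("S", "A", "B", R, r = 1.2e-3)
  bounds <- data.frame(node = c("A", "B"), role = c("inlet", "outlet"),
                       flow_ml_s = 2.5, artery = "S", stringsAsFactors = FALSE)
  ref <- data.frame(node = "A", pressure_mmhg = 90)
  sol <- solve_domain(.make_domain(segs, bounds, ref))
  drop <- sol$nodal_pressures[["A"]] - sol$nodal_pressures[["B"]]
  expect_equal(drop, 2.5 * R, tolerance = 1e-10)
})

test_that("series/parallel reducible ladders agree with hand reduction", {
  # A -- r1 -- B -- {r2 || r3} -- C -- r4 -- D, flow q in at A, out at D
  r1 <- 0.3; r2 <- 1.2; r3 <- 0.8; r4 <- 0.5; q <- 1.7
  r_tot <- r1 + 1 / (1 / r2 + 1 / r3) + r4
  segs <- rbind(.seg("S1", "A", "B", r1), .seg("S2", "B", "C", r2),
                .seg("S3", "B", "C", r3), .seg("S4", "C", "D", r4))
  bounds <- data.frame(node = c("A", "D"), role = c("inlet", "outlet"),
                       flow_ml_s = q, artery = c("S1", "S4"),
                       stringsAsFactors = FALSE)
  ref <- data.frame(node = "A", pressure_mmhg = 100)
  sol <- solve_domain(.make_domain(segs, bounds, ref))
  expect_equal(sol$nodal_pressures[["A"]] - sol$nodal_pressures[["D"]],
               q * r_tot, tolerance = 1e-9)
  # parallel branch currents split inversely to resistance
  expect_equal(sol$segment_flows[["S2"]] / sol$segment_flows[["S3"]],
               r3 / r2, tolerance = 1e-9)
  # pressure decreases monotonically along the flow direction
  p <- sol$nodal_pressures
  expect_true(p[["A"]] > p[["B"]])
  expect_true(p[["B"]] > p[["C"]])
  expect_true(p[["C"]] > p[["D"]])
})

test_that("zero boundary flows give a uniform field at the reference", {
  segs <- rbind(.seg("S1", "A", "B", 1), .seg("S2", "B", "C", 2))
  bounds <- data.frame(node = character(), role = character(),
                       flow_ml_s = numeric(), artery = character())
  ref <- data.frame(node = "B", pressure_mmhg = 77)
  sol <- solve_domain(.make_domain(segs, bounds, ref))
  expect_true(all(abs(sol$nodal_pressures - 77) < 1e-12))
  expect_true(all(abs(sol$segment_flows) < 1e-12))
})

test_that("boundary-flow scaling scales pressure drops linearly", {
  segs <- rbind(.seg("S1", "A", "B", 0.4), .seg("S2", "B", "C", 1.1),
                .seg("S3", "B", "D", 0.9))
  mk <- function(c) data.frame(node = c("A", "C", "D"),
                               role = c("inlet", "outlet", "outlet"),
                               flow_ml_s = c(2, 1.2, 0.8) * c,
                               artery = c("S1", "S2", "S3"),
                               stringsAsFactors = FALSE)
  ref <- data.frame(node = "A", pressure_mmhg = 90)
  s1 <- solve_domain(.make_domain(segs, mk(1), ref))
  s3 <- solve_domain(.make_domain(segs, mk(3), ref))
  d1 <- 90 - s1$nodal_pressures
  d3 <- 90 - s3$nodal_pressures
  expect_equal(d3, 3 * d1, tolerance = 1e-10)
})

test_that("a component without a pressure reference is a structured failure", {
  segs <- rbind(.seg("S1", "A", "B", 1), .seg("S2", "C", "D", 1))
  bounds <- data.frame(node = c("A", "B"), role = c("inlet", "outlet"),
                       flow_ml_s = 1, artery = "S1", stringsAsFactors = FALSE)
  ref <- data.frame(node = "A", pressure_mmhg = 90)
  expect_error(solve_domain(.make_domain(segs, bounds, ref)),
               "no pressure reference")
})

test_that("cut-plane pressure applies the per-length Poiseuille drop", {
  # junction at 92.0 mmHg, MCA1-like segment r = 1.5 mm carrying 2 ml/s:
  # 5 mm in, the drop is 2 x 5mm x 0.01302/mm ~ 0.130 mmHg
  R14 <- poiseuille_resistance(0.014, 1.5e-3)
  segs <- .seg("MCA1_L", "J", "T", R14)
  segs$length_m <- 0.014  # exact geometry, not resistance-matched
  bounds <- data.frame(node = c("J", "T"), role = c("inlet", "outlet"),
                       flow_ml_s = 2.0, artery = "MCA1_L",
                       stringsAsFactors = FALSE)
  ref <- data.frame(node = "J", pressure_mmhg = 92)
  sol <- solve_domain(.make_domain(segs, bounds, ref))
  p5 <- cut_plane_pressure(sol, "MCA1_L", 0.005)
  expect_equal(p5, 92 - 2.0 * poiseuille_resistance(0.005, 1.5e-3),
               tolerance = 1e-10)
  expect_equal(p5, 91.870, tolerance = 1e-3)
  expect_equal(cut_plane_pressure(sol, "MCA1_L", 0), 92)
  expect_error(cut_plane_pressure(sol, "MCA1_L", 0.02), "not inside")
  # zero flow: cut-plane pressure equals the junction pressure anywhere
  sol0 <- solve_domain(.make_domain(segs, bounds[0, ], ref))
  expect_equal(cut_plane_pressure(sol0, "MCA1_L", 0.009), 92)
})

test_that("conservation residual reports injected imbalance", {
  segs <- rbind(.seg("S1", "A", "B", 1), .seg("S2", "B", "C", 1))
  bounds <- data.frame(node = c("A", "C"), role = c("inlet", "outlet"),
                       flow_ml_s = 1.5, artery = c("S1", "S2"),
                       stringsAsFactors = FALSE)
  ref <- data.frame(node = "A", pressure_mmhg = 90)
  sol <- solve_domain(.make_domain(segs, bounds, ref))
  expect_lt(conservation_residual(sol), 1e-12)
  corrupted <- sol
  corrupted$segment_flows[["S2"]] <- corrupted$segment_flows[["S2"]] + 0.25
  expect_equal(conservation_residual(corrupted), 0.25, tolerance = 1e-12)
  empty <- sol
  empty$network$segments <- sol$network$segments[0, ]
  expect_identical(conservation_residual(empty), 0)
})
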
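# Forward simulator: ground truth generation, measurement emulation and
# the sampling distributions of the synthetic cohort.

test_that("forward solve reproduces the hand-solved divider", {
  # branch segments carry exactly 1 mmHg.s/ml each; lumped elements of 39
  # and 59 complete the 40/60 divider behind a 0.13 feed
  net <- make_divider_network(r_feed = 0.13, r_branch = 1.0)
  sub <- make_subject(map = 93)
  truth <- forward_solve(net, sub, c(MCA1_L = 39, ACA2_L = 59))
  # independent oracle: series/parallel reduction of the divider
  r_par <- 1 / (1 / 40 + 1 / 60)
  q_tot <- (93 - 11.6) / (0.13 + r_par)
  p_j <- 93 - q_tot * 0.13
  expect_equal(truth$segment_flows[["ICA_L"]], q_tot, tolerance = 1e-9)
  expect_equal(truth$nodal_pressures[["CT_L"]], p_j, tolerance = 1e-9)
  expect_equal(truth$terminal_flows[["MCA1_L"]], (p_j - 11.6) / 40,
               tolerance = 1e-9)
  expect_equal(truth$terminal_flows[["ACA2_L"]], (p_j - 11.6) / 60,
               tolerance = 1e-9)
  # printed-precision values of the same circuit
  expect_equal(q_tot, 3.3734, tolerance = 1e-4)
  expect_equal(p_j, 92.5615, tolerance = 1e-5)
  expect_equal(truth$terminal_flows[["MCA1_L"]], 2.0240, tolerance = 1e-4)
  expect_equal(truth$terminal_flows[["ACA2_L"]], 1.3494, tolerance = 1e-4)
  expect_lt(truth$max_conservation_residual, 1e-9)
})

test_that("left-right symmetry zeroes the ACoA and mirrors the PCoAs", {
  net <- build_synthetic_cow()
  truth <- forward_solve(net, make_subject(),
                         expand_territorial_resistances(net, terr_sym))
  expect_lt(abs(truth$segment_flows[["ACoA"]]), 1e-12)
  expect_equal(truth$segment_flows[["PCoA_L"]],
               truth$segment_flows[["PCoA_R"]], tolerance = 1e-12)
  lr <- function(id_l, id_r) expect_equal(truth$segment_flows[[id_l]],
                                          truth$segment_flows[[id_r]],
                                          tolerance = 1e-12)
  lr("MCA1_L", "MCA1_R"); lr("ACA1_L", "ACA1_R"); lr("PCA2_L", "PCA2_R")
})

test_that("doubling all resistances halves every flow exactly", {
  # exact linear scaling: doubling segment lengths doubles each segment's
  # Poiseuille resistance, so doubling those together with the lumped
  # elements exactly halves every flow at fixed pressures
  net <- build_synthetic_cow()
  net2 <- net
  net2$segments$length_m <- 2 * net2$segments$length_m
  sub <- make_subject()
  r1 <- expand_territorial_resistances(net, terr_asym)
  t1 <- forward_solve(net, sub, r1)
  t2 <- forward_solve(net2, sub, 2 * r1)
  expect_equal(t2$terminal_flows, t1$terminal_flows / 2, tolerance = 1e-12)
  expect_equal(t2$segment_flows, t1$segment_flows / 2, tolerance = 1e-12)
})

test_that("doubling territorial resistances alone nearly halves flows", {
  # with wide (low-resistance) segments the lumped elements dominate and
  # the halving is accurate to the segment/territory resistance ratio
  geo <- default_cow_geometry()
  geo$radius_mm <- pmax(geo$radius_mm, 3)
  net <- build_synthetic_cow(geometry = geo)
  sub <- make_subject()
  r1 <- expand_territorial_resistances(net, terr_asym)
  t1 <- forward_solve(net, sub, r1)
  t2 <- forward_solve(net, sub, 2 * r1)
  expect_equal(unname(t2$terminal_flows), unname(t1$terminal_flows) / 2,
               tolerance = 1e-3)
})

test_that("conservation holds on randomly jittered anatomies", {
  params <- default_cohort_params()
  worst <- 0
  for (i in 1:25) {
    sub <- sample_subject(params, seed = 2000 + i, group = "non_stenotic")
    net <- build_synthetic_cow(jitter = 0.08, seed = 3000 + i)
    truth <- forward_solve(net, sub$subject,
                           expand_territorial_resistances(net, sub$resistances))
    worst <- max(worst, truth$max_conservation_residual)
  }
  expect_lt(worst, 1e-9)
})

test_that("downstream resistance adds the distal remainder analytically", {
  net <- build_synthetic_cow()
  res <- expand_territorial_resistances(net, terr_sym)
  gt <- ground_truth_downstream_resistance(net, res, cut_distance = 0.005)
  # MCA1: 14 mm at r = 1.5 mm; 9 mm remain distal of the 5 mm plane
  row <- gt[gt$segment_id == "MCA1_L", ]
  expect_equal(row$r_downstream,
               33.8 + poiseuille_resistance(0.009, 1.5e-3), tolerance = 1e-12)
  expect_equal(row$r_downstream, 33.8 + 9 * 0.013017, tolerance = 1e-4)
  # printed-precision anchor: lumped 30 behind the same vessel -> 30.117
  gt30 <- ground_truth_downstream_resistance(
    net, stats::setNames(rep(30, length(res)), names(res)))
  expect_equal(gt30$r_downstream[gt30$segment_id == "MCA1_L"], 30.117,
               tolerance = 1e-3)
  # without the PCoA the PCA plane moves to the PCA1, adding the whole PCA2
  net2 <- build_synthetic_cow(cow_variants(pcoa_l = FALSE))
  res2 <- expand_territorial_resistances(net2, terr_sym)
  gt2 <- ground_truth_downstream_resistance(net2, res2)
  row2 <- gt2[gt2$segment_id == "PCA2_L", ]
  expect_identical(row2$cut_segment, "PCA1_L")
  s <- net2$segments
  expect_equal(row2$r_downstream,
               77.8 +
                 poiseuille_resistance(s$length_m[s$id == "PCA1_L"] - 0.005,
                                       1.1e-3) +
                 poiseuille_resistance(s$length_m[s$id == "PCA2_L"], 1.05e-3),
               tolerance = 1e-10)
  expect_error(ground_truth_downstream_resistance(net, res, cut_distance = 1),
               ">=")
})

test_that("measurement emulation is exact at zero noise and seed-stable", {
  net <- build_synthetic_cow()
  truth <- forward_solve(net, make_subject(),
                         expand_territorial_resistances(net, terr_asym))
  m0 <- emulate_measurements(truth, 0)
  for (i in seq_len(nrow(m0$table))) {
    id <- with(m0$table[i, ],
               sprintf("%s%s%s", artery, ifelse(side == "", "", paste0("_", side)),
                       ifelse(dup > 1, sprintf("_d%d", dup), "")))
    expect_equal(m0$table$flow_ml_s[i], truth$segment_flows[[id]])
  }
  m1 <- emulate_measurements(truth, 0.05, seed = 9)
  m2 <- emulate_measurements(truth, 0.05, seed = 9)
  m3 <- emulate_measurements(truth, 0.05, seed = 10)
  expect_identical(m1$table, m2$table)
  expect_false(identical(m1$table, m3$table))
})

test_that("cross-section averaging shrinks noise by sqrt(n)", {
  net <- make_divider_network()
  truth <- forward_solve(net, make_subject(), c(MCA1_L = 40, ACA2_L = 60))
  q_true <- truth$segment_flows[["MCA1_L"]]
  reps <- vapply(1:4000, function(i)
    emulate_measurements(truth, 0.05, 15L, seed = i)$table$flow_ml_s[2],
    numeric(1))
  expected_sd <- 0.05 * abs(q_true) / sqrt(15)
  expect_equal(mean(reps), q_true, tolerance = 0.01)
  expect_equal(stats::sd(reps), expected_sd, tolerance = 0.05)
})

test_that("subject sampling honours the distribution table", {
  params <- default_cohort_params()
  # degenerate SDs pin every subject at the mean
  p0 <- params
  p0$resistance$sd <- 0
  p0$map$patient["sd"] <- 0
  s0 <- sample_subject(p0, seed = 1, group = "non_stenotic")
  expect_equal(unname(s0$resistances[c("MCA_L", "ACA_L", "PCA_L")]),
               c(33.8, 59.0, 77.8))
  expect_equal(s0$subject$map_value, 93)
  expect_equal(s0$subject$icp_value, 11.6)
  # determinism
  a <- sample_subject(params, seed = 42)
  b <- sample_subject(params, seed = 42)
  expect_identical(a, b)
  # invalid SD is rejected
  pbad <- params; pbad$resistance$sd[1] <- -1
  expect_error(sample_subject(pbad, seed = 1), "SD")
})

test_that("sampled MCA resistance mean is within 3 SE of the target", {
  params <- default_cohort_params()
  draws <- vapply(1:2000, function(i)
    sample_subject(params, seed = 10000 + i,
                   group = "non_stenotic")$resistances[["MCA_L"]],
    numeric(1))
  se <- 10.5 / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 33.8), 3 * se)
})
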
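# Boundary-condition rules: PCoA role resolution, inlet sums, ACA2
# adjustment, reference placement and exact balance of assembled domains.

.meas <- function(rows) flow_measurements(rows)

test_that("PCoA sign resolves to opposite roles in the two domains", {
  m <- .meas(data.frame(artery = c("PCoA", "PCoA"), side = c("L", "R"),
                        dup = 1L, flow_ml_s = c(0.3, -0.3)))
  r <- resolve_pcoa_roles(m)
  expect_identical(r$anterior_role, c("outlet", "inlet"))
  expect_identical(r$posterior_role, c("inlet", "outlet"))
  # antisymmetry under sign flip
  m2 <- .meas(data.frame(artery = c("PCoA", "PCoA"), side = c("L", "R"),
                         dup = 1L, flow_ml_s = c(-0.3, 0.3)))
  r2 <- resolve_pcoa_roles(m2)
  expect_identical(r2$anterior_role, rev(r$anterior_role))
  expect_identical(r2$posterior_role, rev(r$posterior_role))
  # zero flow: outlet in both with zero magnitude; missing: no boundary
  m3 <- .meas(data.frame(artery = "PCoA", side = "L", dup = 1L,
                         flow_ml_s = 0))
  r3 <- resolve_pcoa_roles(m3)
  expect_identical(r3$anterior_role[1], "outlet")
  expect_identical(r3$posterior_role[1], "outlet")
  expect_false(r3$present[2])
})

test_that("ICA inlets are the signed sums of MCA1, ACA1 and PCoA", {
  base <- data.frame(artery = c("MCA1", "ACA1", "MCA1", "ACA1"),
                     side = c("L", "L", "R", "R"), dup = 1L,
                     flow_ml_s = c(2.0, 1.0, 2.0, 1.0))
  with_pcoa <- function(q) rbind(base, data.frame(artery = "PCoA", side = "L",
                                                  dup = 1L, flow_ml_s = q))
  expect_equal(anterior_inlet_flows(.meas(with_pcoa(0.3)))[["L"]], 3.3)
  expect_equal(anterior_inlet_flows(.meas(with_pcoa(-0.3)))[["L"]], 2.7)
  expect_equal(anterior_inlet_flows(.meas(base))[["L"]], 3.0)
  expect_error(anterior_inlet_flows(.meas(base[-2, ])), "missing MCA1 or ACA1")
})

test_that("BA inlet is the mass balance of PCA2 and PCoA flows", {
  mk <- function(pcoa_rows) .meas(rbind(
    data.frame(artery = "PCA2", side = c("L", "R"), dup = 1L,
               flow_ml_s = c(1.0, 1.1)), pcoa_rows))
  expect_equal(posterior_inlet_flow(
    mk(data.frame(artery = "PCoA", side = "L", dup = 1L, flow_ml_s = 0.3))),
    1.8)
  expect_equal(posterior_inlet_flow(
    mk(data.frame(artery = "PCoA", side = "L", dup = 1L, flow_ml_s = -0.3))),
    2.4)
  expect_equal(posterior_inlet_flow(mk(NULL)), 2.1)
  expect_error(suppressWarnings(posterior_inlet_flow(
    mk(data.frame(artery = "PCoA", side = c("L", "R"), dup = 1L,
                  flow_ml_s = c(1.2, 1.0))))), "non-positive BA inflow")
})

test_that("ACA2 adjustment rescales proportionally and preserves zeros", {
  m <- .meas(data.frame(artery = c("ACA1", "ACA1", "ACA2", "ACA2"),
                        side = c("L", "R", "L", "R"), dup = 1L,
                        flow_ml_s = c(1.2, 1.4, 1.3, 1.1)))
  a <- adjust_aca2_outlets(m)
  expect_equal(a$factor, rep(2.6 / 2.4, 2))
  expect_equal(a$adjusted[a$side == "L"], 1.4083, tolerance = 1e-4)
  expect_equal(a$adjusted[a$side == "R"], 1.1917, tolerance = 1e-4)
  expect_equal(sum(a$adjusted), 2.6, tolerance = 1e-12)
  # already balanced: identity
  m2 <- .meas(data.frame(artery = c("ACA1", "ACA1", "ACA2", "ACA2"),
                         side = c("L", "R", "L", "R"), dup = 1L,
                         flow_ml_s = c(1.2, 1.2, 1.2, 1.2)))
  expect_equal(adjust_aca2_outlets(m2)$factor, rep(1, 2))
  # zero branch stays zero
  m3 <- .meas(data.frame(artery = c("ACA1", "ACA1", "ACA2", "ACA2"),
                         side = c("L", "R", "L", "R"), dup = 1L,
                         flow_ml_s = c(1.2, 1.4, 2.4, 0)))
  a3 <- adjust_aca2_outlets(m3)
  expect_equal(a3$adjusted, c(2.6, 0))
  # non-positive total is rejected
  m4 <- .meas(data.frame(artery = c("ACA1", "ACA1", "ACA2"),
                         side = c("L", "R", "L"), dup = 1L,
                         flow_ml_s = c(1.2, 1.4, -0.1)))
  expect_error(adjust_aca2_outlets(m4), "non-positive")
})

test_that("reference pressure follows the group-specific placement rules", {
  sub_ns <- make_subject(group = "non_stenotic", map = 93)
  r <- assign_reference_pressure(sub_ns, "anterior",
                                 inlet_flows = c(L = 3.0, R = 3.2))
  expect_identical(r$node, "ICA_R_root")
  expect_equal(r$pressure_mmhg, 93)
  # tie breaks toward the left
  r_tie <- assign_reference_pressure(sub_ns, "anterior",
                                     inlet_flows = c(L = 3.0, R = 3.0))
  expect_identical(r_tie$node, "ICA_L_root")

  sub_st <- subject_record("S2", "stenotic", map_value = 92, ipsi_side = "L",
                           stenosis_degree_ipsi = 80,
                           stenosis_degree_contra = 67)
  r2 <- assign_reference_pressure(sub_st, "anterior",
                                  inlet_flows = c(L = 2, R = 3),
                                  stenosis_drop = 8.0)
  expect_identical(r2$node, "ICA_R_root")
  expect_equal(r2$pressure_mmhg, 84.0)
  # contralateral stenosis below 50% (or absent): no correction
  sub_st2 <- subject_record("S3", "stenotic", map_value = 92, ipsi_side = "L",
                            stenosis_degree_ipsi = 80,
                            stenosis_degree_contra = 40)
  r3 <- assign_reference_pressure(sub_st2, "anterior",
                                  inlet_flows = c(L = 2, R = 3),
                                  stenosis_drop = 8.0)
  expect_equal(r3$pressure_mmhg, 92)
  # posterior always pins the BA root at MAP
  r4 <- assign_reference_pressure(sub_st, "posterior")
  expect_identical(r4$node, "BA_root")
  expect_equal(r4$pressure_mmhg, 92)
})

test_that("assembled domains balance exactly, including disconnected anteriors", {
  check_balance <- function(variants, meas) {
    net <- build_synthetic_cow(variants)
    asm <- assemble_domains(net, meas, make_subject())
    for (dom in list(asm$anterior, asm$posterior)) {
      b <- dom$boundaries
      expect_equal(sum(b$flow_ml_s[b$role == "inlet"]),
                   sum(b$flow_ml_s[b$role == "outlet"]), tolerance = 1e-12)
      expect_true(all(b$flow_ml_s >= 0))
    }
    asm
  }
  net <- build_synthetic_cow()
  truth <- forward_solve(net, make_subject(),
                         expand_territorial_resistances(net, terr_asym))
  check_balance(cow_variants(), emulate_measurements(truth, 0))
  # noisy measurements still balance exactly (closed-form construction)
  check_balance(cow_variants(), emulate_measurements(truth, 0.1, seed = 3))
  # no ACoA: per-component balance with one reference per component
  net2 <- build_synthetic_cow(cow_variants(acoa = FALSE, pcoa_l = FALSE,
                                           pcoa_r = FALSE))
  truth2 <- forward_solve(net2, make_subject(),
                          expand_territorial_resistances(net2, terr_asym))
  asm2 <- assemble_domains(net2, emulate_measurements(truth2, 0.05, seed = 1),
                           make_subject())
  expect_equal(nrow(asm2$anterior$reference), 2L)
  ant <- asm2$anterior
  for (cmpref in ant$reference$node) {
    # each side balances on its own
    side <- sub("ICA_(.)_root", "\\1", cmpref)
    sel <- grepl(sprintf("_%s", side), ant$boundaries$artery)
    b <- ant$boundaries[sel, ]
    expect_equal(sum(b$flow_ml_s[b$role == "inlet"]),
                 sum(b$flow_ml_s[b$role == "outlet"]), tolerance = 1e-12)
  }
})

test_that("noiseless symmetric forward flows reproduce the true ICA inlets", {
  net <- build_synthetic_cow()
  truth <- forward_solve(net, make_subject(),
                         expand_territorial_resistances(net, terr_sym))
  inlets <- anterior_inlet_flows(emulate_measurements(truth, 0))
  expect_equal(inlets[["L"]], truth$segment_flows[["ICA_L"]],
               tolerance = 1e-10)
  expect_equal(inlets[["R"]], truth$segment_flows[["ICA_R"]],
               tolerance = 1e-10)
})
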
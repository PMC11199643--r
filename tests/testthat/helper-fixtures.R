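# Shared fixtures: tiny hand-checkable networks and measurement builders.

fl <- fluid_properties()

# segment length giving an exact target Poiseuille resistance at radius r
.len_for_resistance <- function(R, r = 1.5e-3) {
  R / poiseuille_resistance(1, r, fluid = fl)
}

# Minimal "divider" network in the package's own label scheme: one ICA
# root feeding a carotid terminus from which two outflow branches leave.
# Branch segments carry an exact known resistance so a two-resistor
# divider is reproduced by folding it into the lumped elements.
make_divider_network <- function(r_feed = 0.13, r_branch = 1.0) {
  segs <- rbind(
    data.frame(id = "ICA_L", label = "ICA", side = "L", dup = 1L,
               prox = "ICA_L_root", dist = "CT_L",
               length_m = .len_for_resistance(r_feed), r_prox_m = 1.5e-3,
               r_dist_m = 1.5e-3, stump = FALSE, stringsAsFactors = FALSE),
    data.frame(id = "MCA1_L", label = "MCA1", side = "L", dup = 1L,
               prox = "CT_L", dist = "MCA1_L_t1",
               length_m = .len_for_resistance(r_branch), r_prox_m = 1.5e-3,
               r_dist_m = 1.5e-3, stump = FALSE, stringsAsFactors = FALSE),
    data.frame(id = "ACA2_L", label = "ACA2", side = "L", dup = 1L,
               prox = "CT_L", dist = "ACA2_L_t1",
               length_m = .len_for_resistance(r_branch), r_prox_m = 1.5e-3,
               r_dist_m = 1.5e-3, stump = FALSE, stringsAsFactors = FALSE))
  nodes <- data.frame(
    id = c("ICA_L_root", "CT_L", "MCA1_L_t1", "ACA2_L_t1"),
    role = c("root", "junction", "terminal", "terminal"),
    stringsAsFactors = FALSE)
  structure(list(segments = segs, nodes = nodes,
                 variants = cow_variants(), stenoses = list()),
            class = "cow_network")
}

# default per-territory resistances, slightly asymmetric
terr_asym <- c(MCA_L = 33.8, MCA_R = 30.0, ACA_L = 59.0, ACA_R = 55.0,
               PCA_L = 77.8, PCA_R = 70.0)
terr_sym <- c(MCA_L = 33.8, MCA_R = 33.8, ACA_L = 59.0, ACA_R = 59.0,
              PCA_L = 77.8, PCA_R = 77.8)

make_subject <- function(id = "S1", group = "non_stenotic", map = 93, ...) {
  subject_record(id, group, map_value = map, ...)
}

# forward-simulate then invert; returns max relative recovery error
recovery_error <- function(network, territorial, subject,
                           noise = 0, seed = NULL) {
  res <- expand_territorial_resistances(network, territorial)
  truth <- forward_solve(network, subject, res)
  meas <- emulate_measurements(truth, noise, seed = seed)
  fit <- cvr_estimate(network, meas, subject)
  gt <- ground_truth_downstream_resistance(network, res)
  m <- merge(fit$branches, gt[c("segment_id", "r_downstream")],
             by = "segment_id")
  max(abs(m$cvr - m$r_downstream) / m$r_downstream)
}

# hand-built left-right symmetric measurement set with zero PCoA flow
symmetric_measurements <- function(q_mca = 2.0, q_aca = 1.3, q_pca = 1.0) {
  flow_measurements(data.frame(
    artery = c("ICA", "ICA", "MCA1", "MCA1", "ACA1", "ACA1", "ACA2", "ACA2",
               "BA", "PCA1", "PCA1", "PCA2", "PCA2", "PCoA", "PCoA"),
    side = c("L", "R", "L", "R", "L", "R", "L", "R", "", "L", "R", "L", "R",
             "L", "R"),
    dup = 1L,
    flow_ml_s = c(q_mca + q_aca, q_mca + q_aca, q_mca, q_mca, q_aca, q_aca,
                  q_aca, q_aca, 2 * q_pca, q_pca, q_pca, q_pca, q_pca, 0, 0),
    stringsAsFactors = FALSE))
}
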
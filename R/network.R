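# Circle-of-Willis network data model.
#
# A network is a list with:
#   segments : data.frame(id, label, side, dup, prox, dist,
#                         length_m, r_prox_m, r_dist_m, stump)
#   nodes    : data.frame(id, role) with role in {root, junction, terminal}
#   variants : the cow_variants flags used to build it (if known)
#   stenoses : named list (by ICA segment id) of stenosis_descriptor
# Segment orientation is proximal -> distal in the nominal antegrade
# direction; negative solved flow means retrograde flow. For the PCoA the
# proximal node is on the carotid (anterior) side, so positive PCoA flow
# means anterior -> posterior by construction.

.cow_root_nodes <- c("ICA_L_root", "ICA_R_root", "BA_root")

#' Anatomical variant flags for a synthetic circle of Willis
#'
#' @param pcoa_l,pcoa_r presence of the left/right posterior communicating
#'   artery.
#' @param acoa presence of the anterior communicating artery.
#' @param fetal_pca_l,fetal_pca_r fetal-type posterior cerebral artery
#'   (hypoplastic PCA1, enlarged PCoA); requires the ipsilateral PCoA.
#' @param dup_mca1_l,dup_mca1_r,dup_aca2_l,dup_aca2_r duplicated (doubled)
#'   arteries, modelled as parallel segments with duplicate indices.
#' @return An object of class `cow_variants`.
#' @export
cow_variants <- function(pcoa_l = TRUE, pcoa_r = TRUE, acoa = TRUE,
                         fetal_pca_l = FALSE, fetal_pca_r = FALSE,
                         dup_mca1_l = FALSE, dup_mca1_r = FALSE,
                         dup_aca2_l = FALSE, dup_aca2_r = FALSE) {
  v <- list(pcoa_l = pcoa_l, pcoa_r = pcoa_r, acoa = acoa,
            fetal_pca_l = fetal_pca_l, fetal_pca_r = fetal_pca_r,
            dup_mca1_l = dup_mca1_l, dup_mca1_r = dup_mca1_r,
            dup_aca2_l = dup_aca2_l, dup_aca2_r = dup_aca2_r)
  stopifnot(all(vapply(v, is.logical, logical(1))))
  if (v$fetal_pca_l && !v$pcoa_l)
    stop("inconsistent variant spec: fetal_pca_l requires pcoa_l")
  if (v$fetal_pca_r && !v$pcoa_r)
    stop("inconsistent variant spec: fetal_pca_r requires pcoa_r")
  structure(v, class = "cow_variants")
}

#' Default per-artery geometry table
#'
#' Lengths and radii for each artery label, drawn once from general
#' anatomical literature ranges. Editable: pass a modified copy to
#' [build_synthetic_cow()].
#'
#' @return data.frame with columns `label`, `length_mm`, `radius_mm`.
#' @export
default_cow_geometry <- function() {
  data.frame(
    label = c("ICA", "MCA1", "ACA1", "ACA2", "ACoA", "BA", "PCA1", "PCA2",
              "PCoA"),
    length_mm = c(25, 14, 13, 20, 3, 25, 8, 20, 15),
    radius_mm = c(2.0, 1.5, 1.2, 1.2, 0.7, 1.6, 1.1, 1.05, 0.7),
    stringsAsFactors = FALSE
  )
}

# geometry for fetal-type posterior circulation on one side
.fetal_radius <- c(PCA1 = 0.5e-3, PCoA = 1.1e-3)

.seg_row <- function(id, label, side, dup, prox, dist, length_m, r_m,
                     stump = FALSE) {
  data.frame(id = id, label = label, side = side, dup = dup,
             prox = prox, dist = dist, length_m = length_m,
             r_prox_m = r_m, r_dist_m = r_m, stump = stump,
             stringsAsFactors = FALSE)
}

.derive_nodes <- function(segments) {
  ids <- unique(c(segments$prox, segments$dist))
  deg <- table(c(segments$prox, segments$dist))
  role <- ifelse(ids %in% .cow_root_nodes, "root",
                 ifelse(deg[ids] == 1L, "terminal", "junction"))
  data.frame(id = ids, role = unname(role), stringsAsFactors = FALSE)
}

#' Build a synthetic circle-of-Willis network
#'
#' Constructs a topological + per-segment-geometry network of the circle
#' of Willis with the requested anatomical variants. Stands in for a
#' CTA-derived segmentation: the complete network has 16 segments (both
#' ICAs, MCA1s, ACA1s, ACA2s, PCA1s, PCA2s, PCoAs, plus ACoA and BA) and
#' three root nodes. Duplicated arteries become parallel segments sharing
#' their proximal junction, with duplicate indices and separate terminal
#' nodes. An optional multiplicative jitter perturbs lengths and radii,
#' reproducibly under `seed`.
#'
#' @param variants a [cow_variants()] object.
#' @param geometry a geometry table as from [default_cow_geometry()].
#' @param jitter fractional SD of a truncated-normal multiplicative
#'   perturbation applied per segment to length and radius (0 = none).
#' @param seed integer seed used when `jitter > 0`.
#' @param stenoses named list of [stenosis_descriptor()]s keyed by ICA
#'   segment id (`"ICA_L"`, `"ICA_R"`).
#' @return A validated object of class `cow_network`.
#' @examples
#' net <- build_synthetic_cow()
#' nrow(net$segments)  # 16
#' @export
build_synthetic_cow <- function(variants = cow_variants(),
                                geometry = default_cow_geometry(),
                                jitter = 0, seed = NULL,
                                stenoses = list()) {
  if (!inherits(variants, "cow_variants")) variants <- do.call(cow_variants, variants)
  g <- geometry
  stopifnot(all(c("label", "length_mm", "radius_mm") %in% names(g)),
            all(g$length_mm > 0), all(g$radius_mm > 0))
  len <- function(lab) g$length_mm[g$label == lab] * 1e-3
  rad <- function(lab) g$radius_mm[g$label == lab] * 1e-3

  segs <- list()
  add <- function(...) segs[[length(segs) + 1L]] <<- .seg_row(...)

  for (s in c("L", "R")) {
    root <- sprintf("ICA_%s_root", s)
    ct <- sprintf("CT_%s", s)        # carotid terminus (PCoA take-off and
    acaj <- sprintf("ACAJ_%s", s)    # MCA1/ACA1 bifurcation collapse here)
    pcaj <- sprintf("PCAJ_%s", s)
    add(sprintf("ICA_%s", s), "ICA", s, 1L, root, ct, len("ICA"), rad("ICA"))
    n_mca <- if (isTRUE(variants[[sprintf("dup_mca1_%s", tolower(s))]])) 2L else 1L
    for (d in seq_len(n_mca)) {
      id <- sprintf("MCA1_%s%s", s, if (d > 1L) sprintf("_d%d", d) else "")
      add(id, "MCA1", s, d, ct, sprintf("MCA1_%s_t%d", s, d),
          len("MCA1"), rad("MCA1"))
    }
    add(sprintf("ACA1_%s", s), "ACA1", s, 1L, ct, acaj, len("ACA1"), rad("ACA1"))
    n_aca <- if (isTRUE(variants[[sprintf("dup_aca2_%s", tolower(s))]])) 2L else 1L
    for (d in seq_len(n_aca)) {
      id <- sprintf("ACA2_%s%s", s, if (d > 1L) sprintf("_d%d", d) else "")
      add(id, "ACA2", s, d, acaj, sprintf("ACA2_%s_t%d", s, d),
          len("ACA2"), rad("ACA2"))
    }
    fetal <- isTRUE(variants[[sprintf("fetal_pca_%s", tolower(s))]])
    add(sprintf("PCA1_%s", s), "PCA1", s, 1L, "BA_top", pcaj, len("PCA1"),
        if (fetal) .fetal_radius[["PCA1"]] else rad("PCA1"))
    add(sprintf("PCA2_%s", s), "PCA2", s, 1L, pcaj,
        sprintf("PCA2_%s_t1", s), len("PCA2"), rad("PCA2"))
    if (isTRUE(variants[[sprintf("pcoa_%s", tolower(s))]]))
      add(sprintf("PCoA_%s", s), "PCoA", s, 1L, ct, pcaj, len("PCoA"),
          if (fetal) .fetal_radius[["PCoA"]] else rad("PCoA"))
  }
  add("BA", "BA", "", 1L, "BA_root", "BA_top", len("BA"), rad("BA"))
  if (isTRUE(variants$acoa))
    add("ACoA", "ACoA", "", 1L, "ACAJ_L", "ACAJ_R", len("ACoA"), rad("ACoA"))

  segments <- do.call(rbind, segs)

  if (jitter > 0) {
    if (is.null(seed)) stop("`seed` is required when jitter > 0")
    withr::with_seed(seed, {
      mult <- function(n) pmax(0.5, pmin(1.5, stats::rnorm(n, 1, jitter)))
      n <- nrow(segments)
      segments$length_m <- segments$length_m * mult(n)
      rm_ <- mult(n)
      segments$r_prox_m <- segments$r_prox_m * rm_
      segments$r_dist_m <- segments$r_dist_m * rm_
    })
  }

  net <- structure(list(segments = segments, nodes = .derive_nodes(segments),
                        variants = variants, stenoses = stenoses),
                   class = "cow_network")
  v <- validate_network(net)
  if (length(v)) stop("built network fails validation: ",
                      paste(v, collapse = "; "))
  net
}

#' @export
print.cow_network <- function(x, ...) {
  cat(sprintf("Circle-of-Willis network: %d segments, %d nodes (%d roots, %d terminals)\n",
              nrow(x$segments), nrow(x$nodes),
              sum(x$nodes$role == "root"), sum(x$nodes$role == "terminal")))
  if (length(x$stenoses))
    cat("  stenoses on:", paste(names(x$stenoses), collapse = ", "), "\n")
  invisible(x)
}

# connected components by label propagation over the segment adjacency
.components <- function(segments, nodes = unique(c(segments$prox, segments$dist))) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(segments))) {
      a <- segments$prox[i]; b <- segments$dist[i]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[a] <- m; comp[b] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

#' Validate a circle-of-Willis network
#'
#' Diagnostic check of the type invariants: positive geometry, distinct
#' end nodes, unique segment ids, connectivity, terminal nodes touching
#' exactly one segment, and presence of the ICA/BA roots.
#'
#' @param network a `cow_network`.
#' @return Character vector of violations; empty iff the network is valid.
#' @export
validate_network <- function(network) {
  s <- network$segments
  out <- character(0)
  bad <- s$id[s$length_m <= 0]
  if (length(bad)) out <- c(out, sprintf("non-positive length in segment %s", bad))
  bad <- s$id[s$r_prox_m <= 0 | s$r_dist_m <= 0]
  if (length(bad)) out <- c(out, sprintf("non-positive radius in segment %s", bad))
  bad <- s$id[s$prox == s$dist]
  if (length(bad)) out <- c(out, sprintf("degenerate segment %s (prox == dist)", bad))
  if (anyDuplicated(s$id))
    out <- c(out, sprintf("duplicate segment id %s", unique(s$id[duplicated(s$id)])))
  # connectivity: every component must be supplied, i.e. contain a root
  # (a network with no PCoAs legitimately separates into an anterior
  # component on the ICAs and a posterior one on the BA)
  comps <- if (nrow(s)) .components(s) else list()
  for (cmp in comps) {
    if (!any(cmp %in% .cow_root_nodes))
      out <- c(out, sprintf("disconnected component with no supplying root: {%s}",
                            paste(cmp, collapse = ", ")))
  }
  deg <- table(c(s$prox, s$dist))
  term <- network$nodes$id[network$nodes$role == "terminal"]
  bad <- term[deg[term] != 1L]
  if (length(bad)) out <- c(out, sprintf("terminal node %s touches >1 segment", bad))
  roots <- network$nodes$id[network$nodes$role == "root"]
  if (!is.null(attr(network, "part"))) {
    # sub-networks from a split need not carry all three roots
  } else {
    missing_roots <- setdiff(.cow_root_nodes, roots)
    if (length(missing_roots))
      out <- c(out, sprintf("missing root node %s", missing_roots))
  }
  out
}

.subnetwork <- function(network, segments, part) {
  sub <- structure(list(segments = segments, nodes = .derive_nodes(segments),
                        variants = network$variants,
                        stenoses = network$stenoses[
                          names(network$stenoses) %in% segments$id]),
                   class = "cow_network")
  attr(sub, "part") <- part
  sub
}

#' Split a network into anterior and posterior domains
#'
#' The anterior part keeps the ICAs, MCA1s, ACA1s, ACA2s and ACoA; the
#' posterior part keeps the BA, PCA1s and PCA2s. Each PCoA is halved at
#' its midpoint into two stump segments (same id, flagged `stump`), one
#' per part, whose cut node becomes a boundary terminal in both parts.
#' This mirrors separating the ring to avoid underdetermination of the
#' flow boundary conditions by the circular structure.
#'
#' @param network a validated `cow_network`.
#' @return list with elements `anterior` and `posterior`, each a
#'   `cow_network` with a `part` attribute.
#' @export
split_anterior_posterior <- function(network) {
  s <- network$segments
  if (!any(s$label == "BA") || !any(s$label == "ICA"))
    stop("cannot split: network has no BA or no ICA")
  ant_labels <- c("ICA", "MCA1", "ACA1", "ACA2", "ACoA")
  post_labels <- c("BA", "PCA1", "PCA2")
  ant <- s[s$label %in% ant_labels, , drop = FALSE]
  post <- s[s$label %in% post_labels, , drop = FALSE]
  for (i in which(s$label == "PCoA")) {
    seg <- s[i, , drop = FALSE]
    cut_node <- sprintf("%s_cut", seg$id)
    r_mid <- (seg$r_prox_m + seg$r_dist_m) / 2
    a <- seg; a$dist <- cut_node; a$length_m <- seg$length_m / 2
    a$r_dist_m <- r_mid; a$stump <- TRUE
    b <- seg; b$prox <- cut_node; b$length_m <- seg$length_m / 2
    b$r_prox_m <- r_mid; b$stump <- TRUE
    ant <- rbind(ant, a)
    post <- rbind(post, b)
  }
  list(anterior = .subnetwork(network, ant, "anterior"),
       posterior = .subnetwork(network, post, "posterior"))
}

# ---- JSON dialect -----------------------------------------------------

#' Write a network to the package JSON dialect
#'
#' The dialect stores the segment table, variant flags and stenosis
#' descriptors at full numeric precision; see
#' `system.file("extdata", "network-schema.json", package = "cowcvr")`.
#'
#' @param network a `cow_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cow_network <- function(network, path) {
  payload <- list(
    format = "cowcvr-network",
    version = 1L,
    segments = network$segments,
    variants = unclass(network$variants),
    stenoses = lapply(network$stenoses, unclass)
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a network from the package JSON dialect
#'
#' @param path file written by [write_cow_network()].
#' @return A validated `cow_network`.
#' @export
read_cow_network <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!identical(payload$format, "cowcvr-network"))
    stop("not a cowcvr network file: ", path)
  segments <- payload$segments
  segments$dup <- as.integer(segments$dup)
  stenoses <- lapply(payload$stenoses, function(st)
    do.call(stenosis_descriptor, st))
  net <- structure(list(segments = segments, nodes = .derive_nodes(segments),
                        variants = do.call(cow_variants, payload$variants),
                        stenoses = stenoses),
                   class = "cow_network")
  v <- validate_network(net)
  if (length(v)) stop("network file fails validation: ",
                      paste(v, collapse = "; "))
  net
}
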
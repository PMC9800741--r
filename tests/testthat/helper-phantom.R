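# Shared fixtures: all phantoms are generated in code at test time.

# Compact phantom for unit tests (fast); the package defaults are the
# full-scale validation conditions used in test-acceptance.R.
small_spec <- function(seed = 1, ...) {
  tree_spec(domain_size_um = c(128, 128, 64), branch_levels = 5L,
            rng_seed = seed, ...)
}

# Straight-cylinder phantom for diameter oracles: a single segment of fixed
# diameter along x at the volume centre, isotropic voxels.
cyl_truth <- function(d_um, len = 60, vox = c(1, 1, 1)) {
  spec <- tree_spec(domain_size_um = c(96, 48, 48), voxel_size_um = vox,
                    n_roots = 1, branch_levels = 1,
                    radius_root_um = d_um / 2, radius_min_um = d_um / 2,
                    radius_decay = 1, rng_seed = 1)
  nodes <- data.frame(id = 1:2, parent = c(NA, 1L),
                      x = c(18, 18 + len), y = c(24, 24), z = c(24, 24),
                      radius_um = d_um / 2, level = 0:1)
  noreflow:::build_truth(spec, nodes)
}

# Greedy one-to-one matching of detected against true points.
match_points <- function(det, tru, radius_um) {
  used <- rep(FALSE, nrow(tru)); tp <- 0L
  for (i in seq_len(nrow(det))) {
    d2 <- (tru$x - det$x[i])^2 + (tru$y - det$y[i])^2 + (tru$z - det$z[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= radius_um^2) { tp <- tp + 1L; used[j] <- TRUE }
  }
  list(tp = tp, n_det = nrow(det), n_tru = nrow(tru))
}

# Memoised full-scale single-phantom analysis (generation defaults), shared
# across acceptance blocks so each phantom is rendered and traced once.
.analysis_cache <- new.env(parent = emptyenv())
analysis_bundle <- function(seed, noise = c("default", "noiseless")) {
  noise <- match.arg(noise)
  key <- paste(seed, noise)
  hit <- get0(key, envir = .analysis_cache)
  if (!is.null(hit)) return(hit)
  tr <- apply_occlusion(generate_tree(tree_spec(rng_seed = seed)),
                        occlusion_spec())
  img <- if (noise == "noiseless") noiseless_imaging() else imaging_spec()
  ch <- render_channels(tr, img)
  em <- segment_vessels(ch$existing)
  g <- classify_edges(skeletonize_graph(em), segment_vessels(ch$functional))
  pts <- detect_blockage_points(g)
  pts <- classify_vessel_type(pts, g, segment_vessels(ch$asma))
  cells <- detect_neutrophils(ch$neutrophil, ch$nucleus, em)
  coloc <- colocalize_blockages(pts, cells, existing_length_um = total_length(g))
  out <- list(truth = tr, graph = g, occlusion = quantify_occlusion(g),
              points = coloc$points, cells = cells, coloc = coloc)
  assign(key, out, envir = .analysis_cache)
  out
}
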
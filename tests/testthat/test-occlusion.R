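# two parallel straight edges of equal length/radius in one tiny graph
two_edge_graph <- function(labels = c(NA, NA)) {
  mk <- function(id, y, from, to) {
    pts <- cbind(seq(5, 45, by = 2), y, 10)
    list(id = id, from = from, to = to, points = pts,
         radius_um = rep(2, nrow(pts)),
         length_um = 40, mean_radius_um = 2,
         label = labels[id])
  }
  g <- vessel_graph(nodes = data.frame(id = 1:4, x = c(5, 45, 5, 45),
                                       y = c(10, 10, 30, 30), z = 10),
                    edges = list(mk(1, 10, 1L, 2L), mk(2, 30, 3L, 4L)),
                    voxel_size_um = c(1, 1, 1))
  g
}

test_that("functional mask equal to the existing mask labels everything functional", {
  tr <- apply_occlusion(generate_tree(small_spec(3)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging(), channels = "existing")
  em <- vessel_mask(ch$existing$data > 0.5, ch$existing$voxel_size_um)
  g <- classify_edges(skeletonize_graph(em), em)
  expect_true(all(vapply(g$edges, `[[`, character(1), "label") == "functional"))
  rep <- quantify_occlusion(g)
  expect_equal(rep$occluded_volume_fraction, 0)
  expect_equal(rep$length_ratio_functional, 1)
})

test_that("an empty functional mask labels everything occluded (total no-reflow)", {
  tr <- apply_occlusion(generate_tree(small_spec(3)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging(), channels = "existing")
  em <- vessel_mask(ch$existing$data > 0.5, ch$existing$voxel_size_um)
  g <- skeletonize_graph(em)
  empty <- vessel_mask(array(FALSE, dim = dim(em$mask)), em$voxel_size_um)
  expect_warning(g <- classify_edges(g, empty), "empty")
  expect_true(all(vapply(g$edges, `[[`, character(1), "label") == "occluded"))
  expect_equal(quantify_occlusion(g)$length_ratio_functional, 0)
})

test_that("two equal edges with one occluded give a 0.5 occluded volume fraction", {
  g <- two_edge_graph(c("functional", "occluded"))
  rep <- quantify_occlusion(g)
  expect_equal(rep$occluded_volume_fraction, 0.5)
  expect_equal(rep$occluded_length_fraction, 0.5)
  expect_equal(rep$length_ratio_functional + rep$occluded_length_fraction, 1)
})

test_that("region masks restrict the report and a disjoint region warns with zero totals", {
  g <- two_edge_graph(c("functional", "occluded"))
  dims <- c(50, 40, 20)
  reg <- array(FALSE, dim = dims); reg[, 1:20, ] <- TRUE   # only edge 1 (y=10)
  rep <- quantify_occlusion(g, region_mask = vessel_mask(reg, c(1, 1, 1)))
  expect_equal(rep$n_edges, 1L)
  expect_equal(rep$occluded_volume_fraction, 0)
  far <- array(FALSE, dim = dims); far[1, 40, 1] <- TRUE
  expect_warning(rep0 <- quantify_occlusion(g, region_mask = vessel_mask(far, c(1, 1, 1))),
                 "disjoint")
  expect_equal(rep0$n_edges, 0L)
})

test_that("raising coverage_tau never converts an occluded edge to functional", {
  tr <- apply_occlusion(generate_tree(small_spec(5)), occlusion_spec())
  ch <- render_channels(tr, imaging_spec(), channels = c("existing", "functional"))
  g0 <- skeletonize_graph(segment_vessels(ch$existing))
  fm <- segment_vessels(ch$functional)
  occ_at <- function(tau) {
    g <- classify_edges(g0, fm, perfusion_params(coverage_tau = tau),
                        split_transitions = FALSE)
    which(vapply(g$edges, `[[`, character(1), "label") == "occluded")
  }
  o3 <- occ_at(0.3); o5 <- occ_at(0.5); o8 <- occ_at(0.8)
  expect_true(all(o3 %in% o5))
  expect_true(all(o5 %in% o8))
})

test_that("noiseless edge labels equal generator truth exactly (oracle equivalence)", {
  for (seed in c(2, 6)) {
    tr <- apply_occlusion(generate_tree(small_spec(seed)), occlusion_spec())
    ch <- render_channels(tr, noiseless_imaging(), channels = "functional")
    fmask <- vessel_mask(ch$functional$data > 0.5, ch$functional$voxel_size_um)
    g <- classify_edges(truth_graph(tr), fmask,
                        perfusion_params(functional_dilation_um = 0),
                        split_transitions = FALSE)
    rec <- vapply(g$edges, `[[`, character(1), "label")
    tru <- unname(tr$edge_labels[as.character(vapply(g$edges, `[[`, integer(1), "to"))])
    expect_identical(rec, tru)
  }
})

test_that("tube and voxel volume methods broadly agree on a phantom", {
  tr <- apply_occlusion(generate_tree(small_spec(4)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging(), channels = c("existing", "functional"))
  em <- segment_vessels(ch$existing)
  g <- classify_edges(skeletonize_graph(em), segment_vessels(ch$functional))
  tube <- quantify_occlusion(g, method = "tube")
  vox <- quantify_occlusion(g, method = "voxel", existing_mask = em)
  expect_lt(abs(tube$occluded_volume_fraction - vox$occluded_volume_fraction), 0.1)
})
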
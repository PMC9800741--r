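test_that("noiseless vessel segmentation overlaps the rendered tube set (Dice >= 0.9)", {
  tr <- apply_occlusion(generate_tree(small_spec(3)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging(), channels = "existing")
  m <- segment_vessels(ch$existing)
  truth <- ch$existing$data > 0.5
  dice <- 2 * sum(m$mask & truth) / (sum(m$mask) + sum(truth))
  expect_gte(dice, 0.9)
})

test_that("degenerate volumes yield empty masks with warnings, not failures", {
  flat <- image_volume(array(0.7, dim = c(24, 24, 12)), c(1, 1, 2), "existing")
  expect_warning(m <- segment_vessels(flat), "threshold")
  expect_false(any(m$mask))
  zero <- image_volume(array(0, dim = c(24, 24, 12)), c(1, 1, 2), "functional")
  expect_warning(m0 <- segment_vessels(zero), "all-zero")
  expect_false(any(m0$mask))
})

test_that("functional mask is contained in the dilated existing mask on noiseless phantoms", {
  tr <- apply_occlusion(generate_tree(small_spec(5)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging(), channels = c("existing", "functional"))
  em <- segment_vessels(ch$existing)
  fm <- segment_vessels(ch$functional)
  dil <- dilate_mask(em$mask, 2, em$voxel_size_um)
  expect_true(all(dil[fm$mask]))
})

test_that("segmentation of a re-rendered binary mask is idempotent", {
  tr <- apply_occlusion(generate_tree(small_spec(4)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging(), channels = "existing")
  m1 <- segment_vessels(ch$existing)
  img2 <- image_volume(array(as.numeric(m1$mask), dim = dim(m1$mask)),
                       m1$voxel_size_um, "existing")
  m2 <- segment_vessels(img2)
  dice <- 2 * sum(m1$mask & m2$mask) / (sum(m1$mask) + sum(m2$mask))
  expect_gte(dice, 0.99)
})

test_that("a straight cylinder skeletonizes to one edge between two endpoints with accurate length", {
  tr <- cyl_truth(6, len = 60)
  ch <- render_channels(tr, noiseless_imaging(), channels = "existing")
  m <- vessel_mask(ch$existing$data > 0.5, ch$existing$voxel_size_um)
  g <- skeletonize_graph(m)
  expect_equal(length(g$edges), 1L)
  expect_equal(nrow(g$nodes), 2L)
  expect_lt(abs(total_length(g) - 60) / 60, 0.05)
  # per-point radii come from the distance transform of the tube
  expect_equal(median(g$edges[[1]]$radius_um, na.rm = TRUE), 3, tolerance = 0.35)
})

test_that("a Y-shaped mask yields exactly one degree-3 junction", {
  spec <- tree_spec(domain_size_um = c(96, 96, 48), voxel_size_um = c(1, 1, 1),
                    n_roots = 1, branch_levels = 2, radius_root_um = 4,
                    radius_min_um = 3, radius_decay = 0.9, rng_seed = 1)
  nodes <- data.frame(id = 1:4, parent = c(NA, 1L, 2L, 2L),
                      x = c(10, 45, 80, 80), y = c(48, 48, 25, 71),
                      z = c(24, 24, 24, 24), radius_um = c(4, 4, 3, 3),
                      level = c(0, 1, 2, 2))
  tr <- noreflow:::build_truth(spec, nodes)
  ch <- render_channels(tr, noiseless_imaging(), channels = "existing")
  g <- skeletonize_graph(vessel_mask(ch$existing$data > 0.5, c(1, 1, 1)))
  deg <- table(c(vapply(g$edges, `[[`, integer(1), "from"),
                 vapply(g$edges, `[[`, integer(1), "to")))
  expect_equal(sum(deg == 3), 1L)
  expect_equal(length(g$edges), 3L)
})

test_that("empty or speck masks yield empty graphs with a warning", {
  m <- vessel_mask(array(FALSE, dim = c(16, 16, 8)), c(1, 1, 2))
  expect_warning(g <- skeletonize_graph(m), "empty")
  expect_equal(length(g$edges), 0L)
})

test_that("skeleton stays inside the mask and conserves length at default noise", {
  tr <- apply_occlusion(generate_tree(small_spec(8)), occlusion_spec())
  ch <- render_channels(tr, imaging_spec(), channels = "existing")
  m <- segment_vessels(ch$existing)
  g <- skeletonize_graph(m)
  # containment within half a voxel diagonal of the mask
  near <- dilate_mask(m$mask, sqrt(sum(m$voxel_size_um^2)) / 2, m$voxel_size_um)
  for (e in g$edges)
    expect_true(all(noreflow:::mask_at_points(near, m$voxel_size_um, e$points)))
  expect_lt(abs(total_length(g) - truth_summary(tr)$total_length_um) /
              truth_summary(tr)$total_length_um, 0.1)
})
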
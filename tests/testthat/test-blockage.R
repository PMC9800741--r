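test_that("an all-functional graph yields no blockage points", {
  tr <- apply_occlusion(generate_tree(small_spec(3)),
                        occlusion_spec(blocked_subtree_fraction = 0))
  ch <- render_channels(tr, noiseless_imaging(), channels = "existing")
  em <- vessel_mask(ch$existing$data > 0.5, ch$existing$voxel_size_um)
  g <- classify_edges(skeletonize_graph(em), em)
  expect_equal(nrow(detect_blockage_points(g)), 0L)
})

test_that("blockage points land on the truth transitions, one per blocked subtree", {
  tr <- apply_occlusion(generate_tree(small_spec(2)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging(), channels = c("existing", "functional"))
  fmask <- vessel_mask(ch$functional$data > 0.5, ch$functional$voxel_size_um)
  g <- classify_edges(truth_graph(tr), fmask, perfusion_params())
  pts <- detect_blockage_points(g)
  expect_equal(nrow(pts), nrow(tr$blockage_points))
  m <- match_points(pts, tr$blockage_points, 5)
  expect_equal(m$tp, m$n_tru)
  # deterministic coordinate ordering
  expect_true(!is.unsorted(pts$x))
})

test_that("vessel type is unknown without an alpha-SMA channel and follows truth flags with one", {
  tr <- apply_occlusion(generate_tree(small_spec(5)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging(),
                        channels = c("existing", "functional", "asma"))
  em <- segment_vessels(ch$existing)
  g <- classify_edges(skeletonize_graph(em), segment_vessels(ch$functional))
  pts <- detect_blockage_points(g)
  expect_true(all(classify_vessel_type(pts, g, NULL)$vessel_type == "unknown"))
  pts <- classify_vessel_type(pts, g, segment_vessels(ch$asma))
  tru <- tr$blockage_points
  checked <- 0L
  for (i in seq_len(nrow(pts))) {
    d2 <- (tru$x - pts$x[i])^2 + (tru$y - pts$y[i])^2 + (tru$z - pts$z[i])^2
    j <- which.min(d2)
    if (d2[j] > 25) next
    truth_type <- if (tru$entry_edge[j] %in% tr$asma_edges) "arteriole" else "capillary"
    expect_equal(pts$vessel_type[i], truth_type)
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("FWHM matches cylinder diameters within one in-plane voxel (noiseless, no PSF)", {
  for (d in c(3, 4, 6, 8, 10, 12)) {
    tr <- cyl_truth(d)
    ch <- render_channels(tr, noiseless_imaging(), channels = "existing")
    p <- diameter_profile(ch$existing, truth_graph(tr), 1, 30)
    expect_lte(abs(p$fwhm_um - d), 1)
    expect_false(p$flagged)
    expect_equal(p$dt_diameter_um, d, tolerance = 0.5)
  }
})

test_that("a constant-intensity window is flagged with undefined FWHM", {
  tr <- cyl_truth(6)
  vol <- image_volume(array(0.5, dim = c(96, 48, 48)), c(1, 1, 1), "existing")
  p <- diameter_profile(vol, truth_graph(tr), 1, 30)
  expect_true(p$flagged)
  expect_true(is.na(p$fwhm_um))
})

test_that("a depth-0.5 narrowing halves the FWHM relative to upstream (ratio within 0.1)", {
  tr <- cyl_truth(8)
  ep <- tr$edge_points[["2"]]
  arc <- noreflow:::polyline_arc(ep$pts)
  dip <- pmax(0, 1 - abs(arc - 30) / 5)
  ep$r <- ep$r * (1 - 0.5 * dip)
  tr$edge_points[["2"]] <- ep
  ch <- render_channels(tr, noiseless_imaging(), channels = "existing")
  g <- truth_graph(tr)
  ratio <- diameter_profile(ch$existing, g, 1, 30)$fwhm_um /
    diameter_profile(ch$existing, g, 1, 10)$fwhm_um
  expect_lte(abs(ratio - 0.5), 0.1)
})

test_that("PSF blur never shrinks the measured FWHM beyond sampling jitter and inflates it at large sigma", {
  tr <- cyl_truth(6)
  g <- truth_graph(tr)
  f <- vapply(c(0, 0.5, 1, 1.5, 2), function(s) {
    ch <- render_channels(tr, imaging_spec(psf_sigma_um = rep(s, 3),
                                           photon_scale = Inf, read_noise_sd = 0,
                                           background_level = 0),
                          channels = "existing")
    diameter_profile(ch$existing, g, 1, 30)$fwhm_um
  }, numeric(1))
  expect_true(all(diff(f) > -0.15))   # half a sampling step of slack
  expect_gt(f[5], f[1])
})

test_that("diameter histograms are normalized and concentrate on a single-caliber phantom", {
  tr <- cyl_truth(6)
  ch <- render_channels(tr, noiseless_imaging(), channels = "existing")
  h <- diameter_distribution(ch$existing, truth_graph(tr), sampling_step_um = 5)
  expect_equal(sum(h$rel_freq), 1)
  expect_gte(max(h$rel_freq), 0.9)
  expect_equal(h$mean_fwhm_um, 6, tolerance = 0.6)
})

test_that("blockage diameters carry a positive narrowing index at constriction sites", {
  tr <- apply_occlusion(generate_tree(small_spec(2)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging(), channels = c("existing", "functional"))
  em <- segment_vessels(ch$existing)
  g <- classify_edges(skeletonize_graph(em), segment_vessels(ch$functional))
  pts <- detect_blockage_points(g)
  pts <- suppressWarnings(measure_blockage_diameters(pts, ch$existing, g))
  ni <- pts$narrowing_index[!is.na(pts$narrowing_index)]
  expect_gt(length(ni), 0)
  expect_gt(mean(ni), 0.15)
})
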
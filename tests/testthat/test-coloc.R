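sphere_volume <- function(dims, vs, centers, radii, role) {
  arr <- if (nrow(centers)) {
    array(noreflow:::cpp_paint_spheres(as.integer(dims), vs, centers, radii), dim = dims)
  } else array(0, dim = dims)
  image_volume(arr, vs, role)
}

test_that("an empty marker channel yields zero detections", {
  dims <- c(48, 48, 24); vs <- c(1, 1, 2)
  marker <- sphere_volume(dims, vs, matrix(numeric(0), ncol = 3), numeric(0), "neutrophil")
  vm <- vessel_mask(array(TRUE, dim = dims), vs)
  cells <- detect_neutrophils(marker, marker, vm)
  expect_equal(nrow(cells), 0L)
})

test_that("the marker+nucleus+intravascular rule is enforced blob by blob", {
  dims <- c(64, 64, 32); vs <- c(1, 1, 2)
  # vessel lumen: a slab through the middle
  lumen <- array(FALSE, dim = dims); lumen[, , 12:20] <- TRUE
  vm <- vessel_mask(lumen, vs)
  centers <- rbind(c(16, 16, 32),   # in lumen, with nucleus -> neutrophil
                   c(48, 16, 32),   # in lumen, no nucleus -> excluded
                   c(16, 48, 6))    # outside lumen, with nucleus -> extravascular
  marker <- sphere_volume(dims, vs, centers, rep(4, 3), "neutrophil")
  nuc <- sphere_volume(dims, vs, centers[c(1, 3), , drop = FALSE], rep(2.8, 2), "nucleus")
  cells <- detect_neutrophils(marker, nuc, vm)
  expect_equal(nrow(cells), 3L)
  expect_equal(sum(cells$is_neutrophil), 1L)
  hit <- cells[cells$is_neutrophil, ]
  expect_lt(sqrt((hit$x - 16)^2 + (hit$y - 16)^2 + (hit$z - 32)^2), 2)
  # without a nucleus channel the rule weakens, with a warning
  expect_warning(weak <- detect_neutrophils(marker, NULL, vm), "weakened")
  expect_equal(sum(weak$is_neutrophil), 2L)
})

test_that("phantom neutrophils are recovered exactly in the noiseless limit", {
  tr <- apply_occlusion(generate_tree(small_spec(2)),
                        occlusion_spec(neutrophil_at_blockage_fraction = 1))
  ch <- render_channels(tr, noiseless_imaging())
  em <- segment_vessels(ch$existing)
  cells <- detect_neutrophils(ch$neutrophil, ch$nucleus, em)
  tru <- tr$cells[tr$cells$type == "neutrophil", ]
  expect_equal(sum(cells$is_neutrophil), nrow(tru))
  det <- cells[cells$is_neutrophil, ]
  for (i in seq_len(nrow(det))) {
    d <- sqrt(min((tru$x - det$x[i])^2 + (tru$y - det$y[i])^2 + (tru$z - det$z[i])^2))
    expect_lt(d, 2)
  }
})

test_that("co-localization fractions cover the no-cell and all-matched extremes", {
  pts <- data.frame(x = c(10, 40, 70), y = 10, z = 10)
  none <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                     is_neutrophil = logical(0))
  rep0 <- colocalize_blockages(pts, none)
  expect_equal(rep0$fraction_without, 1)
  all_cells <- data.frame(x = pts$x + 2, y = pts$y, z = pts$z, is_neutrophil = TRUE)
  rep1 <- colocalize_blockages(pts, all_cells)
  expect_equal(rep1$fraction_without, 0)
  expect_equal(rep1$n_with_neutrophil + rep1$n_without, rep1$n_blockage_points)
  empty <- colocalize_blockages(pts[0, ], all_cells)
  expect_equal(empty$n_blockage_points, 0L)
})

test_that("growing the matching radius never decreases the with-neutrophil count", {
  set.seed(31)
  pts <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100), z = runif(12, 0, 50))
  cells <- data.frame(x = runif(8, 0, 100), y = runif(8, 0, 100), z = runif(8, 0, 50),
                      is_neutrophil = TRUE)
  n_with <- vapply(c(2, 5, 10, 20, 50), function(r)
    colocalize_blockages(pts, cells, matching_radius_um = r)$n_with_neutrophil,
    integer(1))
  expect_true(all(diff(n_with) >= 0))
})

test_that("recovered fraction-without matches the planted neutrophil fraction on phantoms", {
  tr <- apply_occlusion(generate_tree(small_spec(6)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging())
  em <- segment_vessels(ch$existing)
  g <- classify_edges(skeletonize_graph(em), segment_vessels(ch$functional))
  pts <- detect_blockage_points(g)
  cells <- detect_neutrophils(ch$neutrophil, ch$nucleus, em)
  rep <- colocalize_blockages(pts, cells, existing_length_um = total_length(g))
  nbp <- nrow(tr$blockage_points)
  expect_equal(rep$fraction_without, 1 - round(0.3 * nbp) / nbp)
  expect_gt(rep$neutrophil_density_per_mm_vessel, 0)
})
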
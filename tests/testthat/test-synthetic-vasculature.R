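test_that("degenerate single-segment tree has no branch nodes and identity decay keeps radii constant", {
  spec <- tree_spec(n_roots = 1, branch_levels = 1, radius_decay = 1,
                    rng_seed = 42)
  tr <- generate_tree(spec)
  expect_equal(nrow(tr$edges), 1L)
  # no node with more than one child
  kids <- table(tr$edges$parent_node)
  expect_true(all(kids <= 1))
  expect_true(all(abs(unlist(lapply(tr$edge_points, `[[`, "r")) -
                        spec$radius_root_um) < 1e-9))
})

test_that("tree generation is reproducible and radii never increase root-to-leaf", {
  a <- generate_tree(small_spec(7))
  b <- generate_tree(small_spec(7))
  expect_identical(a$nodes, b$nodes)
  for (i in seq_len(nrow(a$edges))) {
    e <- a$edges$id[i]
    pn <- a$edges$parent_node[i]
    expect_lte(a$nodes$radius_um[a$nodes$id == e],
               a$nodes$radius_um[a$nodes$id == pn] + 1e-9)
  }
})

test_that("a domain too small for one root segment fails with the offending extent", {
  expect_error(generate_tree(tree_spec(domain_size_um = c(8, 100, 100))),
               "x-extent")
})

test_that("zero blocked fraction leaves everything functional", {
  tr <- apply_occlusion(generate_tree(small_spec(3)),
                        occlusion_spec(blocked_subtree_fraction = 0))
  expect_true(all(tr$edge_labels == "functional"))
  expect_equal(nrow(tr$blockage_points), 0L)
  expect_equal(truth_summary(tr)$occluded_length_fraction, 0)
})

test_that("occlusion truth is self-consistent: disjoint subtrees, one blockage point per maximal occluded component", {
  for (seed in c(2, 9)) {
    tr <- apply_occlusion(generate_tree(small_spec(seed)),
                          occlusion_spec(blocked_subtree_fraction = 1))
    occ <- names(tr$edge_labels)[tr$edge_labels == "occluded"]
    # every occluded edge downstream of exactly one blockage entry
    covered <- unlist(lapply(tr$blockage_points$entry_edge, function(e)
      noreflow:::subtree_edges(tr, e)))
    expect_equal(sort(as.integer(occ)), sort(covered))
    expect_equal(anyDuplicated(covered), 0L)
    # maximal occluded components of the truth graph match the point count
    tg <- truth_graph(tr)
    labs <- vapply(tg$edges, `[[`, character(1), "label")
    el <- t(vapply(tg$edges[labs == "occluded"], function(e)
      c(as.character(e$from), as.character(e$to)), character(2)))
    ncomp <- igraph::components(igraph::graph_from_edgelist(el, directed = FALSE))$no
    expect_equal(nrow(tr$blockage_points), ncomp)
  }
})

test_that("narrowing sites record the formula diameter and narrowing depth dips the rendered radii", {
  sp <- occlusion_spec(narrowing_depth = 0.5)
  tr <- apply_occlusion(generate_tree(small_spec(4)), sp)
  for (i in seq_len(nrow(tr$narrowing_sites))) {
    e <- tr$blockage_points$entry_edge[i]
    # recorded diameter = 2 * r * (1 - depth) with r the pre-dip entry radius
    lvl <- tr$edges$level[tr$edges$id == e]
    r0 <- max(tr$tree_spec$radius_min_um,
              tr$tree_spec$radius_root_um * tr$tree_spec$radius_decay^(lvl - 2))
    expect_equal(tr$narrowing_sites$true_min_diameter_um[i], 2 * r0 * 0.5,
                 tolerance = 1e-9)
    # the dipped per-point radius at the blockage point is about half original
    ep <- tr$edge_points[[as.character(e)]]
    expect_lt(ep$r[1], r0 * 0.75)
  }
})

test_that("increasing the blocked fraction strictly increases true occluded volume", {
  for (seed in c(1, 5)) {
    base <- generate_tree(small_spec(seed))
    v <- vapply(c(0.2, 0.4, 0.6), function(f)
      truth_summary(apply_occlusion(base, occlusion_spec(blocked_subtree_fraction = f)))$occluded_volume_fraction,
      numeric(1))
    expect_true(all(diff(v) > 0))
  }
})

test_that("noiseless rendering obeys label containment and channel semantics", {
  tr <- apply_occlusion(generate_tree(small_spec(6)), occlusion_spec())
  ch <- render_channels(tr, noiseless_imaging())
  expect_true(all(ch$existing$data[ch$functional$data > 0.5] > 0.5))
  expect_true(any(ch$existing$data > 0.5 & ch$functional$data < 0.5))
  # no cells -> neutrophil channel is flat background
  tr0 <- apply_occlusion(generate_tree(small_spec(6)),
                         occlusion_spec(neutrophil_at_blockage_fraction = 0,
                                        n_perivascular_nuclei = 0))
  ch0 <- render_channels(tr0, noiseless_imaging(), channels = "neutrophil")
  expect_true(all(ch0$neutrophil$data == 0))
})

test_that("rendering with a fixed seed is bit-identical and refuses unresolvable voxels", {
  tr <- apply_occlusion(generate_tree(small_spec(2)), occlusion_spec())
  a <- render_channels(tr, imaging_spec(rng_seed = 11), channels = "existing")
  b <- render_channels(tr, imaging_spec(rng_seed = 11), channels = "existing")
  expect_identical(a$existing$data, b$existing$data)
  bad <- small_spec(2, voxel_size_um = c(1, 1, 4))
  expect_error(render_channels(generate_tree(bad), noiseless_imaging()),
               "unresolvable")
})
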
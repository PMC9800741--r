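#' Specification of a synthetic vascular tree
#'
#' Parameters of the branching arteriole-to-capillary phantom used for
#' ground-truth validation. Defaults describe a cleared-tissue imaging
#' scenario: a 192 x 192 x 96 um block sampled at 1 x 1 x 2 um voxels,
#' two arteriole roots of 5 um radius branching over six generations of
#' short straight segments down to 2 um capillaries.
#'
#' @param domain_size_um physical extent (x, y, z), micrometres.
#' @param voxel_size_um voxel size (x, y, z), micrometres; anisotropic z allowed.
#' @param n_roots number of arteriole roots entering at the x = 0 face.
#' @param branch_levels maximum number of branching generations.
#' @param radius_root_um arteriole (root) radius, micrometres.
#' @param radius_min_um capillary (floor) radius, micrometres.
#' @param radius_decay per-generation multiplicative radius factor in (0, 1].
#' @param segment_length_um length-2 vector (mean, sd) of segment lengths, um.
#' @param branch_angle_deg length-2 vector (mean, sd) of branching angles, degrees.
#' @param rng_seed integer seed; the whole phantom is reproducible from it.
#' @return a validated list of class \code{tree_spec}.
#' @export
tree_spec <- function(domain_size_um = c(192, 192, 96),
                      voxel_size_um = c(1, 1, 2),
                      n_roots = 2L,
                      branch_levels = 6L,
                      radius_root_um = 5,
                      radius_min_um = 2,
                      radius_decay = 0.75,
                      segment_length_um = c(mean = 22, sd = 4),
                      branch_angle_deg = c(mean = 35, sd = 10),
                      rng_seed = 1L) {
  spec <- list(domain_size_um = as.numeric(domain_size_um),
               voxel_size_um = as.numeric(voxel_size_um),
               n_roots = as.integer(n_roots),
               branch_levels = as.integer(branch_levels),
               radius_root_um = radius_root_um,
               radius_min_um = radius_min_um,
               radius_decay = radius_decay,
               segment_length_um = as.numeric(segment_length_um),
               branch_angle_deg = as.numeric(branch_angle_deg),
               rng_seed = as.integer(rng_seed))
  if (any(spec$domain_size_um <= 0)) stop("all domain extents must be positive")
  if (any(spec$voxel_size_um <= 0)) stop("voxel sizes must be positive")
  if (spec$radius_min_um > spec$radius_root_um)
    stop("radius_min_um must not exceed radius_root_um")
  if (spec$radius_decay <= 0 || spec$radius_decay > 1)
    stop("radius_decay must be in (0, 1]")
  if (spec$n_roots < 1L || spec$branch_levels < 1L)
    stop("n_roots and branch_levels must be >= 1")
  class(spec) <- "tree_spec"
  spec
}

#' Specification of occlusion, narrowing and cell placement
#'
#' @param blocked_subtree_fraction fraction in [0, 1] of candidate subtrees
#'   to occlude (candidates are all edges; chosen subtrees are disjoint).
#' @param narrowing_depth fractional radius reduction in [0, 1) at each
#'   blockage point; the lumen never fully vanishes in the rendered geometry.
#' @param narrowing_halfwidth_um axial half-extent of the narrowing dip, um.
#' @param neutrophil_at_blockage_fraction fraction of blockage points that
#'   receive an intravascular neutrophil immediately downstream.
#' @param neutrophil_radius_um neutrophil radius, um.
#' @param asma_radius_threshold_um radius above which a segment carries
#'   alpha-SMA signal (arteriole caliber).
#' @param n_perivascular_nuclei count of nucleus-only perivascular cells
#'   scattered along the tree (extravascular).
#' @param rng_seed optional integer seed; when \code{NULL} a seed is derived
#'   from the tree's seed so the full phantom stays reproducible.
#' @return a validated list of class \code{occlusion_spec}.
#' @export
occlusion_spec <- function(blocked_subtree_fraction = 0.3,
                           narrowing_depth = 0.5,
                           narrowing_halfwidth_um = 5,
                           neutrophil_at_blockage_fraction = 0.3,
                           neutrophil_radius_um = 4,
                           asma_radius_threshold_um = 3,
                           n_perivascular_nuclei = 8L,
                           rng_seed = NULL) {
  spec <- list(blocked_subtree_fraction = blocked_subtree_fraction,
               narrowing_depth = narrowing_depth,
               narrowing_halfwidth_um = narrowing_halfwidth_um,
               neutrophil_at_blockage_fraction = neutrophil_at_blockage_fraction,
               neutrophil_radius_um = neutrophil_radius_um,
               asma_radius_threshold_um = asma_radius_threshold_um,
               n_perivascular_nuclei = as.integer(n_perivascular_nuclei),
               rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  fr <- c(spec$blocked_subtree_fraction, spec$neutrophil_at_blockage_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (spec$narrowing_depth < 0 || spec$narrowing_depth >= 1)
    stop("narrowing_depth must be in [0, 1)")
  class(spec) <- "occlusion_spec"
  spec
}

#' Specification of the imaging model
#'
#' Gaussian PSF blur, Poisson photon noise, additive Gaussian read noise and
#' a constant background, applied per channel after rasterization.
#'
#' @param psf_sigma_um Gaussian PSF sigma (x, y, z), micrometres; zero skips blur.
#' @param photon_scale Poisson intensity scale (expected photons at unit
#'   signal); \code{Inf} disables shot noise.
#' @param read_noise_sd additive Gaussian noise sd (signal units).
#' @param background_level constant background (signal units).
#' @param channel_gains per-channel multipliers, recycled across channels.
#' @param rng_seed optional integer seed; derived from the tree seed when NULL.
#' @return a validated list of class \code{imaging_spec}.
#' @export
imaging_spec <- function(psf_sigma_um = c(0.6, 0.6, 1.8),
                         photon_scale = 80,
                         read_noise_sd = 0.01,
                         background_level = 0.03,
                         channel_gains = 1,
                         rng_seed = NULL) {
  spec <- list(psf_sigma_um = as.numeric(psf_sigma_um),
               photon_scale = photon_scale,
               read_noise_sd = read_noise_sd,
               background_level = background_level,
               channel_gains = channel_gains,
               rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  if (any(spec$psf_sigma_um < 0)) stop("psf sigmas must be >= 0")
  if (!(spec$photon_scale > 0)) stop("photon_scale must be > 0")
  class(spec) <- "imaging_spec"
  spec
}

#' Noiseless imaging settings
#'
#' Convenience constructor: no PSF blur, no shot or read noise, no background.
#' In this limit the functional channel is exactly the subset of the existing
#' channel over functional edges.
#' @return an \code{imaging_spec}.
#' @export
noiseless_imaging <- function() {
  imaging_spec(psf_sigma_um = c(0, 0, 0), photon_scale = Inf,
               read_noise_sd = 0, background_level = 0)
}

# Rotate unit vector d by angle a (radians) towards the direction at azimuth
# phi in the plane perpendicular to d.
rotate_towards <- function(d, a, phi) {
  # orthonormal basis perpendicular to d
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  v <- cos(a) * d + sin(a) * (cos(phi) * e1 + sin(phi) * e2)
  v / sqrt(sum(v^2))
}

#' Generate a branching vascular tree phantom (topology and radii only)
#'
#' Grows a rooted tree of straight polyline segments inside the physical
#' domain. Radii decay per generation by \code{radius_decay} and are floored
#' at \code{radius_min_um}, so radius is monotonically non-increasing along
#' any root-to-leaf path. Segments are clipped at the domain boundary. The
#' result is fully reproducible from \code{rng_seed}.
#'
#' @param spec a \code{\link{tree_spec}}.
#' @return an object of class \code{phantom_truth} holding the skeleton
#'   (nodes with parent pointers), per-point radii along each edge polyline,
#'   and empty occlusion annotations (all edges functional).
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  ds <- spec$domain_size_um
  seg_mu <- spec$segment_length_um[1]
  if (ds[1] < seg_mu * 0.5)
    stop(sprintf("domain x-extent %.1f um too small for one root segment (mean length %.1f um)",
                 ds[1], seg_mu))
  if (min(ds) < 4 * spec$radius_root_um)
    stop(sprintf("domain extent %.1f um too small for root caliber %.1f um",
                 min(ds), spec$radius_root_um))

  with_seed(spec$rng_seed, {
    nodes <- list()   # each: id, parent, x, y, z, radius, level
    nid <- 0L
    margin <- spec$radius_root_um + 1
    add_node <- function(parent, pos, radius, level) {
      nid <<- nid + 1L
      nodes[[nid]] <<- list(id = nid, parent = parent,
                            x = pos[1], y = pos[2], z = pos[3],
                            radius = radius, level = level)
      nid
    }
    clip_to_domain <- function(p0, p1, m) {
      # shrink segment p0->p1 so that p1 stays >= m from every face
      d <- p1 - p0
      tmax <- 1
      for (a in 1:3) {
        if (d[a] > 0) tmax <- min(tmax, (ds[a] - m - p0[a]) / d[a])
        if (d[a] < 0) tmax <- min(tmax, (m - p0[a]) / d[a])
      }
      if (!is.finite(tmax) || tmax <= 0) return(NULL)
      p0 + min(1, tmax) * d
    }
    # occupancy cloud for collision avoidance: segments of distinct branches
    # must not fuse (crossing tubes would merge into one mask component)
    cloud_pts <- matrix(numeric(0), ncol = 3)
    cloud_r <- numeric(0)
    seg_samples <- function(p0, p1) {
      L <- sqrt(sum((p1 - p0)^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(L / 2) + 1L))
      cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]),
            p0[3] + t * (p1[3] - p0[3]))
    }
    collides <- function(p0, p1, r, clearance = 2) {
      if (nrow(cloud_pts) == 0) return(FALSE)
      smp <- seg_samples(p0, p1)
      # ignore the junction zone around the segment start
      d0_new <- sqrt(rowSums(sweep(smp, 2, p0)^2))
      d0_old <- sqrt(rowSums(sweep(cloud_pts, 2, p0)^2))
      keep_new <- d0_new > 6
      keep_old <- d0_old > 6
      if (!any(keep_new) || !any(keep_old)) return(FALSE)
      smp <- smp[keep_new, , drop = FALSE]
      old <- cloud_pts[keep_old, , drop = FALSE]
      oldr <- cloud_r[keep_old]
      for (i in seq_len(nrow(smp))) {
        d <- sqrt(rowSums(sweep(old, 2, smp[i, ])^2))
        if (any(d < oldr + r + clearance)) return(TRUE)
      }
      FALSE
    }
    grow <- function(parent_id, pos, dir, level) {
      if (level > spec$branch_levels) return(invisible(NULL))
      r <- max(spec$radius_min_um, spec$radius_root_um * spec$radius_decay^(level - 1))
      len <- max(5, stats::rnorm(1, spec$segment_length_um[1], spec$segment_length_um[2]))
      m <- r + 1
      p1 <- NULL
      for (try in 1:6) {
        cand <- clip_to_domain(pos, pos + dir * len, m)
        if (!is.null(cand) && sqrt(sum((cand - pos)^2)) >= 4 &&
            !collides(pos, cand, r)) { p1 <- cand; break }
        # re-aim and retry
        dir <- rotate_towards(dir, stats::runif(1, 10, 35) * pi / 180,
                              stats::runif(1, 0, 2 * pi))
      }
      if (is.null(p1)) return(invisible(NULL))
      child <- add_node(parent_id, p1, r, level)
      smp <- seg_samples(pos, p1)
      cloud_pts <<- rbind(cloud_pts, smp)
      cloud_r <<- c(cloud_r, rep(r, nrow(smp)))
      if (level < spec$branch_levels) {
        a1 <- abs(stats::rnorm(1, spec$branch_angle_deg[1], spec$branch_angle_deg[2])) * pi / 180
        a2 <- abs(stats::rnorm(1, spec$branch_angle_deg[1], spec$branch_angle_deg[2])) * pi / 180
        phi <- stats::runif(1, 0, 2 * pi)
        nd <- (p1 - pos) / sqrt(sum((p1 - pos)^2))
        grow(child, p1, rotate_towards(nd, a1, phi), level + 1L)
        grow(child, p1, rotate_towards(nd, a2, phi + pi), level + 1L)
      }
      invisible(NULL)
    }
    for (ri in seq_len(spec$n_roots)) {
      y0 <- ds[2] * (ri - 0.5) / spec$n_roots + stats::rnorm(1, 0, ds[2] * 0.05)
      y0 <- min(max(y0, margin), ds[2] - margin)
      z0 <- min(max(ds[3] / 2 + stats::rnorm(1, 0, ds[3] * 0.1), margin), ds[3] - margin)
      root <- add_node(NA_integer_, c(0, y0, z0), spec$radius_root_um, 0L)
      tilt <- stats::runif(1, 0, 12 * pi / 180)
      grow(root, c(0, y0, z0), rotate_towards(c(1, 0, 0), tilt, stats::runif(1, 0, 2 * pi)), 1L)
    }
    nodes_df <- do.call(rbind, lapply(nodes, function(n)
      data.frame(id = n$id, parent = n$parent, x = n$x, y = n$y, z = n$z,
                 radius_um = n$radius, level = n$level)))
    truth <- build_truth(spec, nodes_df)
    truth
  })
}

# Subdivide each straight parent->child segment into ~2 um steps and attach
# linearly interpolated radii; assemble the phantom_truth container.
build_truth <- function(spec, nodes_df) {
  edge_ids <- nodes_df$id[!is.na(nodes_df$parent)]
  edge_points <- list()
  lens <- numeric(length(edge_ids))
  for (i in seq_along(edge_ids)) {
    e <- edge_ids[i]
    child <- nodes_df[nodes_df$id == e, ]
    par <- nodes_df[nodes_df$id == child$parent, ]
    p0 <- c(par$x, par$y, par$z); p1 <- c(child$x, child$y, child$z)
    L <- sqrt(sum((p1 - p0)^2))
    nstep <- max(2L, ceiling(L / 2) + 1L)
    t <- seq(0, 1, length.out = nstep)
    pts <- cbind(p0[1] + t * (p1[1] - p0[1]),
                 p0[2] + t * (p1[2] - p0[2]),
                 p0[3] + t * (p1[3] - p0[3]))
    r <- par$radius_um + t * (child$radius_um - par$radius_um)
    edge_points[[as.character(e)]] <- list(pts = pts, r = r)
    lens[i] <- L
  }
  edges_df <- data.frame(id = edge_ids,
                         parent_node = nodes_df$parent[match(edge_ids, nodes_df$id)],
                         level = nodes_df$level[match(edge_ids, nodes_df$id)],
                         length_um = lens)
  labels <- stats::setNames(rep("functional", length(edge_ids)), as.character(edge_ids))
  structure(list(tree_spec = spec,
                 nodes = nodes_df,
                 edges = edges_df,
                 edge_points = edge_points,
                 edge_labels = labels,
                 blockage_points = data.frame(x = numeric(0), y = numeric(0),
                                              z = numeric(0), entry_edge = integer(0)),
                 narrowing_sites = data.frame(x = numeric(0), y = numeric(0),
                                              z = numeric(0),
                                              true_min_diameter_um = numeric(0)),
                 cells = data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                                    type = character(0), intravascular = logical(0),
                                    radius_um = numeric(0)),
                 asma_edges = integer(0),
                 occlusion_spec = NULL),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d nodes, %d edges (%.0f um total), %d occluded, %d blockage points, %d cells\n",
              nrow(x$nodes), nrow(x$edges), truth_total_length(x),
              sum(x$edge_labels == "occluded"), nrow(x$blockage_points),
              nrow(x$cells)))
  invisible(x)
}

# Edge ids of the downstream subtree rooted at edge e (inclusive).
subtree_edges <- function(truth, e) {
  children_of <- split(truth$edges$id, truth$edges$parent_node)
  out <- integer(0)
  queue <- e
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    out <- c(out, cur)
    kids <- children_of[[as.character(cur)]]  # edges whose parent node is cur's child node
    if (!is.null(kids)) queue <- c(queue, kids)
  }
  out
}

#' Apply occlusion, narrowing and cell placement to a tree phantom
#'
#' Selects disjoint subtrees to occlude (a seeded priority order over all
#' edges, accepted greedily while skipping any subtree that overlaps one
#' already chosen, until \code{round(fraction * n_edges)} are chosen), places
#' one blockage point at the upstream end of each chosen entry edge, dips the
#' local radius by \code{narrowing_depth} around each blockage point, assigns
#' alpha-SMA to thick edges, and places intravascular neutrophils immediately
#' downstream of a fraction of blockage points plus extravascular
#' perivascular nuclei.
#'
#' Occlusion is expressed only through edge labels (the functional channel
#' omits occluded edges); geometry is never removed from the existing channel.
#'
#' @param truth a \code{phantom_truth} from \code{\link{generate_tree}}.
#' @param spec an \code{\link{occlusion_spec}}.
#' @return the annotated \code{phantom_truth}.
#' @export
apply_occlusion <- function(truth, spec) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(spec, "occlusion_spec"))
  seed <- if (is.null(spec$rng_seed)) truth$tree_spec$rng_seed + 1000L else spec$rng_seed
  truth$occlusion_spec <- spec

  # alpha-SMA: edges whose mean radius exceeds the arteriole caliber threshold
  mean_r <- vapply(truth$edge_points, function(ep) mean(ep$r), numeric(1))
  truth$asma_edges <- truth$edges$id[mean_r[as.character(truth$edges$id)] >=
                                       spec$asma_radius_threshold_um]

  n_edges <- nrow(truth$edges)

  with_seed(seed, {
    if (spec$blocked_subtree_fraction > 0 && n_edges > 0) {
      # maximal disjoint-subtree decomposition induced by the seeded priority:
      # accept candidates greedily, skipping any subtree overlapping one
      # already accepted; the blocked fraction then selects a nested prefix,
      # so increasing the fraction strictly grows the occluded set.
      # candidate entry edges exclude the root trunks: after recanalization
      # the feeding artery is perfused and obstruction sits in downstream
      # microvessels, and a root-edge block would start at the volume face
      # where no functional-to-occluded transition exists to detect
      priority <- sample(truth$edges$id[truth$edges$level >= 2])
      accepted <- integer(0)
      acc_subs <- list()
      blocked_all <- integer(0)
      blocked_nodes <- integer(0)
      sub_cloud <- function(sub) {
        pts <- do.call(rbind, lapply(as.character(sub), function(id)
          truth$edge_points[[id]]$pts))
        r <- unlist(lapply(as.character(sub), function(id) truth$edge_points[[id]]$r))
        list(pts = pts, r = r)
      }
      # full-tree occupancy (point, radius, owning edge) for contact checks
      tree_pts <- do.call(rbind, lapply(as.character(truth$edges$id), function(id)
        truth$edge_points[[id]]$pts))
      tree_r <- unlist(lapply(as.character(truth$edges$id), function(id)
        truth$edge_points[[id]]$r))
      tree_edge <- rep(truth$edges$id, vapply(as.character(truth$edges$id),
        function(id) nrow(truth$edge_points[[id]]$pts), integer(1)))
      # TRUE if the subtree's tubes come within mask-closing range of any
      # tube outside itself anywhere except its own entry junction: such a
      # near-contact welds in the segmented mask and fakes a second
      # functional contact of the occluded component (4 um clears the
      # closing diameter of the default segmentation)
      touches_outside <- function(sub, e) {
        pe <- truth$edges$parent_node[truth$edges$id == e]
        jn <- truth$nodes[truth$nodes$id == pe, ]
        jpos <- c(jn$x, jn$y, jn$z)
        outside <- !(tree_edge %in% c(sub, pe))
        # ignore the junction neighborhood around the entry
        outside <- outside & sqrt(rowSums(sweep(tree_pts, 2, jpos)^2)) > 2 * jn$radius_um + 4
        if (!any(outside)) return(FALSE)
        op <- tree_pts[outside, , drop = FALSE]
        orr <- tree_r[outside]
        cl <- sub_cloud(sub)
        for (i in seq_len(nrow(cl$pts))) {
          d <- sqrt(rowSums(sweep(op, 2, cl$pts[i, ])^2))
          if (any(d < orr + cl$r[i] + 4)) return(TRUE)
        }
        FALSE
      }
      chosen_cloud <- NULL
      for (e in priority) {
        sub <- subtree_edges(truth, e)
        # a blocked subtree must be long enough to resolve as a vessel
        # segment; boundary-clipped stubs below the capillary segment scale
        # are not candidates
        if (sum(vapply(truth$edge_points[as.character(sub)], edge_arc_length,
                       numeric(1))) < 12) next
        # the entry edge must clear its parent junction tube, or the
        # functional-to-occluded transition is invisible in the image
        pr <- truth$nodes$radius_um[truth$nodes$id ==
                truth$edges$parent_node[truth$edges$id == e]]
        if (edge_arc_length(truth$edge_points[[as.character(e)]]) <
            2 * pr + 4) next
        if (touches_outside(sub, e)) next
        # disjointness is topological and spatial: two blocked subtrees that
        # touch at a junction or whose tubes pass within a clearance of each
        # other would render as one fused occluded component, breaking the
        # one-blockage-point-per-subtree correspondence
        snodes <- unique(c(truth$edges$parent_node[match(sub, truth$edges$id)], sub))
        if (length(intersect(sub, blocked_all)) > 0) next
        if (length(intersect(snodes, blocked_nodes)) > 0) next
        cl <- sub_cloud(sub)
        if (!is.null(chosen_cloud)) {
          near <- FALSE
          for (i in seq_len(nrow(cl$pts))) {
            d <- sqrt(rowSums(sweep(chosen_cloud$pts, 2, cl$pts[i, ])^2))
            if (any(d < chosen_cloud$r + cl$r[i] + 8)) { near <- TRUE; break }
          }
          if (near) next
        }
        accepted <- c(accepted, e)
        acc_subs[[length(acc_subs) + 1]] <- sub
        blocked_all <- c(blocked_all, sub)
        blocked_nodes <- c(blocked_nodes, snodes)
        chosen_cloud <- if (is.null(chosen_cloud)) cl
          else list(pts = rbind(chosen_cloud$pts, cl$pts), r = c(chosen_cloud$r, cl$r))
      }
      M <- length(accepted)
      k <- min(M, max(1L, round(spec$blocked_subtree_fraction * M)))
      chosen <- accepted[seq_len(k)]
      blocked <- unlist(acc_subs[seq_len(k)])
      truth$edge_labels[as.character(blocked)] <- "occluded"

      bp <- do.call(rbind, lapply(chosen, function(e) {
        pn <- truth$edges$parent_node[truth$edges$id == e]
        nd <- truth$nodes[truth$nodes$id == pn, ]
        data.frame(x = nd$x, y = nd$y, z = nd$z, entry_edge = e)
      }))
      truth$blockage_points <- bp[order(bp$x, bp$y, bp$z), , drop = FALSE]
      rownames(truth$blockage_points) <- NULL

      # focal narrowing: tent-shaped radius dip centred at each blockage point,
      # applied along the entry edge and the tail of its parent edge
      ns <- list()
      for (j in seq_len(nrow(truth$blockage_points))) {
        b <- truth$blockage_points[j, ]
        e <- b$entry_edge
        r0 <- truth$edge_points[[as.character(e)]]$r[1]
        affected <- c(e, truth$edges$id[truth$edges$id ==
                        truth$nodes$parent[truth$nodes$id == truth$edges$parent_node[truth$edges$id == e]]])
        for (ae in truth$edges$id) {
          ep <- truth$edge_points[[as.character(ae)]]
          d <- sqrt((ep$pts[, 1] - b$x)^2 + (ep$pts[, 2] - b$y)^2 + (ep$pts[, 3] - b$z)^2)
          w <- pmax(0, 1 - d / spec$narrowing_halfwidth_um)
          if (any(w > 0)) {
            ep$r <- ep$r * (1 - spec$narrowing_depth * w)
            truth$edge_points[[as.character(ae)]] <- ep
          }
        }
        ns[[j]] <- data.frame(x = b$x, y = b$y, z = b$z,
                              true_min_diameter_um = 2 * r0 * (1 - spec$narrowing_depth))
      }
      truth$narrowing_sites <- do.call(rbind, ns)

      # neutrophils immediately downstream of a fraction of blockage points
      nbp <- nrow(truth$blockage_points)
      n_neut <- round(spec$neutrophil_at_blockage_fraction * nbp)
      cells <- list()
      if (n_neut > 0) {
        pick <- sample(seq_len(nbp))[seq_len(n_neut)]
        for (j in pick) {
          e <- truth$blockage_points$entry_edge[j]
          ep <- truth$edge_points[[as.character(e)]]
          arc <- c(0, cumsum(sqrt(rowSums(diff(ep$pts)^2))))
          target <- min(max(arc), spec$narrowing_halfwidth_um + spec$neutrophil_radius_um)
          i0 <- which.min(abs(arc - target))
          cells[[length(cells) + 1]] <- data.frame(
            x = ep$pts[i0, 1], y = ep$pts[i0, 2], z = ep$pts[i0, 3],
            type = "neutrophil", intravascular = TRUE,
            radius_um = spec$neutrophil_radius_um)
        }
      }
      # perivascular nuclei: offset outside the lumen at random edge points
      if (spec$n_perivascular_nuclei > 0) {
        for (j in seq_len(spec$n_perivascular_nuclei)) {
          e <- sample(truth$edges$id, 1)
          ep <- truth$edge_points[[as.character(e)]]
          i0 <- sample(nrow(ep$pts), 1)
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          pos <- ep$pts[i0, ] + u * (ep$r[i0] + 3)
          pos <- pmin(pmax(pos, 1), truth$tree_spec$domain_size_um - 1)
          cells[[length(cells) + 1]] <- data.frame(
            x = pos[1], y = pos[2], z = pos[3],
            type = "perivascular_nucleus", intravascular = FALSE, radius_um = 2.5)
        }
      }
      if (length(cells)) truth$cells <- do.call(rbind, cells)
    }
    truth
  })
}

# ---- truth summaries -------------------------------------------------------

edge_arc_length <- function(ep) sum(sqrt(rowSums(diff(ep$pts)^2)))

edge_tube_volume <- function(ep) {
  ds <- sqrt(rowSums(diff(ep$pts)^2))
  rmid <- (ep$r[-1] + ep$r[-length(ep$r)]) / 2
  sum(pi * rmid^2 * ds)
}

#' Ground-truth length and volume summaries of a phantom
#'
#' @param truth a \code{phantom_truth}.
#' @return a list with total/occluded length (um), tube volume (um^3) and
#'   the occluded length and volume fractions.
#' @export
truth_summary <- function(truth) {
  ids <- as.character(truth$edges$id)
  L <- vapply(truth$edge_points[ids], edge_arc_length, numeric(1))
  V <- vapply(truth$edge_points[ids], edge_tube_volume, numeric(1))
  occ <- truth$edge_labels[ids] == "occluded"
  list(total_length_um = sum(L),
       occluded_length_um = sum(L[occ]),
       total_volume_um3 = sum(V),
       occluded_volume_um3 = sum(V[occ]),
       occluded_length_fraction = if (sum(L) > 0) sum(L[occ]) / sum(L) else 0,
       occluded_volume_fraction = if (sum(V) > 0) sum(V[occ]) / sum(V) else 0)
}

truth_total_length <- function(truth) truth_summary(truth)$total_length_um

#' Render the phantom truth into co-registered multi-channel image volumes
#'
#' Paints each channel on one voxel grid: \code{existing} draws all edges as
#' filled tubes of local radius, \code{functional} only functional edges,
#' \code{asma} the alpha-SMA edges, \code{neutrophil} neutrophil spheres and
#' \code{nucleus} the nuclei of all cells. Each channel is then blurred by
#' the PSF, scaled, and degraded with Poisson shot noise, Gaussian read noise
#' and constant background. Noise is reproducible from the seed.
#'
#' @param truth an annotated \code{phantom_truth}.
#' @param img an \code{\link{imaging_spec}}.
#' @param channels which channels to render.
#' @return named list of \code{\link{image_volume}} objects.
#' @export
render_channels <- function(truth, img = imaging_spec(),
                            channels = c("existing", "functional", "asma",
                                         "neutrophil", "nucleus")) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(img, "imaging_spec"))
  ts <- truth$tree_spec
  vs <- ts$voxel_size_um
  if (max(vs) > ts$radius_min_um + 1e-9)
    stop(sprintf("voxel size %.2f um exceeds the minimum capillary radius %.2f um; capillaries would be unresolvable -- reduce voxel_size_um or raise radius_min_um",
                 max(vs), ts$radius_min_um))
  dims <- pmax(as.integer(round(ts$domain_size_um / vs)), 1L)

  segs_of <- function(ids) {
    p0 <- list(); p1 <- list(); r0 <- c(); r1 <- c()
    for (e in ids) {
      ep <- truth$edge_points[[as.character(e)]]
      n <- nrow(ep$pts)
      p0[[length(p0) + 1]] <- ep$pts[-n, , drop = FALSE]
      p1[[length(p1) + 1]] <- ep$pts[-1, , drop = FALSE]
      r0 <- c(r0, ep$r[-n]); r1 <- c(r1, ep$r[-1])
    }
    list(p0 = do.call(rbind, p0), p1 = do.call(rbind, p1), r0 = r0, r1 = r1)
  }
  paint_edges <- function(ids) {
    if (length(ids) == 0)
      return(array(0, dim = dims))
    s <- segs_of(ids)
    array(cpp_paint_capsules(dims, vs, s$p0, s$p1, s$r0, s$r1), dim = dims)
  }
  paint_cells <- function(cells, radius_scale = 1) {
    if (nrow(cells) == 0) return(array(0, dim = dims))
    array(cpp_paint_spheres(dims, vs, as.matrix(cells[, c("x", "y", "z")]),
                            cells$radius_um * radius_scale), dim = dims)
  }

  ids <- truth$edges$id
  clean <- list()
  for (ch in channels) {
    clean[[ch]] <- switch(ch,
      existing = paint_edges(ids),
      functional = paint_edges(ids[truth$edge_labels[as.character(ids)] == "functional"]),
      asma = paint_edges(intersect(ids, truth$asma_edges)),
      neutrophil = paint_cells(truth$cells[truth$cells$type == "neutrophil", , drop = FALSE]),
      nucleus = {
        neu <- truth$cells[truth$cells$type == "neutrophil", , drop = FALSE]
        oth <- truth$cells[truth$cells$type != "neutrophil", , drop = FALSE]
        # a neutrophil's nucleus is smaller than its marker footprint
        pmax(paint_cells(neu, radius_scale = 0.7), paint_cells(oth))
      })
  }

  seed <- if (is.null(img$rng_seed)) ts$rng_seed + 2000L else img$rng_seed
  gains <- rep_len(img$channel_gains, length(channels))
  names(gains) <- channels
  out <- list()
  with_seed(seed, {
    for (ch in channels) {
      sig <- clean[[ch]] * gains[[ch]]
      svox <- img$psf_sigma_um / vs
      if (any(svox > 0)) sig <- array(cpp_gaussian_blur3d(sig, svox), dim = dims)
      sig <- sig + img$background_level
      if (is.finite(img$photon_scale)) {
        sig <- array(stats::rpois(length(sig), lambda = pmax(sig, 0) * img$photon_scale) /
                       img$photon_scale, dim = dims)
      }
      if (img$read_noise_sd > 0)
        sig <- sig + array(stats::rnorm(length(sig), 0, img$read_noise_sd), dim = dims)
      sig[sig < 0] <- 0
      out[[ch]] <- image_volume(sig, vs, channel_role = ch)
    }
  })
  out
}

#' Convert phantom ground truth to a centerline vessel graph
#'
#' Builds a \code{\link{vessel_graph}} directly from the true skeleton
#' (polylines, per-point radii, perfusion labels), bypassing image processing.
#' Used as the oracle arm of recovery tests and available for noiseless
#' analyses.
#'
#' @param truth a \code{phantom_truth}.
#' @return a labeled \code{vessel_graph}.
#' @export
truth_graph <- function(truth) {
  edges <- lapply(seq_len(nrow(truth$edges)), function(i) {
    e <- truth$edges$id[i]
    ep <- truth$edge_points[[as.character(e)]]
    list(id = i,
         from = truth$edges$parent_node[i],
         to = e,
         points = ep$pts,
         radius_um = ep$r,
         length_um = edge_arc_length(ep),
         mean_radius_um = mean(ep$r),
         label = unname(truth$edge_labels[as.character(e)]),
         asma = e %in% truth$asma_edges)
  })
  nodes <- truth$nodes[, c("id", "x", "y", "z")]
  vessel_graph(nodes = nodes, edges = edges,
               voxel_size_um = truth$tree_spec$voxel_size_um)
}
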
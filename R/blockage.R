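#' Detect blockage points at functional-to-occluded transitions
#'
#' Finds the maximal connected components of occluded edges and places one
#' blockage point per component at the location where it abuts a functional
#' edge. When per-edge coverage samples are available (from
#' \code{\link{classify_edges}}), the point is refined sub-edge: walking away
#' from the abutting junction along the entry edge, the point is the last
#' centerline sample still covered by the functional mask. Occluded
#' components touching no functional edge (orphans at the volume boundary)
#' yield a point at their lexicographically smallest endpoint, flagged
#' \code{origin = "orphan"}. Output ordering is deterministic by coordinate.
#'
#' @param graph a labeled \code{\link{vessel_graph}}.
#' @param gap_tolerance_um occluded components whose centerlines approach
#'   within this distance are treated as one (an imaging gap across a severe
#'   constriction can sever one occluded subtree into fragments).
#' @param min_component_length_um occluded components with less total
#'   centerline length than this are ignored as noise fragments.
#' @return a data.frame of class \code{blockage_points} with columns
#'   x, y, z (um), host_edge, component_id, origin, vessel_type,
#'   local_min_diameter_um, upstream_diameter_um, narrowing_index,
#'   neutrophil_within_radius. Zero rows when no edge is occluded.
#' @export
detect_blockage_points <- function(graph, gap_tolerance_um = 4,
                                   min_component_length_um = 8) {
  labs <- edge_labels(graph)
  if (any(is.na(labs))) stop("all edges must be labeled; run classify_edges() first")
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      host_edge = integer(0), component_id = integer(0),
                      origin = character(0), vessel_type = character(0),
                      local_min_diameter_um = numeric(0),
                      upstream_diameter_um = numeric(0),
                      narrowing_index = numeric(0),
                      neutrophil_within_radius = logical(0))
  class(empty) <- c("blockage_points", "data.frame")
  occ_idx <- which(labs == "occluded")
  if (length(occ_idx) == 0) return(empty)

  # components of the occluded subgraph
  el <- t(vapply(graph$edges[occ_idx], function(e)
    c(as.character(e$from), as.character(e$to)), character(2)))
  og <- igraph::graph_from_edgelist(el, directed = FALSE)
  comp <- igraph::components(og)$membership
  node_comp <- stats::setNames(comp, igraph::V(og)$name)
  # cluster components separated only by a small physical gap; a fragment
  # with no functional contact at all (severed downstream piece) may rejoin
  # its parent component across a wider gap
  fun_node_set <- unique(unlist(lapply(graph$edges[labs == "functional"],
                                       function(e) c(e$from, e$to))))
  if (max(comp) > 1 && gap_tolerance_um > 0) {
    ncomp <- max(comp)
    cpts <- lapply(seq_len(ncomp), function(ci) {
      cn <- as.integer(names(node_comp)[node_comp == ci])
      idx <- occ_idx[vapply(graph$edges[occ_idx], function(e)
        (e$from %in% cn) || (e$to %in% cn), logical(1))]
      do.call(rbind, lapply(graph$edges[idx], function(e)
        resample_polyline(e$points, 2)))
    })
    has_abut <- vapply(seq_len(ncomp), function(ci) {
      cn <- as.integer(names(node_comp)[node_comp == ci])
      length(intersect(cn, fun_node_set)) > 0
    }, logical(1))
    parent <- seq_len(ncomp)
    findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_len(ncomp - 1)) for (b in (a + 1):ncomp) {
      if (findp(a) == findp(b)) next
      dmin <- sqrt(min(vapply(seq_len(nrow(cpts[[a]])), function(i)
        min(rowSums(sweep(cpts[[b]], 2, cpts[[a]][i, ])^2)), numeric(1))))
      tol <- if (has_abut[a] && has_abut[b]) gap_tolerance_um
             else 2.5 * gap_tolerance_um
      if (dmin <= tol) parent[findp(b)] <- findp(a)
    }
    relab <- vapply(seq_len(ncomp), findp, integer(1))
    relab <- match(relab, unique(relab))
    node_comp[] <- relab[node_comp]
  }

  # nodes touched by functional edges
  fun_nodes <- unique(unlist(lapply(graph$edges[labs == "functional"],
                                    function(e) c(e$from, e$to))))
  # functional centerline points, for anchoring orphan components at their
  # closest approach to the perfused network (a severed constriction leaves
  # the occluded subtree disconnected right at the blockage)
  fun_pts <- do.call(rbind, lapply(graph$edges[labs == "functional"],
                                   function(e) e$points))
  node_xyz <- function(id) {
    r <- graph$nodes[graph$nodes$id == id, ]
    c(r$x, r$y, r$z)
  }
  out <- list()
  for (ci in seq_len(max(node_comp))) {
    cnodes <- as.integer(names(node_comp)[node_comp == ci])
    cedges <- occ_idx[vapply(graph$edges[occ_idx], function(e)
      (e$from %in% cnodes) || (e$to %in% cnodes), logical(1))]
    if (sum(vapply(graph$edges[cedges], `[[`, numeric(1), "length_um")) <
        min_component_length_um) next
    abut <- intersect(cnodes, fun_nodes)
    if (length(abut) == 0) {
      # orphan: no functional contact in the graph
      endpts <- do.call(rbind, lapply(cnodes, node_xyz))
      pos <- NULL
      host <- cedges[1]
      if (!is.null(fun_pts) && nrow(fun_pts) > 0) {
        # closest approach between the fragment's centerline and the
        # perfused network; when nearby, the blockage sits inside the
        # imaging gap between the two stumps, so take the gap midpoint
        best <- c(Inf, NA, NA)
        for (ei in cedges) {
          cp <- resample_polyline(graph$edges[[ei]]$points, 1)
          for (i in seq_len(nrow(cp))) {
            d2f <- rowSums(sweep(fun_pts, 2, cp[i, ])^2)
            j <- which.min(d2f)
            if (d2f[j] < best[1]) { best <- c(d2f[j], i, j); bce <- ei; bcp <- cp }
          }
        }
        if (sqrt(best[1]) <= 12) {
          pos <- (bcp[best[2], ] + fun_pts[best[3], ]) / 2
          host <- bce
        }
      }
      if (is.null(pos)) {
        o <- order(endpts[, 1], endpts[, 2], endpts[, 3])[1]
        pos <- endpts[o, ]
        host <- cedges[vapply(graph$edges[cedges], function(e)
          e$from == cnodes[o] || e$to == cnodes[o], logical(1))][1]
      }
      out[[length(out) + 1]] <- data.frame(
        x = pos[1], y = pos[2], z = pos[3],
        host_edge = host, component_id = ci, origin = "orphan")
      next
    }
    # the true entry is the thickest occluded contact with the functional
    # network (radius decays root-to-leaf, so crossing-artifact contacts on
    # thin capillaries lose); ties broken by coordinate for determinism
    end_radius <- function(ei, node) {
      e <- graph$edges[[ei]]
      r <- if (e$from == node) e$radius_um[1] else e$radius_um[length(e$radius_um)]
      if (is.na(r)) e$mean_radius_um else r
    }
    axyz <- do.call(rbind, lapply(abut, node_xyz))
    arad <- vapply(abut, function(nd) {
      inc <- cedges[vapply(graph$edges[cedges], function(e)
        e$from == nd || e$to == nd, logical(1))]
      max(vapply(inc, end_radius, numeric(1), node = nd), na.rm = TRUE)
    }, numeric(1))
    ord <- order(-arad, axyz[, 1], axyz[, 2], axyz[, 3])
    junction <- abut[ord[1]]
    jpos <- node_xyz(junction)
    entry <- cedges[vapply(graph$edges[cedges], function(e)
      e$from == junction || e$to == junction, logical(1))]
    if (length(entry) > 1)
      entry <- entry[order(-vapply(entry, end_radius, numeric(1), node = junction))]
    entry <- entry[1]
    e <- graph$edges[[entry]]
    pos <- jpos
    cs <- e$coverage_samples
    if (!is.null(cs) && nrow(cs$points) >= 2) {
      pts <- cs$points; cov <- cs$covered
      # orient so the walk starts at the junction
      d1 <- sum((pts[1, ] - jpos)^2)
      dn <- sum((pts[nrow(pts), ] - jpos)^2)
      if (dn < d1) { pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]; cov <- rev(cov) }
      first_unc <- which(!cov)[1]
      if (!is.na(first_unc) && first_unc > 1) {
        # last covered sample, pulled back by the dilation slack plus half
        # the local tube radius (the parent lumen covers the entry edge's
        # first stretch even with no dilation)
        arc <- polyline_arc(pts)
        slack <- 0
        pp <- attr(graph, "perfusion_params")
        if (!is.null(pp)) slack <- pp$functional_dilation_um
        r_here <- e$radius_um[1]
        if (is.na(r_here)) r_here <- 0
        pos <- polyline_point_at(pts, max(0, arc[first_unc - 1L] - slack -
                                            0.5 * r_here))
      }
    }
    out[[length(out) + 1]] <- data.frame(
      x = pos[1], y = pos[2], z = pos[3],
      host_edge = entry, component_id = ci, origin = "junction")
  }
  res <- do.call(rbind, out)
  res <- res[order(res$x, res$y, res$z), , drop = FALSE]
  rownames(res) <- NULL
  res$vessel_type <- "unknown"
  res$local_min_diameter_um <- NA_real_
  res$upstream_diameter_um <- NA_real_
  res$narrowing_index <- NA_real_
  res$neutrophil_within_radius <- NA
  class(res) <- c("blockage_points", "data.frame")
  res
}

#' Classify blockage points as arteriolar or capillary via the alpha-SMA channel
#'
#' A point is arteriolar iff the host edge's centerline near the point is
#' covered by the alpha-SMA mask at a minimum fraction; capillary otherwise;
#' unknown when no alpha-SMA channel is supplied. The window runs from the
#' point into the host (occluded) vessel with a small standoff, so the
#' alpha-SMA tube of an arteriolar feeder at the junction does not bleed into
#' the classification of a capillary blockage.
#'
#' @param points a \code{blockage_points} data.frame.
#' @param graph the labeled \code{\link{vessel_graph}}.
#' @param asma_mask a \code{\link{vessel_mask}} of the alpha-SMA channel, or NULL.
#' @param tolerance_um centerline window half-length, micrometres (the
#'   one-sided window spans twice this).
#' @param coverage_tau minimum covered fraction to call arteriole.
#' @param dilation_um registration slack applied to the alpha-SMA mask.
#' @param standoff_um distance skipped next to the junction before sampling.
#' @return \code{points} with \code{vessel_type} filled.
#' @export
classify_vessel_type <- function(points, graph, asma_mask,
                                 tolerance_um = 5, coverage_tau = 0.5,
                                 dilation_um = 1, standoff_um = 3) {
  if (is.null(asma_mask)) {
    points$vessel_type <- "unknown"
    return(points)
  }
  m <- asma_mask$mask
  if (dilation_um > 0) m <- dilate_mask(m, dilation_um, asma_mask$voxel_size_um)
  for (i in seq_len(nrow(points))) {
    e <- graph$edges[[points$host_edge[i]]]
    arc <- polyline_arc(e$points)
    d2 <- rowSums(sweep(e$points, 2, c(points$x[i], points$y[i], points$z[i]))^2)
    s0 <- arc[which.min(d2)]
    # sample away from the junction end of the host edge
    away <- s0 < max(arc) / 2
    lo <- if (away) min(s0 + standoff_um, max(arc)) else max(0, s0 - standoff_um - 2 * tolerance_um)
    hi <- if (away) min(s0 + standoff_um + 2 * tolerance_um, max(arc)) else max(0, s0 - standoff_um)
    if (hi <= lo) { lo <- max(0, s0 - tolerance_um); hi <- min(max(arc), s0 + tolerance_um) }
    s <- seq(lo, hi, by = 1)
    pts <- t(vapply(s, function(si) polyline_point_at(e$points, si), numeric(3)))
    cov <- mean(mask_at_points(m, asma_mask$voxel_size_um, pts))
    points$vessel_type[i] <- if (cov >= coverage_tau) "arteriole" else "capillary"
  }
  points
}

#' Perpendicular normalized-intensity diameter profile (FWHM)
#'
#' Samples the image by trilinear interpolation along a line perpendicular to
#' the local centerline tangent, min-max normalizes the profile over its
#' window, and measures the full width at half maximum by linear
#' interpolation of the two half-maximum crossings bracketing the center.
#' Two orthogonal perpendicular directions are measured and averaged to
#' reduce anisotropy bias; both are reported. A z-dominant tangent triggers
#' a warning (axial PSF inflates the apparent width). Profiles exiting the
#' volume are shortened symmetrically with a warning; a flank without a
#' half-maximum crossing (or a constant window) leaves the FWHM undefined
#' and flags the profile.
#'
#' @param vol the \code{\link{image_volume}} to measure on (existing channel).
#' @param graph a \code{\link{vessel_graph}}.
#' @param edge_id edge index.
#' @param arc_um arc position along the edge, micrometres.
#' @param profile_length_um total profile length; default
#'   \code{max(6 * local radius, 10)}.
#' @param step_um sampling step; default half the smallest voxel size.
#' @return an object of class \code{diameter_profile}: positions, normalized
#'   intensities per direction, \code{fwhm_um} (mean of valid directions),
#'   per-direction FWHMs, the distance-transform cross-check diameter, and a
#'   \code{flagged} indicator.
#' @export
diameter_profile <- function(vol, graph, edge_id, arc_um,
                             profile_length_um = NULL, step_um = NULL) {
  e <- graph$edges[[edge_id]]
  arc <- polyline_arc(e$points)
  arc_um <- min(max(arc_um, 0), max(arc))
  center <- polyline_point_at(e$points, arc_um)
  tg <- polyline_tangent_at(e$points, arc_um)
  r_local <- stats::approx(arc, e$radius_um, xout = arc_um, rule = 2)$y
  if (is.na(r_local)) r_local <- e$mean_radius_um
  if (is.null(profile_length_um))
    profile_length_um <- max(6 * max(r_local, 1, na.rm = TRUE), 10)
  if (is.null(step_um)) step_um <- min(vol$voxel_size_um) / 2
  if (abs(tg[3]) > 0.9)
    warning("z-dominant tangent: axial PSF inflates the apparent FWHM")
  # deterministic orthogonal pair perpendicular to the tangent
  ref <- diag(3)[, which.min(abs(tg))]
  u <- ref - sum(ref * tg) * tg; u <- u / sqrt(sum(u^2))
  v <- c(tg[2] * u[3] - tg[3] * u[2],
         tg[3] * u[1] - tg[1] * u[3],
         tg[1] * u[2] - tg[2] * u[1])
  s <- seq(-profile_length_um / 2, profile_length_um / 2, by = step_um)
  measure_dir <- function(dirv) {
    pts <- cbind(center[1] + s * dirv[1], center[2] + s * dirv[2],
                 center[3] + s * dirv[3])
    y <- cpp_trilinear(vol$data, vol$voxel_size_um, pts)
    ss <- s
    if (anyNA(y)) {
      # shorten symmetrically to the largest NA-free window around the center
      ctr <- which.min(abs(ss))
      lo <- ctr; hi <- ctr
      while (lo > 1 && !is.na(y[lo - 1])) lo <- lo - 1
      while (hi < length(y) && !is.na(y[hi + 1])) hi <- hi + 1
      w <- min(ctr - lo, hi - ctr)
      keep <- (ctr - w):(ctr + w)
      warning("profile exits the volume: shortened symmetrically")
      ss <- ss[keep]; y <- y[keep]
    }
    rng <- range(y)
    if (!is.finite(diff(rng)) || diff(rng) < 1e-12)
      return(list(s = ss, y = rep(0, length(y)), fwhm = NA_real_, flagged = TRUE))
    yn <- (y - rng[1]) / diff(rng)
    ctr <- which.min(abs(ss))
    if (yn[ctr] < 0.5)
      return(list(s = ss, y = yn, fwhm = NA_real_, flagged = TRUE))
    cross <- function(idx_seq) {
      prev <- ctr
      for (i in idx_seq) {
        if (yn[i] < 0.5) {
          t <- (yn[prev] - 0.5) / (yn[prev] - yn[i])
          return(ss[prev] + t * (ss[i] - ss[prev]))
        }
        prev <- i
      }
      NA_real_
    }
    left <- if (ctr > 1) cross(seq(ctr - 1, 1)) else NA_real_
    right <- if (ctr < length(ss)) cross(seq(ctr + 1, length(ss))) else NA_real_
    if (is.na(left) || is.na(right))
      return(list(s = ss, y = yn, fwhm = NA_real_, flagged = TRUE))
    list(s = ss, y = yn, fwhm = right - left, flagged = FALSE)
  }
  m1 <- measure_dir(u); m2 <- measure_dir(v)
  fw <- c(m1$fwhm, m2$fwhm)
  structure(list(edge_id = edge_id, arc_um = arc_um, center_um = center,
                 tangent = tg, axes = list(u = u, v = v),
                 profiles = list(m1[c("s", "y")], m2[c("s", "y")]),
                 fwhm_each_um = fw,
                 fwhm_um = if (all(is.na(fw))) NA_real_ else mean(fw, na.rm = TRUE),
                 dt_diameter_um = 2 * r_local,
                 source_channel = vol$channel_role,
                 flagged = m1$flagged && m2$flagged),
            class = "diameter_profile")
}

#' @export
print.diameter_profile <- function(x, ...) {
  cat(sprintf("<diameter_profile> edge %d @ %.1f um: FWHM = %s um (DT cross-check %.2f um)%s\n",
              x$edge_id, x$arc_um,
              if (is.na(x$fwhm_um)) "undefined" else sprintf("%.2f", x$fwhm_um),
              x$dt_diameter_um, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Fill lumen-diameter fields of blockage points
#'
#' For each blockage point, measures the minimum FWHM diameter within a small
#' centerline window around the point (the local constriction) and a baseline
#' FWHM a configurable distance away from the point on the functional
#' (upstream) side of the junction, and derives the narrowing index
#' \code{1 - local_min / upstream}.
#'
#' @param points \code{blockage_points}.
#' @param vol the existing-channel \code{\link{image_volume}}.
#' @param graph the labeled \code{\link{vessel_graph}}.
#' @param window_um half-window scanned for the local minimum, um.
#' @param upstream_distance_um baseline distance from the point, um.
#' @return \code{points} with diameter fields filled.
#' @export
measure_blockage_diameters <- function(points, vol, graph,
                                       window_um = 5, upstream_distance_um = 20) {
  labs <- edge_labels(graph)
  for (i in seq_len(nrow(points))) {
    e <- graph$edges[[points$host_edge[i]]]
    arc <- polyline_arc(e$points)
    d2 <- rowSums(sweep(e$points, 2, c(points$x[i], points$y[i], points$z[i]))^2)
    s0 <- arc[which.min(d2)]
    scan <- seq(max(0, s0 - window_um), min(max(arc), s0 + window_um), by = 1)
    fw <- vapply(scan, function(si)
      suppressWarnings(diameter_profile(vol, graph, points$host_edge[i], si)$fwhm_um),
      numeric(1))
    if (!all(is.na(fw)))
      points$local_min_diameter_um[i] <- min(fw, na.rm = TRUE)
    # upstream baseline: on the adjacent functional edge, a fixed distance
    # from the shared junction
    up <- upstream_baseline(points[i, ], graph, labs, vol, upstream_distance_um)
    points$upstream_diameter_um[i] <- up
    if (!is.na(points$local_min_diameter_um[i]) && !is.na(up) && up > 0)
      points$narrowing_index[i] <- 1 - points$local_min_diameter_um[i] / up
  }
  points
}

upstream_baseline <- function(point, graph, labs, vol, dist_um) {
  e <- graph$edges[[point$host_edge]]
  # which end of the host edge is nearest the point: that's the junction side
  p <- c(point$x, point$y, point$z)
  ends <- rbind(e$points[1, ], e$points[nrow(e$points), ])
  jnode <- if (sum((ends[1, ] - p)^2) <= sum((ends[2, ] - p)^2)) e$from else e$to
  cand <- which(labs == "functional" & vapply(graph$edges, function(g)
    g$from == jnode || g$to == jnode, logical(1)))
  if (length(cand) == 0) return(NA_real_)
  # widest functional neighbor = the feeding vessel
  cand <- cand[order(-vapply(graph$edges[cand], `[[`, numeric(1), "mean_radius_um"))]
  fe <- graph$edges[[cand[1]]]
  arc <- polyline_arc(fe$points)
  s <- if (fe$from == jnode) min(dist_um, max(arc)) else max(0, max(arc) - dist_um)
  suppressWarnings(diameter_profile(vol, graph, cand[1], s)$fwhm_um)
}

#' Diameter frequency distribution over a labeled graph
#'
#' Samples perpendicular FWHM profiles every \code{sampling_step_um} along
#' (by default capillary-caliber) edges and bins the valid diameters into a
#' relative-frequency histogram (summing to 1).
#'
#' @param vol the \code{\link{image_volume}} measured on.
#' @param graph a \code{\link{vessel_graph}}.
#' @param region_mask optional region restriction (edge midpoint rule).
#' @param bin_width_um histogram bin width, micrometres.
#' @param sampling_step_um arc spacing of the profile samples.
#' @param max_mean_radius_um only edges at or below this mean radius are
#'   sampled (capillaries); NULL samples every edge.
#' @param labels restrict to edges with these perfusion labels (NULL = all).
#' @return a list of class \code{diameter_histogram}: \code{breaks_um},
#'   \code{rel_freq}, \code{fwhm_values_um}, \code{n_profiles},
#'   \code{mean_fwhm_um}. Zero valid profiles yield an empty histogram with
#'   a warning.
#' @export
diameter_distribution <- function(vol, graph, region_mask = NULL,
                                  bin_width_um = 0.5, sampling_step_um = 4,
                                  max_mean_radius_um = NULL, labels = NULL) {
  keep <- rep(TRUE, length(graph$edges))
  if (!is.null(region_mask)) {
    mids <- t(vapply(graph$edges, function(e)
      polyline_point_at(e$points, max(polyline_arc(e$points)) / 2), numeric(3)))
    keep <- mask_at_points(region_mask$mask, region_mask$voxel_size_um, mids)
  }
  if (!is.null(max_mean_radius_um))
    keep <- keep & vapply(graph$edges, `[[`, numeric(1), "mean_radius_um") <= max_mean_radius_um
  if (!is.null(labels)) {
    labs <- edge_labels(graph)
    keep <- keep & labs %in% labels
  }
  fw <- c()
  for (i in which(keep)) {
    L <- max(polyline_arc(graph$edges[[i]]$points))
    if (L <= 0) next
    for (s in seq(min(sampling_step_um / 2, L / 2), L, by = sampling_step_um)) {
      f <- suppressWarnings(diameter_profile(vol, graph, i, s)$fwhm_um)
      if (!is.na(f)) fw <- c(fw, f)
    }
  }
  if (length(fw) == 0) {
    warning("zero valid diameter profiles: empty histogram")
    return(structure(list(breaks_um = numeric(0), rel_freq = numeric(0),
                          fwhm_values_um = numeric(0), n_profiles = 0L,
                          mean_fwhm_um = NA_real_, bin_width_um = bin_width_um),
                     class = "diameter_histogram"))
  }
  breaks <- seq(0, (ceiling(max(fw) / bin_width_um) + 1) * bin_width_um,
                by = bin_width_um)
  h <- hist(fw, breaks = breaks, plot = FALSE)
  structure(list(breaks_um = breaks, rel_freq = h$counts / sum(h$counts),
                 fwhm_values_um = fw, n_profiles = length(fw),
                 mean_fwhm_um = mean(fw), bin_width_um = bin_width_um),
            class = "diameter_histogram")
}

#' Average per-sample diameter histograms into a group histogram
#'
#' Group aggregation is the mean of per-sample relative-frequency histograms
#' (each sample weighted equally, matching a per-animal mean +/- SEM
#' structure), on a common set of bins.
#'
#' @param hists list of \code{diameter_histogram} objects.
#' @return a \code{diameter_histogram} with the pooled breaks, the mean
#'   relative frequencies, and the across-sample SEM per bin.
#' @export
aggregate_diameter_histograms <- function(hists) {
  hists <- hists[vapply(hists, function(h) h$n_profiles > 0, logical(1))]
  if (length(hists) == 0) stop("no non-empty histograms to aggregate")
  bw <- hists[[1]]$bin_width_um
  maxb <- max(vapply(hists, function(h) max(h$breaks_um), numeric(1)))
  breaks <- seq(0, maxb, by = bw)
  freq <- vapply(hists, function(h) {
    f <- numeric(length(breaks) - 1)
    f[seq_along(h$rel_freq)] <- h$rel_freq
    f
  }, numeric(length(breaks) - 1))
  freq <- matrix(freq, nrow = length(breaks) - 1)
  structure(list(breaks_um = breaks,
                 rel_freq = rowMeans(freq),
                 sem = apply(freq, 1, stats::sd) / sqrt(ncol(freq)),
                 fwhm_values_um = unlist(lapply(hists, `[[`, "fwhm_values_um")),
                 n_profiles = sum(vapply(hists, `[[`, integer(1), "n_profiles")),
                 mean_fwhm_um = mean(vapply(hists, `[[`, numeric(1), "mean_fwhm_um")),
                 bin_width_um = bw),
            class = "diameter_histogram")
}
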
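#' Perfusion classification parameters
#'
#' Controls the discretization of the dual-label rule (a vessel labeled by
#' the pre-ischemia lectin but not the post-reperfusion lectin is occluded)
#' into a per-edge majority vote over centerline samples.
#'
#' @param coverage_tau minimum covered fraction of an edge's centerline
#'   samples for the edge to be called functional; in (0, 1].
#' @param sampling_step_um centerline sampling spacing, micrometres.
#' @param functional_dilation_um registration slack: the functional mask is
#'   dilated by this radius before sampling.
#' @return a list of class \code{perfusion_params}.
#' @export
perfusion_params <- function(coverage_tau = 0.5, sampling_step_um = 1,
                             functional_dilation_um = 2) {
  if (!(coverage_tau > 0 && coverage_tau <= 1))
    stop("coverage_tau must be in (0, 1]")
  if (sampling_step_um <= 0) stop("sampling_step_um must be positive")
  structure(list(coverage_tau = coverage_tau,
                 sampling_step_um = sampling_step_um,
                 functional_dilation_um = functional_dilation_um),
            class = "perfusion_params")
}

# Resample a polyline at fixed arc spacing (always includes both endpoints).
resample_polyline <- function(pts, step_um) {
  arc <- polyline_arc(pts)
  L <- max(arc)
  if (L <= 0) return(pts[1, , drop = FALSE])
  s <- unique(c(seq(0, L, by = step_um), L))
  t(vapply(s, function(si) polyline_point_at(pts, si), numeric(3)))
}

#' Classify every vessel edge as functional or occluded
#'
#' Samples each edge's centerline at \code{sampling_step_um} and tests each
#' sample against the (slack-dilated) functional mask; an edge is functional
#' iff its covered fraction is at least \code{coverage_tau}, occluded
#' otherwise — an operationalization of the dual-lectin definition of
#' occluded microvessels. Deterministic; per-edge coverage samples are kept
#' on the edge for downstream sub-edge blockage localization.
#'
#' @param graph a \code{\link{vessel_graph}} traced from the existing channel.
#' @param functional_mask a \code{\link{vessel_mask}} of the functional channel
#'   in the same physical frame.
#' @param params a \code{\link{perfusion_params}}.
#' @param split_transitions split an edge whose coverage switches between
#'   persistent covered and uncovered runs (each at least
#'   \code{min_run_um} long) at the transition, so a traced edge straddling
#'   a blockage is not forced into a single label.
#' @param min_run_um minimum run length treated as persistent, micrometres.
#' @return the graph with \code{label}, \code{coverage} (covered fraction) and
#'   \code{coverage_samples} set on every edge. An empty functional mask
#'   labels every edge occluded with a warning (total no-reflow).
#' @export
classify_edges <- function(graph, functional_mask, params = perfusion_params(),
                           split_transitions = TRUE, min_run_um = 6) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(functional_mask, "vessel_mask"))
  m <- functional_mask$mask
  if (!any(m)) warning("functional mask is empty: labeling every edge occluded")
  else if (params$functional_dilation_um > 0)
    m <- dilate_mask(m, params$functional_dilation_um, functional_mask$voxel_size_um)
  next_node <- if (nrow(graph$nodes)) max(graph$nodes$id) + 1L else 1L
  new_edges <- list()
  for (i in seq_along(graph$edges)) {
    e <- graph$edges[[i]]
    pieces <- list(e)
    if (split_transitions) {
      cut_arcs <- coverage_cut_arcs(e, m, functional_mask$voxel_size_um,
                                    params$sampling_step_um, min_run_um)
      if (length(cut_arcs)) {
        pieces <- list()
        arc <- polyline_arc(e$points)
        bounds <- c(0, cut_arcs, max(arc))
        prev_node <- e$from
        for (b in seq_len(length(bounds) - 1)) {
          sel <- which(arc >= bounds[b] - 1e-9 & arc <= bounds[b + 1] + 1e-9)
          if (length(sel) < 2) next
          pts <- e$points[sel, , drop = FALSE]
          last <- b == length(bounds) - 1
          to_node <- if (last) e$to else next_node
          if (!last) {
            graph$nodes <- rbind(graph$nodes,
              data.frame(id = next_node, x = pts[nrow(pts), 1],
                         y = pts[nrow(pts), 2], z = pts[nrow(pts), 3]))
            next_node <- next_node + 1L
          }
          pieces[[length(pieces) + 1]] <- list(
            id = NA_integer_, from = prev_node, to = to_node, points = pts,
            radius_um = e$radius_um[sel],
            length_um = sum(sqrt(rowSums(diff(pts)^2))),
            mean_radius_um = mean(e$radius_um[sel], na.rm = TRUE))
          prev_node <- to_node
        }
        if (length(pieces) == 0) pieces <- list(e)
      }
    }
    for (p in pieces) {
      pts <- resample_polyline(p$points, params$sampling_step_um)
      cov <- mask_at_points(m, functional_mask$voxel_size_um, pts)
      frac <- mean(cov)
      p$coverage <- frac
      p$coverage_samples <- list(points = pts, covered = cov)
      p$label <- if (frac >= params$coverage_tau) "functional" else "occluded"
      p$id <- length(new_edges) + 1L
      new_edges[[length(new_edges) + 1]] <- p
    }
  }
  graph$edges <- new_edges
  attr(graph, "perfusion_params") <- params
  graph
}

# Arc positions at which an edge's functional coverage switches between
# persistent runs; short runs are absorbed into their longer neighbors first.
coverage_cut_arcs <- function(e, mask, vs, step_um, min_run_um) {
  pts <- resample_polyline(e$points, step_um)
  if (nrow(pts) < 4) return(numeric(0))
  cov <- mask_at_points(mask, vs, pts)
  r <- rle(cov)
  min_samp <- max(2L, ceiling(min_run_um / step_um))
  while (length(r$lengths) > 1 && min(r$lengths) < min_samp) {
    k <- which.min(r$lengths)
    r$values[k] <- !r$values[k]
    r <- rle(inverse.rle(r))
  }
  if (length(r$lengths) < 2) return(numeric(0))
  arc <- polyline_arc(pts)
  cuts <- cumsum(r$lengths)
  cuts <- cuts[-length(cuts)]
  # cut midway between the last sample of one run and the first of the next
  (arc[cuts] + arc[cuts + 1]) / 2
}

#' Quantify occlusion over a labeled graph
#'
#' Computes the two headline metrics: the relative occluded volume
#' (occluded / existing) and the relative functional vascular length
#' (functional / existing), over edges whose midpoint falls inside an
#' optional region mask. Volume is computed as the tube integral
#' \eqn{\sum \pi r(s)^2 ds} along each edge by default ("tube"), or from
#' mask voxels assigned to edges ("voxel").
#'
#' @param graph a labeled \code{\link{vessel_graph}}.
#' @param region_mask optional \code{\link{vessel_mask}} restricting the
#'   report to a region (e.g. a striatum-like subvolume).
#' @param method \code{"tube"} or \code{"voxel"}.
#' @param existing_mask required for \code{method = "voxel"}: the existing
#'   channel's mask whose voxels are assigned to the nearest edge.
#' @param region_id identifier copied into the report row.
#' @return an \code{occlusion_report} list: per-edge labels, lengths and
#'   volumes per class, \code{occluded_volume_fraction},
#'   \code{length_ratio_functional}, counts and provenance.
#' @export
quantify_occlusion <- function(graph, region_mask = NULL,
                               method = c("tube", "voxel"),
                               existing_mask = NULL, region_id = "whole") {
  method <- match.arg(method)
  labs <- edge_labels(graph)
  if (any(is.na(labs))) stop("all edges must be labeled; run classify_edges() first")
  keep <- rep(TRUE, length(graph$edges))
  if (!is.null(region_mask)) {
    mids <- t(vapply(graph$edges, function(e)
      polyline_point_at(e$points, max(polyline_arc(e$points)) / 2), numeric(3)))
    keep <- mask_at_points(region_mask$mask, region_mask$voxel_size_um, mids)
    if (!any(keep)) warning("region mask is disjoint from the graph: zero totals")
  }
  edges <- graph$edges[keep]
  labs <- labs[keep]
  L <- vapply(edges, `[[`, numeric(1), "length_um")
  vol_tube <- vapply(edges, function(e) {
    ds <- sqrt(rowSums(diff(e$points)^2))
    rmid <- (e$radius_um[-1] + e$radius_um[-length(e$radius_um)]) / 2
    sum(pi * rmid^2 * ds, na.rm = TRUE)
  }, numeric(1))
  V <- vol_tube
  if (method == "voxel") {
    if (is.null(existing_mask))
      stop("method = 'voxel' requires existing_mask")
    V <- voxel_volumes_per_edge(edges, existing_mask)
  }
  occ <- labs == "occluded"
  Lt <- sum(L); Vt <- sum(V)
  report <- list(region_id = region_id,
                 method = method,
                 n_edges = length(edges),
                 n_functional = sum(!occ),
                 n_occluded = sum(occ),
                 length_total_um = Lt,
                 length_functional_um = sum(L[!occ]),
                 length_occluded_um = sum(L[occ]),
                 volume_total_um3 = Vt,
                 volume_occluded_um3 = sum(V[occ]),
                 occluded_volume_fraction = if (Vt > 0) sum(V[occ]) / Vt else 0,
                 occluded_length_fraction = if (Lt > 0) sum(L[occ]) / Lt else 0,
                 length_ratio_functional = if (Lt > 0) sum(L[!occ]) / Lt else 0,
                 params = attr(graph, "perfusion_params"))
  class(report) <- "occlusion_report"
  report
}

#' @export
print.occlusion_report <- function(x, ...) {
  cat(sprintf("<occlusion_report> region=%s  edges=%d (%d occluded)\n",
              x$region_id, x$n_edges, x$n_occluded))
  cat(sprintf("  occluded volume fraction: %.3f (%s)\n", x$occluded_volume_fraction, x$method))
  cat(sprintf("  functional length ratio : %.3f\n", x$length_ratio_functional))
  invisible(x)
}

#' @export
as.data.frame.occlusion_report <- function(x, ...) {
  data.frame(region_id = x$region_id, method = x$method,
             n_edges = x$n_edges, n_functional = x$n_functional,
             n_occluded = x$n_occluded,
             length_total_um = x$length_total_um,
             length_functional_um = x$length_functional_um,
             length_occluded_um = x$length_occluded_um,
             volume_total_um3 = x$volume_total_um3,
             volume_occluded_um3 = x$volume_occluded_um3,
             occluded_volume_fraction = x$occluded_volume_fraction,
             occluded_length_fraction = x$occluded_length_fraction,
             length_ratio_functional = x$length_ratio_functional)
}

# Assign every foreground voxel of the existing mask to its nearest labeled
# edge (by centerline sample) and sum physical voxel volumes per edge.
voxel_volumes_per_edge <- function(edges, existing_mask) {
  m <- existing_mask$mask
  vs <- existing_mask$voxel_size_um
  vox <- which(m, arr.ind = TRUE)
  if (nrow(vox) == 0) return(numeric(length(edges)))
  vpos <- sweep(vox - 0.5, 2, vs, `*`)
  samp <- do.call(rbind, lapply(seq_along(edges), function(i) {
    pts <- resample_polyline(edges[[i]]$points, 2)
    cbind(pts, i)
  }))
  # nearest centerline sample per voxel, chunked to bound memory
  vol_vox <- prod(vs)
  out <- numeric(length(edges))
  chunk <- 20000L
  for (start in seq(1, nrow(vpos), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(vpos))
    d2 <- outer(rowSums(vpos[idx, , drop = FALSE]^2), rowSums(samp[, 1:3]^2), `+`) -
      2 * vpos[idx, , drop = FALSE] %*% t(samp[, 1:3])
    nearest <- samp[max.col(-d2, ties.method = "first"), 4]
    tab <- table(nearest)
    out[as.integer(names(tab))] <- out[as.integer(names(tab))] + as.numeric(tab) * vol_vox
  }
  out
}
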
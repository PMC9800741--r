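#' Centerline vessel graph
#'
#' Nodes are junctions and endpoints with physical coordinates; edges are
#' centerline polylines with a per-point radius (from the distance transform
#' of the source mask) and derived attributes (arc length, mean radius,
#' perfusion label, alpha-SMA flag).
#'
#' @param nodes data.frame with columns id, x, y, z (micrometres).
#' @param edges list of edges; each a list with fields \code{id}, \code{from},
#'   \code{to} (node ids), \code{points} (n x 3 matrix, um), \code{radius_um}
#'   (length n), \code{length_um}, \code{mean_radius_um}, and optional
#'   \code{label} ("functional"/"occluded"), \code{asma}, \code{coverage}.
#' @param voxel_size_um voxel size of the source grid (provenance).
#' @return an object of class \code{vessel_graph}.
#' @export
vessel_graph <- function(nodes, edges, voxel_size_um = c(1, 1, 1)) {
  for (e in edges) {
    if (abs(e$length_um - sum(sqrt(rowSums(diff(e$points)^2)))) >
        1e-6 * max(1, e$length_um))
      stop("edge length inconsistent with its polyline arc length")
  }
  structure(list(nodes = nodes, edges = edges,
                 voxel_size_um = as.numeric(voxel_size_um)),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  labs <- edge_labels(x)
  cat(sprintf("<vessel_graph> %d nodes, %d edges, total length %.1f um",
              nrow(x$nodes), length(x$edges), total_length(x)))
  if (!all(is.na(labs)))
    cat(sprintf("  (%d functional / %d occluded)",
                sum(labs == "functional", na.rm = TRUE),
                sum(labs == "occluded", na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
total_length <- function(graph) {
  sum(vapply(graph$edges, `[[`, numeric(1), "length_um"))
}

edge_labels <- function(graph) {
  vapply(graph$edges, function(e) e$label %||% NA_character_, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# igraph view of the node/edge topology (edge index carried as attribute).
as_igraph <- function(graph) {
  if (length(graph$edges) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  el <- t(vapply(graph$edges, function(e) c(as.character(e$from), as.character(e$to)),
                 character(2)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$edge_index <- seq_along(graph$edges)
  g
}

# ---------------------------------------------------------------------------

#' Skeletonize a vessel mask into a centerline graph
#'
#' The mask is resampled to isotropic voxels at the smallest voxel size
#' (3D thinning assumes isotropy), thinned to a curve skeleton by
#' topology-preserving removal of simple points, and converted to a graph:
#' skeleton voxels with other than two neighbors become nodes, voxel chains
#' between them become polyline edges. Short terminal spurs (thinning
#' artifacts of tube caps) are pruned, degree-2 nodes left behind are merged,
#' polylines are lightly smoothed to suppress voxel staircase length bias,
#' and per-point radii are attached from the Euclidean distance transform of
#' the mask.
#'
#' @param mask a \code{\link{vessel_mask}}.
#' @param prune_spur_factor terminal branches shorter than
#'   \code{max(prune_spur_factor * local radius, prune_spur_min_um)} are removed.
#' @param prune_spur_min_um absolute spur floor, micrometres.
#' @param smooth_mask_um Gaussian sigma (um) applied to the resampled mask
#'   indicator before the 0.5 cut; suppresses noise-induced surface roughness
#'   that would otherwise seed spurious skeleton branches.
#' @param smooth_window odd moving-average window (points) for polyline smoothing.
#' @return a \code{\link{vessel_graph}}; empty if the mask has no interior.
#' @export
skeletonize_graph <- function(mask, prune_spur_factor = 2,
                              prune_spur_min_um = 5, smooth_mask_um = 0.5,
                              smooth_window = 5) {
  stopifnot(inherits(mask, "vessel_mask"))
  empty <- vessel_graph(nodes = data.frame(id = integer(0), x = numeric(0),
                                           y = numeric(0), z = numeric(0)),
                        edges = list(), voxel_size_um = mask$voxel_size_um)
  if (!any(mask$mask)) {
    warning("empty mask: returning empty graph")
    return(empty)
  }
  iso <- resample_isotropic(mask$mask, mask$voxel_size_um)
  if (smooth_mask_um > 0) {
    f <- array(as.numeric(iso$mask), dim = dim(iso$mask))
    f <- array(cpp_gaussian_blur3d(f, smooth_mask_um / iso$voxel_size_um),
               dim = dim(f))
    iso$mask <- array(f >= 0.5, dim = dim(f))
  }
  skel <- cpp_thin3d(iso$mask)
  if (sum(skel) < 2) {
    warning("mask has no extended interior: returning empty graph")
    return(empty)
  }
  dmap <- distance_map_um(mask$mask, mask$voxel_size_um)

  g <- skeleton_to_graph(skel, iso$voxel_size_um)
  g <- prune_spurs(g, dmap, mask$voxel_size_um, prune_spur_factor, prune_spur_min_um)
  g <- collapse_short_edges(g)
  g <- smooth_graph(g, smooth_window)
  g <- extend_terminals(g, mask$mask, mask$voxel_size_um, dmap)
  g <- attach_radii(g, dmap, mask$voxel_size_um)
  g$voxel_size_um <- mask$voxel_size_um
  g
}

# Thinning and spur pruning retract tube ends; grow every degree-1 endpoint
# along its end tangent while it stays inside the mask and clear of the end
# cap (the distance transform falls off inside the hemispherical cap, so the
# walk stops once it drops below a fraction of the tip radius).
extend_terminals <- function(g, mask, vs, dmap, step_um = NULL, max_um = 15) {
  if (is.null(step_um)) step_um <- min(vs) / 2
  deg <- table(c(vapply(g$edges, `[[`, integer(1), "from"),
                 vapply(g$edges, `[[`, integer(1), "to")))
  for (i in seq_along(g$edges)) {
    e <- g$edges[[i]]
    for (end in c("from", "to")) {
      if (deg[[as.character(e[[end]])]] != 1) next
      pts <- e$points
      n <- nrow(pts)
      if (n < 3) next
      if (end == "from") { tip <- pts[1, ]; ref <- pts[min(4, n), ] }
      else { tip <- pts[n, ]; ref <- pts[max(1, n - 3), ] }
      tg <- tip - ref
      nt <- sqrt(sum(tg^2))
      if (nt < 1e-9) next
      tg <- tg / nt
      r_tip <- mask_dt_at(dmap, vs, matrix(tip, ncol = 3))
      if (is.na(r_tip)) r_tip <- 0
      ext <- list()
      p <- tip
      for (k in seq_len(ceiling(max_um / step_um))) {
        p2 <- p + tg * step_um
        if (!mask_at_points(mask, vs, matrix(p2, ncol = 3))) break
        if (mask_dt_at(dmap, vs, matrix(p2, ncol = 3)) < 0.8 * r_tip) break
        ext[[length(ext) + 1]] <- p2
        p <- p2
      }
      if (length(ext)) {
        em <- do.call(rbind, ext)
        pts <- if (end == "from") rbind(em[rev(seq_len(nrow(em))), , drop = FALSE], pts)
               else rbind(pts, em)
        e$points <- pts
        e$radius_um <- rep(NA_real_, nrow(pts))
        e$length_um <- sum(sqrt(rowSums(diff(pts)^2)))
      }
    }
    g$edges[[i]] <- e
  }
  g
}

# Build node/edge topology from a skeleton voxel set (26-connectivity).
skeleton_to_graph <- function(skel, vs) {
  d <- dim(skel)
  lin <- which(skel)
  nz <- length(lin)
  # voxel coordinates (1-based)
  z <- (lin - 1) %/% (d[1] * d[2])
  rem <- (lin - 1) - z * d[1] * d[2]
  y <- rem %/% d[1]
  x <- rem %% d[1]
  coord <- cbind(x, y, z)  # 0-based
  key <- lin                # sorted linear indices of skeleton voxels
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  adj <- vector("list", nz)
  for (o in seq_len(nrow(offs))) {
    nx <- coord[, 1] + offs[o, 1]; ny <- coord[, 2] + offs[o, 2]; nzc <- coord[, 3] + offs[o, 3]
    ok <- nx >= 0 & ny >= 0 & nzc >= 0 & nx < d[1] & ny < d[2] & nzc < d[3]
    nkey <- 1 + nx + d[1] * (ny + d[2] * nzc)
    j <- match(nkey, key)
    hit <- which(ok & !is.na(j))
    for (i in hit) adj[[i]] <- c(adj[[i]], j[i])
  }
  deg <- lengths(adj)
  is_node <- deg != 2L
  if (!any(is_node)) is_node[1] <- TRUE   # pure cycle: cut it at one voxel
  node_idx <- which(is_node)
  node_id <- integer(nz); node_id[node_idx] <- seq_along(node_idx)
  pos_um <- sweep(coord + 0.5, 2, vs, `*`)

  edges <- list()
  visited <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b), pmin(a, b)[1])
  mark <- function(a, b) assign(paste(min(a, b), max(a, b)), TRUE, envir = visited)
  seen <- function(a, b) isTRUE(get0(paste(min(a, b), max(a, b)), envir = visited))
  for (ni in node_idx) {
    for (nb in adj[[ni]]) {
      if (seen(ni, nb)) next
      path <- c(ni, nb)
      mark(ni, nb)
      prev <- ni; cur <- nb
      while (!is_node[cur]) {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0) break
        nxt <- nxt[1]
        mark(cur, nxt)
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      pts <- pos_um[path, , drop = FALSE]
      if (nrow(pts) < 2) next
      edges[[length(edges) + 1]] <- list(
        id = length(edges) + 1L,
        from = node_id[path[1]],
        to = node_id[path[length(path)]],
        points = pts,
        radius_um = rep(NA_real_, nrow(pts)),
        length_um = sum(sqrt(rowSums(diff(pts)^2))),
        mean_radius_um = NA_real_)
    }
  }
  nodes <- data.frame(id = seq_along(node_idx),
                      x = pos_um[node_idx, 1],
                      y = pos_um[node_idx, 2],
                      z = pos_um[node_idx, 3])
  vessel_graph(nodes = nodes, edges = edges, voxel_size_um = vs)
}

# Remove terminal edges shorter than max(factor * local radius, min_um);
# iterate, then merge degree-2 nodes.
prune_spurs <- function(g, dmap, vs, factor, min_um) {
  repeat {
    if (length(g$edges) <= 1) break
    deg <- table(c(vapply(g$edges, `[[`, integer(1), "from"),
                   vapply(g$edges, `[[`, integer(1), "to")))
    drop <- logical(length(g$edges))
    for (i in seq_along(g$edges)) {
      e <- g$edges[[i]]
      d_from <- deg[[as.character(e$from)]]
      d_to <- deg[[as.character(e$to)]]
      if (d_from > 1 && d_to > 1) next          # not terminal
      r_local <- stats::median(mask_dt_at(dmap, vs, e$points), na.rm = TRUE)
      if (is.na(r_local)) r_local <- 0
      if (e$length_um < max(factor * r_local, min_um)) drop[i] <- TRUE
    }
    # keep at least one edge; don't drop isolated components entirely
    if (!any(drop)) break
    keep_guard <- vapply(g$edges, function(e)
      deg[[as.character(e$from)]] == 1 && deg[[as.character(e$to)]] == 1, logical(1))
    drop[keep_guard] <- FALSE
    if (!any(drop)) break
    g$edges <- g$edges[!drop]
    g <- merge_degree2(g)
  }
  g
}

merge_degree2 <- function(g) {
  repeat {
    from <- vapply(g$edges, `[[`, integer(1), "from")
    to <- vapply(g$edges, `[[`, integer(1), "to")
    deg <- table(c(from, to))
    mid <- as.integer(names(deg)[deg == 2])
    merged <- FALSE
    for (nd in mid) {
      inc <- which(from == nd | to == nd)
      if (length(inc) != 2) next
      e1 <- g$edges[[inc[1]]]; e2 <- g$edges[[inc[2]]]
      if (identical(inc[1], inc[2])) next
      # orient e1 to end at nd, e2 to start at nd
      if (e1$from == nd) { e1$points <- e1$points[rev(seq_len(nrow(e1$points))), , drop = FALSE]
                           tmp <- e1$from; e1$from <- e1$to; e1$to <- tmp
                           e1$radius_um <- rev(e1$radius_um) }
      if (e2$to == nd)   { e2$points <- e2$points[rev(seq_len(nrow(e2$points))), , drop = FALSE]
                           tmp <- e2$from; e2$from <- e2$to; e2$to <- tmp
                           e2$radius_um <- rev(e2$radius_um) }
      if (e1$to != nd || e2$from != nd) next   # self-loop at nd; skip
      pts <- rbind(e1$points, e2$points[-1, , drop = FALSE])
      enew <- list(id = e1$id, from = e1$from, to = e2$to, points = pts,
                   radius_um = c(e1$radius_um, e2$radius_um[-1]),
                   length_um = sum(sqrt(rowSums(diff(pts)^2))),
                   mean_radius_um = NA_real_)
      g$edges <- c(g$edges[-inc], list(enew))
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  # renumber edges deterministically by first point
  ord <- order(vapply(g$edges, function(e) e$points[1, 1], numeric(1)),
               vapply(g$edges, function(e) e$points[1, 2], numeric(1)),
               vapply(g$edges, function(e) e$points[1, 3], numeric(1)))
  g$edges <- g$edges[ord]
  for (i in seq_along(g$edges)) g$edges[[i]]$id <- i
  used <- sort(unique(c(vapply(g$edges, `[[`, integer(1), "from"),
                        vapply(g$edges, `[[`, integer(1), "to"))))
  g$nodes <- g$nodes[g$nodes$id %in% used, , drop = FALSE]
  g
}

# Contract internal sliver edges (junction clusters left by thinning): an
# edge shorter than min_um joining two junctions is removed and its endpoints
# merged, so perfusion votes are never cast by junction slivers.
collapse_short_edges <- function(g, min_um = 3) {
  repeat {
    from <- vapply(g$edges, `[[`, integer(1), "from")
    to <- vapply(g$edges, `[[`, integer(1), "to")
    deg <- table(c(from, to))
    len <- vapply(g$edges, `[[`, numeric(1), "length_um")
    cand <- which(len < min_um & from != to &
                    vapply(seq_along(g$edges), function(i)
                      deg[[as.character(from[i])]] >= 3 &&
                      deg[[as.character(to[i])]] >= 3, logical(1)))
    # contracting parallel short edges leaves trivial self-loops: drop them
    loops <- which(from == to & len < 2 * min_um)
    if (length(loops)) { g$edges <- g$edges[-loops]; next }
    if (length(cand) == 0) break
    i <- cand[1]
    a <- from[i]; b <- to[i]
    # merge node b into a at their midpoint
    pa <- g$nodes[g$nodes$id == a, c("x", "y", "z")]
    pb <- g$nodes[g$nodes$id == b, c("x", "y", "z")]
    g$nodes[g$nodes$id == a, c("x", "y", "z")] <- (pa + pb) / 2
    g$nodes <- g$nodes[g$nodes$id != b, , drop = FALSE]
    g$edges <- g$edges[-i]
    for (j in seq_along(g$edges)) {
      if (g$edges[[j]]$from == b) g$edges[[j]]$from <- a
      if (g$edges[[j]]$to == b) g$edges[[j]]$to <- a
    }
  }
  merge_degree2(g)
}

# moving-average smoothing of polylines, endpoints fixed
smooth_graph <- function(g, window) {
  if (window < 3) return(g)
  for (i in seq_along(g$edges)) {
    pts <- g$edges[[i]]$points
    n <- nrow(pts)
    if (n > window) {
      sm <- apply(pts, 2, function(v) stats::filter(v, rep(1 / window, window), sides = 2))
      inner <- 2:(n - 1)
      ok <- inner[!is.na(sm[inner, 1])]
      pts[ok, ] <- sm[ok, ]
      g$edges[[i]]$points <- pts
      g$edges[[i]]$length_um <- sum(sqrt(rowSums(diff(pts)^2)))
    }
  }
  g
}

mask_dt_at <- function(dmap, vs, pts) {
  d <- dim(dmap)
  idx <- sapply(1:3, function(a) pmin(pmax(round(pts[, a] / vs[a] + 0.5), 1L), d[a]))
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  dmap[cbind(idx[, 1], idx[, 2], idx[, 3])]
}

attach_radii <- function(g, dmap, vs) {
  for (i in seq_along(g$edges)) {
    r <- mask_dt_at(dmap, vs, g$edges[[i]]$points)
    g$edges[[i]]$radius_um <- as.numeric(r)
    g$edges[[i]]$mean_radius_um <- mean(r, na.rm = TRUE)
  }
  g
}
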
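SCHEMA_VERSION <- "1.0"

#' Write an image volume as multi-page TIFF with a voxel-size sidecar
#'
#' The stack is written as one 32-bit float page per z-slice; physical voxel
#' sizes (PhysicalSizeX/Y/Z, micrometres), the channel role and the intensity
#' scale are recorded in a JSON sidecar next to the TIFF
#' (\code{<path>.json}). Intensities are scaled into [0, 1] for storage and
#' rescaled on read.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_image_volume <- function(vol, path) {
  d <- dim(vol$data)
  scale <- max(max(vol$data), 1)
  pages <- lapply(seq_len(d[3]), function(k) t(vol$data[, , k]) / scale)  # rows = y
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(schema_version = SCHEMA_VERSION,
               PhysicalSizeX = vol$voxel_size_um[1],
               PhysicalSizeY = vol$voxel_size_um[2],
               PhysicalSizeZ = vol$voxel_size_um[3],
               PhysicalSizeUnit = "um",
               channel_role = vol$channel_role,
               intensity_scale = scale,
               size = d)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image volume written by \code{\link{write_image_volume}}
#'
#' @param path TIFF path; \code{<path>.json} must hold the voxel-size sidecar.
#' @return an \code{\link{image_volume}}.
#' @export
read_image_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$size)
  arr <- array(0, dim = d)
  for (k in seq_len(d[3])) arr[, , k] <- t(pages[[k]]) * meta$intensity_scale
  image_volume(arr, c(meta$PhysicalSizeX, meta$PhysicalSizeY, meta$PhysicalSizeZ),
               channel_role = meta$channel_role)
}

#' Write phantom ground truth as a versioned JSON sidecar
#' @param truth a \code{phantom_truth}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_phantom_truth <- function(truth, path) {
  obj <- list(schema_version = SCHEMA_VERSION,
              tree_spec = unclass(truth$tree_spec),
              occlusion_spec = if (is.null(truth$occlusion_spec)) NULL
                               else unclass(truth$occlusion_spec),
              nodes = truth$nodes,
              edges = truth$edges,
              edge_points = lapply(truth$edge_points, function(ep)
                list(pts = ep$pts, r = ep$r)),
              edge_labels = as.list(truth$edge_labels),
              blockage_points = truth$blockage_points,
              narrowing_sites = truth$narrowing_sites,
              cells = truth$cells,
              asma_edges = truth$asma_edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read phantom ground truth written by \code{\link{write_phantom_truth}}
#' @param path JSON path.
#' @return a \code{phantom_truth}.
#' @export
read_phantom_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- obj$tree_spec
  spec <- tree_spec(domain_size_um = ts$domain_size_um,
                    voxel_size_um = ts$voxel_size_um,
                    n_roots = ts$n_roots, branch_levels = ts$branch_levels,
                    radius_root_um = ts$radius_root_um,
                    radius_min_um = ts$radius_min_um,
                    radius_decay = ts$radius_decay,
                    segment_length_um = ts$segment_length_um,
                    branch_angle_deg = ts$branch_angle_deg,
                    rng_seed = ts$rng_seed)
  ospec <- NULL
  if (!is.null(obj$occlusion_spec)) {
    os <- obj$occlusion_spec
    ospec <- occlusion_spec(blocked_subtree_fraction = os$blocked_subtree_fraction,
                            narrowing_depth = os$narrowing_depth,
                            narrowing_halfwidth_um = os$narrowing_halfwidth_um,
                            neutrophil_at_blockage_fraction = os$neutrophil_at_blockage_fraction,
                            neutrophil_radius_um = os$neutrophil_radius_um,
                            asma_radius_threshold_um = os$asma_radius_threshold_um,
                            n_perivascular_nuclei = os$n_perivascular_nuclei,
                            rng_seed = os$rng_seed)
  }
  fix_df <- function(df, template) {
    if (is.null(df) || length(df) == 0 || (is.data.frame(df) && nrow(df) == 0))
      return(template)
    as.data.frame(df)
  }
  nodes <- as.data.frame(obj$nodes)
  nodes <- nodes[, c("id", "parent", "x", "y", "z", "radius_um", "level")]
  edges <- as.data.frame(obj$edges)
  edges <- edges[, c("id", "parent_node", "level", "length_um")]
  truth <- structure(list(
    tree_spec = spec,
    nodes = nodes,
    edges = edges,
    edge_points = lapply(obj$edge_points, function(ep)
      list(pts = matrix(unlist(ep$pts), ncol = 3,
                        byrow = !is.matrix(ep$pts)) , r = as.numeric(unlist(ep$r)))),
    edge_labels = unlist(obj$edge_labels),
    blockage_points = fix_df(obj$blockage_points,
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0), entry_edge = integer(0))),
    narrowing_sites = fix_df(obj$narrowing_sites,
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                 true_min_diameter_um = numeric(0))),
    cells = fix_df(obj$cells,
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0), type = character(0),
                 intravascular = logical(0), radius_um = numeric(0))),
    asma_edges = as.integer(unlist(obj$asma_edges)),
    occlusion_spec = ospec), class = "phantom_truth")
  for (i in seq_along(truth$edge_points)) {
    ep <- obj$edge_points[[i]]
    truth$edge_points[[i]]$pts <- if (is.matrix(ep$pts)) ep$pts else
      do.call(rbind, lapply(ep$pts, unlist))
  }
  truth
}

#' Write a vessel graph as JSON (nodes, edges, per-point radii, labels)
#' @param graph a \code{\link{vessel_graph}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_vessel_graph <- function(graph, path) {
  obj <- list(schema_version = SCHEMA_VERSION,
              voxel_size_um = graph$voxel_size_um,
              nodes = graph$nodes,
              edges = lapply(graph$edges, function(e)
                list(id = e$id, from = e$from, to = e$to,
                     points = e$points, radius_um = e$radius_um,
                     length_um = e$length_um, mean_radius_um = e$mean_radius_um,
                     label = e$label %||% NA, asma = e$asma %||% NA,
                     coverage = e$coverage %||% NA)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a vessel graph written by \code{\link{write_vessel_graph}}
#' @param path JSON path.
#' @return a \code{\link{vessel_graph}}.
#' @export
read_vessel_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- lapply(seq_len(if (is.data.frame(obj$edges)) 0 else length(obj$edges)),
                  function(i) NULL)
  raw <- obj$edges
  mk_edge <- function(e) {
    pts <- if (is.matrix(e$points)) e$points else do.call(rbind, lapply(e$points, unlist))
    lab <- e$label
    list(id = e$id, from = e$from, to = e$to, points = pts,
         radius_um = as.numeric(unlist(e$radius_um)),
         length_um = e$length_um, mean_radius_um = e$mean_radius_um,
         label = if (is.null(lab) || (length(lab) == 1 && is.na(lab))) NULL else lab,
         asma = if (is.null(e$asma) || (length(e$asma) == 1 && is.na(e$asma))) NULL else e$asma,
         coverage = if (is.null(e$coverage) || (length(e$coverage) == 1 && is.na(e$coverage))) NULL else e$coverage)
  }
  edges <- if (is.data.frame(raw)) lapply(seq_len(nrow(raw)), function(i) {
    mk_edge(lapply(raw, function(col) if (is.list(col)) col[[i]] else col[i]))
  }) else lapply(raw, mk_edge)
  vessel_graph(nodes = as.data.frame(obj$nodes), edges = edges,
               voxel_size_um = obj$voxel_size_um)
}

#' Export a vessel graph in SWC format
#'
#' Flattens every edge polyline into SWC sample rows
#' (\code{id type x y z radius parent}). The SWC type column carries the
#' perfusion label: 2 = functional, 3 = occluded, 0 = unlabeled. Junction
#' connectivity across edges is preserved through shared node samples.
#'
#' @param graph a \code{\link{vessel_graph}}.
#' @param path output SWC path.
#' @return \code{path}, invisibly.
#' @export
write_swc <- function(graph, path) {
  rows <- list()
  nid <- 0L
  node_sample <- new.env(hash = TRUE)   # graph node id -> swc sample id
  for (e in graph$edges) {
    type <- switch(e$label %||% "none", functional = 2L, occluded = 3L, 0L)
    n <- nrow(e$points)
    prev <- -1L
    from_key <- as.character(e$from)
    for (i in seq_len(n)) {
      if (i == 1 && !is.null(get0(from_key, envir = node_sample))) {
        prev <- get0(from_key, envir = node_sample)
        next
      }
      nid <- nid + 1L
      r <- e$radius_um[i]
      rows[[length(rows) + 1]] <- sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                                          nid, type, e$points[i, 1], e$points[i, 2],
                                          e$points[i, 3],
                                          if (is.na(r)) 1 else r, prev)
      if (i == 1) assign(from_key, nid, envir = node_sample)
      if (i == n) assign(as.character(e$to), nid, envir = node_sample)
      prev <- nid
    }
  }
  writeLines(c("# SWC export; type: 2=functional 3=occluded 0=unlabeled; units um",
               unlist(rows)), path)
  invisible(path)
}
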
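#' 3D image volume with physical voxel sizes
#'
#' The substrate of all image operations: a 3D intensity array together with
#' its physical voxel size in micrometres and the biological role of the
#' channel it came from. Arrays are stored column-major with
#' \code{dim = c(nx, ny, nz)}; physical coordinates are micrometres with the
#' origin at the volume corner and voxel centres at \code{(i - 0.5) *
#' voxel_size_um}.
#'
#' @param data numeric 3D array of non-negative intensities.
#' @param voxel_size_um numeric length-3 vector (x, y, z) of voxel edge
#'   lengths in micrometres; anisotropic z is allowed.
#' @param channel_role one of \code{"existing"}, \code{"functional"},
#'   \code{"asma"}, \code{"neutrophil"}, \code{"nucleus"}.
#' @return an object of class \code{image_volume}.
#' @export
image_volume <- function(data, voxel_size_um,
                         channel_role = c("existing", "functional", "asma",
                                          "neutrophil", "nucleus")) {
  channel_role <- match.arg(channel_role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("'voxel_size_um' must be 3 positive values")
  if (any(data < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  structure(list(data = data,
                 voxel_size_um = as.numeric(voxel_size_um),
                 channel_role = channel_role),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> role=%s  %d x %d x %d voxels  (%.3g x %.3g x %.3g um/voxel)\n",
              x$channel_role, d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Binary vessel mask
#'
#' A boolean voxel grid sharing the source volume's grid, with provenance
#' (channel role and the parameters that produced it).
#'
#' @param mask logical 3D array.
#' @param voxel_size_um physical voxel size, micrometres.
#' @param provenance list recording channel role and parameter digest.
#' @return an object of class \code{vessel_mask}.
#' @export
vessel_mask <- function(mask, voxel_size_um, provenance = list()) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("'mask' must be a logical 3D array")
  structure(list(mask = mask,
                 voxel_size_um = as.numeric(voxel_size_um),
                 provenance = provenance),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<vessel_mask> %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

# Euclidean distance map (um) of foreground to the nearest background voxel.
distance_map_um <- function(mask, voxel_size_um) {
  sqrt(cpp_edt_sq(mask, as.numeric(voxel_size_um)))
}

#' Dilate or erode a binary mask by a physical radius
#'
#' Morphology with a Euclidean ball of physical radius, computed through the
#' anisotropic distance transform so anisotropic voxels are handled exactly.
#'
#' @param mask logical 3D array.
#' @param radius_um dilation (positive) radius in micrometres.
#' @param voxel_size_um voxel size in micrometres.
#' @return logical 3D array.
#' @export
dilate_mask <- function(mask, radius_um, voxel_size_um) {
  if (radius_um <= 0) return(mask)
  d2 <- cpp_edt_sq(!mask, as.numeric(voxel_size_um))
  out <- mask | (d2 <= radius_um^2)
  dim(out) <- dim(mask)
  out
}

erode_mask <- function(mask, radius_um, voxel_size_um) {
  if (radius_um <= 0) return(mask)
  d2 <- cpp_edt_sq(mask, as.numeric(voxel_size_um))
  out <- mask & (d2 > radius_um^2)
  dim(out) <- dim(mask)
  out
}

# Morphological closing with a Euclidean ball.
close_mask <- function(mask, radius_um, voxel_size_um) {
  erode_mask(dilate_mask(mask, radius_um, voxel_size_um), radius_um, voxel_size_um)
}

# Nearest-voxel lookup of a logical array at physical points (n x 3 um).
# Points outside the volume are FALSE.
mask_at_points <- function(mask, voxel_size_um, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  d <- dim(mask)
  idx <- sapply(1:3, function(a) pmin(pmax(round(pts[, a] / voxel_size_um[a] + 0.5), 1L), d[a]))
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  inside <- pts[, 1] >= 0 & pts[, 2] >= 0 & pts[, 3] >= 0 &
    pts[, 1] <= d[1] * voxel_size_um[1] &
    pts[, 2] <= d[2] * voxel_size_um[2] &
    pts[, 3] <= d[3] * voxel_size_um[3]
  out <- mask[cbind(idx[, 1], idx[, 2], idx[, 3])]
  out & inside
}

# Trilinear sampling of an image_volume at physical points; NA outside.
sample_volume <- function(vol, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  cpp_trilinear(vol$data, vol$voxel_size_um, pts)
}

# Resample a logical mask to isotropic voxels at min(voxel_size) by linear
# interpolation of the indicator followed by a 0.5 cut; 3D thinning assumes
# isotropy.
resample_isotropic <- function(mask, voxel_size_um, iso_um = min(voxel_size_um)) {
  d <- dim(mask)
  if (all(abs(voxel_size_um - iso_um) < 1e-9))
    return(list(mask = mask, voxel_size_um = rep(iso_um, 3)))
  extent <- d * voxel_size_um
  nd <- pmax(as.integer(round(extent / iso_um)), 1L)
  grid <- expand.grid(x = (seq_len(nd[1]) - 0.5) * iso_um,
                      y = (seq_len(nd[2]) - 0.5) * iso_um,
                      z = (seq_len(nd[3]) - 0.5) * iso_um)
  vals <- cpp_trilinear(array(as.numeric(mask), dim = d), voxel_size_um,
                        as.matrix(grid))
  vals[is.na(vals)] <- 0
  out <- array(vals >= 0.5, dim = nd)
  list(mask = out, voxel_size_um = rep(iso_um, 3))
}
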
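#' Detect intravascular neutrophils
#'
#' A detection is counted as a neutrophil iff it satisfies the full marker
#' rule: a marker-channel blob of neutrophil size, overlapping a
#' nucleus-channel blob, with its centroid inside the (slack-dilated) vessel
#' lumen. Blobs are found by Gaussian smoothing, thresholding and 3D
#' connected components, then size-filtered by equivalent spherical diameter.
#'
#' @param marker neutrophil-marker \code{\link{image_volume}}.
#' @param nucleus nucleus-channel \code{\link{image_volume}}, or NULL. With no
#'   nucleus channel the rule is weakened: \code{nucleus_present} is NA and
#'   every size-qualified intravascular marker blob is counted, with a
#'   prominent warning.
#' @param vessel_mask \code{\link{vessel_mask}} of the existing channel.
#' @param smooth_sigma_um Gaussian smoothing sigma before thresholding, um.
#' @param threshold_k blob threshold = mean + \code{threshold_k} * sd of the
#'   smoothed channel; robust for sparse bright blobs on flat background.
#' @param min_diameter_um,max_diameter_um equivalent-diameter acceptance band.
#' @param intravascular_slack_um dilation applied to the vessel mask before
#'   the centroid-in-lumen test.
#' @return a data.frame of class \code{cell_detections}: centroid (um),
#'   equivalent_diameter_um, marker_mean_intensity, nucleus_present,
#'   intravascular, is_neutrophil.
#' @export
detect_neutrophils <- function(marker, nucleus, vessel_mask,
                               smooth_sigma_um = 1,
                               threshold_k = 5,
                               min_diameter_um = 4, max_diameter_um = 12,
                               intravascular_slack_um = 1) {
  stopifnot(inherits(marker, "image_volume"), inherits(vessel_mask, "vessel_mask"))
  vs <- marker$voxel_size_um
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      equivalent_diameter_um = numeric(0),
                      marker_mean_intensity = numeric(0),
                      nucleus_present = logical(0), intravascular = logical(0),
                      is_neutrophil = logical(0))
  class(empty) <- c("cell_detections", "data.frame")
  blobs <- find_blobs(marker, smooth_sigma_um, threshold_k)
  if (is.null(blobs)) return(empty)
  lab <- blobs$labels
  nuc_mask <- NULL
  if (is.null(nucleus)) {
    warning("no nucleus channel supplied: the marker+nucleus neutrophil rule is weakened to marker-only")
  } else {
    nb <- find_blobs(nucleus, smooth_sigma_um, threshold_k)
    nuc_mask <- if (is.null(nb)) array(FALSE, dim(lab)) else nb$labels > 0
  }
  lumen <- dilate_mask(vessel_mask$mask, intravascular_slack_um, vs)
  vol_vox <- prod(vs)
  ids <- seq_len(blobs$n)
  rows <- lapply(ids, function(id) {
    sel <- which(lab == id)
    nv <- length(sel)
    eq_d <- 2 * (3 * nv * vol_vox / (4 * pi))^(1 / 3)
    if (eq_d < min_diameter_um || eq_d > max_diameter_um) return(NULL)
    ai <- arrayInd(sel, dim(lab))
    centroid <- colMeans(sweep(ai - 0.5, 2, vs, `*`))
    nuc <- if (is.null(nuc_mask)) NA else any(nuc_mask[sel])
    intra <- mask_at_points(lumen, vs, matrix(centroid, ncol = 3))
    data.frame(x = centroid[1], y = centroid[2], z = centroid[3],
               equivalent_diameter_um = eq_d,
               marker_mean_intensity = mean(marker$data[sel]),
               nucleus_present = nuc,
               intravascular = as.logical(intra))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$is_neutrophil <- out$intravascular &
    (if (is.null(nuc_mask)) TRUE else out$nucleus_present)
  out <- out[order(out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cell_detections", "data.frame")
  out
}

# Smooth + threshold + 26-connected components; returns NULL when nothing
# exceeds the threshold. Blobs are cut at half their peak brightness so the
# apparent size tracks the cell, not the threshold; mean + k*sd acts as a
# noise floor for near-empty channels.
find_blobs <- function(vol, smooth_sigma_um, threshold_k) {
  x <- vol$data
  if (smooth_sigma_um > 0)
    x <- array(cpp_gaussian_blur3d(x, smooth_sigma_um / vol$voxel_size_um), dim = dim(x))
  thr <- max(0.5 * stats::quantile(x, 0.9999, names = FALSE),
             mean(x) + threshold_k * stats::sd(x))
  if (!is.finite(thr) || !any(x > thr)) return(NULL)
  m <- x > thr
  dim(m) <- dim(x)
  lab <- cpp_label3d(m)
  list(labels = array(lab, dim = dim(x)), n = max(lab))
}

#' Co-localize blockage points with neutrophils
#'
#' A blockage point is "with neutrophil" iff at least one intravascular
#' neutrophil centroid lies within \code{matching_radius_um} of it.
#'
#' @param points a \code{blockage_points} data.frame.
#' @param cells a \code{cell_detections} data.frame (only rows with
#'   \code{is_neutrophil} are matched).
#' @param matching_radius_um matching radius, micrometres (about one
#'   neutrophil diameter by default).
#' @param existing_length_um optional total existing-vessel length (um) for
#'   the per-millimetre neutrophil density.
#' @return a \code{coloc_report} list with counts, \code{fraction_without},
#'   the matching radius, and the neutrophil density per mm of vessel; the
#'   input points with \code{neutrophil_within_radius} filled are attached
#'   as \code{$points}.
#' @export
colocalize_blockages <- function(points, cells, matching_radius_um = 10,
                                 existing_length_um = NA_real_) {
  neut <- cells[isTRUE_v(cells$is_neutrophil), , drop = FALSE]
  n_bp <- nrow(points)
  with_flag <- logical(n_bp)
  if (n_bp > 0 && nrow(neut) > 0) {
    for (i in seq_len(n_bp)) {
      d2 <- (neut$x - points$x[i])^2 + (neut$y - points$y[i])^2 +
        (neut$z - points$z[i])^2
      with_flag[i] <- any(d2 <= matching_radius_um^2)
    }
  }
  points$neutrophil_within_radius <- with_flag
  rep <- list(n_blockage_points = n_bp,
              n_with_neutrophil = sum(with_flag),
              n_without = n_bp - sum(with_flag),
              fraction_without = if (n_bp > 0) 1 - sum(with_flag) / n_bp else NA_real_,
              matching_radius_um = matching_radius_um,
              n_neutrophils = nrow(neut),
              neutrophil_density_per_mm_vessel =
                if (is.na(existing_length_um) || existing_length_um <= 0) NA_real_
                else nrow(neut) / (existing_length_um / 1000),
              points = points)
  class(rep) <- "coloc_report"
  rep
}

isTRUE_v <- function(x) !is.na(x) & x

#' @export
print.coloc_report <- function(x, ...) {
  cat(sprintf("<coloc_report> %d blockage points: %d with / %d without neutrophil (fraction without = %s) at %.1f um\n",
              x$n_blockage_points, x$n_with_neutrophil, x$n_without,
              if (is.na(x$fraction_without)) "NA" else sprintf("%.3f", x$fraction_without),
              x$matching_radius_um))
  invisible(x)
}

#' @export
as.data.frame.coloc_report <- function(x, ...) {
  data.frame(n_blockage_points = x$n_blockage_points,
             n_with_neutrophil = x$n_with_neutrophil,
             n_without = x$n_without,
             fraction_without = x$fraction_without,
             matching_radius_um = x$matching_radius_um,
             n_neutrophils = x$n_neutrophils,
             neutrophil_density_per_mm_vessel = x$neutrophil_density_per_mm_vessel)
}
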
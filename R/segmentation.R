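#' Segment vessels from a single channel
#'
#' Re-implements, with open operators, a surface-style vessel extraction:
#' a wide-Gaussian estimate of the background is subtracted, the residual is
#' thresholded at a configurable percentile (or a fixed value), the binary
#' result is morphologically closed with a small Euclidean ball, and
#' connected components below a minimum voxel count are discarded. The
#' procedure is deterministic for fixed parameters.
#'
#' @param vol an \code{\link{image_volume}} with role existing, functional
#'   or asma.
#' @param threshold_percentile percentile (0-100) of the background-subtracted
#'   residual used to estimate the brightness of vascular structure. Default
#'   99.9 so the estimate stays inside the vessel intensity mode even when
#'   vessels occupy well under a percent of the volume.
#' @param threshold_fraction the actual cut is this fraction of the percentile
#'   value (half-maximum by default), so the mask extends to the half-height
#'   of bright structures rather than their upper tail.
#' @param noise_floor_k the threshold is never below
#'   \code{median + noise_floor_k * MAD} of the residual, which keeps a
#'   nearly-empty channel (e.g. total no-reflow) from thresholding into noise.
#' @param fixed_threshold optional absolute residual threshold overriding the
#'   percentile rule.
#' @param background_sigma_um sigma of the wide Gaussian background estimate;
#'   roughly ten times the largest vessel radius.
#' @param closing_radius_um radius of the morphological closing ball, um.
#' @param min_component_voxels components smaller than this are removed.
#' @return a \code{\link{vessel_mask}} sharing the source grid. An all-zero
#'   volume yields an empty mask with a warning.
#' @export
segment_vessels <- function(vol, threshold_percentile = 99.9,
                            threshold_fraction = 0.5,
                            noise_floor_k = 8,
                            fixed_threshold = NULL,
                            background_sigma_um = 40,
                            closing_radius_um = 1.5,
                            min_component_voxels = 50) {
  stopifnot(inherits(vol, "image_volume"))
  prov <- list(channel_role = vol$channel_role,
               threshold_percentile = threshold_percentile,
               threshold_fraction = threshold_fraction,
               fixed_threshold = fixed_threshold,
               background_sigma_um = background_sigma_um,
               closing_radius_um = closing_radius_um,
               min_component_voxels = min_component_voxels)
  d <- dim(vol$data)
  if (all(vol$data == 0)) {
    warning("all-zero volume: returning empty mask")
    return(vessel_mask(array(FALSE, dim = d), vol$voxel_size_um, prov))
  }
  svox <- background_sigma_um / vol$voxel_size_um
  # wide background kernels use the O(N) box approximation; narrow ones the
  # exact separable Gaussian
  bg <- if (max(svox) > 5) array(cpp_box_blur3d(vol$data, svox), dim = d)
        else array(cpp_gaussian_blur3d(vol$data, svox), dim = d)
  resid <- vol$data - bg
  thr <- if (!is.null(fixed_threshold)) fixed_threshold else
    max(threshold_fraction * stats::quantile(resid, threshold_percentile / 100,
                                             names = FALSE),
        stats::median(resid) + noise_floor_k * stats::mad(resid))
  if (thr <= 1e-8 * max(vol$data)) {
    # constant (or numerically flat) volume: no structure to segment
    warning("no structure above the adaptive threshold: returning empty mask")
    return(vessel_mask(array(FALSE, dim = d), vol$voxel_size_um, prov))
  }
  m <- resid >= thr
  dim(m) <- d
  if (!any(m)) {
    warning("no structure above the adaptive threshold: returning empty mask")
    return(vessel_mask(m, vol$voxel_size_um, prov))
  }
  if (closing_radius_um > 0) m <- close_mask(m, closing_radius_um, vol$voxel_size_um)
  if (min_component_voxels > 1) {
    lab <- cpp_label3d(m)
    sz <- tabulate(lab[lab > 0])
    keep <- which(sz >= min_component_voxels)
    m <- array(lab %in% keep, dim = d)
  }
  vessel_mask(m, vol$voxel_size_um, prov)
}
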
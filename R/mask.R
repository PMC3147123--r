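#' Threshold an intensity image to a binary mask
#'
#' Pixels below half of the maximum intensity are excluded, then only the
#' largest connected component is retained (background speckle and secondary
#' objects such as fiducial markers are dropped).
#'
#' @param image numeric matrix of intensities (image convention: row 1 = top).
#' @return logical matrix of the same dimension.
#' @export
mask_from_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stopf("image must be a numeric matrix")
  mx <- max(image)
  if (!is.finite(mx) || mx <= 0)
    stopf("image has no pixel above zero")
  mask <- image >= 0.5 * mx
  if (!any(mask)) stopf("mask empty after thresholding")
  lab <- EBImage::bwlabel(mask * 1L)
  sizes <- tabulate(lab[lab > 0])
  mask <- matrix(lab == which.max(sizes), nrow = nrow(image))
  mask
}

#' Extract and decimate the boundary contour of a binary mask
#'
#' Traces the exterior boundary pixels of the (single) object in `mask`,
#' keeps one of every `keep_every` contour pixels, and converts them to mm
#' coordinates (origin at `center_px`, y axis pointing up).
#'
#' @param mask logical/0-1 matrix with one connected object.
#' @param keep_every decimation factor (default 5: one of every five contour
#'   pixels is kept).
#' @param pixel_mm pixel size in mm.
#' @param center_px optional `c(row, col)` of the coordinate origin; defaults
#'   to the mask centroid.
#' @return counter-clockwise polygon matrix (mm) with attribute `center_px`.
#' @export
extract_boundary <- function(mask, keep_every = 5, pixel_mm = 0.5,
                             center_px = NULL) {
  if (!any(mask)) stopf("mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  if (any(idx[, 1] %in% c(1L, nrow(mask))) ||
      any(idx[, 2] %in% c(1L, ncol(mask))))
    stopf("mask touches the image border; boundary incomplete")
  lab <- EBImage::bwlabel(mask * 1L)
  if (max(lab) != 1)
    stopf("mask must contain exactly one connected component (found %d)",
          max(lab))
  keep_every <- as.integer(keep_every)
  stopifnot(keep_every >= 1)
  contour <- EBImage::ocontour(lab)[[1]]   # 0-based (row-1, col-1) pairs
  rows <- contour[, 1] + 1
  cols <- contour[, 2] + 1
  sel <- seq(1, length(rows), by = keep_every)
  rows <- rows[sel]; cols <- cols[sel]
  if (is.null(center_px)) center_px <- c(mean(idx[, 1]), mean(idx[, 2]))
  poly <- cbind(x = (cols - center_px[2]) * pixel_mm,
                y = (center_px[1] - rows) * pixel_mm)
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  attr(poly, "center_px") <- center_px
  attr(poly, "pixel_mm") <- pixel_mm
  poly
}
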
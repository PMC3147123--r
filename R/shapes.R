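## Programmatic phantom shape catalogue.  Each shape is star-shaped about the
## origin and defined by a radial function r(theta) in units of `scale`, so the
## generated polygons are always simple (non-self-intersecting) and carry exact
## geometric ground truth.

.shape_radius <- list(
  circle   = function(th) rep(1, length(th)),
  ellipse  = function(th) {
    a <- 1; b <- 0.72
    a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  },
  bean     = function(th) 0.78 + 0.12 * cos(th) - 0.20 * cos(2 * th),
  trilobe  = function(th) 0.85 + 0.13 * cos(3 * th),
  pear     = function(th) 0.80 + 0.16 * cos(th) + 0.06 * cos(2 * th),
  peanut   = function(th) 0.72 + 0.24 * cos(2 * th),
  dshape   = function(th) 1 - 0.32 * pmax(cos(th), 0)^2,
  blob     = function(th) 0.80 + 0.10 * cos(2 * th) + 0.06 * sin(3 * th) +
    0.045 * cos(5 * th)
)

#' Available phantom shape identifiers
#'
#' @return character vector of shape ids accepted by [make_shape()].
#' @export
shape_ids <- function() names(.shape_radius)

#' Generate a phantom shape as polygon and MR-like binary mask
#'
#' Produces the boundary polygon (mm, counter-clockwise, centred on the
#' origin) of one of the catalogue shapes, together with a binary raster mask
#' emulating a thresholded MR slice of the phantom.  The mask uses image
#' convention: row 1 is the top of the image, and pixel size is `pixel_mm`.
#'
#' @param shape_id one of [shape_ids()].
#' @param scale nominal radius of the shape in mm (> 0).
#' @param n_points number of polygon vertices.
#' @param pixel_mm raster pixel size in mm (default 0.5).
#' @return list with `polygon` (n x 2 matrix, mm), `mask` (logical matrix),
#'   `pixel_mm`, `shape_id`, `scale`.
#' @examples
#' sh <- make_shape("circle", scale = 25)
#' abs(polygon_area(sh$polygon) - pi * 25^2) / (pi * 25^2) < 0.01
#' @export
make_shape <- function(shape_id, scale = 25, n_points = 96, pixel_mm = 0.5) {
  if (!is.character(shape_id) || length(shape_id) != 1 ||
      !shape_id %in% names(.shape_radius)) {
    stopf("unknown shape_id '%s'; valid ids: %s",
          as.character(shape_id)[1], paste(shape_ids(), collapse = ", "))
  }
  if (!is.numeric(scale) || scale <= 0) stopf("scale must be > 0")
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  r <- scale * .shape_radius[[shape_id]](th)
  stopifnot(all(r > 0))
  poly <- cbind(x = r * cos(th), y = r * sin(th))
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]

  half <- ceiling(1.35 * scale / pixel_mm)
  n_px <- 2 * half + 1
  ctr <- half + 1                       # pixel index of the origin
  cols <- seq_len(n_px); rows <- seq_len(n_px)
  px <- (rep(cols, each = n_px) - ctr) * pixel_mm      # x of each pixel centre
  py <- (ctr - rep(rows, times = n_px)) * pixel_mm     # y, row 1 = top
  inside <- points_in_polygon(poly, cbind(px, py))
  mask <- matrix(inside, nrow = n_px, ncol = n_px)     # [row, col]

  list(polygon = poly, mask = mask, pixel_mm = pixel_mm,
       shape_id = shape_id, scale = scale)
}
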
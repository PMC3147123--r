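#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rnorm integrate lm coef fitted
#' @importFrom utils write.csv read.csv write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Signed area of a polygon
#'
#' Positive for counter-clockwise vertex order (shoelace formula).
#'
#' @param poly two-column matrix of vertices, open (first point not repeated).
#' @return signed area in squared input units.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

## Even-odd point-in-polygon via mgcv; poly open, pts n x 2.
points_in_polygon <- function(poly, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), pts)
}

## Minimum distance from each point to the (closed) polygon outline.
dist_to_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(a))) {
    vx <- b[s, 1] - a[s, 1]; vy <- b[s, 2] - a[s, 2]
    L2 <- vx^2 + vy^2
    t <- ((pts[, 1] - a[s, 1]) * vx + (pts[, 2] - a[s, 2]) * vy) / L2
    t <- pmin(1, pmax(0, t))
    dx <- pts[, 1] - (a[s, 1] + t * vx)
    dy <- pts[, 2] - (a[s, 2] + t * vy)
    dmin <- pmin(dmin, dx^2 + dy^2)
  }
  sqrt(dmin)
}

## TRUE if any two non-adjacent edges of the closed polygon intersect.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

## Wrap angles to (-pi, pi].
wrap_to_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

## Run code with a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
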
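#' Fit a parabolic model to a SAM contour
#'
#' The shoot apical meristem (SAM) silhouette in a median longitudinal
#' section is closely approximated by a downward-opening parabola. The
#' contour is spline-resampled at evenly spaced stations and fitted by
#' least squares to the full quadratic y = c0 + c1 x + c2 x^2; the vertex
#' gives the apex, the shape coefficient is a = -c2, height h is the vertex
#' elevation above the base level (the minimum y of the contour endpoints,
#' i.e. the P1-notch level), and the radius r solves y(+/-r) = base level.
#'
#' @param contour A \code{sam_contour} (see \code{\link{sam_contour}}) or a
#'   two-column matrix/data.frame of (x, y) points in micrometres, apex up.
#' @param n_stations Number of spline-resampled stations used for the
#'   regression (>= 7; default 51).
#' @return An object of class \code{parabolic_fit}: list with \code{a}
#'   (1/um), \code{h} (um), \code{r} (um), \code{rmse} (um),
#'   \code{n_points}, and the vertex coordinates.
#' @examples
#' x <- seq(-80, 80, length.out = 51)
#' fit_parabola(cbind(x, 100 - (100 / 80^2) * x^2))
#' @export
fit_parabola <- function(contour, n_stations = 51) {
  pts <- as_contour_points(contour)
  if (nrow(pts) < 7) stop("contour must have at least 7 points")
  if (n_stations < 7) stop("n_stations must be >= 7")
  o <- order(pts[, 1])
  x <- pts[o, 1]; y <- pts[o, 2]
  # spline resampling at evenly spaced stations across the traced range
  xs <- seq(min(x), max(x), length.out = n_stations)
  ys <- stats::spline(x, y, xout = xs, ties = mean)$y
  fit <- stats::lm.fit(cbind(1, xs, xs^2), ys)
  cf <- unname(fit$coefficients)
  if (!is.finite(cf[3]) || cf[3] >= 0)
    stop("degenerate contour: not concave-down (no parabolic apex)")
  a <- -cf[3]
  vx <- -cf[2] / (2 * cf[3])
  vy <- cf[1] + cf[2] * vx + cf[3] * vx^2
  # P1-notch base level: the lower of the two contour endpoints, read from
  # the fitted curve so point noise does not bias the base downward. When
  # the two ends are statistically indistinguishable (a symmetric trace)
  # their average is used, since min() of two noisy equal means is biased.
  fitted_ends <- cf[1] + cf[2] * xs[c(1, n_stations)] +
    cf[3] * xs[c(1, n_stations)]^2
  rmse <- sqrt(mean(fit$residuals^2))
  se_end <- rmse * sqrt(10 / n_stations)
  base_y <- if (abs(diff(fitted_ends)) > 3 * se_end) min(fitted_ends)
            else mean(fitted_ends)
  h <- vy - base_y
  if (h <= 0) stop("degenerate contour: apex does not rise above the base")
  r <- sqrt(h / a)
  structure(list(a = a, h = h, r = r, rmse = rmse,
                 n_points = nrow(pts), vertex = c(x = vx, y = vy),
                 base_y = base_y),
            class = "parabolic_fit")
}

#' @export
print.parabolic_fit <- function(x, ...) {
  cat(sprintf(
    "Parabolic SAM fit: h = %.3f um, r = %.3f um, a = %.6g 1/um (rmse %.3g um, %d points)\n",
    x$h, x$r, x$a, x$rmse, x$n_points))
  invisible(x)
}

#' @export
coef.parabolic_fit <- function(object, ...) {
  c(a = object$a, h = object$h, r = object$r)
}

#' Derive the SAM microphenotype set from height and radius
#'
#' Given apex height h and base radius r of the parabolic SAM model
#' y = h - (h/r^2) x^2, computes the derived shape statistics used as
#' phenotypes: ratio h/r, diameter 2r, midsection area (4/3) h r (the
#' parabolic-segment area), volume of the paraboloid of revolution
#' (pi/2) r^2 h, shape coefficient a = h/r^2, lateral surface area
#' (pi r / (6 h^2)) ((r^2 + 4 h^2)^(3/2) - r^3), and profile arc length
#' sqrt(r^2 + 4 h^2) + (r^2 / (2 h)) asinh(2 h / r).
#'
#' @param h Apex height in micrometres (> 0).
#' @param r Base radius in micrometres (> 0). Vectorized over h and r.
#' @return A data.frame with columns \code{height}, \code{radius},
#'   \code{ratio}, \code{diameter}, \code{midsection_area}, \code{volume},
#'   \code{coefficient}, \code{surface_area}, \code{arc_length}.
#' @examples
#' microphenotypes(100, 80)
#' @export
microphenotypes <- function(h, r) {
  if (any(!is.finite(h)) || any(!is.finite(r)) || any(h <= 0) || any(r <= 0))
    stop("h and r must be positive and finite")
  data.frame(
    height = h,
    radius = r,
    ratio = h / r,
    diameter = 2 * r,
    midsection_area = (4 / 3) * h * r,
    volume = (pi / 2) * r^2 * h,
    coefficient = h / r^2,
    surface_area = (pi * r / (6 * h^2)) * ((r^2 + 4 * h^2)^(3 / 2) - r^3),
    arc_length = sqrt(r^2 + 4 * h^2) + (r^2 / (2 * h)) * asinh(2 * h / r)
  )
}

#' Model-estimated versus directly measured SAM midsection area
#'
#' The parabolic model estimates the midsection area as (4/3) h r from the
#' fitted parameters; the direct measure is the polygon (shoelace) area of
#' the traced contour closed along its base chord.
#'
#' @param contour A \code{sam_contour} or (x, y) matrix in micrometres.
#' @return List with \code{estimated} and \code{measured} areas (um^2) and
#'   the \code{fit}.
#' @export
area_estimated_vs_measured <- function(contour) {
  pts <- as_contour_points(contour)
  fit <- fit_parabola(contour)
  est <- (4 / 3) * fit$h * fit$r
  o <- order(pts[, 1])
  poly_x <- pts[o, 1]; poly_y <- pts[o, 2]
  if (polygon_self_intersects(poly_x, poly_y))
    stop("contour polygon is self-intersecting; cannot measure area")
  # closing edge runs along the base chord from the last point back to the first
  n <- length(poly_x)
  meas <- abs(sum(poly_x * c(poly_y[-1], poly_y[1]) -
                  c(poly_x[-1], poly_x[1]) * poly_y)) / 2
  list(estimated = est, measured = meas, fit = fit)
}

# Checks the traced chain (excluding the base-closure edge) for segment
# crossings: an x-ordered function-graph chain cannot cross itself, so a hit
# marks a genuinely malformed trace (e.g. a figure-eight ordering). The
# closure edge is exempt because measurement noise legitimately dips a few
# boundary points below the base chord. Cheap segment-pair check (contours
# are ~10^2 points).
polygon_self_intersects <- function(x, y) {
  n <- length(x) - 1L  # chain segments only, no closure edge
  if (n < 3) return(FALSE)
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  cross_ok <- function(i, j) {
    d <- function(px, py, qx, qy, rx, ry) (qx - px) * (ry - py) - (qy - py) * (rx - px)
    p <- seg[i, ]; q <- seg[j, ]
    d1 <- d(p[1], p[2], p[3], p[4], q[1], q[2])
    d2 <- d(p[1], p[2], p[3], p[4], q[3], q[4])
    d3 <- d(q[1], q[2], q[3], q[4], p[1], p[2])
    d4 <- d(q[1], q[2], q[3], q[4], p[3], p[4])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (cross_ok(i, j)) return(TRUE)
    }
  }
  FALSE
}

#' Construct a SAM contour object
#'
#' @param x,y Point coordinates in micrometres, apex up.
#' @param genotype,replicate Identifiers carried through the pipeline.
#' @return A \code{sam_contour} data.frame with columns \code{genotype},
#'   \code{replicate}, \code{x}, \code{y}.
#' @export
sam_contour <- function(x, y, genotype = NA_character_, replicate = NA_integer_) {
  stopifnot(length(x) == length(y))
  if (length(x) < 7) stop("a contour needs at least 7 points")
  xc <- x - x[which.max(y)]
  if (!any(xc < 0) || !any(xc > 0))
    stop("contour must cover both sides of the apex")
  structure(data.frame(genotype = genotype, replicate = replicate,
                       x = x, y = y, stringsAsFactors = FALSE),
            class = c("sam_contour", "data.frame"))
}

as_contour_points <- function(contour) {
  if (inherits(contour, "sam_contour"))
    return(cbind(contour$x, contour$y))
  m <- as.matrix(contour)
  if (ncol(m) > 2) m <- m[, c("x", "y")]
  storage.mode(m) <- "double"
  m
}

#' Extract a SAM contour from a grayscale image
#'
#' Replaces manual tracing: Otsu-thresholds the image, keeps the largest
#' connected foreground component, walks its upper boundary (minimum image
#' row per column, i.e. the apex-side edge), and converts pixel coordinates
#' to micrometres. Image row indices increase downward; the returned contour
#' is apex-up in physical coordinates.
#'
#' @param image Numeric matrix in [0, 1] (rows = image rows) or an
#'   EBImage \code{Image}.
#' @param pixel_scale Micrometres per pixel.
#' @param invert Set when the dome is dark on a bright background.
#' @return A \code{sam_contour}.
#' @export
contour_from_image <- function(image, pixel_scale = 1, invert = FALSE) {
  m <- img_matrix(image)
  if (invert) m <- max(m) - m
  thr <- otsu_threshold(as.vector(m))
  fg <- m > thr
  if (!any(fg)) stop("no foreground component found in image")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(tab)
  comp <- EBImage::imageData(lab) == keep
  # EBImage x = matrix row; treat columns of the input matrix as image x
  cols <- which(apply(comp, 2, any))
  top_row <- vapply(cols, function(j) min(which(comp[, j])), integer(1))
  x_um <- (cols - 0.5) * pixel_scale
  y_um <- (nrow(m) - (top_row - 0.5)) * pixel_scale  # flip y-down to y-up
  sam_contour(x_um, y_um)
}

img_matrix <- function(image) {
  if (inherits(image, "Image")) {
    d <- EBImage::imageData(image)
    if (length(dim(d)) > 2) d <- d[, , 1]
    # EBImage stores x (columns of display) in dim 1; transpose to row/col
    return(t(d))
  }
  as.matrix(image)
}

# Otsu threshold on a raw intensity vector (between-class variance maximizer
# on a 256-bin histogram). Operates on masked pixel vectors, which a
# whole-image thresholder would bias.
otsu_threshold <- function(v, n_bins = 256) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, brk, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}
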
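#' Pearson correlation with Fisher-transformation significance
#'
#' Computes Pearson's product-moment correlation between two numeric vectors
#' and evaluates its significance with the Fisher z transformation:
#' z = atanh(r), se = 1/sqrt(n - 3), two-sided p = 2 * (1 - pnorm(|z|/se)).
#' Missing values are removed pairwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @return An object of class \code{correlation_result}: a list with
#'   \code{r}, \code{n}, \code{z} (Fisher z), \code{p} (two-sided), and
#'   \code{p_label} (the printed form, \code{"<2.22e-16"} below the double
#'   epsilon floor).
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50)
#' pearson_fisher(x, y)
#' @export
pearson_fisher <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs for the Fisher test")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in x or y")
  r <- stats::cor(x, y)
  # |r| = 1 exactly (e.g. y == x): atanh diverges; report the machine floor
  r_clamped <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  z <- atanh(r_clamped)
  se <- 1 / sqrt(n - 3)
  p <- 2 * stats::pnorm(abs(z) / se, lower.tail = FALSE)
  floor_p <- 2.22e-16
  structure(list(
    r = r, n = n, z = z, se = se, p = p,
    p_label = if (p < floor_p) sprintf("<%.3g", floor_p) else format(p)
  ), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson's r = %.4f (n = %d), Fisher z = %.4f, P %s\n",
              x$r, x$n, x$z,
              if (startsWith(x$p_label, "<")) x$p_label
              else paste0("= ", signif(x$p, 4))))
  invisible(x)
}

#' Assign genotypes to SAM-volume size classes by quartile
#'
#' Splits a panel into \code{small} (lower quartile), \code{intermediate}
#' (middle two quartiles) and \code{large} (upper quartile) by the
#' type-7 (linear interpolation) quartiles of the supplied values.
#' Values exactly on a quartile boundary fall in the lower class.
#'
#' @param volumes Named numeric vector of per-genotype values (typically
#'   BLUP+intercept SAM volumes); names are genotype ids.
#' @return A data.frame with columns \code{genotype}, \code{volume},
#'   \code{class} (factor small/intermediate/large), plus attributes
#'   \code{q1}/\code{q3} holding the quartile bounds used.
#' @export
classify_sizes <- function(volumes) {
  if (length(volumes) < 4) stop("need at least 4 genotypes to form quartiles")
  if (is.null(names(volumes))) names(volumes) <- seq_along(volumes)
  q <- stats::quantile(volumes, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) stop("degenerate quantiles: volumes carry no spread")
  cls <- ifelse(volumes <= q[1], "small",
                ifelse(volumes > q[2], "large", "intermediate"))
  # deterministic order for ties spanning a boundary: genotype-id order
  out <- data.frame(genotype = names(volumes), volume = unname(volumes),
                    class = factor(cls, levels = c("small", "intermediate", "large")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "q1") <- q[1]
  attr(out, "q3") <- q[2]
  out
}

#' Two-sample t test (Welch by default)
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom; \code{pooled = TRUE} restores the classic equal-variance form.
#' Two groups with zero variance and equal means return t = 0, p = 1 by
#' convention rather than an error.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance Student form instead of Welch.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
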
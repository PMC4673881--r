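#' Segment nuclei in a stained SAM section image
#'
#' Re-implementation of a standard nuclei-counting pipeline on a single
#' optical section: Gaussian smoothing, background subtraction, Otsu
#' threshold computed within the SAM mask, watershed split of touching
#' nuclei on the distance transform, and centroid extraction; objects
#' below a minimum-area floor are discarded.
#'
#' @param image Numeric matrix in [0, 1], rows = image rows (y-down).
#' @param mask Logical matrix of the SAM region, same shape.
#' @param pixel_scale Micrometres per pixel.
#' @param sigma Smoothing sigma in pixels (default 1.5).
#' @param min_area_px Minimum object area in pixels (default 4).
#' @return Object of class \code{nuclei_segmentation}: list with
#'   \code{centroids_px} (row, col matrix), \code{centroids_um}
#'   (x, y in the apex-up physical frame of the mask bounding box),
#'   \code{labels} (integer label matrix), \code{n} (nucleus count).
#' @export
segment_nuclei <- function(image, mask, pixel_scale = 1, sigma = 1.5,
                           min_area_px = 4) {
  if (!all(dim(image) == dim(mask))) stop("image and mask shapes differ")
  if (!any(mask)) stop("empty mask")
  # EBImage images index [x, y]; transpose our row/col matrices
  img_e <- EBImage::Image(t(image))
  sm <- EBImage::gblur(img_e, sigma = sigma)
  smv <- t(EBImage::imageData(sm))
  bg <- stats::median(smv[mask])
  fgv <- pmax(smv - bg, 0)
  vals <- fgv[mask]
  if (max(vals) <= 0)
    return(empty_segmentation(dim(image)))
  thr <- otsu_threshold(vals)
  bw <- fgv > thr & mask
  if (!any(bw)) return(empty_segmentation(dim(image)))
  bw_e <- EBImage::Image(t(bw) * 1)
  dm <- EBImage::distmap(bw_e)
  lab_e <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- t(EBImage::imageData(lab_e))
  areas <- tabulate(lab[lab > 0])
  small <- which(areas < min_area_px)
  if (length(small)) lab[lab %in% small] <- 0L
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(empty_segmentation(dim(image)))
  # intensity-weighted centroids: unbiased for blob-like nuclei
  cent <- t(vapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    wt <- fgv[w]
    if (sum(wt) <= 0) wt <- rep(1, nrow(w))
    colSums(w * wt) / sum(wt)
  }, numeric(2)))
  colnames(cent) <- c("row", "col")
  lab2 <- lab
  for (j in seq_along(ids)) lab2[lab == ids[j]] <- j
  structure(list(centroids_px = cent,
                 centroids_um = cbind(x = (cent[, "col"] - 0.5) * pixel_scale,
                                      y = (nrow(image) - cent[, "row"] + 0.5) *
                                        pixel_scale),
                 labels = lab2, n = nrow(cent),
                 pixel_scale = pixel_scale),
            class = "nuclei_segmentation")
}

empty_segmentation <- function(d) {
  structure(list(centroids_px = matrix(numeric(0), 0, 2,
                                       dimnames = list(NULL, c("row", "col"))),
                 centroids_um = matrix(numeric(0), 0, 2,
                                       dimnames = list(NULL, c("x", "y"))),
                 labels = matrix(0L, d[1], d[2]), n = 0L,
                 pixel_scale = NA_real_),
            class = "nuclei_segmentation")
}

#' @export
print.nuclei_segmentation <- function(x, ...) {
  cat(sprintf("nuclei segmentation: %d nuclei\n", x$n))
  invisible(x)
}

#' Voronoi cell lattice over a SAM mask
#'
#' Partitions the mask pixels by nearest nucleus centroid (Euclidean
#' distance, ties broken toward the lowest centroid index) into a lattice
#' of cells; reports per-cell areas, the SAM cell number (SCN = number of
#' centroids) and the average SAM cell size (ASCS = mask area / SCN).
#' The partition is exhaustive: cell areas sum to the mask area exactly at
#' pixel resolution.
#'
#' @param centroids_px Matrix with columns row, col (pixel coordinates),
#'   as from \code{\link{segment_nuclei}}.
#' @param mask Logical matrix of the SAM region.
#' @param pixel_scale Micrometres per pixel.
#' @return Object of class \code{cell_lattice}: list with \code{labels}
#'   (integer matrix; 0 outside mask), \code{areas_um2} (per-cell),
#'   \code{scn}, \code{ascs_um2}, \code{mask_area_um2}.
#' @export
tessellate_cells <- function(centroids_px, mask, pixel_scale = 1) {
  if (nrow(centroids_px) == 0) stop("need at least one centroid")
  px <- which(mask, arr.ind = TRUE)
  inside <- centroids_px[, 1] >= 1 & centroids_px[, 1] <= nrow(mask) &
    centroids_px[, 2] >= 1 & centroids_px[, 2] <= ncol(mask)
  in_mask <- inside & mask[cbind(pmax(pmin(round(centroids_px[, 1]),
                                           nrow(mask)), 1),
                                 pmax(pmin(round(centroids_px[, 2]),
                                           ncol(mask)), 1))]
  if (!all(in_mask))
    warning(sum(!in_mask), " centroid(s) fall outside the mask; still used")
  best_d <- rep(Inf, nrow(px))
  best_i <- rep(0L, nrow(px))
  for (i in seq_len(nrow(centroids_px))) {
    d <- (px[, 1] - centroids_px[i, 1])^2 + (px[, 2] - centroids_px[i, 2])^2
    upd <- d < best_d          # strict: ties keep the earlier (lower) index
    best_d[upd] <- d[upd]
    best_i[upd] <- i
  }
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[px] <- best_i
  counts <- tabulate(best_i, nbins = nrow(centroids_px))
  scn <- nrow(centroids_px)
  mask_area <- sum(mask) * pixel_scale^2
  structure(list(labels = labels,
                 areas_um2 = counts * pixel_scale^2,
                 scn = scn,
                 ascs_um2 = mask_area / scn,
                 mask_area_um2 = mask_area,
                 pixel_scale = pixel_scale),
            class = "cell_lattice")
}

#' @export
print.cell_lattice <- function(x, ...) {
  cat(sprintf("cell lattice: SCN = %d, ASCS = %.2f um^2 (mask %.1f um^2)\n",
              x$scn, x$ascs_um2, x$mask_area_um2))
  invisible(x)
}

#' Two-way ANOVA of cell traits on genotype class and SAM volume
#'
#' Models SCN or ASCS as genotype class (COM/ALT) x SAM volume with
#' sequential (Type-I) sums of squares: response ~ genotype + volume +
#' genotype:volume.
#'
#' @param table data.frame with columns \code{genotype_class} (factor with
#'   >= 2 levels), \code{volume}, and the response column.
#' @param response Name of the response column (e.g. "scn" or "ascs").
#' @return The \code{anova} table of the linear model fit.
#' @export
scn_ascs_anova <- function(table, response = "scn") {
  need <- c("genotype_class", "volume", response)
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  y <- table[[response]]
  if (stats::sd(y) == 0) stop("zero-variance response")
  g <- factor(table$genotype_class)
  if (nlevels(g) < 2) stop("need >= 2 genotype classes")
  if (any(table(g) < 3)) stop("need >= 3 observations per class")
  d <- data.frame(y = y, genotype = g, volume = table$volume)
  fit <- stats::lm(y ~ genotype + volume + genotype:volume, data = d)
  asgn <- fit$assign
  if (any(is.na(stats::coef(fit)))) {
    terms_lab <- attr(stats::terms(fit), "term.labels")
    bad <- unique(terms_lab[asgn[is.na(stats::coef(fit))]])
    stop("rank-deficient design: aliased term(s) ", paste(bad, collapse = ", "))
  }
  stats::anova(fit)
}
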
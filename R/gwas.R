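#' VanRaden genomic relationship (kinship) matrix
#'
#' K = W W' / (2 sum p_k (1 - p_k)) where W is the genotype matrix centered
#' by twice the ALT allele frequency. Missing genotypes are mean-imputed
#' per site for this computation only (never written back). With the
#' inbred {0, 2} coding this is the standard centered-genotype scaling
#' whose diagonal averages near 1 + F (inbreeding raises it above the
#' outbred expectation of 1).
#'
#' @param geno A \code{genotype_matrix} (post-filter).
#' @return Object of class \code{kinship_matrix}: the n x n symmetric
#'   matrix with attribute \code{method = "vanraden"}.
#' @export
vanraden_kinship <- function(geno) {
  X <- impute_calls(geno)
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("kinship undefined: all sites monomorphic")
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  W <- sweep(X, 2, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(geno$individuals, geno$individuals)
  structure(K, method = "vanraden", class = c("kinship_matrix", "matrix"))
}

impute_calls <- function(geno) {
  X <- geno$calls
  storage.mode(X) <- "double"
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- cm[idx[, 2]]
  X
}

#' Genotype principal components
#'
#' PCs of the mean-imputed, column-centered genotype matrix, used as
#' population-structure covariates in the mixed-model scan.
#'
#' @param geno A \code{genotype_matrix}.
#' @param n Number of components to return.
#' @return n_individuals x n matrix of PC scores.
#' @export
genotype_pcs <- function(geno, n = 3) {
  X <- impute_calls(geno)
  X <- sweep(X, 2, colMeans(X))
  n <- min(n, nrow(X) - 1, ncol(X))
  pc <- stats::prcomp(X, center = FALSE, rank. = n)
  scores <- pc$x[, seq_len(n), drop = FALSE]
  rownames(scores) <- geno$individuals
  scores
}

# REML profile log-likelihood for the single-kinship mixed model, on the
# eigenbasis of K: y* ~ N(X* b, sigma2_g diag(lambda + delta)) with
# delta = sigma2_e / sigma2_g. Returns the profiled quantities.
reml_profile <- function(log_delta, yr, Xr, lambda) {
  delta <- exp(log_delta)
  w <- 1 / (lambda + delta)
  XtW <- t(Xr * w)
  A <- XtW %*% Xr
  b <- solve(A, XtW %*% yr)
  res <- yr - Xr %*% b
  n <- length(yr); q <- ncol(Xr)
  rss <- sum(w * res^2)
  s2 <- rss / (n - q)
  ll <- -0.5 * ((n - q) * (log(2 * pi * s2) + 1) + sum(log(lambda + delta)) +
                  determinant(A, logarithm = TRUE)$modulus)
  list(ll = as.numeric(ll), delta = delta, beta = b, sigma2_g = s2,
       sigma2_e = s2 * delta)
}

# ML profile log-likelihood (used for covariate-set comparison, where REML
# likelihoods are not comparable across different fixed-effect matrices)
ml_profile <- function(log_delta, yr, Xr, lambda) {
  delta <- exp(log_delta)
  w <- 1 / (lambda + delta)
  XtW <- t(Xr * w)
  b <- solve(XtW %*% Xr, XtW %*% yr)
  rss <- sum(w * (yr - Xr %*% b)^2)
  n <- length(yr)
  s2 <- rss / n
  -0.5 * (n * (log(2 * pi * s2) + 1) + sum(log(lambda + delta)))
}

fit_null_mlm <- function(y, K, covariates = NULL) {
  n <- length(y)
  if (stats::sd(y) == 0) stop("zero-variance phenotype")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values, 0) + 1e-8   # PSD jitter
  U <- eig$vectors
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)
  opt <- stats::optimize(function(ld) reml_profile(ld, yr, Xr, lambda)$ll,
                         interval = c(-10, 10), maximum = TRUE, tol = 1e-6)
  prof <- reml_profile(opt$maximum, yr, Xr, lambda)
  opt_ml <- stats::optimize(function(ld) ml_profile(ld, yr, Xr, lambda),
                            interval = c(-10, 10), maximum = TRUE,
                            tol = 1e-6)
  list(U = U, lambda = lambda, yr = yr, Xr = Xr, X = X,
       delta = prof$delta, sigma2_g = prof$sigma2_g,
       sigma2_e = prof$sigma2_e, reml_ll = prof$ll,
       ml_ll = opt_ml$objective, beta = prof$beta)
}

#' Select population-structure covariates for the mixed model
#'
#' Fits the null mixed model (kinship random effect) with 0..max_pcs
#' genotype principal components as fixed covariates and returns the set
#' minimizing BIC. The BIC uses the maximum-likelihood (not REML)
#' log-likelihood, since REML likelihoods are not comparable across
#' different fixed-effect matrices.
#'
#' @param y Phenotype vector (BLUP+intercept per individual).
#' @param K Kinship matrix.
#' @param PCs Matrix of candidate PCs (columns ordered).
#' @param max_pcs Maximum number of PCs to consider.
#' @return List with \code{n_pcs}, \code{covariates} (matrix or NULL),
#'   \code{bic} (vector over candidate counts).
#' @export
select_covariates <- function(y, K, PCs, max_pcs = 3) {
  max_pcs <- min(max_pcs, if (is.null(PCs)) 0 else ncol(PCs))
  n <- length(y)
  bic <- vapply(0:max_pcs, function(k) {
    cov_k <- if (k == 0) NULL else PCs[, seq_len(k), drop = FALSE]
    fit <- fit_null_mlm(y, K, cov_k)
    # parameters: fixed effects + two variance components
    (1 + k + 2) * log(n) - 2 * fit$ml_ll
  }, numeric(1))
  k_best <- which.min(bic) - 1L
  list(n_pcs = k_best,
       covariates = if (k_best == 0) NULL
                    else PCs[, seq_len(k_best), drop = FALSE],
       bic = stats::setNames(bic, paste0("pc", 0:max_pcs)))
}

#' Unified mixed linear model association scan
#'
#' Tests each SNP in the model y = X b + s a + u + e with
#' u ~ N(0, sigma2_g K), via a single eigendecomposition of K and a 1-D
#' REML profile over delta = sigma2_e/sigma2_g under the null. With P3D
#' ("population parameters previously determined", the default) the null
#' variance components are reused for every SNP and each marker test is a
#' generalized least squares fit on the eigen-rotated data with a Wald t
#' test on n - rank(X) - 1 degrees of freedom; without P3D, delta is
#' re-estimated per SNP. Missing genotypes are mean-imputed per site for
#' testing only.
#'
#' @param y Phenotype vector aligned with \code{geno$individuals}.
#' @param geno A \code{genotype_matrix} (post-filter).
#' @param K Kinship matrix (default VanRaden from \code{geno}).
#' @param covariates Optional fixed covariate matrix (e.g. PCs).
#' @param p3d Reuse null variance components per SNP (default TRUE).
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @return Object of class \code{mlm_scan}: per-SNP data.frame
#'   \code{results} (chrom, pos, effect, se, t, neglog10p), model metadata
#'   (\code{sigma2_g}, \code{sigma2_e}, \code{delta}, \code{n_pcs},
#'   \code{p3d}, \code{M}, \code{threshold}).
#' @export
mlm_scan <- function(y, geno, K = NULL, covariates = NULL, p3d = TRUE,
                     alpha = 0.01) {
  stopifnot(length(y) == nrow(geno$calls))
  if (is.null(K)) K <- vanraden_kinship(geno)
  null_fit <- fit_null_mlm(y, K, covariates)
  U <- null_fit$U; lambda <- null_fit$lambda
  yr <- as.vector(null_fit$yr); Xr <- null_fit$Xr
  n <- length(yr); q <- ncol(Xr)
  S <- impute_calls(geno)
  Sr <- crossprod(U, S)
  M <- ncol(Sr)
  if (p3d) {
    w <- 1 / (lambda + null_fit$delta)
    XtW <- t(Xr * w)
    A_inv <- solve(XtW %*% Xr)
    # weighted residualization of y and every SNP on X (FWL)
    proj <- function(v) v - Xr %*% (A_inv %*% (XtW %*% v))
    y_t <- as.vector(proj(yr))
    S_t <- proj(Sr)
    sxx <- colSums(w * S_t^2)
    sxy <- colSums(w * S_t * y_t)
    syy <- sum(w * y_t^2)
    mono <- sxx < 1e-12
    effect <- ifelse(mono, NA, sxy / sxx)
    rss <- pmax(syy - effect^2 * sxx, 0)
    df <- n - q - 1
    s2 <- rss / df
    se <- sqrt(s2 / sxx)
    tstat <- effect / se
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  } else {
    effect <- se <- tstat <- p <- rep(NA_real_, M)
    df <- n - q - 1
    for (k in seq_len(M)) {
      Xk <- cbind(Xr, Sr[, k])
      if (stats::sd(Sr[, k]) < 1e-12) next
      opt <- stats::optimize(function(ld) reml_profile(ld, yr, Xk, lambda)$ll,
                             interval = c(-10, 10), maximum = TRUE,
                             tol = 1e-6)
      pr <- reml_profile(opt$maximum, yr, Xk, lambda)
      w <- 1 / (lambda + pr$delta)
      Ainv <- solve(t(Xk * w) %*% Xk)
      effect[k] <- pr$beta[q + 1]
      se[k] <- sqrt(pr$sigma2_g * Ainv[q + 1, q + 1])
      tstat[k] <- effect[k] / se[k]
      p[k] <- 2 * stats::pt(abs(tstat[k]), df, lower.tail = FALSE)
    }
  }
  neglog10p <- -(stats::pt(abs(tstat), df, lower.tail = FALSE,
                           log.p = TRUE) + log(2)) / log(10)
  res <- data.frame(chrom = geno$sites$chrom, pos = geno$sites$pos,
                    com = geno$sites$com, alt = geno$sites$alt,
                    effect = effect, se = se, t = tstat, p = p,
                    neglog10p = neglog10p, stringsAsFactors = FALSE)
  structure(list(results = res, M = M,
                 threshold = bonferroni_threshold(alpha, M), alpha = alpha,
                 sigma2_g = null_fit$sigma2_g,
                 sigma2_e = null_fit$sigma2_e, delta = null_fit$delta,
                 n_pcs = q - 1L, p3d = p3d,
                 individuals = geno$individuals),
            class = "mlm_scan")
}

#' @export
print.mlm_scan <- function(x, ...) {
  cat(sprintf(
    "Mixed-model scan: %d SNPs, %d PC covariates, P3D = %s\n",
    x$M, x$n_pcs, x$p3d))
  cat(sprintf("  variance components: sigma2_g = %.4g, sigma2_e = %.4g\n",
              x$sigma2_g, x$sigma2_e))
  cat(sprintf("  Bonferroni threshold (alpha = %g): -log10 p > %.2f; %d TAS\n",
              x$alpha, x$threshold,
              sum(x$results$neglog10p > x$threshold, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.mlm_scan <- function(object, ...) {
  print(object)
  tas <- trait_associated_snps(object)
  if (nrow(tas)) {
    cat("Top associations:\n")
    print(utils::head(tas[order(-tas$neglog10p),
                          c("chrom", "pos", "effect", "neglog10p")], 10))
  }
  invisible(object)
}

#' Manhattan plot of an association scan
#'
#' @param x An \code{mlm_scan}.
#' @param ... Passed to \code{plot}.
#' @export
plot.mlm_scan <- function(x, ...) {
  r <- x$results
  chrom_f <- factor(r$chrom, levels = unique(r$chrom))
  off <- c(0, cumsum(tapply(r$pos, chrom_f, max)))[as.integer(chrom_f)]
  graphics::plot(off + r$pos, r$neglog10p, pch = 16, cex = 0.5,
                 col = c("grey30", "steelblue")[1 + as.integer(chrom_f) %% 2],
                 xlab = "position", ylab = expression(-log[10] * italic(p)),
                 main = "SAM volume association scan", ...)
  graphics::abline(h = x$threshold, lty = 3, col = "red")
  invisible(x)
}

#' Bonferroni genome-wide significance threshold
#'
#' T = -log10(alpha / M) for M tests at family-wise error rate alpha, in
#' -log10 p units.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param M Number of tests (>= 1).
#' @return The threshold T.
#' @examples
#' bonferroni_threshold(0.01, 923000 + 358000)  # 8.11
#' @export
bonferroni_threshold <- function(alpha, M) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (M < 1) stop("M must be >= 1")
  -log10(alpha / M)
}

#' Trait-associated SNPs of a scan
#'
#' @param scan An \code{mlm_scan}.
#' @param threshold Override the scan's Bonferroni threshold.
#' @return The rows of the result table with -log10 p above the threshold.
#' @export
trait_associated_snps <- function(scan, threshold = scan$threshold) {
  r <- scan$results
  r[!is.na(r$neglog10p) & r$neglog10p > threshold, , drop = FALSE]
}

#' Map trait-associated SNPs to candidate genes
#'
#' A TAS is assigned every gene within \code{window} bases of the SNP
#' position; the inside-gene flag is set when the gene interval itself
#' contains it. Distance is the gap (number of bases strictly between the
#' SNP and the gene boundary; 0 if inside), the GenomicRanges convention.
#'
#' @param tas data.frame with \code{chrom} and \code{pos} (1-based).
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive, as read from GFF3/BED via
#'   \code{\link{read_gene_annotations}}), or a \code{GRanges}.
#' @param window Window size in bp (default 100000).
#' @return data.frame of assignments: tas chrom/pos, gene_id, distance,
#'   inside.
#' @export
map_candidates <- function(tas, genes, window = 1e5) {
  if (nrow(tas) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      gene_id = character(0), distance = integer(0),
                      inside = logical(0)))
  if (!methods::is(genes, "GRanges")) {
    genes_gr <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start, genes$end),
      gene_id = genes$gene_id)
  } else genes_gr <- genes
  known <- as.character(GenomicRanges::seqnames(genes_gr))
  miss <- setdiff(unique(tas$chrom), unique(known))
  for (mc in miss)
    warning("TAS chromosome '", mc, "' absent from gene annotation")
  tas_gr <- GenomicRanges::GRanges(tas$chrom,
                                   IRanges::IRanges(tas$pos, tas$pos))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(tas_gr, genes_gr, maxgap = window))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(tas_gr[qi], genes_gr[si])
  data.frame(chrom = tas$chrom[qi], pos = tas$pos[qi],
             gene_id = genes_gr$gene_id[si],
             distance = as.integer(d), inside = d == 0L,
             stringsAsFactors = FALSE)
}

#' Read gene annotations from BED or GFF3
#'
#' @param path Annotation file (.bed or .gff3/.gff).
#' @return data.frame with gene_id, chrom, start, end (1-based inclusive),
#'   strand.
#' @export
read_gene_annotations <- function(path) {
  gr <- rtracklayer::import(path)
  id <- if (!is.null(gr$gene_id)) gr$gene_id
        else if (!is.null(gr$ID)) gr$ID
        else if (!is.null(gr$name)) gr$name
        else paste0("gene", seq_along(gr))
  data.frame(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' ALT-allele burden versus phenotype
#'
#' Counts the ALT-homozygous calls per individual over the TAS sites
#' (missing calls skipped) and correlates the burden with the phenotype
#' via \code{\link{pearson_fisher}}.
#'
#' @param tas data.frame of TAS with chrom/pos (rows of a scan result or
#'   any site list present in \code{geno}).
#' @param geno The \code{genotype_matrix}.
#' @param y Phenotype vector aligned with individuals.
#' @return List with \code{burden} (per-individual ALT counts) and
#'   \code{cor} (a \code{correlation_result}).
#' @export
alt_burden <- function(tas, geno, y) {
  if (nrow(tas) == 0) stop("TAS set is empty")
  key <- paste(geno$sites$chrom, geno$sites$pos, sep = ":")
  idx <- match(paste(tas$chrom, tas$pos, sep = ":"), key)
  if (any(is.na(idx))) stop("some TAS sites absent from the genotype matrix")
  counts <- rowSums(geno$calls[, idx, drop = FALSE] == 2L, na.rm = TRUE)
  if (stats::sd(counts) == 0)
    stop("undefined correlation: every individual has the same ALT burden")
  list(burden = counts, cor = pearson_fisher(counts, y))
}
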
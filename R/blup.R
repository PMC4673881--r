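#' BLUP phenotypes across replicated trials
#'
#' Fits the mixed model y_ij = mu + rho_j + g_i + e_ij with replicate
#' (growth batch) as a fixed effect and genotype as a random effect, by
#' REML. Per-genotype phenotypes are reported in BLUP+intercept form, and
#' the entry-mean repeatability (entry-mean heritability) is
#' H^2 = sigma2_g / (sigma2_g + sigma2_e / n_bar) with n_bar the harmonic
#' mean of per-genotype replicate counts. Sum-to-zero replicate contrasts
#' make the intercept the grand replicate-level mean. Accounts for missing
#' genotype x replicate cells (e.g. failed germination).
#'
#' @param table data.frame with columns \code{genotype}, \code{replicate}
#'   and a phenotype column.
#' @param value Name of the phenotype column (default "volume").
#' @return Object of class \code{blup_fit}: list with \code{intercept},
#'   \code{blup} (named per-genotype BLUPs), \code{blup_plus_intercept},
#'   \code{replicate_effects}, \code{sigma2_g}, \code{sigma2_e},
#'   \code{n_bar}, \code{H2}, and the underlying \code{lme4} fit.
#' @examples
#' tab <- expand.grid(genotype = letters[1:6], replicate = 1:3)
#' tab$volume <- rnorm(6)[as.integer(tab$genotype)] + rnorm(18, sd = 0.3)
#' fit_blup(tab)
#' @export
fit_blup <- function(table, value = "volume") {
  if (!all(c("genotype", "replicate", value) %in% names(table)))
    stop("table needs genotype, replicate and '", value, "' columns")
  y <- table[[value]]
  if (!is.numeric(y) || any(!is.finite(y))) stop("non-numeric phenotype values")
  d <- data.frame(y = y,
                  genotype = factor(table$genotype),
                  replicate = factor(table$replicate))
  reps_per_geno <- table(d$genotype)
  if (all(reps_per_geno < 2))
    stop("variance components unidentifiable: every genotype is a singleton")
  if (nlevels(d$genotype) < 2) stop("need at least 2 genotypes")
  single_rep <- nlevels(d$replicate) < 2
  form <- if (single_rep) y ~ (1 | genotype) else y ~ replicate + (1 | genotype)
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = d,
               contrasts = if (single_rep) NULL
                           else list(replicate = stats::contr.sum),
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_g <- max(vc$vcov[vc$grp == "genotype"], 1e-12)
  sigma2_e <- max(vc$vcov[vc$grp == "Residual"], 1e-12)
  fe <- lme4::fixef(fit)
  intercept <- unname(fe[1])
  re <- lme4::ranef(fit)$genotype
  blup <- stats::setNames(re[, 1], rownames(re))
  n_bar <- length(reps_per_geno) / sum(1 / as.numeric(reps_per_geno))
  H2 <- sigma2_g / (sigma2_g + sigma2_e / n_bar)
  rep_eff <- if (single_rep) numeric(0) else {
    eff <- fe[-1]
    stats::setNames(c(eff, -sum(eff)), levels(d$replicate))
  }
  structure(list(intercept = intercept, blup = blup,
                 blup_plus_intercept = blup + intercept,
                 replicate_effects = rep_eff,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 n_bar = n_bar, H2 = H2, model = fit),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf(
    "BLUP fit: %d genotypes, n_bar = %.2f, sigma2_g = %.4g, sigma2_e = %.4g, H2 = %.3f\n",
    length(x$blup), x$n_bar, x$sigma2_g, x$sigma2_e, x$H2))
  invisible(x)
}

#' @export
coef.blup_fit <- function(object, ...) object$blup_plus_intercept

#' Entry-mean repeatability of a fitted BLUP model
#'
#' H^2 = sigma2_g / (sigma2_g + sigma2_e / n_bar): the fraction of
#' entry-mean variance that is genetic.
#'
#' @param result A \code{blup_fit}.
#' @return The repeatability in [0, 1].
#' @export
repeatability <- function(result) {
  stopifnot(inherits(result, "blup_fit"))
  result$H2
}
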
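#' Simulation configuration for the synthetic SAM study
#'
#' Bundles every parameter the generators need. Defaults emulate the study
#' conditions: a diverse inbred panel of 369 genotypes grown in 4
#' biological replicates, rare alternate (ALT) alleles so the common allele
#' exceeds 91\% frequency, subpopulation structure, RNAseq-style
#' missingness, and a rare-allele large-effect genetic architecture whose
#' variance components imply an entry-mean repeatability of SAM volume near
#' 0.84 and an ALT-burden correlation with volume near 0.5 (see the
#' methods vignette for the derivation).
#'
#' @param seed Master seed; every generator derives its own substream.
#' @param n_genotypes,n_replicates Panel size and biological replicates.
#' @param n_snps Number of simulated SNP sites.
#' @param n_subpops Number of subpopulations in the panel.
#' @param alt_freq_range Per-site ALT allele frequency range (drawn
#'   uniformly); must lie in (0, 0.5].
#' @param missing_rate Genotype call missingness, uniform over the matrix.
#' @param structure_conc Dirichlet concentration controlling how strongly a
#'   site's ALT carriers cluster within one subpopulation (smaller =
#'   stronger structure; rare alleles become subpopulation-private).
#' @param causal_effects data.frame with columns \code{snp} (site index)
#'   and \code{effect} (um^3 added to SAM volume per ALT genotype);
#'   default: 12 evenly spaced sites at +65000 um^3 each, the rare-allele
#'   large-effect regime derived in the methods vignette.
#' @param h2_polygenic Plot-level polygenic heritability
#'   sigma_g^2 / (sigma_g^2 + sigma_e^2) excluding the causal SNPs.
#' @param pheno_mean Mean SAM volume mu (um^3).
#' @param resid_sd Replicate-level residual sd sigma_e (um^3).
#' @param batch_effect_sd SD of additive replicate (growth-batch) shifts
#'   (um^3).
#' @param germination_drop Fraction of genotype x replicate cells lost to
#'   failed germination.
#' @param noise_sd Contour point measurement noise (um).
#' @param n_points Points per traced contour.
#' @param ratio_meanlog,ratio_sdlog Log-normal parameters of the
#'   height/radius aspect ratio across genotypes.
#' @param pixel_scale Micrometres per pixel for rendered images.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_genotypes = 369,
                       n_replicates = 4,
                       n_snps = 5000,
                       n_subpops = 3,
                       alt_freq_range = c(0.01, 0.09),
                       missing_rate = 0.2,
                       structure_conc = 1,
                       causal_effects = NULL,
                       h2_polygenic = 0.45,
                       pheno_mean = 390000,
                       resid_sd = 70000,
                       batch_effect_sd = 10000,
                       germination_drop = 0.05,
                       noise_sd = 2,
                       n_points = 100,
                       ratio_meanlog = log(2),
                       ratio_sdlog = 0.1,
                       pixel_scale = 0.5) {
  if (is.null(causal_effects))
    causal_effects <- data.frame(
      snp = unique(round(seq_len(12) * n_snps / 13)),
      effect = 65000)
  cfg <- list(seed = seed, n_genotypes = n_genotypes,
              n_replicates = n_replicates, n_snps = n_snps,
              n_subpops = n_subpops, alt_freq_range = alt_freq_range,
              missing_rate = missing_rate, structure_conc = structure_conc,
              causal_effects = causal_effects, h2_polygenic = h2_polygenic,
              pheno_mean = pheno_mean, resid_sd = resid_sd,
              batch_effect_sd = batch_effect_sd,
              germination_drop = germination_drop, noise_sd = noise_sd,
              n_points = n_points, ratio_meanlog = ratio_meanlog,
              ratio_sdlog = ratio_sdlog, pixel_scale = pixel_scale)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(seed) != 1 || !is.finite(seed)) stop("invalid seed")
    for (nm in c("n_genotypes", "n_replicates", "n_snps", "n_subpops",
                 "n_points"))
      if (cfg[[nm]] < 1) stop("count '", nm, "' must be positive")
    for (nm in c("missing_rate", "germination_drop"))
      if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
        stop("fraction '", nm, "' must be in [0, 1]")
    if (h2_polygenic < 0 || h2_polygenic >= 1)
      stop("h2_polygenic must be in [0, 1)")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
    if (length(alt_freq_range) != 2 ||
        alt_freq_range[1] <= 0 || alt_freq_range[2] > 0.5 ||
        alt_freq_range[1] > alt_freq_range[2])
      stop("alt_freq_range must lie within (0, 0.5]")
    if (nrow(causal_effects) > 0 &&
        (any(causal_effects$snp < 1) || any(causal_effects$snp > n_snps)))
      stop("causal snp indices out of range")
  })
  invisible(cfg)
}

# Per-generator substreams off the master seed, so modules can be re-run
# independently and still reproduce byte-identically.
substream <- function(cfg, k) {
  set.seed((as.integer(cfg$seed) %% 199999L) * 7919L + k)
}

#' Simulate the genotype panel's ground truth
#'
#' Draws everything downstream generators share: subpopulation assignments,
#' the genotype matrix, per-genotype true SAM dimensions (height, radius)
#' and volumes with causal-SNP and polygenic contributions, and the true
#' variance components. The truth object is consumed by tests and by the
#' other generators, never by the analysis pipeline.
#'
#' @param cfg A \code{sim_config}.
#' @return List of class \code{sam_truth} with elements \code{genotypes}
#'   (a \code{genotype_matrix}), \code{subpop}, \code{true_volume},
#'   \code{true_h}, \code{true_r}, \code{causal} (data.frame),
#'   \code{sigma2_g}, \code{sigma2_e}, \code{mu}.
#' @export
sim_truth <- function(cfg) {
  geno <- sim_genotypes(cfg)
  substream(cfg, 3L)
  n <- cfg$n_genotypes
  sigma2_e <- cfg$resid_sd^2
  sigma2_g <- cfg$h2_polygenic / (1 - cfg$h2_polygenic) * sigma2_e
  # polygenic values correlated through the realized genomic relationship
  calls <- geno$calls
  p <- colMeans(calls, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0  # sites with every call missing carry no information
  W <- sweep(ifelse(is.na(calls), 2 * rep(p, each = n), calls), 2, 2 * p)
  u <- stats::rnorm(ncol(W))
  g_raw <- as.vector(W %*% u)
  g <- if (stats::sd(g_raw) > 0)
    g_raw / stats::sd(g_raw) * sqrt(sigma2_g) else rep(0, n)
  causal <- cfg$causal_effects
  beta_part <- rep(0, n)
  if (nrow(causal) > 0) {
    # biology acts through the true (pre-missingness) genotype
    G_causal <- geno$calls_complete[, causal$snp, drop = FALSE]
    beta_part <- as.vector(G_causal %*% (causal$effect / 2))
  }
  true_volume <- cfg$pheno_mean + beta_part + g
  true_volume <- pmax(true_volume, 0.05 * cfg$pheno_mean)
  ratio <- stats::rlnorm(n, cfg$ratio_meanlog, cfg$ratio_sdlog)
  # V = (pi/2) r^2 h with rho = h/r  =>  h = (2 V rho^2 / pi)^(1/3)
  true_h <- (2 * true_volume * ratio^2 / pi)^(1 / 3)
  true_r <- true_h / ratio
  structure(list(genotypes = geno, subpop = geno$subpop,
                 true_volume = true_volume, true_h = true_h,
                 true_r = true_r, causal = causal,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 mu = cfg$pheno_mean), class = "sam_truth")
}

#' Simulate a homozygous inbred genotype matrix
#'
#' Calls are coded 0 (COM/COM) and 2 (ALT/ALT); the panel is fully inbred
#' so no heterozygotes occur. Each site draws its ALT frequency uniformly
#' from \code{alt_freq_range} and places exactly that fraction of ALT
#' carriers, allocated with subpopulation-biased weights (Dirichlet
#' concentration \code{structure_conc}) so rare alleles tend to be private
#' to one subpopulation — which is what induces detectable population
#' structure. Missing calls (\code{NA}) are sprinkled uniformly at
#' \code{missing_rate}.
#'
#' @param cfg A \code{sim_config}.
#' @return A \code{\link{genotype_matrix}} with an extra \code{subpop}
#'   element (true subpopulation of each individual).
#' @export
sim_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  substream(cfg, 2L)
  n <- cfg$n_genotypes; m <- cfg$n_snps
  subpop <- sort(rep_len(seq_len(cfg$n_subpops), n))
  p_site <- stats::runif(m, cfg$alt_freq_range[1], cfg$alt_freq_range[2])
  calls <- matrix(0L, n, m)
  for (k in seq_len(m)) {
    n_alt <- max(1L, round(p_site[k] * n))
    w_sub <- stats::rgamma(cfg$n_subpops, shape = cfg$structure_conc)
    w_sub <- w_sub / sum(w_sub)
    carriers <- sample.int(n, n_alt, prob = w_sub[subpop])
    calls[carriers, k] <- 2L
  }
  calls_complete <- calls
  if (cfg$missing_rate > 0) {
    nmiss <- round(cfg$missing_rate * length(calls))
    calls[sample.int(length(calls), nmiss)] <- NA_integer_
  }
  ids <- sprintf("G%03d", seq_len(n))
  sites <- data.frame(chrom = "1",
                      pos = seq_len(m) * 100L,
                      com = "A", alt = "T",
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, sites, ids, source = "simulated")
  gm$subpop <- subpop
  gm$true_alt_freq <- p_site
  gm$calls_complete <- calls_complete  # pre-missingness truth, tests only
  gm
}

#' Simulate the phenotype replicate table
#'
#' Generates SAM volume observations y_ij = mu + sum_k beta_k g_ik / 2 +
#' g_i + b_j + e_ij: causal-SNP effects, a polygenic genotype effect
#' correlated through the realized genomic relationship, additive
#' replicate (batch) shifts, and i.i.d. residuals. A fraction of genotype
#' x replicate cells is dropped to emulate failed germination.
#'
#' @param truth A \code{sam_truth} from \code{\link{sim_truth}} (or a
#'   \code{sim_config}, in which case the truth is simulated first).
#' @param cfg The \code{sim_config}.
#' @return List with \code{table} (data.frame genotype, replicate, volume)
#'   and \code{truth}.
#' @export
sim_phenotypes <- function(truth, cfg) {
  if (inherits(truth, "sim_config")) { cfg <- truth; truth <- sim_truth(cfg) }
  validate_sim_config(cfg)
  substream(cfg, 4L)
  n <- cfg$n_genotypes; nr <- cfg$n_replicates
  batch <- stats::rnorm(nr, 0, cfg$batch_effect_sd)
  tab <- expand.grid(genotype = truth$genotypes$individuals,
                     replicate = seq_len(nr),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(tab$genotype, truth$genotypes$individuals)
  tab$volume <- truth$true_volume[gi] + batch[tab$replicate] +
    stats::rnorm(nrow(tab), 0, cfg$resid_sd)
  if (cfg$germination_drop > 0) {
    drop <- stats::runif(nrow(tab)) < cfg$germination_drop
    # keep at least one replicate per genotype
    first_of <- !duplicated(tab$genotype)
    tab <- tab[!(drop & !first_of), , drop = FALSE]
  }
  rownames(tab) <- NULL
  truth$batch <- batch
  list(table = tab, truth = truth)
}

#' Simulate traced SAM contours
#'
#' For each genotype x replicate, the replicate-level (h, r) are derived
#' from the replicate's volume (batch + residual perturbations of the
#' genotype's true volume at the genotype's aspect ratio), and
#' \code{n_points} points are sampled on the parabola
#' y = h - (h/r^2) x^2 over x in [-r, r] with i.i.d. Gaussian vertical
#' noise of sd \code{noise_sd}.
#'
#' @param truth A \code{sam_truth} (or a \code{sim_config}).
#' @param cfg The \code{sim_config}.
#' @return List with \code{contours} (list of \code{sam_contour}),
#'   \code{hr} (data.frame of the generating replicate-level h, r), and
#'   \code{truth}.
#' @export
sim_contours <- function(truth, cfg) {
  if (inherits(truth, "sim_config")) { cfg <- truth; truth <- sim_truth(cfg) }
  validate_sim_config(cfg)
  ph <- sim_phenotypes(truth, cfg)
  substream(cfg, 5L)
  tab <- ph$table
  gi <- match(tab$genotype, truth$genotypes$individuals)
  ratio <- truth$true_h[gi] / truth$true_r[gi]
  v <- pmax(tab$volume, 0.05 * cfg$pheno_mean)
  h <- (2 * v * ratio^2 / pi)^(1 / 3)
  r <- h / ratio
  contours <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    x <- seq(-r[i], r[i], length.out = cfg$n_points)
    y <- h[i] - (h[i] / r[i]^2) * x^2 +
      stats::rnorm(cfg$n_points, 0, cfg$noise_sd)
    contours[[i]] <- sam_contour(x, y, genotype = tab$genotype[i],
                                 replicate = tab$replicate[i])
  }
  list(contours = contours,
       hr = data.frame(genotype = tab$genotype, replicate = tab$replicate,
                       h = h, r = r, stringsAsFactors = FALSE),
       truth = truth)
}

#' Render a synthetic nuclei image inside a parabolic SAM mask
#'
#' Places approximately (parabolic segment area) / \code{mean_cell_area}
#' nuclei centroids by hard-core (minimum-distance) dart throwing inside
#' the parabola y = h - (h/r^2) x^2, renders each as a Gaussian blob on a
#' pixel grid, and adds Gaussian background noise.
#'
#' @param h,r SAM height and radius in micrometres.
#' @param mean_cell_area Target mean cell area (um^2, > 0).
#' @param cfg A \code{sim_config} (pixel_scale and seed are used).
#' @param background_noise SD of additive background noise (image in
#'   [0, 1] scale).
#' @param blob_sigma_um Gaussian blob sigma in micrometres (default
#'   0.22 sqrt(mean_cell_area)).
#' @return List with \code{image} (numeric matrix, rows = image rows,
#'   y-down), \code{mask} (logical matrix), \code{centroids_um}
#'   (true centroid coordinates, apex-up physical frame),
#'   \code{pixel_scale}.
#' @export
sim_nuclei_image <- function(h, r, mean_cell_area, cfg,
                             background_noise = 0.02,
                             blob_sigma_um = NULL) {
  if (mean_cell_area <= 0) stop("mean_cell_area must be positive")
  validate_sim_config(cfg)
  substream(cfg, 6L)
  ps <- cfg$pixel_scale
  pad <- 4 * ps
  width_um <- 2 * r + 2 * pad
  height_um <- h + 2 * pad
  nc <- ceiling(width_um / ps); nr_ <- ceiling(height_um / ps)
  # physical coords: x in [-r-pad, r-pad], y in [0 - pad, h + pad], apex up
  px_x <- ((seq_len(nc) - 0.5) * ps) - r - pad
  px_y <- height_um - ((seq_len(nr_) - 0.5) * ps) - pad  # row 1 = top
  inside <- function(x, y) y >= 0 & y <= h - (h / r^2) * x^2
  mask <- outer(px_y, px_x, function(y, x) inside(x, y))
  target_n <- round((4 / 3) * h * r / mean_cell_area)
  d_min <- 0.72 * sqrt(mean_cell_area)
  sig <- if (is.null(blob_sigma_um)) 0.18 * sqrt(mean_cell_area) else blob_sigma_um
  # nuclei sit inside the tissue, away from the boundary, so rendered blobs
  # are not clipped by the mask
  margin <- 2 * sig
  clear <- function(x, y)
    inside(x, y + margin) & inside(x - margin, y) & inside(x + margin, y) &
      y >= margin
  cx <- numeric(0); cy <- numeric(0)
  attempts <- 0L
  while (length(cx) < target_n && attempts < 500L * target_n) {
    attempts <- attempts + 1L
    x0 <- stats::runif(1, -r, r); y0 <- stats::runif(1, 0, h)
    if (!clear(x0, y0)) next
    if (length(cx) > 0 && min((cx - x0)^2 + (cy - y0)^2) < d_min^2) next
    cx <- c(cx, x0); cy <- c(cy, y0)
  }
  img <- matrix(0, nr_, nc)
  for (k in seq_along(cx)) {
    jx <- which(abs(px_x - cx[k]) < 4 * sig)
    iy <- which(abs(px_y - cy[k]) < 4 * sig)
    if (!length(jx) || !length(iy)) next
    gx <- exp(-((px_x[jx] - cx[k])^2) / (2 * sig^2))
    gy <- exp(-((px_y[iy] - cy[k])^2) / (2 * sig^2))
    img[iy, jx] <- img[iy, jx] + outer(gy, gx)
  }
  img <- img / max(1, max(img))
  if (background_noise > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, background_noise),
                        nrow(img))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask,
       centroids_um = cbind(x = cx, y = cy),
       pixel_scale = ps,
       px_x = px_x, px_y = px_y)
}

#' Simulate sequencing reads with simplified alignments
#'
#' Draws reads uniformly along a reference sequence for each individual,
#' substitutes ALT bases at the individual's ALT-homozygous variant sites,
#' assigns per-base PHRED qualities from a profile, and emits the matching
#' minimal alignment records (reads are generated from known positions, so
#' alignment is exact).
#'
#' @param reference Single reference sequence (character string of ACGT).
#' @param variant_sites data.frame with columns \code{pos} (1-based),
#'   \code{ref}, \code{alt}.
#' @param genotypes Integer matrix (individuals x sites) of {0, 2, NA}
#'   calls; rownames are individual ids. NA sites contribute no ALT base.
#' @param depth Mean per-base coverage (> 0).
#' @param quality_profile Either \code{list(type = "constant", q = 40)} or
#'   \code{list(type = "tail_degraded", q = 35, q_tail = 8, tail_len = 10)}.
#' @param read_len Read length (default 75).
#' @param seed Seed for this generator.
#' @return List per individual: \code{reads} (data.frame id, bases, quals
#'   list-column) and \code{alignments} (data.frame in minimal SAM fields).
#' @export
sim_reads <- function(reference, variant_sites, genotypes, depth,
                      quality_profile = list(type = "constant", q = 40),
                      read_len = 75, seed = 1) {
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  ref_chars <- strsplit(reference, "")[[1]]
  L <- length(ref_chars)
  if (read_len > L) stop("read_len exceeds reference length")
  inds <- rownames(genotypes)
  if (is.null(inds)) inds <- sprintf("I%02d", seq_len(nrow(genotypes)))
  qual_for <- function() {
    if (quality_profile$type == "constant")
      rep(quality_profile$q, read_len)
    else if (quality_profile$type == "tail_degraded") {
      q <- rep(quality_profile$q, read_len)
      tl <- quality_profile$tail_len
      q[(read_len - tl + 1):read_len] <- quality_profile$q_tail
      q
    } else stop("unknown quality profile type")
  }
  out <- vector("list", length(inds)); names(out) <- inds
  for (ii in seq_along(inds)) {
    chars <- ref_chars
    alt_sites <- which(!is.na(genotypes[ii, ]) & genotypes[ii, ] == 2L)
    chars[variant_sites$pos[alt_sites]] <- variant_sites$alt[alt_sites]
    n_reads <- ceiling(depth * L / read_len)
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    ids <- sprintf("%s_r%04d", inds[ii], seq_len(n_reads))
    bases <- vapply(starts, function(s)
      paste(chars[s:(s + read_len - 1L)], collapse = ""), character(1))
    quals <- replicate(n_reads, qual_for(), simplify = FALSE)
    nm <- vapply(seq_len(n_reads), function(k) {
      s <- starts[k]
      sum(chars[s:(s + read_len - 1L)] != ref_chars[s:(s + read_len - 1L)])
    }, integer(1))
    reads <- data.frame(id = ids, bases = bases, stringsAsFactors = FALSE)
    reads$quals <- quals
    aln <- data.frame(qname = ids, flag = 0L, rname = "ref1", pos = starts,
                      mapq = 60L, cigar = paste0(read_len, "M"),
                      seq = bases, stringsAsFactors = FALSE)
    aln$qual <- vapply(quals, phred_string, character(1))
    aln$nm <- nm
    aln$tail_len <- 0L
    aln$unique <- TRUE
    out[[ii]] <- list(reads = reads, alignments = aln)
  }
  out
}

phred_string <- function(q) intToUtf8(pmin(q, 93) + 33L)
phred_values <- function(s) utf8ToInt(s) - 33L
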
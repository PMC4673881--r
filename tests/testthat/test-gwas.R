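test_that("kinship of identical individuals equals the diagonal entry", {
  calls <- rbind(c(0L, 2L, 0L, 2L, 0L), c(0L, 2L, 0L, 2L, 0L),
                 c(2L, 0L, 2L, 0L, 2L))
  sites <- data.frame(chrom = "1", pos = 1:5 * 10L, com = "A", alt = "T")
  gm <- genotype_matrix(calls, sites, c("a", "b", "c"))
  K <- vanraden_kinship(gm)
  expect_equal(K["a", "b"], K["a", "a"], tolerance = 1e-12)
  expect_equal(K, t(K))
})

test_that("unrelated equifrequent panels have near-zero mean kinship", {
  set.seed(12)
  # centering forces the off-diagonal mean to -mean(diag)/(n-1), which with
  # the inbred diagonal near 2 needs n >> 100 to fall inside +/- 0.02
  n <- 250
  calls <- matrix(sample(c(0L, 2L), n * 10000, replace = TRUE), n)
  sites <- data.frame(chrom = "1", pos = seq_len(10000), com = "A", alt = "T")
  K <- vanraden_kinship(genotype_matrix(calls, sites, sprintf("i%03d", 1:n)))
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("subpopulation structure raises within-group kinship", {
  cfg <- sim_config(seed = 4, n_genotypes = 120, n_snps = 1500,
                    n_subpops = 2, structure_conc = 0.1)
  gm <- sim_genotypes(cfg)
  K <- vanraden_kinship(gm)
  same <- outer(gm$subpop, gm$subpop, "==") & upper.tri(K)
  diff <- outer(gm$subpop, gm$subpop, "!=") & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff]))
  expect_error(vanraden_kinship(genotype_matrix(
    matrix(0L, 4, 3), data.frame(chrom = "1", pos = 1:3, com = "A",
                                 alt = "T"), letters[1:4])),
    "monomorphic")
})

test_that("with identity kinship and no heritability the scan is OLS", {
  set.seed(15)
  n <- 80
  cfg <- sim_config(seed = 15, n_genotypes = n, n_snps = 120,
                    missing_rate = 0, structure_conc = 1e6)
  gm <- sim_genotypes(cfg)
  y <- rnorm(n)
  K <- diag(n)
  dimnames(K) <- list(gm$individuals, gm$individuals)
  sc <- mlm_scan(y, gm, K = K)
  ols_p <- apply(gm$calls, 2, function(s) {
    if (sd(s) == 0) return(NA)
    summary(lm(y ~ s))$coefficients[2, 4]
  })
  keep <- !is.na(ols_p)
  expect_equal(sc$results$p[keep], unname(ols_p[keep]), tolerance = 1e-4)
})

test_that("eigen-rotated GLS equals the dense V-inverse oracle", {
  set.seed(16)
  n <- 30
  cfg <- sim_config(seed = 16, n_genotypes = n, n_snps = 300,
                    missing_rate = 0.1)
  gm <- sim_genotypes(cfg)
  K <- vanraden_kinship(gm)
  tr <- sim_truth(cfg)
  y <- tr$true_volume + rnorm(n, 0, 30000)
  sc <- mlm_scan(y, gm, K = K)
  V <- sc$sigma2_g * K + sc$sigma2_e * diag(n)
  S <- samgwas:::impute_calls(gm)
  for (k in c(3, 57, 140)) {
    if (sd(S[, k]) < 1e-8) next
    o <- dense_gls_oracle(y, cbind(1, S[, k]), V)
    expect_equal(sc$results$effect[k], o$beta[2], tolerance = 1e-6)
    # Wald t from the dense solve (same per-SNP scale re-estimation;
    # both use df = n - 2 here)
    t_dense <- o$beta[2] / sqrt(o$s2 * o$cov_unscaled[2, 2])
    expect_equal(sc$results$t[k], t_dense, tolerance = 1e-6)
  }
})

test_that("consistently permuting individuals leaves p-values unchanged", {
  cfg <- sim_config(seed = 18, n_genotypes = 50, n_snps = 200)
  tr <- sim_truth(cfg)
  y <- tr$true_volume
  gm <- tr$genotypes
  sc1 <- mlm_scan(y, gm)
  set.seed(1)
  perm <- sample(50)
  gm2 <- genotype_matrix(gm$calls[perm, ], gm$sites,
                         gm$individuals[perm])
  sc2 <- mlm_scan(y[perm], gm2)
  expect_equal(sc1$results$neglog10p, sc2$results$neglog10p,
               tolerance = 1e-6)
})

test_that("Bonferroni threshold follows -log10(alpha / M)", {
  expect_equal(round(bonferroni_threshold(0.01, 923000 + 358000), 2), 8.11)
  expect_equal(bonferroni_threshold(0.05, 1), -log10(0.05), tolerance = 1e-12)
  expect_equal(bonferroni_threshold(0.01, 100), 4)
  # strictly increasing in M; doubling M adds log10(2)
  expect_equal(bonferroni_threshold(0.01, 2e5) - bonferroni_threshold(0.01, 1e5),
               log10(2), tolerance = 1e-12)
  expect_error(bonferroni_threshold(0, 10), "alpha")
  expect_error(bonferroni_threshold(0.01, 0), "M")
})

test_that("candidate mapping honors the window and inside-gene flags", {
  genes <- data.frame(gene_id = "g1", chrom = "1",
                      start = 550001L, end = 560000L)
  tas <- data.frame(chrom = "1", pos = c(500000L, 555000L))
  asn <- map_candidates(tas, genes, window = 1e5)
  expect_equal(nrow(asn), 2)
  far <- asn[asn$pos == 500000L, ]
  expect_equal(far$distance, 50000L)
  expect_false(far$inside)
  near <- asn[asn$pos == 555000L, ]
  expect_equal(near$distance, 0L)
  expect_true(near$inside)
  # unknown chromosome warns per record
  expect_warning(map_candidates(data.frame(chrom = "9", pos = 1L), genes),
                 "absent")
})

test_that("random TAS-gene assignment matches brute force all-pairs", {
  set.seed(19)
  tas <- data.frame(chrom = sample(c("1", "2"), 50, replace = TRUE),
                    pos = sample.int(2e6, 50))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      chrom = sample(c("1", "2"), 20, replace = TRUE),
                      start = sample.int(19e5, 20))
  genes$end <- genes$start + sample.int(5e4, 20)
  w <- 1e5
  asn <- map_candidates(tas, genes, window = w)
  brute <- do.call(rbind, lapply(seq_len(nrow(tas)), function(i) {
    hits <- lapply(seq_len(nrow(genes)), function(j) {
      if (tas$chrom[i] != genes$chrom[j]) return(NULL)
      # gap distance: bases strictly between the SNP and the gene boundary
      d <- if (tas$pos[i] >= genes$start[j] && tas$pos[i] <= genes$end[j]) 0L
           else if (tas$pos[i] < genes$start[j])
             genes$start[j] - tas$pos[i] - 1L
           else tas$pos[i] - genes$end[j] - 1L
      if (d <= w) data.frame(pos = tas$pos[i], gene_id = genes$gene_id[j],
                             distance = d) else NULL
    })
    do.call(rbind, hits)
  }))
  key <- function(d) sort(paste(d$pos, d$gene_id, d$distance))
  expect_identical(key(asn), key(brute))
})

test_that("gene annotations survive a GFF3 write/read round trip", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "genes.gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t100\t500\t.\t+\t.\tID=gA",
               "2\tsrc\tgene\t900\t1500\t.\t-\t.\tID=gB"), path)
  g <- read_gene_annotations(path)
  expect_equal(g$gene_id, c("gA", "gB"))
  expect_equal(g$start, c(100, 900))
  expect_equal(g$end, c(500, 1500))
})

test_that("ALT burden behaves across degenerate and strong-signal cases", {
  cfg <- sim_config(seed = 22, n_genotypes = 40, n_snps = 100,
                    missing_rate = 0)
  gm <- sim_genotypes(cfg)
  tas <- gm$sites[1:5, ]
  y <- rnorm(40)
  # all-COM TAS set gives constant zero burden
  gm0 <- gm
  gm0$calls[, 1:5] <- 0L
  expect_error(alt_burden(tas, gm0, y), "same ALT burden")
  # noiseless additive burden correlates perfectly
  counts <- rowSums(gm$calls[, 1:5] == 2L)
  if (sd(counts) > 0) {
    res <- alt_burden(tas, gm, 5 + 2 * counts)
    expect_equal(res$cor$r, 1, tolerance = 1e-12)
    expect_identical(unname(res$burden), unname(counts))
  }
  expect_error(alt_burden(tas[0, ], gm, y), "empty")
})

test_that("burden correlation lands in the tuned regime near r = 0.5", {
  rs <- sapply(1:25, function(s) {
    cfg <- sim_config(seed = 300 + s, n_genotypes = 200, n_snps = 400)
    tr <- sim_truth(cfg)
    ph <- sim_phenotypes(tr, cfg)
    fit <- fit_blup(ph$table)
    y <- fit$blup_plus_intercept[tr$genotypes$individuals]
    alt_burden(tr$genotypes$sites[tr$causal$snp, ], tr$genotypes, y)$cor$r
  })
  expect_lt(abs(median(rs) - 0.5), 0.1)
})

test_that("model selection tracks simulated population structure", {
  suppressWarnings({
    n0 <- sapply(1:10, function(s) {
      cfg <- sim_config(seed = 400 + s, n_genotypes = 120, n_snps = 500,
                        structure_conc = 1e6, causal_effects = empty_causal)
      tr <- sim_truth(cfg)
      y <- tr$true_volume + rnorm(120, 0, 30000)
      g <- filter_sites(tr$genotypes)
      select_covariates(y, vanraden_kinship(g), genotype_pcs(g, 3))$n_pcs
    })
    expect_gte(mean(n0 == 0), 0.8)
    n1 <- sapply(1:10, function(s) {
      cfg <- sim_config(seed = 500 + s, n_genotypes = 120, n_snps = 500,
                        n_subpops = 2, structure_conc = 0.05,
                        causal_effects = empty_causal)
      tr <- sim_truth(cfg)
      y <- tr$true_volume + 150000 * (tr$subpop == 1) + rnorm(120, 0, 30000)
      g <- filter_sites(tr$genotypes)
      select_covariates(y, vanraden_kinship(g), genotype_pcs(g, 3))$n_pcs
    })
    expect_gte(mean(n1 >= 1), 0.7)
    # max_pcs = 0 trivially returns the kinship-only model
    cfg <- sim_config(seed = 1, n_genotypes = 40, n_snps = 100)
    tr <- sim_truth(cfg)
    sel0 <- select_covariates(tr$true_volume, vanraden_kinship(tr$genotypes),
                              genotype_pcs(tr$genotypes, 3), max_pcs = 0)
    expect_equal(sel0$n_pcs, 0L)
    expect_null(sel0$covariates)
  })
})

test_that("P3D tracks exact per-SNP REML (sanity bound, not equality)", {
  cfg <- sim_config(seed = 23, n_genotypes = 200, n_snps = 100)
  tr <- sim_truth(cfg)
  y <- tr$true_volume
  g <- filter_sites(tr$genotypes)
  s1 <- mlm_scan(y, g, p3d = TRUE)
  s2 <- mlm_scan(y, g, p3d = FALSE)
  ok <- !is.na(s1$results$neglog10p) & !is.na(s2$results$neglog10p)
  diffs <- abs(s1$results$neglog10p[ok] - s2$results$neglog10p[ok])
  expect_lt(median(diffs), 0.05)
  expect_lt(max(diffs), 0.5)
})

test_that("a strong causal SNP tops the scan", {
  hits <- sapply(1:20, function(s) {
    cfg <- sim_config(seed = 600 + s, n_genotypes = 400, n_snps = 500,
                      causal_effects = data.frame(snp = 250L, effect = 1))
    gm <- sim_genotypes(cfg)
    g <- gm$calls_complete[, 250]
    beta <- sqrt(0.15 / 0.85 / var(g))  # SNP explains 15% of variance
    y <- beta * g + rnorm(400)
    geno <- filter_sites(gm)
    idx <- which(geno$sites$pos == 250L * 100L)
    if (length(idx) != 1) return(NA)
    sc <- mlm_scan(y, geno)
    which.max(sc$results$neglog10p) == idx
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})
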
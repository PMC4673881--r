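test_that("high-quality reads pass trimming unchanged", {
  rd <- read_record("r1", strrep("A", 40), rep(40L, 40))
  expect_identical(trim_read(rd), rd)
  # uniformly bad read trims to empty
  bad <- read_record("r2", strrep("A", 30), rep(10L, 30))
  expect_equal(nchar(trim_read(bad)$bases), 0)
})

test_that("end-trim plus window scan matches a brute-force scanner", {
  rd <- read_record("r3", strrep("C", 50), c(rep(30L, 30), rep(5L, 20)))
  out <- trim_read(rd)
  expect_equal(nchar(out$bases), 30)
  # randomized quality strings against the brute-force window oracle
  set.seed(21)
  for (i in 1:200) {
    n <- sample(5:80, 1)
    q <- sample(0:40, n, replace = TRUE)
    rd <- read_record("x", strrep("G", n), q)
    out <- trim_read(rd)
    # oracle: iterate (end strip, first-failing-window truncation) to a
    # fixpoint on the quality vector alone
    qq <- q
    repeat {
      lo <- 1; while (lo <= length(qq) && qq[lo] < 15) lo <- lo + 1
      hi <- length(qq); while (hi >= lo && qq[hi] < 15) hi <- hi - 1
      q2 <- if (lo > hi) integer(0) else qq[lo:hi]
      q2 <- q2[seq_len(brute_trim_phase2(q2))]
      if (identical(q2, qq)) break
      qq <- q2
    }
    expect_equal(out$quals, qq)
    # idempotence
    expect_identical(trim_read(out), out)
  }
})

test_that("alignment filter encodes the mismatch and tail boundaries", {
  expect_true(keep_alignment(36, 2, 0))    # two or less per 36 bp
  expect_false(keep_alignment(36, 3, 0))
  expect_false(keep_alignment(75, 0, 5))   # fewer than five per 75 bp
  expect_true(keep_alignment(75, 0, 4))
  expect_false(keep_alignment(36, 0, 0, unique = FALSE))
  # proration uses the ceiling of the length ratio
  expect_true(keep_alignment(37, 4, 0))    # ceil(37/36) = 2 units
  expect_false(keep_alignment(37, 5, 0))
  expect_true(keep_alignment(76, 0, 9))    # ceil(76/75) = 2 units
  expect_false(keep_alignment(76, 0, 10))
})

make_pileup <- function(bases, quals, off_start, off_end, ref = "A") {
  obs <- data.frame(read = sprintf("r%d", seq_along(bases)), base = bases,
                    qual = quals, off_start = off_start, off_end = off_end,
                    stringsAsFactors = FALSE)
  structure(list(chrom = "1", pos = 10L, ref = ref, obs = obs),
            class = "pileup_site")
}

test_that("homozygous site calls respect support, quality and edge rules", {
  # minimal passing ALT call: 5 interior reads at q = 20
  p <- make_pileup(rep("T", 5), rep(20L, 5), rep(5L, 5), rep(5L, 5))
  expect_equal(as.integer(call_site(p)), 2L)
  # four supporting reads is below the bound
  p4 <- make_pileup(rep("T", 4), rep(40L, 4), rep(5L, 4), rep(5L, 4))
  expect_true(is.na(call_site(p4)))
  # 6 ALT reads, but 2 edge-masked and 1 below q20 -> 3 usable -> missing
  p6 <- make_pileup(rep("T", 6), c(40L, 40L, 40L, 40L, 40L, 19L),
                    c(5L, 5L, 2L, 5L, 5L, 5L), c(5L, 5L, 5L, 1L, 5L, 5L))
  expect_true(is.na(call_site(p6)))
  expect_equal(brute_call(p6$obs, "A"), NA_integer_)
  # reference-supporting pileup calls COM-hom
  pr <- make_pileup(rep("A", 7), rep(30L, 7), rep(4L, 7), rep(4L, 7))
  expect_equal(as.integer(call_site(pr)), 0L)
})

test_that("randomized pileups agree with the brute-force caller", {
  set.seed(33)
  for (i in 1:300) {
    n <- sample(1:15, 1)
    p <- make_pileup(sample(c("A", "T"), n, replace = TRUE, prob = c(0.4, 0.6)),
                     sample(10:40, n, replace = TRUE),
                     sample(0:8, n, replace = TRUE),
                     sample(0:8, n, replace = TRUE))
    expect_identical(as.integer(call_site(p)), brute_call(p$obs, "A"))
  }
})

test_that("consensus merge keeps agreement and blanks conflict", {
  sites <- data.frame(chrom = "1", pos = c(10L, 20L, 30L),
                      com = "A", alt = "T", stringsAsFactors = FALSE)
  m1 <- genotype_matrix(rbind(c(0L, 0L, NA)), sites, "I1")
  m2 <- genotype_matrix(rbind(c(0L, 2L, 2L)), sites, "I1")
  mg <- merge_consensus(list(m1, m2))
  expect_equal(as.vector(mg$calls), c(0L, NA, 2L))
  # order invariance
  mg2 <- merge_consensus(list(m2, m1))
  expect_identical(mg$calls, mg2$calls)
  # conflicting ALT alleles at a shared key is an error
  m3 <- genotype_matrix(rbind(c(0L, 0L, 0L)),
                        transform(sites, alt = c("G", "T", "T")), "I1")
  expect_error(merge_consensus(list(m1, m3)), "different alleles")
})

test_that("MAF/missingness filter matches brute-force recounting", {
  set.seed(44)
  n <- 400
  mafs <- c(0.005, 0.0075, 0.01, 0.02, 0.05, 0.2, 0.4, 0.005, 0.3, 0.015)
  calls <- sapply(mafs, function(p) {
    v <- rep(0L, n); v[sample(n, round(p * n))] <- 2L; v
  })
  # site 6 mostly missing (61%), site 7 exactly 60%
  calls[sample(n, 244), 6] <- NA
  calls[sample(n, 240), 7] <- NA
  sites <- data.frame(chrom = "1", pos = seq(10, 100, 10), com = "A",
                      alt = "T", stringsAsFactors = FALSE)
  m <- genotype_matrix(calls, sites, sprintf("I%03d", 1:n))
  f <- filter_sites(m)
  # brute force: recompute maf over non-missing and missingness per site
  keep <- sapply(seq_len(ncol(calls)), function(k) {
    v <- calls[, k]
    fa <- mean(v[!is.na(v)] == 2L)
    min(fa, 1 - fa) >= 0.01 && mean(is.na(v)) <= 0.60
  })
  expect_equal(ncol(f$calls), sum(keep))
  expect_equal(f$sites$pos, sites$pos[keep])
  # the 3-in-400 example: MAF 0.0075 < 0.01 is dropped
  expect_false(20 %in% f$sites$pos)
  # strict "over 60%": exactly 60% missing is kept (maf permitting)
  expect_true(70 %in% f$sites$pos == keep[7])
  # idempotence
  f2 <- filter_sites(f)
  expect_identical(f2$calls, f$calls)
})

test_that("read-to-matrix round trip reconstructs simulated genotypes", {
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  pos <- seq(80, by = 40, length.out = 6)
  refb <- substring(ref, pos, pos)
  altb <- vapply(refb, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  truth <- matrix(sample(c(0L, 2L), 8 * 6, replace = TRUE), 8, 6,
                  dimnames = list(sprintf("I%02d", 1:8), NULL))
  rd <- sim_reads(ref, data.frame(pos = pos, ref = refb, alt = altb),
                  truth, depth = 20, seed = 9)
  gm <- call_genotypes(lapply(rd, `[[`, "alignments"), pos, refb)
  expect_identical(unname(gm$calls), unname(truth))
})

test_that("FASTQ, SAM and VCF round-trip through files", {
  tmp <- withr::local_tempdir()
  set.seed(10)
  ref <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  geno <- matrix(c(2L, 0L), 1, 2, dimnames = list("I01", NULL))
  sites <- data.frame(pos = c(30, 90), ref = substring(ref, c(30, 90),
                                                       c(30, 90)))
  sites$alt <- vapply(sites$ref, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  rd <- sim_reads(ref, sites, geno, depth = 3, seed = 2)
  fq <- file.path(tmp, "reads.fastq")
  write_fastq(rd$I01$reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$bases, rd$I01$reads$bases)
  expect_equal(back$quals, rd$I01$reads$quals)
  sam <- file.path(tmp, "aln.sam")
  write_sam(rd$I01$alignments, sam)
  aback <- read_sam(sam)
  expect_equal(aback$pos, rd$I01$alignments$pos)
  expect_equal(aback$seq, rd$I01$alignments$seq)
  expect_equal(aback$nm, rd$I01$alignments$nm)
  # VCF via the vcfR parser
  gm <- sim_genotypes(sim_config(seed = 2, n_genotypes = 12, n_snps = 20))
  vcf <- file.path(tmp, "geno.vcf")
  write_vcf(gm, vcf)
  gback <- read_vcf_matrix(vcf)
  expect_identical(unname(gback$calls), unname(gm$calls))
  expect_equal(gback$sites$pos, gm$sites$pos)
  expect_equal(gback$individuals, gm$individuals)
})
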
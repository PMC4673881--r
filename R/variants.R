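#' Construct a homozygous genotype matrix
#'
#' Container for an inbred-panel genotype matrix: calls are coded 0
#' (COM/COM homozygote), 2 (ALT/ALT homozygote) or \code{NA} (missing);
#' heterozygotes do not occur in a fully inbred panel.
#'
#' @param calls Integer matrix, individuals x sites, values in {0, 2, NA}.
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{com}, \code{alt}.
#' @param individuals Character vector of individual ids (rows of calls).
#' @param source Provenance tag, e.g. "rnaseq", "genomic", "merged".
#' @return Object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(calls, sites, individuals,
                            source = "unknown") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 2L) | is.na(calls)))
    stop("calls must be 0, 2 or NA (homozygous inbred coding)")
  if (nrow(calls) != length(individuals))
    stop("individuals must match rows of calls")
  if (ncol(calls) != nrow(sites))
    stop("sites must match columns of calls")
  rownames(calls) <- individuals
  structure(list(calls = calls, sites = sites,
                 individuals = individuals, source = source),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix [%s]: %d individuals x %d sites, %.1f%% missing\n",
              x$source, nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Per-site minor allele frequency and missingness
#'
#' MAF is computed over non-missing calls only; the COM allele is the
#' majority allele, so MAF = min(f_ALT, 1 - f_ALT) and lies in [0, 0.5].
#'
#' @param m A \code{genotype_matrix}.
#' @return data.frame with \code{maf} and \code{missingness} per site.
#' @export
site_stats <- function(m) {
  f_alt <- colMeans(m$calls == 2L, na.rm = TRUE)
  f_alt[is.nan(f_alt)] <- 0
  data.frame(maf = pmin(f_alt, 1 - f_alt),
             missingness = colMeans(is.na(m$calls)))
}

#' Two-phase quality trimming of a sequencing read
#'
#' Phase 1 strips bases from each read end while their PHRED quality is
#' below \code{q_threshold}. Phase 2 slides overlapping windows of
#' \code{window} bases 5' to 3' over the remainder and truncates the read
#' at the start of the first window whose mean quality falls below the
#' threshold (\code{mode = "first_fail"}); \code{mode = "last_pass"} keeps
#' everything through the end of the last passing window instead. Reads
#' shorter than one window after phase 1 are kept as-is. An empty read is
#' a valid output.
#'
#' @param read List with \code{id}, \code{bases} (string), \code{quals}
#'   (integer vector, 0-40 scale), lengths matching.
#' @param q_threshold PHRED threshold (default 15).
#' @param window Window length in bp (default 10).
#' @param mode Truncation interpretation (see above).
#' @return The trimmed read (same structure; possibly zero-length).
#' @export
trim_read <- function(read, q_threshold = 15, window = 10,
                      mode = c("first_fail", "last_pass")) {
  mode <- match.arg(mode)
  # the two phases are iterated to a fixpoint: a window truncation can leave
  # a low-quality base at the new 3' end, which the end-strip then removes —
  # so trimming is idempotent
  repeat {
    out <- trim_read_once(read, q_threshold, window, mode)
    if (identical(out, read)) return(out)
    read <- out
  }
}

trim_read_once <- function(read, q_threshold, window, mode) {
  q <- read$quals
  stopifnot(nchar(read$bases) == length(q))
  n <- length(q)
  # phase 1: strip low-quality runs from both ends
  lo <- 1L
  while (lo <= n && q[lo] < q_threshold) lo <- lo + 1L
  hi <- n
  while (hi >= lo && q[hi] < q_threshold) hi <- hi - 1L
  if (lo > hi) return(read_record(read$id, "", integer(0)))
  q2 <- q[lo:hi]
  b2 <- substr(read$bases, lo, hi)
  len <- length(q2)
  if (len >= window) {
    means <- vapply(seq_len(len - window + 1L),
                    function(s) mean(q2[s:(s + window - 1L)]), numeric(1))
    if (mode == "first_fail") {
      bad <- which(means < q_threshold)
      if (length(bad)) {
        keep <- bad[1] - 1L
        q2 <- q2[seq_len(keep)]
        b2 <- substr(b2, 1L, keep)
      }
    } else {
      good <- which(means >= q_threshold)
      keep <- if (length(good)) max(good) + window - 1L else 0L
      q2 <- q2[seq_len(keep)]
      b2 <- substr(b2, 1L, keep)
    }
  }
  read_record(read$id, b2, q2)
}

#' @rdname trim_read
#' @param id Read id.
#' @param bases Base string.
#' @param quals Integer PHRED qualities.
#' @export
read_record <- function(id, bases, quals) {
  stopifnot(nchar(bases) == length(quals))
  list(id = id, bases = bases, quals = as.integer(quals))
}

#' Confident-alignment filter
#'
#' A read alignment is retained iff it is unique, has at most 2 mismatches
#' per 36 bp of read length, and fewer than 5 unaligned tail bases per
#' 75 bp of read length. Per-length allowances are prorated with a ceiling
#' on the length ratio, and the boundary semantics follow "two or less"
#' (inclusive) and "fewer than five" (strict).
#'
#' @param len Aligned read length (bp).
#' @param mismatches Mismatch count.
#' @param tail_len Unaligned tail length (bp).
#' @param unique Logical, mapped uniquely.
#' @return Logical keep/reject (vectorized).
#' @export
keep_alignment <- function(len, mismatches, tail_len, unique = TRUE) {
  if (any(tail_len < 0) || any(mismatches < 0)) stop("negative counts")
  unique &
    mismatches <= 2 * ceiling(len / 36) &
    tail_len < 5 * ceiling(len / 75)
}

#' Build pileups from simplified alignments
#'
#' Collects, at each requested reference position, the aligned base, base
#' quality and offsets from the read's start and end for every alignment
#' covering the position (fully aligned \code{<len>M} records).
#'
#' @param alignments data.frame with columns \code{qname}, \code{pos}
#'   (1-based), \code{seq}, \code{qual} (PHRED+33 string).
#' @param positions Integer vector of 1-based reference positions.
#' @param ref_base Character vector of reference bases at those positions.
#' @param chrom Chromosome name tag.
#' @return List of \code{pileup_site} objects (chrom, pos, ref,
#'   obs data.frame with read, base, qual, off_start, off_end).
#' @export
pileup_sites <- function(alignments, positions, ref_base, chrom = "1") {
  lens <- nchar(alignments$seq)
  lapply(seq_along(positions), function(k) {
    p <- positions[k]
    cov <- which(alignments$pos <= p & alignments$pos + lens - 1L >= p)
    if (length(cov)) {
      off <- p - alignments$pos[cov]          # 0-based from read start
      obs <- data.frame(
        read = alignments$qname[cov],
        base = substr(alignments$seq[cov], off + 1L, off + 1L),
        qual = vapply(seq_along(cov), function(i)
          phred_values(substr(alignments$qual[cov[i]], off[i] + 1L,
                              off[i] + 1L)), integer(1)),
        off_start = off,
        off_end = lens[cov] - 1L - off,
        stringsAsFactors = FALSE)
    } else {
      obs <- data.frame(read = character(0), base = character(0),
                        qual = integer(0), off_start = integer(0),
                        off_end = integer(0))
    }
    structure(list(chrom = chrom, pos = p, ref = ref_base[k], obs = obs),
              class = "pileup_site")
  })
}

#' Call a homozygous genotype at one pileup site
#'
#' Observations within \code{edge} bases of either read end or with base
#' quality below \code{min_q} are discarded. The site is called
#' ALT-homozygous iff at least \code{min_reads} unique reads support the
#' ALT base and the ALT supporting fraction is at least \code{purity};
#' COM-homozygous by the mirrored rule on the reference base; otherwise
#' missing. "Unique reads" are distinct read ids.
#'
#' @param pileup A \code{pileup_site}.
#' @param min_q Minimum base quality (default 20).
#' @param min_reads Minimum unique supporting reads (default 5).
#' @param edge Ignore the first and last \code{edge} aligned bases of each
#'   read (default 3).
#' @param purity Homozygous-call purity fraction (default 0.9).
#' @return Integer call: 0 (COM-hom), 2 (ALT-hom) or NA (missing), with
#'   attribute \code{alt} (the ALT base, or NA).
#' @export
call_site <- function(pileup, min_q = 20, min_reads = 5, edge = 3,
                      purity = 0.9) {
  obs <- pileup$obs
  use <- obs$off_start >= edge & obs$off_end >= edge & obs$qual >= min_q
  obs <- obs[use & !duplicated(obs$read), , drop = FALSE]
  if (nrow(obs) == 0)
    return(structure(NA_integer_, alt = NA_character_))
  is_ref <- obs$base == pileup$ref
  n_ref <- sum(is_ref)
  alt_tab <- table(obs$base[!is_ref])
  alt_base <- if (length(alt_tab)) names(alt_tab)[which.max(alt_tab)] else NA
  n_alt <- if (is.na(alt_base)) 0L else alt_tab[[alt_base]]
  denom <- n_ref + n_alt
  if (n_alt >= min_reads && n_alt / denom >= purity)
    return(structure(2L, alt = alt_base))
  if (n_ref >= min_reads && n_ref / denom >= purity)
    return(structure(0L, alt = alt_base))
  structure(NA_integer_, alt = alt_base)
}

#' Call a genotype matrix from per-individual alignments
#'
#' Applies \code{\link{keep_alignment}}, builds pileups at the given
#' positions for each individual and calls each site with
#' \code{\link{call_site}}.
#'
#' @param aln_by_individual Named list (per individual) of alignment
#'   data.frames as produced by \code{\link{sim_reads}} (with \code{nm},
#'   \code{tail_len}, \code{unique} columns).
#' @param positions,ref_base Site positions (1-based) and reference bases.
#' @param chrom Chromosome tag.
#' @param ... Passed to \code{\link{call_site}}.
#' @return A \code{genotype_matrix} with source "rnaseq".
#' @export
call_genotypes <- function(aln_by_individual, positions, ref_base,
                           chrom = "1", ...) {
  inds <- names(aln_by_individual)
  calls <- matrix(NA_integer_, length(inds), length(positions))
  alt_obs <- rep(NA_character_, length(positions))
  for (ii in seq_along(inds)) {
    aln <- aln_by_individual[[ii]]
    keep <- keep_alignment(nchar(aln$seq), aln$nm, aln$tail_len, aln$unique)
    piles <- pileup_sites(aln[keep, , drop = FALSE], positions, ref_base,
                          chrom)
    for (k in seq_along(piles)) {
      cl <- call_site(piles[[k]], ...)
      calls[ii, k] <- as.integer(cl)
      if (is.na(alt_obs[k]) && !is.na(attr(cl, "alt")))
        alt_obs[k] <- attr(cl, "alt")
    }
  }
  sites <- data.frame(chrom = chrom, pos = positions, com = ref_base,
                      alt = ifelse(is.na(alt_obs), "N", alt_obs),
                      stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, inds, source = "rnaseq")
}

#' Consensus merge of repeated genotyping runs
#'
#' For individuals genotyped multiple times, scores the consensus call per
#' site: identical non-missing calls are kept, conflicting non-missing
#' calls become missing, and missing calls are ignored whenever any
#' concrete call exists. Order of the runs does not matter.
#'
#' @param runs List of \code{genotype_matrix} objects over the same
#'   individuals and sites (matched by chrom:pos site keys).
#' @return A single merged \code{genotype_matrix}.
#' @export
merge_consensus <- function(runs) {
  stopifnot(length(runs) >= 1)
  key <- function(m) paste(m$sites$chrom, m$sites$pos, sep = ":")
  k0 <- key(runs[[1]])
  ind0 <- runs[[1]]$individuals
  concrete <- function(a) !is.na(a) & a != "N"
  for (m in runs[-1]) {
    if (!identical(key(m), k0)) stop("site keys differ between runs")
    if (!identical(m$individuals, ind0)) stop("individuals differ between runs")
    if (any(m$sites$com != runs[[1]]$sites$com))
      stop("site key collision with different alleles (REF mismatch)")
    both <- concrete(m$sites$alt) & concrete(runs[[1]]$sites$alt)
    if (any(both & m$sites$alt != runs[[1]]$sites$alt))
      stop("site key collision with different alleles (ALT mismatch)")
  }
  stack <- array(unlist(lapply(runs, function(m) m$calls)),
                 dim = c(dim(runs[[1]]$calls), length(runs)))
  mn <- apply(stack, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_integer_
    else if (all(v == v[1])) v[1]
    else NA_integer_
  })
  sites <- runs[[1]]$sites
  alts <- do.call(cbind, lapply(runs, function(m) m$sites$alt))
  pick <- apply(alts, 1, function(a) {
    a <- a[!is.na(a) & a != "N"]
    if (length(a)) a[1] else "N"
  })
  sites$alt <- pick
  genotype_matrix(mn, sites, ind0, source = "merged")
}

#' Combine genotype matrices over disjoint or overlapping site sets
#'
#' Concatenates the site sets of two sources (e.g. RNAseq-derived and
#' genomic SNPs) over the same individuals; sites present in both sources
#' (same chrom:pos) are consensus-merged with the conflict-to-missing rule.
#'
#' @param a,b \code{genotype_matrix} objects over the same individuals.
#' @return A combined \code{genotype_matrix} with source "merged".
#' @export
combine_matrices <- function(a, b) {
  if (!identical(a$individuals, b$individuals))
    stop("individuals differ between sources")
  ka <- paste(a$sites$chrom, a$sites$pos, sep = ":")
  kb <- paste(b$sites$chrom, b$sites$pos, sep = ":")
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  calls_shared <- NULL
  if (length(shared)) {
    ca <- a$calls[, ia, drop = FALSE]
    cb <- b$calls[, ib, drop = FALSE]
    agree <- is.na(ca) | is.na(cb) | ca == cb
    merged <- ifelse(is.na(ca), cb, ifelse(is.na(cb), ca,
                                           ifelse(ca == cb, ca, NA)))
    merged[!agree] <- NA
    calls_shared <- merged
  }
  only_a <- setdiff(seq_along(ka), ia)
  only_b <- setdiff(seq_along(kb), ib)
  calls <- cbind(a$calls[, only_a, drop = FALSE],
                 b$calls[, only_b, drop = FALSE], calls_shared)
  sites <- rbind(a$sites[only_a, , drop = FALSE],
                 b$sites[only_b, , drop = FALSE],
                 a$sites[ia, , drop = FALSE])
  o <- order(sites$chrom, sites$pos)
  genotype_matrix(calls[, o, drop = FALSE], sites[o, , drop = FALSE],
                  a$individuals, source = "merged")
}

#' MAF / missingness site filter
#'
#' Retains a site iff its minor allele frequency (over non-missing calls)
#' is at least \code{maf_min} and its missingness is at most
#' \code{miss_max} ("missing in over 60\%" is a strict exclusion, so
#' exactly 60\% missing is kept).
#'
#' @param m A \code{genotype_matrix}.
#' @param maf_min Minimum MAF (default 0.01).
#' @param miss_max Maximum missingness (default 0.60).
#' @return The filtered \code{genotype_matrix}; attribute
#'   \code{retention} records counts before/after.
#' @export
filter_sites <- function(m, maf_min = 0.01, miss_max = 0.60) {
  st <- site_stats(m)
  keep <- st$maf >= maf_min & st$missingness <= miss_max
  if (!any(keep)) warning("no sites survive the MAF/missingness filter")
  out <- genotype_matrix(m$calls[, keep, drop = FALSE],
                         m$sites[keep, , drop = FALSE],
                         m$individuals, source = m$source)
  attr(out, "retention") <- c(before = ncol(m$calls), after = sum(keep))
  out
}

# ---- file formats ---------------------------------------------------------

#' Write / read FASTQ (PHRED+33)
#'
#' Thin wrappers over Biostrings' FASTQ machinery for the read lists used
#' by the variants module.
#'
#' @param reads data.frame with \code{id}, \code{bases} and a \code{quals}
#'   list-column of integer qualities.
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  qs <- vapply(reads$quals, phred_string, character(1))
  dna <- Biostrings::DNAStringSet(reads$bases)
  q <- Biostrings::PhredQuality(Biostrings::BStringSet(qs))
  qdna <- Biostrings::QualityScaledDNAStringSet(dna, q)
  names(qdna) <- reads$id
  Biostrings::writeQualityScaledXStringSet(qdna, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # readQualityScaledDNAStringSet warns that it drops the mcols it creates
  # internally from the FASTQ ids; nothing of ours is lost
  qdna <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(qdna),
             bases = as.character(qdna),
             stringsAsFactors = FALSE) -> out
  out$quals <- lapply(as.character(Biostrings::quality(qdna)), phred_values)
  out
}

#' Write / read minimal SAM alignment records
#'
#' The simplified alignments carry the 11 mandatory SAM columns plus an
#' \code{NM:i:} mismatch tag; headerless, fully-aligned \code{<len>M}
#' records only.
#'
#' @param aln Alignment data.frame (see \code{\link{sim_reads}}).
#' @param path Output file.
#' @export
write_sam <- function(aln, path) {
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                   aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                   aln$cigar, aln$seq, aln$qual, aln$nm)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("NM:i:", "", tag[1])) else 0L
  }, integer(1))
  data.frame(qname = vapply(f, `[`, "", 1),
             flag = as.integer(vapply(f, `[`, "", 2)),
             rname = vapply(f, `[`, "", 3),
             pos = as.integer(vapply(f, `[`, "", 4)),
             mapq = as.integer(vapply(f, `[`, "", 5)),
             cigar = vapply(f, `[`, "", 6),
             seq = vapply(f, `[`, "", 10),
             qual = vapply(f, `[`, "", 11),
             nm = nm, tail_len = 0L, unique = TRUE,
             stringsAsFactors = FALSE)
}

#' Write a genotype matrix as VCF v4.2
#'
#' GT-only records, homozygous calls written as 0/0 and 1/1, missing as
#' ./. . Read back with \code{\link{read_vcf_matrix}} (vcfR-based).
#'
#' @param m A \code{genotype_matrix}.
#' @param path Output .vcf file.
#' @export
write_vcf <- function(m, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", m$individuals), collapse = "\t"))
  gt <- matrix("./.", nrow(m$calls), ncol(m$calls))
  gt[!is.na(m$calls) & m$calls == 0L] <- "0/0"
  gt[!is.na(m$calls) & m$calls == 2L] <- "1/1"
  body <- vapply(seq_len(ncol(m$calls)), function(k) {
    paste(c(m$sites$chrom[k], m$sites$pos[k], ".", m$sites$com[k],
            m$sites$alt[k], ".", "PASS", ".", "GT", gt[, k]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @param source Source tag for the returned matrix.
#' @export
read_vcf_matrix <- function(path, source = "vcf") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- matrix(NA_integer_, ncol(gt), nrow(gt))
  calls[t(gt) %in% c("0/0", "0|0")] <- 0L
  calls[t(gt) %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      com = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, colnames(gt), source = source)
}
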
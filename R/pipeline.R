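#' Run the full SAM morphometrics-to-GWAS pipeline on synthetic data
#'
#' Orchestrates one reproducible end-to-end run: simulate the panel,
#' trace and fit contours, derive microphenotypes, compute BLUP+intercept
#' SAM volumes and repeatability, build the genotype matrix (a read-called
#' RNAseq-style transcript window combined with the panel-wide genotypes),
#' filter it, run the mixed-model association scan with kinship and PC
#' covariates, call trait-associated SNPs at the Bonferroni threshold, map
#' candidate genes in a window, correlate ALT burden with volume, and
#' quantify SCN/ASCS on synthetic nuclei images. All outputs and a run
#' manifest (seeds, thresholds, per-file checksums) are written under
#' \code{out_dir}.
#'
#' @param cfg A \code{\link{sim_config}} (or a path to a YAML file whose
#'   fields are \code{sim_config} arguments).
#' @param out_dir Output directory (created if missing).
#' @param alpha Family-wise error rate for the TAS threshold.
#' @param window Candidate-gene window in bp.
#' @param maf_min,miss_max Site filters.
#' @param max_pcs Maximum PC covariates considered.
#' @param n_read_sites Number of transcript sites genotyped from simulated
#'   reads.
#' @param cytometry_reps Images per genotype class in the cytometry stage.
#' @param plots Write the morphospace and Manhattan PNGs.
#' @return The manifest (invisibly a list, also written as
#'   \code{manifest.json}).
#' @export
run_sam_pipeline <- function(cfg, out_dir, alpha = 0.01, window = 1e5,
                             maf_min = 0.01, miss_max = 0.60, max_pcs = 3,
                             n_read_sites = 5, cytometry_reps = 4,
                             plots = TRUE) {
  if (is.character(cfg)) cfg <- do.call(sim_config, yaml::read_yaml(cfg))
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- stage("simulate", sim_truth(cfg))
  con <- stage("simulate", sim_contours(truth, cfg))
  write_contours_tsv(con$contours, file.path(out_dir, "contours.tsv"))

  morpho <- stage("morphometrics", {
    fits <- lapply(con$contours, fit_parabola)
    data.frame(genotype = vapply(con$contours, function(ct) ct$genotype[1], ""),
               replicate = vapply(con$contours, function(ct)
                 ct$replicate[1], 1L),
               do.call(rbind, lapply(fits, function(f)
                 microphenotypes(f$h, f$r))),
               rmse = vapply(fits, function(f) f$rmse, 0),
               stringsAsFactors = FALSE)
  })
  write_tsv(morpho, file.path(out_dir, "microphenotypes.tsv"))

  blup <- stage("blup", fit_blup(morpho, value = "volume"))
  blup_tab <- data.frame(genotype = names(blup$blup_plus_intercept),
                         volume_blup = unname(blup$blup_plus_intercept),
                         stringsAsFactors = FALSE)
  write_tsv(blup_tab, file.path(out_dir, "blup_volume.tsv"))
  sizes <- stage("blup", classify_sizes(blup$blup_plus_intercept))
  write_tsv(sizes, file.path(out_dir, "size_classes.tsv"))

  geno_comb <- stage("variants", {
    genomic <- truth$genotypes
    # RNAseq-style source: a transcript window genotyped from reads
    ref <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
    pos <- seq(50, by = 60, length.out = n_read_sites)
    refb <- substring(ref, pos, pos)
    altb <- vapply(refb, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
    truth_calls <- truth$genotypes$calls_complete[, seq_len(n_read_sites),
                                                  drop = FALSE]
    rownames(truth_calls) <- genomic$individuals
    reads <- sim_reads(ref, data.frame(pos = pos, ref = refb, alt = altb),
                       truth_calls, depth = 12, seed = cfg$seed + 17)
    rna <- call_genotypes(lapply(reads, `[[`, "alignments"), pos, refb,
                          chrom = "T1")
    write_vcf(rna, file.path(out_dir, "rnaseq_snps.vcf"))
    write_vcf(genomic, file.path(out_dir, "genomic_snps.vcf"))
    combine_matrices(rna, genomic)
  })
  geno <- stage("variants", filter_sites(geno_comb, maf_min, miss_max))
  write_tsv(cbind(geno$sites, site_stats(geno)),
            file.path(out_dir, "site_stats.tsv"))

  scan <- stage("gwas", {
    y <- blup$blup_plus_intercept[geno$individuals]
    K <- vanraden_kinship(geno)
    PCs <- genotype_pcs(geno, n = max_pcs)
    sel <- select_covariates(y, K, PCs, max_pcs = max_pcs)
    sc <- mlm_scan(y, geno, K = K, covariates = sel$covariates,
                   alpha = alpha)
    sc$covariate_selection <- sel$bic
    sc
  })
  write_tsv(scan$results, file.path(out_dir, "gwas_results.tsv"))
  tas <- trait_associated_snps(scan)
  write_tsv(tas, file.path(out_dir, "tas.tsv"))

  genes <- stage("gwas", {
    # annotation: one gene spanning each causal site plus decoys
    ca_pos <- truth$genotypes$sites$pos[truth$causal$snp]
    decoy <- seq(5000, max(truth$genotypes$sites$pos), length.out = 10)
    g <- data.frame(
      gene_id = sprintf("GENE%03d", seq_len(length(ca_pos) + length(decoy))),
      chrom = "1",
      start = as.integer(c(ca_pos - 2000, decoy)),
      end = as.integer(c(ca_pos + 2000, decoy + 3000)))
    g$start <- pmax(g$start, 1L)
    g
  })
  assignments <- stage("gwas", map_candidates(tas, genes, window = window))
  write_tsv(assignments, file.path(out_dir, "candidate_genes.tsv"))

  burden <- stage("gwas", {
    bt <- if (nrow(tas) > 0) tas
          else truth$genotypes$sites[truth$causal$snp, , drop = FALSE]
    y <- blup$blup_plus_intercept[geno_comb$individuals]
    alt_burden(bt, geno_comb, y)
  })

  cyto <- stage("cytometry", {
    cls <- split(sizes$genotype, sizes$class)
    pick <- c(utils::head(cls$small, cytometry_reps),
              utils::head(cls$large, cytometry_reps))
    rows <- lapply(pick, function(g) {
      i <- match(g, truth$genotypes$individuals)
      cell_area <- if (g %in% cls$small) 28 else 40
      im <- sim_nuclei_image(truth$true_h[i], truth$true_r[i], cell_area,
                             cfg)
      seg <- segment_nuclei(im$image, im$mask, pixel_scale = cfg$pixel_scale)
      lat <- tessellate_cells(seg$centroids_px, im$mask,
                              pixel_scale = cfg$pixel_scale)
      data.frame(genotype = g,
                 genotype_class = if (g %in% cls$small) "COM" else "ALT",
                 volume = (pi / 2) * truth$true_r[i]^2 * truth$true_h[i],
                 scn = lat$scn, ascs = lat$ascs_um2)
    })
    do.call(rbind, rows)
  })
  write_tsv(cyto, file.path(out_dir, "cytometry.tsv"))
  cyto_anova <- stage("cytometry", scn_ascs_anova(cyto, response = "scn"))
  utils::write.table(cbind(term = rownames(cyto_anova),
                           as.data.frame(cyto_anova)),
                     file.path(out_dir, "cytometry_anova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (plots) {
    grDevices::png(file.path(out_dir, "morphospace.png"), 800, 600)
    hr <- stats::aggregate(cbind(height, radius) ~ genotype, morpho, mean)
    cls <- sizes$class[match(hr$genotype, sizes$genotype)]
    graphics::plot(hr$radius, hr$height,
                   col = c("blue", "grey40", "red")[as.integer(cls)],
                   pch = 16, xlab = "radius (um)", ylab = "height (um)",
                   main = "SAM morphospace")
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "manhattan.png"), 1000, 500)
    plot(scan)
    grDevices::dev.off()
  }

  text_outputs <- list.files(out_dir, pattern = "\\.(tsv|vcf)$",
                             full.names = TRUE)
  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg)[!vapply(cfg, is.data.frame, TRUE)],
    causal_effects = cfg$causal_effects,
    thresholds = list(alpha = alpha, window = window, maf_min = maf_min,
                      miss_max = miss_max, bonferroni = scan$threshold),
    repeatability = blup$H2,
    n_sites_tested = scan$M,
    n_tas = nrow(tas),
    burden_r = burden$cor$r,
    burden_p = burden$cor$p,
    covariate_bic = scan$covariate_selection,
    checksums = as.list(tools::md5sum(text_outputs))
  )
  names(manifest$checksums) <- basename(text_outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
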
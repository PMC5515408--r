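#' Canonical E-box and control motif sets
#'
#' All ten distinct E-boxes (CANNTG collapsed over reverse complement),
#' the non-E-box palindrome AACGTT, and two neutral control hexamers.
#' The published control oligo hexamers are not printed in the text, so
#' the defaults are neutral palindromes; override per config.
#'
#' @return character vector of canonical hexamers.
#' @export
ebox_motifs <- function() {
  nn <- expand.grid(DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  unique(canonical_hexamer(paste0("CA", nn[, 1], nn[, 2], "TG")))
}

#' @rdname ebox_motifs
#' @export
control_motifs <- function() c("ATCGAT", "TTCGAA")

default_site_plan <- function() {
  data.frame(
    motif = c("CACGTG", "CACGCG", "CATGTG", "CACGTT", "CATGCG", "CACGAG",
              "AACGTT", "CATATG", "CGCGTT"),
    count = c(60L, 15L, 15L, 15L, 15L, 15L, 80L, 15L, 15L),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic dose model
#'
#' Doses are set an order of magnitude apart around the low-affinity
#' tier's Kd so that low-affinity sites are detected mostly at the high
#' dose while canonical sites are detected at both: the regime in which
#' protein overexpression preferentially creates low-affinity peaks.
#'
#' @param seed RNG seed.
#' @param sigma_h lognormal height-noise sd.
#' @return a [peak_model()].
#' @export
default_peak_model <- function(seed = 1, sigma_h = 0.25) {
  peak_model(concentration = c(lowMYC = 0.25, highMYC = 2.5),
             theta_det = 0.25, h0 = 20, sigma_h = sigma_h, seed = seed)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode generates every input (probe library, array
#' intensities, genome with planted sites, dose-dependent peak calls,
#' competition curves), then runs scoring, motif ranking, PWMs,
#' scanning, enrichment, co-occurrence, annotation, dose comparison,
#' coverage and EMSA fitting, writing TSV artifacts, a JSON report and
#' a run log (seeds, thresholds, config hash) to `out_dir`. Real mode
#' consumes a genome FASTA, two peak tables and a gene BED via
#' `config$paths` and runs the genomic arm (plus the PBM arm when a
#' published score table is supplied).
#'
#' @param config an [analysis_config()].
#' @param mode `"synthetic"` or `"real"`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of result objects.
#' @export
run_pipeline <- function(config = analysis_config(),
                         mode = c("synthetic", "real"), out_dir) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "analysis_config"))
  if (mode == "real") {
    need <- c("genome", "peaks_high", "peaks_low", "genes")
    missing <- setdiff(need, names(config$paths))
    if (length(missing)) {
      abort_invalid(paste0("run_pipeline: real mode needs paths: ",
                           paste(missing, collapse = ", ")))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  res <- list()
  log <- c(sprintf("eboxscape run log"),
           sprintf("mode: %s", mode),
           sprintf("config_hash: %d", config_hash(config)),
           sprintf("seed: %d", seed))

  affin <- default_affinity_table()

  if (mode == "synthetic") {
    lib <- build_probe_library(seed = seed)
    arr <- gen_pbm_intensities(lib, affin, noise_cv = 0.2, seed = seed + 1)
    genome <- gen_genome(n_chrom = 2, length = 150000, gc = 0.41,
                         seed = seed + 2)
    planted <- plant_sites(genome, default_site_plan(), seed = seed + 3,
                           affinity = affin)
    genome <- planted$genome
    truth <- planted$truth
    genes <- gen_gene_models(genome, n_genes = 25, seed = seed + 4)
    model <- default_peak_model(seed = seed + 5)
    peaks_low <- gen_peaks(truth, model, "lowMYC", nchar(genome))
    peaks_high <- gen_peaks(truth, model, "highMYC", nchar(genome))
    write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
    write_tsv(truth, file.path(out_dir, "truth_sites.tsv"))
    write_bed(transform(genes, name = gene_id), file.path(out_dir, "genes.bed"))
    write_tsv(arr, file.path(out_dir, "pbm_intensities.tsv"))
    scores_src <- normalize_array(arr)
    var12_map <- setNames(lib$var12, lib$id)
  } else {
    genome <- read_genome_fasta(config$paths$genome)
    genes_bed <- read_bed(config$paths$genes)
    genes <- data.frame(gene_id = genes_bed$name, chrom = genes_bed$chrom,
                        start = genes_bed$start, end = genes_bed$end,
                        strand = genes_bed$strand %||% "+",
                        stringsAsFactors = FALSE)
    genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
    peaks_low <- read_peaks(config$paths$peaks_low)
    peaks_high <- read_peaks(config$paths$peaks_high)
    lib <- build_probe_library(seed = seed)
    var12_map <- setNames(lib$var12, lib$id)
    scores_src <- if (!is.null(config$paths$s1_scores)) {
      s1 <- read_s1_scores(config$paths$s1_scores)
      v <- attr(s1, "var12")
      if (!is.null(v)) var12_map <- v
      s1
    } else NULL
  }

  # ---- PBM arm -------------------------------------------------------
  if (!is.null(scores_src)) {
    scores <- scores_src
    lib_eff <- data.frame(id = names(var12_map), var12 = unname(var12_map),
                          stringsAsFactors = FALSE)
    cat_map <- lib$category[match(lib_eff$id, lib$id)]
    cat_map[is.na(cat_map)] <- "core6"
    lib_eff$category <- cat_map
    write_tsv(scores, file.path(out_dir, "pbm_scores.tsv"))
    dimers <- unique(scores$dimer)
    thr95 <- lapply(dimers, function(d) null_threshold(scores, d, config$q_high))
    names(thr95) <- dimers
    ranked <- lapply(dimers, function(d) {
      rank_motifs(bound_probes(scores, d, thr95[[d]]), lib_eff)
    })
    names(ranked) <- dimers
    for (d in dimers) {
      write_tsv(ranked[[d]], file.path(out_dir, paste0("motif_rank_", d, ".tsv")))
      log <- c(log, sprintf("null_q%.2f[%s]: %.4f", config$q_high, d, thr95[[d]]))
    }
    res$ranked <- ranked
    res$common <- common_motifs(ranked[[1]], ranked[[2]])
    res$high_confidence <- high_confidence_motifs(scores, lib_eff,
                                                  q_low = config$q_low,
                                                  q_high = config$q_high,
                                                  dimers = dimers)
    res$r2 <- score_correlation(scores, dimers)
    log <- c(log, sprintf("score_R2: %.4f", res$r2))
    # rank-sliced PWMs over core probes above the permissive threshold
    thr80 <- null_threshold(scores, dimers[1], config$q_low)
    core_bound <- bound_probes(scores, dimers[1], thr80, categories = "core6")
    slices <- list(c(1, 50), c(51, 100), c(101, 350))
    res$pwms <- lapply(slices, function(sl) {
      sl[2] <- min(sl[2], nrow(core_bound))
      if (sl[1] > sl[2]) return(NULL)
      build_pwm(core_bound, lib_eff, sl, pseudocount = config$pwm_pseudocount)
    })
    for (i in seq_along(res$pwms)) {
      if (!is.null(res$pwms[[i]])) {
        write_pfm(res$pwms[[i]],
                  file.path(out_dir, sprintf("pwm_slice%d.pfm", i)))
      }
    }
    if (mode == "synthetic") {
      res$flank_pwms <- flank_quartile_pwms(scores, lib, side = "right",
                                            dimer = dimers[1],
                                            pseudocount = config$pwm_pseudocount)
    }
  }

  # ---- genomic arm ---------------------------------------------------
  keep <- function(p) p[p$pvalue < config$peak_pvalue_cutoff, , drop = FALSE]
  peaks_low <- keep(peaks_low); peaks_high <- keep(peaks_high)
  write_peaks(peaks_high, file.path(out_dir, "peaks_high.tsv"))
  write_peaks(peaks_low, file.path(out_dir, "peaks_low.tsv"))
  chrom_sizes <- nchar(genome)
  summits_high <- make_summits(peaks_high, config$summit_radius, chrom_sizes)
  summits_low <- make_summits(peaks_low, config$summit_radius, chrom_sizes)
  motifs <- unique(c(ebox_motifs(), NE, control_motifs()))
  hits <- scan_motifs(genome, motifs)
  gcounts <- genome_motif_counts(genome, motifs)
  write_tsv(hits, file.path(out_dir, "motif_hits.tsv"))

  nf_all <- normalized_frequency(summits_high, hits, gcounts)
  top_peaks <- top_fraction_peaks(peaks_high, config$top_fraction)
  nf_top <- normalized_frequency(make_summits(top_peaks, config$summit_radius,
                                              chrom_sizes), hits, gcounts)
  write_tsv(nf_all, file.path(out_dir, "nf_summits_all.tsv"))
  write_tsv(nf_top, file.path(out_dir, "nf_summits_top.tsv"))
  res$nf_all <- nf_all; res$nf_top <- nf_top

  cme_hits <- hits[hits$motif == CME, ]
  ne_hits <- hits[hits$motif == NE, ]
  venn <- rbind(
    data.frame(set = "peaks", t(cooccurrence_partition(peaks_high, cme_hits, ne_hits))),
    data.frame(set = "summits", t(cooccurrence_partition(summits_high, cme_hits, ne_hits)))
  )
  write_tsv(venn, file.path(out_dir, "venn_cme_ne.tsv"))
  res$venn <- venn

  ann <- annotate_regions(summits_high, genes, config$promoter_window)
  write_tsv(ann, file.path(out_dir, "summit_annotation.tsv"))
  res$annotation <- ann

  fc_count <- condition_fold_change(summits_high, summits_low, hits,
                                    c(CME, NE), mode = "count")
  fc_height <- condition_fold_change(summits_high, summits_low, hits,
                                     c(CME, NE), mode = "mean_height")
  write_tsv(fc_count, file.path(out_dir, "fold_change_count.tsv"))
  write_tsv(fc_height, file.path(out_dir, "fold_change_height.tsv"))
  res$fold_change <- list(count = fc_count, mean_height = fc_height)

  res$spatial <- spatial_distribution(summits_high, cme_hits,
                                      window = config$summit_radius)
  write_tsv(res$spatial, file.path(out_dir, "spatial_cme.tsv"))

  if (!is.null(res$ranked)) {
    top21 <- top_motifs(res$ranked[[1]], n = 21)
    res$coverage <- topk_coverage(summits_high, scan_motifs(genome, top21), top21)
    log <- c(log, sprintf("top21_coverage: %.4f", res$coverage))
  }
  res$strata <- stratify_by_fold(peaks_high)

  # ---- EMSA arm (synthetic only) -------------------------------------
  if (mode == "synthetic") {
    assay <- competition_assay(P_tot = 0.3, K_L = 1 / affinity_of(affin, CME))
    true_KC <- c(CME = 1 / affinity_of(affin, CME),
                 CACGTT = 1 / affinity_of(affin, "CACGTT"),
                 NE = 1 / affinity_of(affin, NE),
                 Ctrl = Inf)
    curves <- gen_competition_curves(assay, true_KL = assay$K_L,
                                     true_KC = true_KC, noise_sd = 5,
                                     n_rep = 3, seed = seed + 6)
    write_tsv(curves, file.path(out_dir, "emsa_curves.tsv"))
    fits <- fit_relative_affinity(curves, assay, reference = "NE",
                                  kl_anchor = "CME")
    write_tsv(fits, file.path(out_dir, "emsa_fits.tsv"))
    res$emsa <- summarize_affinity_table(list(MAXMAX = fits))
    write_tsv(res$emsa, file.path(out_dir, "affinity_summary.tsv"))
  }

  report <- list(
    mode = mode, seed = seed, config_hash = config_hash(config),
    n_peaks_high = nrow(peaks_high), n_peaks_low = nrow(peaks_low),
    r2 = res$r2, common_motifs = res$common,
    high_confidence_motifs = res$high_confidence,
    top_motif = if (!is.null(res$ranked)) res$ranked[[1]]$motif[1] else NULL,
    coverage_top21 = res$coverage,
    fold_change_count = if (!is.null(res$fold_change))
      setNames(res$fold_change$count$fold_change, res$fold_change$count$motif)
      else NULL
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(res)
}
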
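#' Generate a random background genome
#'
#' Sequences are iid over ACGT with a configurable GC fraction; no
#' repeat structure is simulated (the background only has to support
#' motif-count statistics).
#'
#' @param n_chrom number of chromosomes.
#' @param length length of each chromosome in bp (>= 1000).
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed.
#' @return named character vector of sequences (`chr1`, `chr2`, ...).
#' @export
gen_genome <- function(n_chrom = 1, length = 1e5, gc = 0.41, seed = 1) {
  if (length(length) != 1 || !is.finite(length) || length < 1000) {
    abort_invalid("gen_genome: length must be a single value >= 1000")
  }
  if (gc <= 0 || gc >= 1) abort_invalid("gen_genome: gc must be in (0, 1)")
  stopifnot(n_chrom >= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_chrom), function(i) {
      paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  seqs
}

#' Plant motif sites into a genome
#'
#' Overwrites non-overlapping loci with the given 6-mer motifs (each on
#' a random strand) and records the ground truth. Planted sites are
#' separated by at least `min_gap` bp and never overlap one another.
#'
#' @param genome named character vector of sequences.
#' @param plan data frame with columns `motif` (6-mer) and `count`, or a
#'   named integer vector motif -> count.
#' @param min_gap minimum gap between planted sites (bp).
#' @param seed RNG seed.
#' @param affinity optional `affinity_table` used to record a Kd
#'   (`1 / affinity`) per planted site in the truth table.
#' @return list with elements `genome` (modified sequences) and `truth`,
#'   a data frame (`chrom`, `start` 0-based, `motif`, `strand`, `kd`).
#' @export
plant_sites <- function(genome, plan, min_gap = 50, seed = 1,
                        affinity = default_affinity_table()) {
  genome <- as_genome_character(genome)
  if (!is.data.frame(plan)) {
    plan <- data.frame(motif = names(plan), count = as.integer(plan),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(is_dna_string(plan$motif, 6L)), all(plan$count >= 0))
  total <- sum(plan$count)
  if (total == 0) {
    return(list(genome = genome,
                truth = data.frame(chrom = character(0), start = integer(0),
                                   motif = character(0), strand = character(0),
                                   kd = numeric(0))))
  }
  # capacity check: each site consumes 6 + min_gap bp
  if (total * (6 + min_gap) > sum(nchar(genome))) {
    abort_invalid("plant_sites: genome too small for the requested plan")
  }
  with_seed(seed, {
    # draw candidate loci uniformly, reject overlaps/gap violations
    lens <- nchar(genome)
    chrom_prob <- lens / sum(lens)
    placed <- vector("list", total)
    occupied <- lapply(genome, function(s) integer(0))
    motifs <- rep(plan$motif, plan$count)
    motifs <- sample(motifs)   # interleave motif identities across the genome
    k <- 0L; tries <- 0L
    while (k < total) {
      tries <- tries + 1L
      if (tries > 200L * total) {
        abort_invalid("plant_sites: unable to place all sites (genome too crowded)")
      }
      ci <- sample(length(genome), 1, prob = chrom_prob)
      pos <- sample(lens[ci] - 5L, 1)   # 1-based start
      lo <- max(1L, pos - 5L - min_gap); hi <- pos + 5L + min_gap
      if (any(occupied[[ci]] >= lo & occupied[[ci]] <= hi)) next
      k <- k + 1L
      occupied[[ci]] <- c(occupied[[ci]], pos)
      strand <- sample(c("+", "-"), 1)
      placed[[k]] <- list(ci = ci, pos = pos, motif = motifs[k], strand = strand)
    }
  })
  truth <- do.call(rbind, lapply(placed, function(p) {
    data.frame(chrom = names(genome)[p$ci], start = p$pos - 1L,
               motif = p$motif, strand = p$strand, stringsAsFactors = FALSE)
  }))
  for (p in placed) {
    insert <- if (p$strand == "+") p$motif else revcomp(p$motif)
    substr(genome[p$ci], p$pos, p$pos + 5L) <- insert
  }
  truth$kd <- 1 / affinity_of(affinity, truth$motif)
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Generate disjoint gene models
#'
#' Places `n_genes` non-overlapping gene spans on the genome; the TSS is
#' the span start on the + strand and the span end on the - strand.
#'
#' @param genome named character vector of sequences.
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @param span_range min/max gene length (bp).
#' @return data frame (`gene_id`, `chrom`, `start`, `end` 0-based
#'   half-open, `strand`, `tss`).
#' @export
gen_gene_models <- function(genome, n_genes = 20, seed = 1,
                            span_range = c(2000, 10000)) {
  genome <- as_genome_character(genome)
  if (n_genes == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), tss = integer(0)))
  }
  lens <- nchar(genome)
  if (n_genes * mean(span_range) > sum(lens)) {
    abort_invalid("gen_gene_models: genome too small for the requested genes")
  }
  with_seed(seed, {
    spans <- vector("list", n_genes)
    occupied <- lapply(genome, function(s) cbind(start = integer(0), end = integer(0)))
    k <- 0L; tries <- 0L
    while (k < n_genes) {
      tries <- tries + 1L
      if (tries > 500L * n_genes) {
        abort_invalid("gen_gene_models: unable to place all genes")
      }
      ci <- sample(length(genome), 1, prob = lens / sum(lens))
      w <- sample(span_range[1]:span_range[2], 1)
      if (lens[ci] <= w) next
      s <- sample(lens[ci] - w, 1) - 1L   # 0-based
      e <- s + w
      occ <- occupied[[ci]]
      if (nrow(occ) && any(s < occ[, "end"] & e > occ[, "start"])) next
      k <- k + 1L
      occupied[[ci]] <- rbind(occ, c(start = s, end = e))
      spans[[k]] <- data.frame(chrom = names(genome)[ci], start = s, end = e,
                               strand = sample(c("+", "-"), 1),
                               stringsAsFactors = FALSE)
    }
  })
  genes <- do.call(rbind, spans)
  genes$gene_id <- sprintf("gene%03d", seq_len(n_genes))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes <- genes[order(genes$chrom, genes$start),
                 c("gene_id", "chrom", "start", "end", "strand", "tss")]
  rownames(genes) <- NULL
  genes
}
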
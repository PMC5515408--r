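#' Scan a genome for exact hexamer motif occurrences
#'
#' Finds all exact matches of each motif on both strands. Motifs are
#' canonicalized first (so a motif and its reverse complement are the
#' same query); palindromic motifs yield one hit per position with
#' strand `+`. N runs in the genome never match.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param motifs character vector of 6-mers over ACGT.
#' @return data frame (`motif` canonical, `chrom`, `start` 0-based,
#'   `end` = start + 6, `strand`), sorted by motif, chrom, start.
#' @export
scan_motifs <- function(genome, motifs) {
  if (!all(is_dna_string(motifs, 6L))) {
    abort_invalid("scan_motifs: motifs must be unambiguous 6-mers over ACGT")
  }
  genome <- as_genome_character(genome)
  motifs <- unique(canonical_hexamer(motifs))
  subject <- Biostrings::DNAStringSet(genome)
  hits <- lapply(motifs, function(m) {
    rc <- revcomp(m)
    strands <- if (m == rc) "+" else c("+", "-")
    per_strand <- lapply(strands, function(st) {
      pat <- if (st == "+") m else rc
      ml <- Biostrings::vmatchPattern(pat, subject)
      do.call(rbind, lapply(seq_along(ml), function(i) {
        s <- BiocGenerics::start(ml[[i]])
        if (length(s) == 0) return(NULL)
        data.frame(motif = m, chrom = names(genome)[i], start = s - 1L,
                   end = s + 5L, strand = st, stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, per_strand)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(motif = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out <- out[order(out$motif, out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Genome-wide motif occurrence counts
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param motifs character vector of 6-mers.
#' @return named integer vector of total hit counts per canonical
#'   motif.
#' @export
genome_motif_counts <- function(genome, motifs) {
  hits <- scan_motifs(genome, motifs)
  motifs <- unique(canonical_hexamer(motifs))
  cnt <- table(factor(hits$motif, levels = motifs))
  setNames(as.integer(cnt), names(cnt))
}
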
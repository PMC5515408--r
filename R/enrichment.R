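# GRanges helpers: package data frames use 0-based half-open starts,
# GenomicRanges is 1-based closed — shift on the way in only.
regions_gr <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}
hits_gr <- function(hits) {
  GenomicRanges::GRanges(hits$chrom,
                         IRanges::IRanges(hits$start + 1L, hits$end))
}

# logical: is each hit fully contained in >= 1 region
hit_in_region <- function(hits, regions) {
  if (nrow(hits) == 0 || nrow(regions) == 0) return(rep(FALSE, nrow(hits)))
  ov <- GenomicRanges::findOverlaps(hits_gr(hits), regions_gr(regions),
                                    type = "within")
  out <- rep(FALSE, nrow(hits))
  out[unique(S4Vectors::queryHits(ov))] <- TRUE
  out
}

# logical: does each region fully contain >= 1 of the hits
region_has_hit <- function(regions, hits) {
  if (nrow(regions) == 0) return(logical(0))
  if (nrow(hits) == 0) return(rep(FALSE, nrow(regions)))
  ov <- GenomicRanges::findOverlaps(hits_gr(hits), regions_gr(regions),
                                    type = "within")
  out <- rep(FALSE, nrow(regions))
  out[unique(S4Vectors::subjectHits(ov))] <- TRUE
  out
}

#' Genome-normalized motif frequency in a region set
#'
#' For each motif, counts the motif instances fully contained in at
#' least one region (each instance counted once, however many regions
#' cover it) and divides by the motif's genome-wide occurrence count.
#'
#' @param regions region data frame (`chrom`, `start`, `end`).
#' @param hits motif-hit data frame from [scan_motifs()].
#' @param genome_counts named genome-wide counts per motif, e.g. from
#'   [genome_motif_counts()].
#' @return data frame (`motif`, `hits_in_regions`, `hits_genome`,
#'   `normalized_frequency`); motifs absent from the genome are dropped
#'   with a warning.
#' @export
normalized_frequency <- function(regions, hits, genome_counts) {
  motifs <- names(genome_counts)
  absent <- motifs[genome_counts == 0]
  if (length(absent)) {
    warning("normalized_frequency: motif(s) absent from genome omitted: ",
            paste(absent, collapse = ", "))
    motifs <- setdiff(motifs, absent)
  }
  rows <- lapply(motifs, function(m) {
    h <- hits[hits$motif == m, , drop = FALSE]
    inside <- sum(hit_in_region(h, regions))
    data.frame(motif = m, hits_in_regions = inside,
               hits_genome = as.integer(genome_counts[[m]]),
               normalized_frequency = inside / genome_counts[[m]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(motif = character(0), hits_in_regions = integer(0),
               hits_genome = integer(0), normalized_frequency = numeric(0))
  rownames(out) <- NULL
  out
}

#' Two-motif co-occurrence partition of a region set
#'
#' Assigns every region to exactly one cell of the 2x2 containment
#' table: contains only motif A, only motif B, both, or neither.
#'
#' @param regions region data frame.
#' @param hits_A,hits_B motif-hit data frames (e.g. the canonical E-box
#'   and the non-E-box hexamer).
#' @return named integer vector (`A_only`, `B_only`, `both`,
#'   `neither`), summing to the number of regions.
#' @export
cooccurrence_partition <- function(regions, hits_A, hits_B) {
  a <- region_has_hit(regions, hits_A)
  b <- region_has_hit(regions, hits_B)
  c(A_only = sum(a & !b), B_only = sum(!a & b),
    both = sum(a & b), neither = sum(!a & !b))
}

#' Annotate regions as promoter / intragenic / intergenic
#'
#' Category is decided by the region's apex with precedence promoter >
#' intragenic > intergenic: promoter when the apex lies within
#' `promoter_window` bp of any TSS, intragenic when inside a gene span.
#' The nearest TSS's gene and the strand-aware signed distance
#' (positive downstream of the TSS) are recorded.
#'
#' @param regions region data frame with an `apex` column and ids in
#'   `peak_id` (or `id`).
#' @param genes gene data frame from [gen_gene_models()] (or any table
#'   with `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`).
#' @param promoter_window promoter half-width around the TSS (bp,
#'   default 2000).
#' @return data frame (`region_id`, `category`, `nearest_gene`,
#'   `tss_distance`).
#' @export
annotate_regions <- function(regions, genes, promoter_window = 2000) {
  ids <- regions$peak_id %||% regions$id
  if (is.null(ids)) ids <- sprintf("region%04d", seq_len(nrow(regions)))
  n <- nrow(regions)
  if (is.null(genes) || nrow(genes) == 0) {
    return(data.frame(region_id = ids, category = rep("intergenic", n),
                      nearest_gene = NA_character_,
                      tss_distance = NA_integer_, stringsAsFactors = FALSE))
  }
  category <- character(n); nearest <- character(n); dist <- integer(n)
  for (i in seq_len(n)) {
    apex <- regions$apex[i]
    same <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) {
      category[i] <- "intergenic"; nearest[i] <- NA_character_
      dist[i] <- NA_integer_
      next
    }
    d_abs <- abs(apex - same$tss)
    j <- which.min(d_abs)
    signed <- apex - same$tss[j]
    if (same$strand[j] == "-") signed <- -signed
    nearest[i] <- same$gene_id[j]
    dist[i] <- as.integer(signed)
    inside <- any(apex >= same$start & apex < same$end)
    category[i] <- if (d_abs[j] <= promoter_window) "promoter"
                   else if (inside) "intragenic" else "intergenic"
  }
  data.frame(region_id = ids, category = category, nearest_gene = nearest,
             tss_distance = dist, stringsAsFactors = FALSE)
}

#' Fold change of motif-containing summits between conditions
#'
#' For each motif, the count mode reports the ratio of the number of
#' motif-containing summits in the high condition over the low
#' condition; the mean-height mode reports the ratio of mean peak
#' heights of those summits.
#'
#' @param summits_high,summits_low summit data frames for the two
#'   conditions (same genome and motif scan).
#' @param hits motif-hit data frame covering all motifs of interest.
#' @param motifs canonical motifs to report.
#' @param mode `"count"` or `"mean_height"`.
#' @return data frame (`motif`, `high`, `low`, `fold_change`); a zero
#'   denominator yields `Inf` with a warning.
#' @export
condition_fold_change <- function(summits_high, summits_low, hits, motifs,
                                  mode = c("count", "mean_height")) {
  mode <- match.arg(mode)
  rows <- lapply(motifs, function(m) {
    h <- hits[hits$motif == m, , drop = FALSE]
    sel_hi <- region_has_hit(summits_high, h)
    sel_lo <- region_has_hit(summits_low, h)
    if (mode == "count") {
      hi <- sum(sel_hi); lo <- sum(sel_lo)
    } else {
      hi <- mean(summits_high$height[sel_hi])
      lo <- mean(summits_low$height[sel_lo])
    }
    if (isTRUE(lo == 0) || is.nan(lo)) {
      warning("condition_fold_change: zero/undefined denominator for ", m)
      fc <- Inf
    } else fc <- hi / lo
    data.frame(motif = m, high = hi, low = lo, fold_change = fc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spatial distribution of motif hits around summit apexes
#'
#' Histograms the offsets of motif midpoints from their summit apex,
#' normalized by the number of summits, to show whether a motif
#' clusters at summit centers.
#'
#' @param summits summit data frame with `apex`.
#' @param hits motif-hit data frame for one motif.
#' @param bin bin width (bp).
#' @param window half-window around the apex (bp); 100 for summits, 350
#'   for the extended flank analysis.
#' @return data frame (`offset` bin center, `count`, `frequency` =
#'   count / number of summits).
#' @export
spatial_distribution <- function(summits, hits, bin = 10, window = 100) {
  breaks <- seq(-window, window, by = bin)
  mids <- hits$start + 3L
  offsets <- unlist(lapply(seq_len(nrow(summits)), function(i) {
    sel <- hits$chrom == summits$chrom[i] &
      hits$start >= summits$apex[i] - window &
      hits$end <= summits$apex[i] + window
    mids[sel] - summits$apex[i]
  }))
  offsets <- offsets[offsets >= -window & offsets < window]
  cut_idx <- findInterval(offsets, breaks, rightmost.closed = FALSE)
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1)
  data.frame(offset = breaks[-length(breaks)] + bin / 2, count = counts,
             frequency = counts / max(1L, nrow(summits)))
}

#' Fraction of summits covered by a motif list
#'
#' @param summits summit data frame.
#' @param hits motif-hit data frame (any set of motifs).
#' @param motifs motif list (canonicalized); typically the top in-vitro
#'   bound motifs minus the GC-rich entries.
#' @return fraction in [0, 1] of summits fully containing at least one
#'   hit of any listed motif.
#' @export
topk_coverage <- function(summits, hits, motifs) {
  if (nrow(summits) == 0) abort_invalid("topk_coverage: empty summit set")
  if (length(motifs) == 0) return(0)
  motifs <- unique(canonical_hexamer(motifs))
  h <- hits[hits$motif %in% motifs, , drop = FALSE]
  mean(region_has_hit(summits, h))
}

#' Top motifs of a ranked list, excluding GC-rich entries
#'
#' @param ranked ranked motif table from [rank_motifs()].
#' @param n number of motifs to keep after exclusion (default 21).
#' @param exclude_gc_rich drop motifs classified `GC-rich` first.
#' @return character vector of canonical motifs.
#' @export
top_motifs <- function(ranked, n = 21, exclude_gc_rich = TRUE) {
  m <- ranked
  if (exclude_gc_rich) m <- m[m$class != "GC-rich", , drop = FALSE]
  head(m$motif, n)
}
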
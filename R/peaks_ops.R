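#' Summit regions around peak apexes
#'
#' One region per peak: `[apex - radius, apex + radius)`, clamped to the
#' chromosome when sizes are supplied. The conventional radius of 100 bp
#' gives 200-bp summits; a radius of 350 bp covers the extended
#' flank-analysis window.
#'
#' @param peaks peak data frame with `chrom`, `apex` columns.
#' @param radius half-width in bp (default 100).
#' @param chrom_sizes optional named chromosome lengths for clamping.
#' @return data frame (`chrom`, `start`, `end`, `apex`, `peak_id`, plus
#'   `height`/`pvalue`/`condition` carried over when present).
#' @export
make_summits <- function(peaks, radius = 100, chrom_sizes = NULL) {
  stopifnot(radius > 0)
  start <- peaks$apex - radius
  end <- peaks$apex + radius
  if (!is.null(chrom_sizes)) {
    end <- pmin(as.integer(chrom_sizes[peaks$chrom]), end)
  }
  start <- pmax(0L, start)
  out <- data.frame(chrom = peaks$chrom, start = as.integer(start),
                    end = as.integer(end), apex = peaks$apex,
                    peak_id = peaks$id, stringsAsFactors = FALSE)
  for (col in c("height", "pvalue", "condition")) {
    if (col %in% names(peaks)) out[[col]] <- peaks[[col]]
  }
  rownames(out) <- NULL
  out
}

#' Most significant fraction of a peak set
#'
#' Keeps the `ceil(fraction * N)` peaks with the smallest values of the
#' ranking key (p-value by default); ties are broken by height
#' (descending) then id.
#'
#' @param peaks peak data frame.
#' @param fraction fraction in (0, 1].
#' @param key ranking column (smaller = better), default `"pvalue"`.
#' @return subset of `peaks`.
#' @export
top_fraction_peaks <- function(peaks, fraction = 0.33, key = "pvalue") {
  stopifnot(fraction > 0, fraction <= 1, key %in% names(peaks))
  n <- ceiling(fraction * nrow(peaks))
  ord <- order(peaks[[key]],
               if ("height" %in% names(peaks)) -peaks$height else seq_len(nrow(peaks)),
               peaks$id)
  out <- peaks[head(ord, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify peaks into Low / Medium / High fold-enrichment tertiles
#'
#' Tertile split by the `height` (fold-enrichment) column; sizes differ
#' by at most 1. Equal heights are ordered stably by id, so the split is
#' deterministic.
#'
#' @param peaks peak data frame with a `height` column.
#' @return named list of three peak data frames (`Low`, `Medium`,
#'   `High`), a partition of the input.
#' @export
stratify_by_fold <- function(peaks) {
  stopifnot("height" %in% names(peaks))
  n <- nrow(peaks)
  ord <- order(peaks$height, peaks$id)
  sizes <- diff(floor(n * 0:3 / 3))
  grp <- rep(c("Low", "Medium", "High"), times = sizes)
  out <- split(peaks[ord, , drop = FALSE], factor(grp, levels = c("Low", "Medium", "High")))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
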
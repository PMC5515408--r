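#' Normalize raw PBM intensities into binding scores
#'
#' Per probe and dimer channel, the score is the log2 of the median of
#' the triplicate spot intensities divided by the channel's median spot
#' intensity. Median-of-triplicates over per-array-median is robust,
#' scale-free, and reproducible without the original scanner pipeline.
#'
#' @param raw array table (`probe_id`, `category`, `dimer`, `rep`,
#'   `intensity`), three replicates per probe/dimer.
#' @return score table data frame (`probe_id`, `category`, `dimer`,
#'   `score`).
#' @export
normalize_array <- function(raw) {
  need <- c("probe_id", "dimer", "rep", "intensity")
  if (!all(need %in% names(raw))) {
    abort_invalid("normalize_array: missing array-table columns")
  }
  counts <- table(raw$probe_id, raw$dimer)
  if (any(counts != 3)) {
    abort_invalid("normalize_array: every (probe, dimer) needs exactly 3 replicates")
  }
  if (any(raw$intensity <= 0)) {
    floorv <- min(raw$intensity[raw$intensity > 0])
    warning("normalize_array: non-positive intensities floored to ", floorv)
    raw$intensity[raw$intensity <= 0] <- floorv
  }
  has_cat <- "category" %in% names(raw)
  out <- do.call(rbind, lapply(split(raw, raw$dimer), function(d) {
    d <- d[order(d$probe_id, d$rep), ]
    m <- matrix(d$intensity, nrow = 3)   # one column per probe
    med <- colSums(m) - apply(m, 2, max) - apply(m, 2, min)  # median of 3
    arr_med <- median(d$intensity)
    df <- data.frame(probe_id = d$probe_id[seq(1, nrow(d), by = 3)],
                     dimer = d$dimer[1],
                     score = log2(med / arr_med), stringsAsFactors = FALSE)
    if (has_cat) {
      df$category <- d$category[seq(1, nrow(d), by = 3)]
      df <- df[, c("probe_id", "category", "dimer", "score")]
    }
    df
  }))
  rownames(out) <- NULL
  out
}

#' Empirical-null binding threshold from random probes
#'
#' The threshold is the empirical `q`-quantile (linear interpolation
#' between order statistics) of the random-probe scores of one dimer
#' channel. The mean + 2 sd of the random scores is attached as a
#' companion diagnostic, since at q = 0.95 the two conventions roughly
#' agree for well-behaved nulls.
#'
#' @param scores score table with a `category` column.
#' @param dimer channel name.
#' @param q quantile in (0, 1).
#' @return threshold value with attribute `mean_plus_2sd`.
#' @export
null_threshold <- function(scores, dimer, q = 0.95) {
  stopifnot(q > 0, q < 1)
  null <- scores$score[scores$dimer == dimer & scores$category == "random"]
  if (length(null) < 2) {
    abort_invalid("null_threshold: need >= 2 random-category probes")
  }
  thr <- unname(quantile(null, q, type = 7))
  attr(thr, "mean_plus_2sd") <- mean(null) + 2 * sd(null)
  thr
}

#' Probes bound above a threshold
#'
#' @param scores score table.
#' @param dimer channel name.
#' @param threshold score cutoff (strictly greater-than).
#' @param categories categories to keep; defaults to all designed
#'   (non-random) categories. Use `"core6"` for fixed-register PWM
#'   analyses.
#' @return score-table rows with `score > threshold`, sorted descending
#'   by score (ties by probe id).
#' @export
bound_probes <- function(scores, dimer, threshold,
                         categories = c("core6", "flank_left", "flank_right",
                                        "cme_mut")) {
  b <- scores[scores$dimer == dimer & scores$score > threshold, , drop = FALSE]
  if (!is.null(categories) && "category" %in% names(b)) {
    b <- b[b$category %in% categories, , drop = FALSE]
  }
  b <- b[order(-b$score, b$probe_id), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Rank motifs of bound probes
#'
#' Collapses a bound probe set to core-register hexamers (canonical
#' orientation) and ranks motifs by their best probe score; ties are
#' broken lexicographically by motif.
#'
#' @param bound bound score-table rows (from [bound_probes()]).
#' @param library probe library mapping probe ids to 12-mers.
#' @return data frame (`motif`, `rank`, `best_score`, `n_probes`,
#'   `class`).
#' @export
rank_motifs <- function(bound, library) {
  if (nrow(bound) == 0) abort_invalid("rank_motifs: empty bound set")
  var12 <- library$var12[match(bound$probe_id, library$id)]
  motif <- motif_of_probe(var12)
  agg <- data.frame(motif = motif, score = bound$score)
  best <- vapply(split(agg$score, agg$motif), max, numeric(1))
  n <- vapply(split(agg$score, agg$motif), length, integer(1))
  out <- data.frame(motif = names(best), best_score = unname(best),
                    n_probes = unname(n), stringsAsFactors = FALSE)
  out <- out[order(-out$best_score, out$motif), ]
  out$rank <- seq_len(nrow(out))
  out$class <- classify_motif(out$motif)
  rownames(out) <- NULL
  out[, c("motif", "rank", "best_score", "n_probes", "class")]
}

#' Motifs common to two ranked lists
#'
#' @param listA,listB ranked motif tables or character vectors of
#'   canonical motifs.
#' @return sorted character vector of shared motifs.
#' @export
common_motifs <- function(listA, listB) {
  a <- if (is.data.frame(listA)) listA$motif else listA
  b <- if (is.data.frame(listB)) listB$motif else listB
  sort(intersect(a, b))
}

#' High-confidence motifs bound by both dimers
#'
#' Motifs from the union of the two dimers' stringent (q_high) ranked
#' lists whose best probe also clears the permissive (q_low) null
#' threshold in both channels.
#'
#' @param scores score table with both dimers.
#' @param library probe library.
#' @param q_low permissive null quantile (default 0.80).
#' @param q_high stringent null quantile used for the ranked lists
#'   (default 0.95).
#' @param dimers the two channel names.
#' @return sorted character vector of canonical motifs.
#' @export
high_confidence_motifs <- function(scores, library, q_low = 0.80,
                                   q_high = 0.95,
                                   dimers = c("MYCMAX", "MAXMAX")) {
  stopifnot(length(dimers) == 2, all(dimers %in% scores$dimer))
  ranked <- lapply(dimers, function(d) {
    thr <- null_threshold(scores, d, q_high)
    b <- bound_probes(scores, d, thr)
    if (nrow(b) == 0) character(0) else rank_motifs(b, library)$motif
  })
  union95 <- union(ranked[[1]], ranked[[2]])
  low_sets <- lapply(dimers, function(d) {
    thr <- null_threshold(scores, d, q_low)
    b <- bound_probes(scores, d, thr)
    if (nrow(b) == 0) character(0)
    else unique(motif_of_probe(library$var12[match(b$probe_id, library$id)]))
  })
  sort(intersect(union95, intersect(low_sets[[1]], low_sets[[2]])))
}

#' Squared Pearson correlation between the two dimer channels
#'
#' @param scores score table with both dimers on shared probes.
#' @param dimers the two channel names.
#' @return R^2 over all paired probes.
#' @export
score_correlation <- function(scores, dimers = c("MYCMAX", "MAXMAX")) {
  a <- scores[scores$dimer == dimers[1], c("probe_id", "score")]
  b <- scores[scores$dimer == dimers[2], c("probe_id", "score")]
  m <- merge(a, b, by = "probe_id")
  m <- m[complete.cases(m), ]
  if (nrow(m) < 3) abort_invalid("score_correlation: need >= 3 paired probes")
  cor(m$score.x, m$score.y)^2
}
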
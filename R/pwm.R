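new_pwm <- function(counts, pseudocount) {
  freq <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  ent <- apply(freq, 2, function(f) -sum(ifelse(f > 0, f * log2(f), 0)))
  structure(list(freq = freq, counts = counts, ic = 2 - ent,
                 n = sum(counts[, 1]), pseudocount = pseudocount),
            class = "pwm")
}

#' Position weight matrix from ranked bound core probes
#'
#' Counts bases over the 8-mer window `aNNNNNNg` of each probe
#' (positions 3-10 of the 12-mer), with both orientations collapsed:
#' a probe whose core hexamer canonicalizes to its reverse complement
#' contributes the reverse-complemented 8-mer. Frequencies use a
#' pseudocount per base per column; the information content per column
#' is `2 - entropy` in bits.
#'
#' @param bound ordered bound probe set (core6 category) from
#'   [bound_probes()].
#' @param library probe library.
#' @param rank_slice integer pair `(from, to)` selecting ranks within
#'   the ordered bound set (e.g. `c(1, 50)`).
#' @param pseudocount per-base pseudocount (default 0.25).
#' @return object of class `pwm` with elements `freq` (4 x 8), `counts`,
#'   `ic`, `n`.
#' @export
build_pwm <- function(bound, library, rank_slice = c(1, nrow(bound)),
                      pseudocount = 0.25) {
  stopifnot(length(rank_slice) == 2)
  if (rank_slice[1] < 1 || rank_slice[2] > nrow(bound) ||
      rank_slice[1] > rank_slice[2]) {
    abort_invalid("build_pwm: rank slice out of bounds or empty")
  }
  sel <- bound[rank_slice[1]:rank_slice[2], , drop = FALSE]
  cat <- library$category[match(sel$probe_id, library$id)]
  if (!all(cat == "core6")) {
    abort_invalid("build_pwm: bound set must contain core6 probes only")
  }
  var12 <- library$var12[match(sel$probe_id, library$id)]
  win <- substr(var12, 3, 10)
  core <- substr(var12, 4, 9)
  flipped <- canonical_hexamer(core) != core
  win[flipped] <- revcomp(win[flipped])
  mat <- matrix(0, 4, 8, dimnames = list(DNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(win, ""))
  for (j in 1:8) {
    t <- table(factor(chars[, j], levels = DNA_BASES))
    mat[, j] <- as.numeric(t)
  }
  new_pwm(mat, pseudocount)
}

#' Flank-position PWMs by binding-score quartile
#'
#' Splits the 64 flank probes of one side into score quartiles
#' (descending score, ties by probe id; 16 probes each) and builds a
#' 3-column PWM of the substituted flank trimer per quartile. The
#' top 25% quartile holds the best-bound flanks; enrichment of a base in
#' the 75-100% quartile marks a disfavored flank.
#'
#' @param scores score table.
#' @param library probe library.
#' @param side `"left"` or `"right"`.
#' @param dimer channel name.
#' @param pseudocount per-base pseudocount.
#' @return named list of four `pwm` objects (`top25`, `q25_50`,
#'   `q50_75`, `q75_100`).
#' @export
flank_quartile_pwms <- function(scores, library, side = c("left", "right"),
                                dimer = "MYCMAX", pseudocount = 0.25) {
  side <- match.arg(side)
  cat_name <- paste0("flank_", side)
  ids <- library$id[library$category == cat_name]
  s <- scores[scores$dimer == dimer & scores$probe_id %in% ids, , drop = FALSE]
  if (nrow(s) != 64) {
    abort_invalid("flank_quartile_pwms: expected the 64 flank probes of one side")
  }
  s <- s[order(-s$score, s$probe_id), ]
  var12 <- library$var12[match(s$probe_id, library$id)]
  tri <- if (side == "left") substr(var12, 1, 3) else substr(var12, 10, 12)
  groups <- split(tri, rep(1:4, each = 16))
  names(groups) <- c("top25", "q25_50", "q50_75", "q75_100")
  lapply(groups, function(g) {
    chars <- do.call(rbind, strsplit(g, ""))
    mat <- matrix(0, 4, 3, dimnames = list(DNA_BASES, NULL))
    for (j in 1:3) {
      mat[, j] <- as.numeric(table(factor(chars[, j], levels = DNA_BASES)))
    }
    new_pwm(mat, pseudocount)
  })
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM over", ncol(x$freq), "positions from", x$n, "sequences",
      "(pseudocount", x$pseudocount, ")\n")
  print(round(x$freq, 3))
  cat("IC (bits):", paste(round(x$ic, 2), collapse = " "), "\n")
  invisible(x)
}

#' Write a PWM as a position-frequency-matrix text file
#'
#' Four tab-separated rows (A, C, G, T) of raw counts, the layout
#' standard PFM consumers read.
#'
#' @param pwm a `pwm` object.
#' @param path output file.
#' @export
write_pfm <- function(pwm, path) {
  lines <- apply(pwm$counts, 1, function(r) paste(r, collapse = "\t"))
  writeLines(paste0(rownames(pwm$counts), "\t", lines), path)
  invisible(path)
}
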
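#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rnorm runif sd setNames uniroot optimize cor complete.cases rbinom
#' @importFrom utils head read.delim write.table modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic generator in the package funnels through this, so
# identical arguments (seed included) give byte-identical output.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Reverse complement for plain upper-case ACGT character vectors.
# Biostrings handles XStringSet objects; this avoids round-tripping
# millions of short k-mers through S4 containers.
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, "", fixed = TRUE), function(b) {
    paste(comp[rev(b)], collapse = "")
  }, character(1))
}

is_dna_string <- function(x, len = NULL) {
  ok <- grepl("^[ACGT]+$", x)
  if (!is.null(len)) ok <- ok & nchar(x) == len
  ok
}

all_hexamers <- function() {
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, DNA_BASES,
                   DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  # column-major expand.grid: reverse so the first base varies slowest
  sort(apply(g[, 6:1], 1, paste, collapse = ""))
}

all_kmers <- function(k) {
  if (k == 6) return(all_hexamers())
  g <- do.call(expand.grid, c(rep(list(DNA_BASES), k),
                              list(stringsAsFactors = FALSE)))
  sort(apply(g[, k:1, drop = FALSE], 1, paste, collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_invalid <- function(msg) stop(msg, call. = FALSE)

# coerce a named character genome or DNAStringSet to named character
as_genome_character <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  toupper(genome)
}
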
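# shared fixtures: built once per test run, all seeded

# small probe library for fast PBM tests (full core6 set is kept: the
# design is the object under test)
fixture_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- build_probe_library(seed = 42)
    lib
  }
})

fixture_scores <- local({
  cache <- list()
  function(noise_cv = 0, seed = 1) {
    key <- paste(noise_cv, seed)
    if (is.null(cache[[key]])) {
      arr <- gen_pbm_intensities(fixture_library(), noise_cv = noise_cv,
                                 seed = seed)
      cache[[key]] <<- normalize_array(arr)
    }
    cache[[key]]
  }
})

# brute-force motif scan oracle: vectorized substring enumeration,
# independent of the Biostrings-backed implementation
oracle_scan_count <- function(seq, motif) {
  L <- nchar(seq)
  if (L < 6) return(0L)
  wins <- substring(seq, 1:(L - 5), 6:L)
  rc <- revcomp(motif)
  if (motif == rc) sum(wins == motif)
  else sum(wins == motif) + sum(wins == rc)
}

# brute-force containment: does region [s, e) fully contain a hit?
oracle_region_has_hit <- function(region, hits) {
  any(hits$chrom == region$chrom &
        hits$start >= region$start & hits$end <= region$end)
}

random_peaks <- function(n, seed, conditions = "highMYC", chrom = "chr1") {
  set.seed(seed)
  apex <- sort(sample(500:99500, n))
  data.frame(chrom = chrom, start = apex - 250L, end = apex + 250L,
             apex = apex, height = runif(n, 1, 50),
             pvalue = 10^-runif(n, 9, 40),
             condition = sample(conditions, n, replace = TRUE),
             id = sprintf("pk%04d", seq_len(n)), stringsAsFactors = FALSE)
}
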
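#' Default flank penalty table
#'
#' Multiplicative penalties applied to flank-category probes whose
#' substituted flank carries a disfavored base. The default penalizes an
#' A immediately 3' of the core (position n10 of the 12-mer,
#' `tgaCACGTGn10n11n12`): complexes bind poorly to CACGTGa-type
#' sequences.
#'
#' @return data frame (`side`, `offset` 1-3 within the flank trimer,
#'   `base`, `multiplier`).
#' @export
default_flank_penalty <- function() {
  data.frame(side = "right", offset = 1L, base = "A", multiplier = 0.3,
             stringsAsFactors = FALSE)
}

# Effective affinity of a 12-mer: best hexamer window on either strand
# (canonical lookup covers the reverse strand). Windows away from the
# core register (start position 4) are attenuated: sites shifted toward
# the linker/cap are less accessible on the array, so a probe carrying
# a shifted copy of a strong site scores below the in-register probe.
probe_affinity <- function(var12, affinity, offregister = 0.7) {
  starts <- 1:7
  win <- vapply(starts, function(s) substr(var12, s, s + 5L), character(length(var12)))
  if (is.null(dim(win))) win <- matrix(win, nrow = length(var12))
  a <- apply(win, 2, function(m) affinity_of(affinity, m))
  if (is.null(dim(a))) a <- matrix(a, nrow = length(var12))
  w <- ifelse(starts == 4L, 1, offregister)
  apply(sweep(a, 2, w, "*"), 1, max)
}

#' Simulate PBM fluorescence intensities
#'
#' Spot intensity is `background + scale * a* * exp(N(0, log(1 +
#' noise_cv)^2))` where `a*` is the probe's best hexamer-window affinity
#' (both strands), times a flank multiplier for flank-category probes
#' with disfavored substituted flanks. Three replicate spots per probe
#' and two dimer channels (MYCMAX, MAXMAX) are emitted.
#'
#' @param library a [build_probe_library()] result.
#' @param affinity an [affinity_table()].
#' @param flank_penalty penalty table as in [default_flank_penalty()],
#'   or `NULL` for none.
#' @param noise_cv coefficient of variation of the multiplicative spot
#'   noise (>= 0).
#' @param seed RNG seed.
#' @param background,scale intensity model constants (arbitrary
#'   fluorescence units).
#' @param dimers channel names.
#' @return array table data frame (`probe_id`, `category`, `dimer`,
#'   `rep`, `intensity`).
#' @export
gen_pbm_intensities <- function(library, affinity = default_affinity_table(),
                                flank_penalty = default_flank_penalty(),
                                noise_cv = 0.2, seed = 1,
                                background = 50, scale = 2000,
                                dimers = c("MYCMAX", "MAXMAX")) {
  stopifnot(is.data.frame(library), noise_cv >= 0)
  known <- c("core6", "flank_left", "flank_right", "cme_mut", "random")
  if (!all(library$category %in% known)) {
    abort_invalid("gen_pbm_intensities: unknown probe category in library")
  }
  a <- probe_affinity(library$var12, affinity)
  if (!is.null(flank_penalty) && nrow(flank_penalty)) {
    for (i in seq_len(nrow(flank_penalty))) {
      fp <- flank_penalty[i, ]
      cat_name <- paste0("flank_", fp$side)
      pos <- if (fp$side == "left") fp$offset else 9L + fp$offset
      hit <- library$category == cat_name &
        substr(library$var12, pos, pos) == fp$base
      a[hit] <- a[hit] * fp$multiplier
    }
  }
  n <- nrow(library)
  sdlog <- log(1 + noise_cv)
  grid <- expand.grid(rep = 1:3, dimer = dimers, stringsAsFactors = FALSE)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
      noise <- if (noise_cv > 0) exp(rnorm(n, 0, sdlog)) else rep(1, n)
      data.frame(probe_id = library$id, category = library$category,
                 dimer = grid$dimer[g], rep = grid$rep[g],
                 intensity = background + scale * a * noise,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- out[order(out$dimer, out$probe_id, out$rep), ]
  rownames(out) <- NULL
  out
}
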
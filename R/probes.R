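PBM_LINKER <- "CGTCGATATAGTAATCTTAGCTATTAA"
PBM_CAP <- "GCCGG"
CME_VAR12 <- "TGACACGTGGTA"
CME <- "CACGTG"
NE <- "AACGTT"

# Printed-form aliases for orientations the CA-prefix rule cannot decide:
# CATGTG (both orientations start CA), CGCGTT and CGGGGG (neither does).
CANONICAL_ALIASES <- c("CATGTG", "CGCGTT", "CGGGGG")

#' Canonical orientation of a hexamer
#'
#' Collapses a hexamer and its reverse complement onto one reporting
#' orientation: prefer the orientation whose first two bases are `CA`
#' (the E-box half-site convention, so e.g. AACGTG is reported as
#' CACGTT); when both or neither orientation starts with `CA`, an alias
#' table of conventional printed forms decides, falling back to the
#' lexicographic minimum. Palindromes are their own canonical form.
#'
#' @param hexamer character vector of 6-mers over ACGT.
#' @param aliases character vector of preferred printed forms used for
#'   otherwise ambiguous cases.
#' @return character vector of canonical hexamers.
#' @export
canonical_hexamer <- function(hexamer, aliases = CANONICAL_ALIASES) {
  if (!all(is_dna_string(hexamer, 6L))) {
    abort_invalid("canonical_hexamer: inputs must be 6-mers over ACGT")
  }
  rc <- revcomp(hexamer)
  fwd_ca <- startsWith(hexamer, "CA")
  rev_ca <- startsWith(rc, "CA")
  out <- ifelse(fwd_ca & !rev_ca, hexamer,
         ifelse(rev_ca & !fwd_ca, rc, NA_character_))
  amb <- is.na(out)
  if (any(amb)) {
    f <- hexamer[amb]; r <- rc[amb]
    pick <- ifelse(f %in% aliases, f,
            ifelse(r %in% aliases, r, pmin(f, r)))
    out[amb] <- pick
  }
  out
}

#' Classify a hexamer motif
#'
#' `E-box` if the motif matches CANNTG in either orientation; `GC-rich`
#' if at most one base is A or T and no E-box half site (CAC/CAT prefix
#' or GTG/ATG suffix in either orientation) is present; everything else
#' is `E-box-variant/non-E-box`.
#'
#' @param hexamer character vector of 6-mers.
#' @return character vector of class labels.
#' @export
classify_motif <- function(hexamer) {
  hexamer <- toupper(hexamer)
  rc <- revcomp(hexamer)
  is_ebox <- grepl("^CA..TG$", hexamer) | grepl("^CA..TG$", rc)
  at_count <- vapply(strsplit(hexamer, ""), function(b) sum(b %in% c("A", "T")),
                     integer(1))
  half <- function(x) {
    grepl("^(CAC|CAT)", x) | grepl("(GTG|ATG)$", x)
  }
  has_half <- half(hexamer) | half(rc)
  ifelse(is_ebox, "E-box",
         ifelse(at_count <= 1 & !has_half, "GC-rich",
                "E-box-variant/non-E-box"))
}

#' Build the custom PBM probe library
#'
#' Enumerates the probe categories of the custom array design: all 4096
#' core hexamer probes `tgaNNNNNNgta`, 64 + 64 flank probes with every
#' 3-mer substitution of the left (`nnnCACGTGgta`) or right
#' (`tgaCACGTGnnn`) flank of the canonical E-box core, `n_cme_mut`
#' distinct random mutants of the 12-mer `tgaCACGTGgta` at Hamming
#' distance 3-6, and `n_random` fully random 12-mers used as the
#' empirical null. Each probe's spotted sequence is
#' linker (27 nt) + variable 12-mer + cap (5 nt) = 44 nt.
#'
#' @param n_cme_mut number of CME-mutant probes (default 518).
#' @param n_random number of random null probes (default 100).
#' @param seed RNG seed controlling the mutant and random sets.
#' @return a `probe_library` data frame with columns `id`, `category`,
#'   `var12`, `core_hex`, `full_seq`.
#' @export
build_probe_library <- function(n_cme_mut = 518, n_random = 100, seed = 1) {
  stopifnot(n_cme_mut >= 0, n_random >= 0)
  hex <- all_hexamers()
  core <- data.frame(
    id = paste0("core6_", hex),
    category = "core6",
    var12 = paste0("TGA", hex, "GTA"),
    stringsAsFactors = FALSE
  )
  tri <- all_kmers(3)
  flank_l <- data.frame(
    id = paste0("flankL_", tri),
    category = "flank_left",
    var12 = paste0(tri, CME, "GTA"),
    stringsAsFactors = FALSE
  )
  flank_r <- data.frame(
    id = paste0("flankR_", tri),
    category = "flank_right",
    var12 = paste0("TGA", CME, tri),
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    mut <- character(0)
    ref <- strsplit(CME_VAR12, "")[[1]]
    # rejection-sample distinct 12-mers at Hamming distance 3-6 from the CME probe
    while (length(mut) < n_cme_mut) {
      need <- n_cme_mut - length(mut)
      cand <- vapply(seq_len(need * 2L), function(i) {
        k <- sample(3:6, 1)
        pos <- sample(12L, k)
        b <- ref
        for (p in pos) b[p] <- sample(setdiff(DNA_BASES, b[p]), 1)
        paste(b, collapse = "")
      }, character(1))
      mut <- unique(c(mut, cand))
    }
    mut <- mut[seq_len(n_cme_mut)]
    rnd <- vapply(seq_len(n_random), function(i) {
      paste(sample(DNA_BASES, 12, replace = TRUE), collapse = "")
    }, character(1))
  })
  cme_mut <- if (n_cme_mut > 0) data.frame(
    id = sprintf("cmeMut_%03d", seq_len(n_cme_mut)),
    category = "cme_mut", var12 = mut, stringsAsFactors = FALSE
  ) else NULL
  random <- if (n_random > 0) data.frame(
    id = sprintf("random_%03d", seq_len(n_random)),
    category = "random", var12 = rnd, stringsAsFactors = FALSE
  ) else NULL
  lib <- rbind(core, flank_l, flank_r, cme_mut, random)
  lib$core_hex <- substr(lib$var12, 4, 9)
  lib$full_seq <- paste0(PBM_LINKER, lib$var12, PBM_CAP)
  rownames(lib) <- NULL
  class(lib) <- c("probe_library", "data.frame")
  lib
}

#' Core-register motif of a probe
#'
#' All designed probes share the core register: positions 4-9 of the
#' variable 12-mer hold the hexamer under test. The extracted hexamer is
#' reported in canonical orientation, so a probe and the probe carrying
#' the reverse-complemented 12-mer map to the same motif.
#'
#' @param var12 character vector of 12-mer variable regions (or a
#'   `probe_library`, from which `var12` is taken).
#' @return character vector of canonical hexamers.
#' @export
motif_of_probe <- function(var12) {
  if (is.data.frame(var12)) var12 <- var12$var12
  if (!all(is_dna_string(var12, 12L))) {
    abort_invalid("motif_of_probe: var12 must be 12-mers over ACGT")
  }
  canonical_hexamer(substr(var12, 4, 9))
}
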
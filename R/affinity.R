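#' Relative-affinity lookup table for hexamer motifs
#'
#' An affinity table maps canonical-orientation hexamers to dimensionless
#' relative binding affinities, with a floor value for every unlisted
#' hexamer. The default mirrors the tiered picture of MYC/MAX binding:
#' the canonical E-box CACGTG at the top, close E-box variants in a
#' medium tier, the non-E-box palindrome AACGTT and similarly weak
#' hexamers in a low tier (defined as 1), and a non-specific floor.
#'
#' @param entries named numeric vector, names are hexamers (any
#'   orientation; canonicalized on construction), values are relative
#'   affinities > 0.
#' @param default_affinity affinity for hexamers absent from `entries`;
#'   must not exceed the smallest listed affinity.
#' @param tiers optional named character vector of tier labels
#'   (`high`/`medium`/`low`/`none`) parallel to `entries`.
#' @return an object of class `affinity_table`.
#' @export
affinity_table <- function(entries, default_affinity = 0.05, tiers = NULL) {
  stopifnot(is.numeric(entries), length(entries) > 0,
            !is.null(names(entries)), all(entries > 0),
            default_affinity > 0)
  nm <- canonical_hexamer(toupper(names(entries)))
  if (anyDuplicated(nm)) {
    abort_invalid("affinity_table: duplicate hexamers after canonicalization")
  }
  names(entries) <- nm
  if (default_affinity > min(entries)) {
    abort_invalid("affinity_table: default_affinity must be <= smallest listed affinity")
  }
  if (!is.null(tiers)) {
    stopifnot(length(tiers) == length(entries),
              all(tiers %in% c("high", "medium", "low", "none")))
    names(tiers) <- nm
  }
  structure(list(entries = entries, default_affinity = default_affinity,
                 tiers = tiers),
            class = "affinity_table")
}

#' Default tiered affinity table
#'
#' Relative to the low tier (AACGTT = 1): CACGTG = 25, the five medium
#' E-box variants (CACGCG, CATGTG, CACGTT, CATGCG, CACGAG) = 5, the low
#' tier (AACGTT, CATATG, CGCGTT) = 1, everything else 0.05.
#'
#' @return an `affinity_table`.
#' @export
default_affinity_table <- function() {
  entries <- c(
    CACGTG = 25,
    CACGCG = 5, CATGTG = 5, CACGTT = 5, CATGCG = 5, CACGAG = 5,
    AACGTT = 1, CATATG = 1, CGCGTT = 1
  )
  tiers <- c("high", rep("medium", 5), rep("low", 3))
  affinity_table(entries, default_affinity = 0.05, tiers = tiers)
}

#' Look up relative affinity of hexamers
#'
#' @param table an `affinity_table`.
#' @param hexamer character vector of hexamers (any orientation).
#' @return numeric vector of affinities.
#' @export
affinity_of <- function(table, hexamer) {
  stopifnot(inherits(table, "affinity_table"))
  key <- canonical_hexamer(toupper(hexamer))
  out <- unname(table$entries[key])
  out[is.na(out)] <- table$default_affinity
  out
}

#' Tier label of hexamers in an affinity table
#' @inheritParams affinity_of
#' @return character vector (`high`/`medium`/`low`/`none`).
#' @export
tier_of <- function(table, hexamer) {
  stopifnot(inherits(table, "affinity_table"))
  if (is.null(table$tiers)) return(rep("none", length(hexamer)))
  key <- canonical_hexamer(toupper(hexamer))
  out <- unname(table$tiers[key])
  out[is.na(out)] <- "none"
  out
}

#' @export
print.affinity_table <- function(x, ...) {
  cat("Affinity table:", length(x$entries), "listed hexamers, floor",
      x$default_affinity, "\n")
  df <- data.frame(hexamer = names(x$entries), affinity = unname(x$entries),
                   tier = if (is.null(x$tiers)) NA_character_ else unname(x$tiers))
  print(df[order(-df$affinity), ], row.names = FALSE)
  invisible(x)
}
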
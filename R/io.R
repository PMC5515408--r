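#' Write a genome as FASTA
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param path output file; sequences wrapped at 60 columns.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(as_genome_character(genome))
  }
  Biostrings::writeXStringSet(genome, path, width = 60)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write intervals as BED6
#'
#' Coordinates are written as stored: 0-based half-open, the BED
#' convention.
#'
#' @param df data frame with `chrom`, `start`, `end`; optional `name`
#'   (or `id`/`gene_id`/`peak_id`), `score`, `strand`.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  name <- df$name %||% df$id %||% df$gene_id %||% df$peak_id %||%
    sprintf("feature%04d", seq_len(nrow(df)))
  bed <- data.frame(df$chrom, df$start, df$end, name,
                    df$score %||% 0, df$strand %||% ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (3-6 columns)
#'
#' @param path BED file.
#' @return data frame (`chrom`, `start`, `end`, and `name`, `score`,
#'   `strand` when present).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6))]
  if (any(df$start < 0) || any(df$end <= df$start)) {
    abort_invalid(paste0("read_bed: invalid interval in ", path))
  }
  df
}

#' Write / read a peak table
#'
#' Eight-column TSV: chrom, start, end, apex, height, pvalue,
#' condition, id (0-based half-open).
#'
#' @param peaks peak data frame.
#' @param path file path.
#' @export
write_peaks <- function(peaks, path) {
  cols <- c("chrom", "start", "end", "apex", "height", "pvalue",
            "condition", "id")
  stopifnot(all(cols %in% names(peaks)))
  write.table(peaks[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "apex", "height", "pvalue",
            "condition", "id")
  if (!all(need %in% names(df))) {
    abort_invalid(paste0("read_peaks: missing columns in ", path))
  }
  bad <- which(df$start > df$apex | df$apex >= df$end | df$height <= 0 |
                 df$pvalue <= 0 | df$pvalue > 1)
  if (length(bad)) {
    abort_invalid(paste0("read_peaks: invalid peak record at line ",
                         bad[1] + 1L))
  }
  df
}

#' Generic TSV helpers used for all tabular artifacts
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a supplementary PBM score table
#'
#' Reads a published probe/score table (TSV, or XLSX when the `readxl`
#' package is installed) into a long score table with one row per probe
#' per dimer. Column names are matched case-insensitively via
#' `column_map`, tolerant of header renames.
#'
#' @param path TSV or XLSX file.
#' @param column_map named list mapping internal names (`probe`,
#'   `mycmax`, `maxmax`, optional `category`) to regular expressions
#'   matched against the file's headers.
#' @return score table (`probe_id`, `category`, `dimer`, `score`) with
#'   `var12` attached as an attribute when probe sequences are present.
#' @export
read_s1_scores <- function(path,
                           column_map = list(probe = "probe|sequence|seq",
                                             mycmax = "myc", maxmax = "max.?max",
                                             category = "categ|type")) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort_invalid("read_s1_scores: reading XLSX requires the readxl package")
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  find_col <- function(re, required = TRUE) {
    i <- grep(re, names(df), ignore.case = TRUE)
    if (length(i) == 0) {
      if (required) abort_invalid(paste0("read_s1_scores: no column matching '", re, "'"))
      return(NA_integer_)
    }
    i[1]
  }
  pc <- find_col(column_map$probe)
  # MAX:MAX column may also match the MYC regex ("max" vs "myc"): resolve
  # MYC first, then exclude it from the MAX:MAX search.
  mycc <- grep(column_map$mycmax, names(df), ignore.case = TRUE)
  maxc <- setdiff(grep(column_map$maxmax, names(df), ignore.case = TRUE), mycc)
  if (length(mycc) == 0 || length(maxc) == 0) {
    abort_invalid("read_s1_scores: could not locate both dimer score columns")
  }
  catc <- find_col(column_map$category, required = FALSE)
  probe <- as.character(df[[pc]])
  seq_like <- is_dna_string(toupper(probe), 12L)
  probe_id <- if (all(seq_like)) paste0("probe_", toupper(probe)) else probe
  category <- if (!is.na(catc)) as.character(df[[catc]]) else
    rep("core6", length(probe))
  long <- rbind(
    data.frame(probe_id = probe_id, category = category, dimer = "MYCMAX",
               score = as.numeric(df[[mycc[1]]]), stringsAsFactors = FALSE),
    data.frame(probe_id = probe_id, category = category, dimer = "MAXMAX",
               score = as.numeric(df[[maxc[1]]]), stringsAsFactors = FALSE)
  )
  if (all(seq_like)) attr(long, "var12") <- setNames(toupper(probe), probe_id)
  long
}
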
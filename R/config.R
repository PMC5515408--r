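#' Analysis configuration
#'
#' Houses the pipeline's tunable constants: the stringent and permissive
#' empirical-null quantiles (0.95 / 0.80), summit radius (100 bp) and
#' extension radius (250 bp), promoter half-window (2 kb), the
#' top-fraction cut for most-significant peaks (33% by p-value), the
#' peak-caller p-value cutoff (1e-08), and the PWM pseudocount (0.25).
#'
#' @param q_high stringent null quantile.
#' @param q_low permissive null quantile; must be < `q_high`.
#' @param summit_radius summit half-width (bp).
#' @param extension_radius extra flank for extended summits (bp).
#' @param promoter_window promoter half-window around the TSS (bp).
#' @param top_fraction fraction of most significant peaks.
#' @param peak_pvalue_cutoff peak significance cutoff in (0, 1].
#' @param pwm_pseudocount per-base PWM pseudocount.
#' @param seed master RNG seed.
#' @param paths named list of input/output paths (real mode needs
#'   `genome`, `peaks_high`, `peaks_low`, `genes`).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(q_high = 0.95, q_low = 0.80, summit_radius = 100,
                            extension_radius = 250, promoter_window = 2000,
                            top_fraction = 0.33, peak_pvalue_cutoff = 1e-08,
                            pwm_pseudocount = 0.25, seed = 1, paths = list()) {
  if (!(q_low > 0 && q_low < q_high && q_high < 1)) {
    abort_invalid("analysis_config: need 0 < q_low < q_high < 1")
  }
  if (summit_radius <= 0 || extension_radius <= 0 || promoter_window <= 0) {
    abort_invalid("analysis_config: radii and windows must be positive")
  }
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    abort_invalid("analysis_config: top_fraction must be in (0, 1]")
  }
  if (!(peak_pvalue_cutoff > 0 && peak_pvalue_cutoff <= 1)) {
    abort_invalid("analysis_config: peak_pvalue_cutoff must be in (0, 1]")
  }
  structure(list(q_high = q_high, q_low = q_low, summit_radius = summit_radius,
                 extension_radius = extension_radius,
                 promoter_window = promoter_window,
                 top_fraction = top_fraction,
                 peak_pvalue_cutoff = peak_pvalue_cutoff,
                 pwm_pseudocount = pwm_pseudocount, seed = seed,
                 paths = paths),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys fall back to defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else abort_invalid("read_config: expected a .yaml/.yml or .json file")
  known <- names(formals(analysis_config))
  bad <- setdiff(names(lst), known)
  if (length(bad)) {
    abort_invalid(paste0("read_config: unknown key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(analysis_config, lst)
}

#' Write an analysis configuration
#'
#' @param config an `analysis_config`.
#' @param path output `.yaml` or `.json` file.
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  # stable content hash for the run log (no file needed)
  lst <- unclass(config)
  json <- jsonlite::toJSON(lst[order(names(lst))], auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(json) * seq_len(nchar(json))) %% 2147483647L
}
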
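#' Dose-dependent synthetic peak model
#'
#' Encodes a mass-action occupancy model: a planted site with
#' dissociation scale `Kd = 1 / affinity` is occupied with probability
#' `theta = c / (c + Kd)` at protein dose `c`. A site emits a peak when
#' `theta * exp(N(0, sigma_h^2))` exceeds the detection threshold, so
#' low-affinity sites appear only at high doses — the qualitative
#' behaviour of low-affinity non-E-box loci under protein
#' overexpression.
#'
#' @param concentration named numeric vector of protein doses, one per
#'   condition (e.g. `c(lowMYC = 0.05, highMYC = 0.5)`), in the same
#'   arbitrary units as the site Kd (`1 / relative affinity`).
#' @param theta_det detection threshold in (0, 1).
#' @param h0 height scale (fold-enrichment units).
#' @param sigma_h lognormal noise sd on occupancy/height (log scale).
#' @param apex_jitter peak apex jitter, uniform on `[-apex_jitter,
#'   apex_jitter]` bp around the planted site midpoint.
#' @param width_mean,width_sd peak width distribution (bp).
#' @param seed RNG seed.
#' @return object of class `peak_model`.
#' @export
peak_model <- function(concentration = c(lowMYC = 0.05, highMYC = 0.5),
                       theta_det = 0.3, h0 = 20, sigma_h = 0.25,
                       apex_jitter = 20, width_mean = 500, width_sd = 100,
                       seed = 1) {
  stopifnot(all(concentration > 0), !is.null(names(concentration)),
            theta_det > 0, theta_det < 1, h0 > 0, sigma_h >= 0,
            apex_jitter >= 0, width_mean > 6)
  structure(list(concentration = concentration, theta_det = theta_det,
                 h0 = h0, sigma_h = sigma_h, apex_jitter = apex_jitter,
                 width_mean = width_mean, width_sd = width_sd, seed = seed),
            class = "peak_model")
}

#' Site occupancy under the mass-action model
#'
#' @param c protein dose.
#' @param kd site dissociation scale.
#' @return occupancy `c / (c + kd)` in (0, 1).
#' @export
occupancy <- function(c, kd) c / (c + kd)

#' Emit synthetic peak calls from planted sites
#'
#' Each truth-table site is tested for detection at the condition's
#' dose; detected sites yield one peak with apex near the site midpoint,
#' height `h0 * theta * lognoise` and a p-value surrogate that decreases
#' monotonically in height (`10^-height`).
#'
#' @param truth truth table from [plant_sites()].
#' @param model a [peak_model()].
#' @param condition condition name; must match a concentration entry.
#' @param chrom_sizes optional named lengths used to clamp peak bounds.
#' @return peak data frame (`chrom`, `start`, `end`, `apex`, `height`,
#'   `pvalue`, `condition`, `id`) in 0-based half-open coordinates.
#' @export
gen_peaks <- function(truth, model, condition, chrom_sizes = NULL) {
  stopifnot(inherits(model, "peak_model"))
  if (!condition %in% names(model$concentration)) {
    abort_invalid(paste0("gen_peaks: no concentration set for condition '",
                         condition, "'"))
  }
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      apex = integer(0), height = numeric(0), pvalue = numeric(0),
                      condition = character(0), id = character(0))
  if (is.null(truth) || nrow(truth) == 0) return(empty)
  conc <- model$concentration[[condition]]
  theta <- occupancy(conc, truth$kd)
  # per-condition stream so conditions are independently reproducible
  seed_c <- model$seed + match(condition, names(model$concentration))
  with_seed(seed_c, {
    noise <- exp(rnorm(nrow(truth), 0, model$sigma_h))
    jit <- if (model$apex_jitter > 0) {
      as.integer(round(runif(nrow(truth), -model$apex_jitter, model$apex_jitter)))
    } else rep(0L, nrow(truth))
    widths <- pmax(50L, as.integer(round(rnorm(nrow(truth), model$width_mean,
                                               model$width_sd))))
  })
  emit <- theta * noise > model$theta_det
  if (!any(emit)) return(empty)
  mid <- truth$start + 3L
  apex <- mid[emit] + jit[emit]
  half <- widths[emit] %/% 2L
  start <- apex - half
  end <- apex + half
  chrom <- truth$chrom[emit]
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[chrom]
    start <- pmax(0L, start)
    end <- pmin(as.integer(lim), end)
    apex <- pmax(start, pmin(apex, end - 1L))
  } else {
    start <- pmax(0L, start)
    apex <- pmax(start, apex)
  }
  height <- model$h0 * theta[emit] * noise[emit]
  peaks <- data.frame(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    apex = as.integer(apex), height = height,
    pvalue = 10^(-height),          # monotone decreasing in height
    condition = condition,
    id = sprintf("%s_peak%04d", condition, seq_along(apex)),
    stringsAsFactors = FALSE
  )
  rownames(peaks) <- NULL
  peaks
}
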
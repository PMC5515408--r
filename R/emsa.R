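#' Competition EMSA assay description
#'
#' Amounts are in pmol and the reaction volume in microlitres, so
#' concentrations (pmol/ul = uM) follow directly; `K_L` and `K_C` are in
#' uM. The model uses full mass balance (no trace-probe approximation):
#' at 0.5 pmol labeled probe and pmol-scale protein in 10 ul, ligand
#' depletion is not negligible.
#'
#' @param P_tot protein amount (pmol).
#' @param K_L labeled-probe dissociation constant (uM).
#' @param V reaction volume (ul, default 10).
#' @param L_tot labeled probe amount (pmol, default 0.5).
#' @param C_tot vector of competitor amounts (pmol), including 0.
#' @return object of class `competition_assay`.
#' @export
competition_assay <- function(P_tot, K_L, V = 10, L_tot = 0.5,
                              C_tot = c(0, 0.25, 0.4, 0.6, 1, 1.5, 2.5, 4, 6,
                                        10, 16, 25, 40, 65, 100, 160, 250,
                                        400, 600)) {
  stopifnot(V > 0, L_tot > 0, P_tot > 0, K_L > 0, length(C_tot) >= 1)
  if (any(C_tot < 0)) abort_invalid("competition_assay: negative competitor amounts")
  if (!any(C_tot == 0)) abort_invalid("competition_assay: amounts must include a zero-competitor point")
  structure(list(V = V, L_tot = L_tot, P_tot = P_tot, K_L = K_L,
                 C_tot = sort(unique(C_tot))),
            class = "competition_assay")
}

# Free-protein concentration solving the two-ligand mass balance
#   p + p*L/(K_L+p) + p*C/(K_C+p) = P_tot   (all concentrations)
# The left side is strictly increasing in p, so the root is bracketed in
# [0, P_tot] and found by uniroot at ~1e-12 relative tolerance.
free_protein <- function(Pc, Lc, Cc, K_L, K_C) {
  f <- function(p) p + p * Lc / (K_L + p) + p * Cc / (K_C + p) - Pc
  if (f(Pc) < 0) return(Pc)   # numerically saturated
  r <- uniroot(f, c(0, Pc), tol = max(Pc * 1e-13, .Machine$double.xmin))
  r$root
}

#' Predict the competition-EMSA readout
#'
#' Solves the two-ligand equilibrium (labeled probe with constant
#' `K_L`, competitor with constant `K_C`) for each competitor amount and
#' returns the bound labeled probe as a percentage of the
#' zero-competitor point.
#'
#' @param assay a [competition_assay()].
#' @param C_tot competitor amounts (pmol); defaults to the assay's.
#' @param K_C competitor dissociation constant (uM); `Inf` for a
#'   non-binding competitor.
#' @return numeric vector of bound percentages (100 at `C_tot = 0`).
#' @export
predict_fraction_bound <- function(assay, C_tot = assay$C_tot, K_C) {
  stopifnot(inherits(assay, "competition_assay"), K_C > 0)
  if (any(C_tot < 0)) abort_invalid("predict_fraction_bound: negative amounts")
  Pc <- assay$P_tot / assay$V
  Lc <- assay$L_tot / assay$V
  bound <- function(Cc) {
    if (is.infinite(K_C)) {
      p <- free_protein(Pc, Lc, 0, assay$K_L, 1)  # competitor inert
    } else {
      p <- free_protein(Pc, Lc, Cc, assay$K_L, K_C)
    }
    p * Lc / (assay$K_L + p)
  }
  b0 <- bound(0)
  vapply(C_tot / assay$V, function(Cc) 100 * bound(Cc) / b0, numeric(1))
}

#' Simulate replicated competition curves
#'
#' Noiseless means come from [predict_fraction_bound()]; replicate noise
#' is additive Gaussian on the percentage scale, truncated to [0, 100].
#'
#' @param assay a [competition_assay()].
#' @param true_KL labeled-probe dissociation constant (uM) to simulate.
#' @param true_KC named vector of competitor dissociation constants
#'   (uM); `Inf` simulates a non-binding control.
#' @param noise_sd replicate noise sd (percentage points).
#' @param n_rep replicates per point.
#' @param seed RNG seed.
#' @return curve data frame (`competitor`, `amount_pmol`, `rep`,
#'   `bound_pct`).
#' @export
gen_competition_curves <- function(assay, true_KL, true_KC, noise_sd = 5,
                                   n_rep = 3, seed = 1) {
  stopifnot(inherits(assay, "competition_assay"), true_KL > 0,
            all(true_KC > 0), !is.null(names(true_KC)), noise_sd >= 0,
            n_rep >= 1)
  sim_assay <- assay
  sim_assay$K_L <- true_KL
  out <- do.call(rbind, lapply(names(true_KC), function(comp) {
    mu <- predict_fraction_bound(sim_assay, sim_assay$C_tot, true_KC[[comp]])
    expand.grid(rep = seq_len(n_rep), amount_pmol = sim_assay$C_tot,
                KEEP.OUT.ATTRS = FALSE)[, 2:1] |>
      transform(competitor = comp, mu = rep(mu, each = n_rep))
  }))
  with_seed(seed, {
    noise <- if (noise_sd > 0) rnorm(nrow(out), 0, noise_sd) else 0
  })
  out$bound_pct <- pmin(100, pmax(0, out$mu + noise))
  out <- out[, c("competitor", "amount_pmol", "rep", "bound_pct")]
  rownames(out) <- NULL
  out
}

# sum-of-squares of a candidate K_C (and optionally K_L) against a curve
curve_ss <- function(assay, amounts, bound, K_C, K_L = assay$K_L) {
  a <- assay
  a$K_L <- K_L
  pred <- predict_fraction_bound(a, amounts, K_C)
  sum((bound - pred)^2)
}

#' Fit relative affinities from competition curves
#'
#' Per-competitor least squares of the equilibrium model on the bound%
#' readout. `K_L` is either supplied through the assay or anchored by
#' jointly fitting the self-competition curve (`kl_anchor`), where the
#' competitor is the labeled probe's own sequence so `K_C = K_L`.
#' Competitors whose fit is no better than the flat 100% line, or whose
#' fitted `K_C` exceeds `nonbinding_factor` times the reference `K_C`,
#' are reported as non-binding.
#'
#' @param curves curve data frame as from [gen_competition_curves()].
#' @param assay a [competition_assay()] template.
#' @param reference competitor label whose affinity is defined as 1.
#' @param kl_anchor optional competitor label of the self-competition
#'   curve used to fit `K_L`.
#' @param nonbinding_factor non-binding cutoff on `K_C / K_C(reference)`
#'   (default 1000).
#' @param log10_bounds search bounds for `log10(K_C)` in uM.
#' @return data frame (`competitor`, `K_C`, `se_log10K`, `rel_affinity`,
#'   `nonbinding`), plus attribute `K_L`.
#' @export
fit_relative_affinity <- function(curves, assay, reference,
                                  kl_anchor = NULL, nonbinding_factor = 1000,
                                  log10_bounds = c(-7, 7)) {
  stopifnot(inherits(assay, "competition_assay"))
  comps <- unique(curves$competitor)
  if (!reference %in% comps) {
    abort_invalid("fit_relative_affinity: reference competitor has no curve")
  }
  split_curves <- split(curves, curves$competitor)
  for (cc in split_curves) {
    if (length(unique(cc$amount_pmol)) < 3) {
      abort_invalid("fit_relative_affinity: need >= 3 competitor amounts per curve")
    }
  }
  fit_one <- function(amounts, bound, K_L = NULL) {
    obj <- function(lk) {
      k <- 10^lk
      if (is.null(K_L)) curve_ss(assay, amounts, bound, k, K_L = k)
      else curve_ss(assay, amounts, bound, k, K_L = K_L)
    }
    o <- optimize(obj, log10_bounds, tol = 1e-10)
    # curvature-based standard error of log10 K
    h <- 1e-4
    d2 <- (obj(o$minimum + h) - 2 * o$objective + obj(o$minimum - h)) / h^2
    npt <- length(bound)
    sigma2 <- o$objective / max(1, npt - 1)
    se <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
    list(lk = o$minimum, ss = o$objective, se = se)
  }
  K_L <- assay$K_L
  if (!is.null(kl_anchor)) {
    if (!kl_anchor %in% comps) {
      abort_invalid("fit_relative_affinity: kl_anchor competitor has no curve")
    }
    anchor <- split_curves[[kl_anchor]]
    K_L <- 10^fit_one(anchor$amount_pmol, anchor$bound_pct, K_L = NULL)$lk
  }
  # stage 1: per-competitor fits at the (anchored or supplied) K_L
  stage1 <- vapply(comps, function(comp) {
    cc <- split_curves[[comp]]
    if (!is.null(kl_anchor) && comp == kl_anchor) return(log10(K_L))
    fit_one(cc$amount_pmol, cc$bound_pct, K_L = K_L)$lk
  }, numeric(1))
  # stage 2 (anchored only): joint least squares across all curves with
  # the anchor's K_C tied to K_L — the efficient use of the
  # self-competition information
  if (!is.null(kl_anchor)) {
    total_ss <- function(lks) {
      kl <- 10^lks[[kl_anchor]]
      sum(vapply(comps, function(comp) {
        cc <- split_curves[[comp]]
        curve_ss(assay, cc$amount_pmol, cc$bound_pct, 10^lks[[comp]], K_L = kl)
      }, numeric(1)))
    }
    o <- stats::optim(stage1, function(p) total_ss(setNames(p, comps)),
                      method = "L-BFGS-B",
                      lower = rep(log10_bounds[1], length(comps)),
                      upper = rep(log10_bounds[2], length(comps)),
                      control = list(factr = 1e4))
    stage1 <- setNames(o$par, comps)
    K_L <- 10^stage1[[kl_anchor]]
  }
  res <- lapply(comps, function(comp) {
    cc <- split_curves[[comp]]
    lk <- stage1[[comp]]
    ss <- curve_ss(assay, cc$amount_pmol, cc$bound_pct, 10^lk, K_L = K_L)
    # curvature-based standard error of log10 K at the joint optimum
    obj <- function(l) curve_ss(assay, cc$amount_pmol, cc$bound_pct, 10^l, K_L = K_L)
    h <- 1e-4
    d2 <- (obj(lk + h) - 2 * ss + obj(lk - h)) / h^2
    sigma2 <- ss / max(1, length(cc$bound_pct) - 1)
    se <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
    ss_flat <- sum((cc$bound_pct - 100)^2)
    data.frame(competitor = comp, K_C = 10^lk, se_log10K = se,
               ss_fit = ss, ss_flat = ss_flat, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  k_ref <- res$K_C[res$competitor == reference]
  res$rel_affinity <- k_ref / res$K_C
  res$nonbinding <- res$K_C > nonbinding_factor * k_ref |
    res$ss_fit >= res$ss_flat * (1 - 1e-9)
  res$rel_affinity[res$nonbinding] <- NA_real_
  res <- res[, c("competitor", "K_C", "se_log10K", "rel_affinity", "nonbinding")]
  attr(res, "K_L") <- K_L
  res
}

#' Summarize fitted relative affinities as a tier table
#'
#' @param fits result of [fit_relative_affinity()] (one dimer), or a
#'   named list of such results (one per dimer).
#' @param motifs optional motif universe; motifs without a curve get an
#'   `n.a.` row.
#' @param pbm_scores optional named vector of PBM-derived relative
#'   scores shown as a companion column.
#' @param cutoffs class cutoffs on relative affinity: High > `high`,
#'   Medium in (`medium`, `high`], Low in [`low`, `medium`].
#' @return data frame (`motif`, `dimer`, `rel_affinity`, `pbm_score`,
#'   `class`) where `class` is High/Medium/Low/`-` (non-binding) or
#'   `n.a.` (not assayed).
#' @export
summarize_affinity_table <- function(fits, motifs = NULL, pbm_scores = NULL,
                                     cutoffs = c(high = 10, medium = 2, low = 0.5)) {
  if (is.data.frame(fits)) fits <- list(dimer = fits)
  out <- do.call(rbind, lapply(names(fits), function(dm) {
    f <- fits[[dm]]
    all_m <- unique(c(motifs, f$competitor))
    idx <- match(all_m, f$competitor)
    rel <- f$rel_affinity[idx]
    nb <- f$nonbinding[idx]
    cls <- ifelse(is.na(idx), "n.a.",
           ifelse(nb, "-",
           ifelse(rel > cutoffs[["high"]], "High",
           ifelse(rel > cutoffs[["medium"]], "Medium",
           ifelse(rel >= cutoffs[["low"]], "Low", "-")))))
    data.frame(motif = all_m, dimer = dm, rel_affinity = rel,
               pbm_score = if (is.null(pbm_scores)) NA_real_
                           else unname(pbm_scores[all_m]),
               class = cls, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
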
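# brute-force oracle: grid search over free protein minimizing the
# mass-balance residual, independent of the root-finder
oracle_fraction_bound <- function(assay, C_tot, K_C) {
  Pc <- assay$P_tot / assay$V
  Lc <- assay$L_tot / assay$V
  bound_at <- function(Cc) {
    grid <- seq(0, Pc, length.out = 200001)
    resid <- abs(grid + grid * Lc / (assay$K_L + grid) +
                   grid * Cc / (K_C + grid) - Pc)
    p <- grid[which.min(resid)]
    p * Lc / (assay$K_L + p)
  }
  100 * bound_at(C_tot / assay$V) / bound_at(0)
}

test_that("predict_fraction_bound anchors, saturates and dose-responds", {
  a <- competition_assay(P_tot = 0.3, K_L = 0.04)
  expect_equal(predict_fraction_bound(a, 0, K_C = 1), 100)
  # non-binding competitor: flat at 100%
  expect_equal(predict_fraction_bound(a, c(0, 10, 600), K_C = Inf),
               rep(100, 3))
  # strictly decreasing in C for finite K_C
  b <- predict_fraction_bound(a, a$C_tot, K_C = 0.5)
  expect_true(all(diff(b) < 0))
  expect_error(predict_fraction_bound(a, -1, K_C = 1), "negative")
})

test_that("equilibrium solution matches the grid-search oracle", {
  a <- competition_assay(P_tot = 0.7, K_L = 0.09, L_tot = 0.5, V = 10,
                         C_tot = c(0, 2, 20))
  for (kc in c(0.02, 0.4, 3)) {
    got <- predict_fraction_bound(a, c(2, 20), K_C = kc)
    want <- c(oracle_fraction_bound(a, 2, kc), oracle_fraction_bound(a, 20, kc))
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("bound% is invariant to rescaling volume and amounts together", {
  a1 <- competition_assay(P_tot = 0.3, K_L = 0.04, V = 10, L_tot = 0.5,
                          C_tot = c(0, 5, 50))
  a2 <- competition_assay(P_tot = 3, K_L = 0.04, V = 100, L_tot = 5,
                          C_tot = c(0, 50, 500))
  expect_equal(predict_fraction_bound(a1, c(0, 5, 50), K_C = 0.3),
               predict_fraction_bound(a2, c(0, 50, 500), K_C = 0.3))
})

test_that("generator and forward model agree pointwise without noise", {
  a <- competition_assay(P_tot = 0.3, K_L = 0.04)
  cur <- gen_competition_curves(a, true_KL = 0.04,
                                true_KC = c(NE = 0.8, Ctrl = Inf),
                                noise_sd = 0, n_rep = 2, seed = 1)
  ne <- cur[cur$competitor == "NE" & cur$rep == 1, ]
  expect_equal(ne$bound_pct,
               predict_fraction_bound(a, ne$amount_pmol, K_C = 0.8),
               tolerance = 1e-9)
  ctrl <- cur[cur$competitor == "Ctrl", ]
  expect_true(all(ctrl$bound_pct == 100))
  expect_equal(cur, gen_competition_curves(a, 0.04, c(NE = 0.8, Ctrl = Inf),
                                           0, 2, 1))
  expect_error(
    gen_competition_curves(competition_assay(0.3, 0.04, C_tot = c(0, -1)),
                           0.04, c(NE = 1), 0, 1, 1), "negative")
})

test_that("noiseless fits recover the planted constants almost exactly", {
  a <- competition_assay(P_tot = 0.3, K_L = 0.04)
  cur <- gen_competition_curves(a, 0.04,
                                c(CME = 0.04, V1 = 0.2, NE = 0.8, Ctrl = Inf),
                                noise_sd = 0, n_rep = 1, seed = 1)
  f <- fit_relative_affinity(cur, a, reference = "NE", kl_anchor = "CME")
  expect_equal(f$K_C[f$competitor == "CME"], 0.04, tolerance = 1e-6)
  expect_equal(f$K_C[f$competitor == "NE"], 0.8, tolerance = 1e-6)
  expect_equal(f$rel_affinity[f$competitor == "CME"], 20, tolerance = 1e-5)
  expect_equal(f$rel_affinity[f$competitor == "V1"], 4, tolerance = 1e-5)
  expect_true(f$nonbinding[f$competitor == "Ctrl"])
  expect_false(any(f$nonbinding[f$competitor != "Ctrl"]))
  expect_equal(attr(f, "K_L"), 0.04, tolerance = 1e-6)
})

test_that("label symmetry: identical competitors get identical fits", {
  a <- competition_assay(P_tot = 0.3, K_L = 0.04)
  cur <- gen_competition_curves(a, 0.04, c(X = 0.3, NE = 0.8), 0, 1, 1)
  twin <- cur[cur$competitor == "X", ]
  twin$competitor <- "Y"
  f <- fit_relative_affinity(rbind(cur, twin), a, reference = "NE")
  expect_equal(f$K_C[f$competitor == "X"], f$K_C[f$competitor == "Y"])
})

test_that("K-ratio recovery at 5% noise (reduced seed sweep)", {
  a <- competition_assay(P_tot = 0.3, K_L = 0.04)
  for (r in c(5, 33)) {
    ok <- sum(vapply(1:15, function(s) {
      cur <- gen_competition_curves(a, 0.04, c(CME = 0.04, NE = 0.04 * r),
                                    noise_sd = 5, n_rep = 3, seed = s)
      f <- fit_relative_affinity(cur, a, reference = "NE", kl_anchor = "CME")
      abs(f$rel_affinity[f$competitor == "CME"] / r - 1) < 0.15
    }, logical(1)))
    expect_gte(ok, 12)   # full 100-seed study: test-acceptance.R
  }
})

test_that("affinity summary reproduces planted tiers and conventions", {
  a <- competition_assay(P_tot = 0.3, K_L = 0.04)
  cur <- gen_competition_curves(a, 0.04,
                                c(CME = 0.04, CACGTT = 0.2, NE = 1,
                                  Ctrl = Inf),
                                noise_sd = 0, n_rep = 1, seed = 1)
  f <- fit_relative_affinity(cur, a, reference = "NE", kl_anchor = "CME")
  tab <- summarize_affinity_table(list(MAXMAX = f),
                                  motifs = c("CME", "CACGTT", "NE", "Ctrl",
                                             "CATGTG"))
  expect_equal(tab$rel_affinity[tab$motif == "NE"], 1, tolerance = 1e-6)
  expect_equal(tab$class[tab$motif == "CME"], "High")      # 25 > 10
  expect_equal(tab$class[tab$motif == "CACGTT"], "Medium") # 5 in (2, 10]
  expect_equal(tab$class[tab$motif == "NE"], "Low")
  expect_equal(tab$class[tab$motif == "Ctrl"], "-")
  expect_equal(tab$class[tab$motif == "CATGTG"], "n.a.")
})

test_that("insufficient data errors are informative", {
  a <- competition_assay(P_tot = 0.3, K_L = 0.04, C_tot = c(0, 5))
  cur <- gen_competition_curves(a, 0.04, c(NE = 0.8), 0, 1, 1)
  expect_error(fit_relative_affinity(cur, a, reference = "NE"), ">= 3")
})
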
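toy_array <- function(intens, probes = paste0("p", seq_along(intens))) {
  do.call(rbind, lapply(seq_along(intens), function(i) {
    data.frame(probe_id = probes[i], category = "core6", dimer = "MYCMAX",
               rep = 1:3, intensity = intens[[i]], stringsAsFactors = FALSE)
  }))
}

test_that("normalize_array scores log2 of median over array median", {
  # triplicates (100,100,100) on an array whose median is 100 -> score 0
  arr <- toy_array(list(c(100, 100, 100), c(50, 100, 200), c(10, 100, 1000)))
  sc <- normalize_array(arr)
  expect_equal(sc$score, c(0, 0, 0))  # all probe medians equal the array median
  # median robustness: (50, 100, 200) has median 100 regardless of tails
  arr2 <- toy_array(list(c(100, 100, 100), c(50, 100, 200), c(1, 400, 400)))
  sc2 <- normalize_array(arr2)
  expect_equal(sc2$score[sc2$probe_id == "p2"], log2(100 / median(arr2$intensity)))
})

test_that("scores are invariant to global rescaling and guard bad input", {
  arr <- gen_pbm_intensities(fixture_library()[1:50, ], noise_cv = 0.3, seed = 2)
  sc1 <- normalize_array(arr)
  arr7 <- transform(arr, intensity = intensity * 7)
  expect_equal(normalize_array(arr7)$score, sc1$score)
  expect_error(normalize_array(arr[-1, ]), "3 replicates")
  arr0 <- arr; arr0$intensity[1] <- 0
  expect_warning(normalize_array(arr0), "floored")
})

test_that("null_threshold matches hand-computed quantiles", {
  sc <- data.frame(probe_id = paste0("r", 1:100), category = "random",
                   dimer = "MYCMAX", score = as.numeric(1:100))
  # type-7 linear interpolation: q95 of 1..100 is 95.05
  thr <- null_threshold(sc, "MYCMAX", 0.95)
  expect_equal(as.numeric(thr), 95.05)
  expect_equal(attr(thr, "mean_plus_2sd"), mean(1:100) + 2 * sd(1:100))
  expect_lte(as.numeric(null_threshold(sc, "MYCMAX", 0.80)), as.numeric(thr))
  # degenerate constant null
  sc0 <- transform(sc, score = 0)
  expect_equal(as.numeric(null_threshold(sc0, "MYCMAX", 0.95)), 0)
  expect_error(null_threshold(sc[1, ], "MYCMAX"), "random")
})

test_that("bound set shrinks as the threshold rises and respects categories", {
  sc <- fixture_scores(noise_cv = 0.2, seed = 3)
  thr80 <- null_threshold(sc, "MYCMAX", 0.80)
  thr95 <- null_threshold(sc, "MYCMAX", 0.95)
  b80 <- bound_probes(sc, "MYCMAX", thr80)
  b95 <- bound_probes(sc, "MYCMAX", thr95)
  expect_gte(nrow(b80), nrow(b95))
  expect_true(all(b95$probe_id %in% b80$probe_id))
  expect_true(all(diff(b95$score) <= 0))
  expect_equal(nrow(bound_probes(sc, "MYCMAX", Inf)), 0)
  expect_true(all(bound_probes(sc, "MYCMAX", thr95, "core6")$category == "core6"))
  expect_false(any(b95$category == "random"))
})

test_that("motif ranking puts the strongest motif first with documented ties", {
  sc <- fixture_scores(noise_cv = 0, seed = 1)
  lib <- fixture_library()
  for (d in c("MYCMAX", "MAXMAX")) {
    thr <- null_threshold(sc, d, 0.95)
    r <- rank_motifs(bound_probes(sc, d, thr), lib)
    expect_equal(r$motif[1], "CACGTG")
    expect_equal(r$rank, seq_len(nrow(r)))
    # ties broken lexicographically by motif
    tied <- r[r$best_score == r$best_score[2], ]
    if (nrow(tied) > 1) expect_equal(tied$motif, sort(tied$motif))
  }
  expect_error(rank_motifs(bound_probes(sc, "MYCMAX", Inf), lib), "empty")
})

test_that("common and high-confidence motif sets behave as set operations", {
  expect_equal(common_motifs(c("CACGTG", "AACGTT"), c("CACGTG", "AACGTT")),
               c("AACGTT", "CACGTG"))
  expect_equal(common_motifs(c("CACGTG"), c("AACGTT")), character(0))
  sc <- fixture_scores(noise_cv = 0, seed = 1)
  lib <- fixture_library()
  hc <- high_confidence_motifs(sc, lib)
  expect_true("AACGTT" %in% hc)
  expect_true("CACGTG" %in% hc)
  # when every designed probe sits below the null, the set is empty
  sc_dead <- sc
  designed <- sc_dead$category != "random"
  sc_dead$score[designed] <- sc_dead$score[designed] - 100
  expect_equal(length(high_confidence_motifs(sc_dead, lib)), 0)
})

test_that("score correlation is a squared Pearson correlation", {
  sc <- data.frame(probe_id = rep(paste0("p", 1:50), 2),
                   category = "core6",
                   dimer = rep(c("MYCMAX", "MAXMAX"), each = 50),
                   score = c(1:50, 1:50))
  expect_equal(score_correlation(sc), 1)
  set.seed(4)
  sc$score <- rnorm(100)
  expect_lt(score_correlation(sc), 0.15)
  expect_error(score_correlation(sc[c(1, 51), ]), "paired")
})

test_that("noiseless end-to-end recovery is exact and stable across seeds", {
  lib <- fixture_library()
  ok <- ok_hc <- 0L
  for (s in 1:5) {
    sc <- fixture_scores(noise_cv = 0.2, seed = s)
    r1 <- rank_motifs(bound_probes(sc, "MYCMAX",
                                   null_threshold(sc, "MYCMAX", 0.95)), lib)
    r2 <- rank_motifs(bound_probes(sc, "MAXMAX",
                                   null_threshold(sc, "MAXMAX", 0.95)), lib)
    if (r1$motif[1] == "CACGTG" && r2$motif[1] == "CACGTG") ok <- ok + 1L
    if ("AACGTT" %in% high_confidence_motifs(sc, lib)) ok_hc <- ok_hc + 1L
  }
  expect_equal(ok, 5L)
  expect_equal(ok_hc, 5L)
})
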
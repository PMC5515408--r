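test_that("summits are apex +/- radius, clamped at chromosome edges", {
  pk <- data.frame(chrom = "chr1", start = 500, end = 1500, apex = 1000,
                   height = 5, pvalue = 1e-10, condition = "highMYC",
                   id = "pk1")
  s <- make_summits(pk, 100)
  expect_equal(c(s$start, s$end), c(900, 1100))
  pk$apex <- 50
  s2 <- make_summits(pk, 100, chrom_sizes = c(chr1 = 10000))
  expect_equal(c(s2$start, s2$end), c(0, 150))
  s3 <- make_summits(pk, 350)
  expect_equal(s3$end - pmax(0, pk$apex - 350), 400)  # clamped at 0
})

test_that("top_fraction_peaks uses the ceil rule and matches sort-and-slice", {
  pk <- random_peaks(9, seed = 1)
  expect_equal(nrow(top_fraction_peaks(pk, 0.33)), 3)
  expect_equal(top_fraction_peaks(pk, 1), {
    x <- pk[order(pk$pvalue, -pk$height, pk$id), ]; rownames(x) <- NULL; x
  })
  for (s in 1:5) {
    pk <- random_peaks(57, seed = s)
    got <- top_fraction_peaks(pk, 0.33)
    brute <- pk[order(pk$pvalue), ][seq_len(ceiling(0.33 * 57)), ]
    expect_setequal(got$id, brute$id)
  }
})

test_that("fold strata partition the peak set into balanced tertiles", {
  pk <- random_peaks(9, seed = 2)
  pk$height <- 1:9
  st <- stratify_by_fold(pk)
  expect_equal(st$Low$height, 1:3)
  expect_equal(st$Medium$height, 4:6)
  expect_equal(st$High$height, 7:9)
  for (n in c(10, 11, 100)) {
    pk <- random_peaks(n, seed = n)
    st <- stratify_by_fold(pk)
    sizes <- vapply(st, nrow, integer(1))
    expect_equal(sum(sizes), n)
    expect_lte(diff(range(sizes)), 1)
    expect_setequal(unlist(lapply(st, `[[`, "id")), pk$id)
  }
  # ties: stable split by id
  pk$height <- 1
  expect_identical(stratify_by_fold(pk), stratify_by_fold(pk))
})

test_that("normalized frequency is 1 under whole-genome regions, 0 under none", {
  g <- gen_genome(1, 20000, 0.5, seed = 3)
  motifs <- c("CACGTG", "AACGTT")
  hits <- scan_motifs(g, motifs)
  cnt <- genome_motif_counts(g, motifs)
  whole <- data.frame(chrom = "chr1", start = 0, end = 20000)
  nf <- normalized_frequency(whole, hits, cnt)
  expect_equal(nf$normalized_frequency, rep(1, 2))
  none <- whole[0, ]
  nf0 <- normalized_frequency(none, hits, cnt)
  expect_equal(nf0$normalized_frequency, rep(0, 2))
  expect_warning(
    normalized_frequency(whole, hits, c(cnt, XXXXXX = 0L)), "omitted")
})

test_that("normalized frequency matches a hand-counted toy case", {
  # 10 kb toy: 3 CACGTG inside the region, 2 outside; 1 AACGTT inside, 3 outside
  base <- paste(rep("AT", 5000), collapse = "")
  place <- function(seq, pos1, motif) {
    substr(seq, pos1, pos1 + 5) <- motif
    seq
  }
  s <- base
  for (p in c(1001, 1501, 1901)) s <- place(s, p, "CACGTG")
  for (p in c(3001, 8001)) s <- place(s, p, "CACGTG")
  s <- place(s, 1201, "AACGTT")
  for (p in c(4001, 5001, 9001)) s <- place(s, p, "AACGTT")
  g <- c(chr1 = s)
  region <- data.frame(chrom = "chr1", start = 950, end = 2050)
  hits <- scan_motifs(g, c("CACGTG", "AACGTT"))
  cnt <- genome_motif_counts(g, c("CACGTG", "AACGTT"))
  nf <- normalized_frequency(region, hits, cnt)
  expect_equal(nf$hits_in_regions[nf$motif == "CACGTG"], 3)
  expect_equal(nf$normalized_frequency[nf$motif == "CACGTG"], 3 / 5)
  expect_equal(nf$normalized_frequency[nf$motif == "AACGTT"], 1 / 4)
  # boundary: a hit straddling the region edge is not contained
  region2 <- data.frame(chrom = "chr1", start = 1003, end = 2050)
  nf2 <- normalized_frequency(region2, hits, cnt)
  expect_equal(nf2$hits_in_regions[nf2$motif == "CACGTG"], 2)
})

test_that("co-occurrence cells partition regions and match brute force", {
  g <- gen_genome(1, 100000, 0.5, seed = 4)
  planted <- plant_sites(g, c(CACGTG = 30, AACGTT = 30), seed = 5)
  hits <- scan_motifs(planted$genome, c("CACGTG", "AACGTT"))
  ha <- hits[hits$motif == "CACGTG", ]
  hb <- hits[hits$motif == "AACGTT", ]
  for (s in 1:5) {
    regions <- random_peaks(40, seed = 200 + s)
    regions$start <- pmax(0, regions$apex - 100)
    regions$end <- regions$apex + 100
    part <- cooccurrence_partition(regions, ha, hb)
    expect_equal(sum(part), nrow(regions))
    brute <- t(vapply(seq_len(nrow(regions)), function(i) {
      a <- oracle_region_has_hit(regions[i, ], ha)
      b <- oracle_region_has_hit(regions[i, ], hb)
      c(a & !b, !a & b, a & b, !a & !b)
    }, logical(4)))
    expect_equal(unname(part), unname(colSums(brute)))
  }
})

test_that("region annotation matches hand-derived categories", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = "chr1",
    start = c(10000, 30000, 60000),
    end = c(20000, 40000, 80000),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  apexes <- c(9000, 11500, 15000, 25000, 39500, 41000, 59000, 70000, 83000, 500)
  expected <- c("promoter",    # 1 kb upstream of g1 TSS
                "promoter",    # 1.5 kb downstream of g1 TSS
                "intragenic",  # inside g1, 5 kb from TSS
                "intergenic",  # between g1 and g2
                "promoter",    # g2 is minus strand: TSS at 39999
                "promoter",    # 1 kb beyond g2 end, within 2 kb of its TSS
                "promoter",    # 1 kb upstream of g3
                "intragenic",  # deep inside g3
                "intergenic",  # 3 kb past g3 end
                "intergenic")  # far from everything
  regions <- data.frame(chrom = "chr1", start = apexes - 100,
                        end = apexes + 100, apex = apexes,
                        peak_id = sprintf("r%02d", seq_along(apexes)))
  ann <- annotate_regions(regions, genes, promoter_window = 2000)
  expect_equal(ann$category, expected)
  # signed distances are strand-aware: downstream positive
  expect_equal(ann$tss_distance[1], -1000)
  expect_equal(ann$tss_distance[2], 1500)
  expect_equal(ann$tss_distance[5], 499)   # minus strand: 39500 is downstream
  # categories always exhaustive
  expect_true(all(ann$category %in% c("promoter", "intragenic", "intergenic")))
})

test_that("condition fold changes behave on identical and dose-split inputs", {
  g <- gen_genome(1, 100000, 0.5, seed = 6)
  planted <- plant_sites(g, c(CACGTG = 30, AACGTT = 40), seed = 7)
  hits <- scan_motifs(planted$genome, c("CACGTG", "AACGTT"))
  m <- peak_model(concentration = c(lowMYC = 0.25, highMYC = 2.5),
                  theta_det = 0.25, sigma_h = 0, apex_jitter = 0, seed = 8)
  lo <- make_summits(gen_peaks(planted$truth, m, "lowMYC"), 100)
  hi <- make_summits(gen_peaks(planted$truth, m, "highMYC"), 100)
  fc_same <- condition_fold_change(hi, hi, hits, c("CACGTG", "AACGTT"))
  expect_equal(fc_same$fold_change, c(1, 1))
  fc <- suppressWarnings(
    condition_fold_change(hi, lo, hits, c("CACGTG", "AACGTT")))
  expect_gt(fc$fold_change[fc$motif == "AACGTT"],
            fc$fold_change[fc$motif == "CACGTG"])
  fc_h <- condition_fold_change(hi, hi, hits, "CACGTG", mode = "mean_height")
  expect_equal(fc_h$fold_change, 1)
})

test_that("spatial distribution totals the in-window hits", {
  summits <- data.frame(chrom = "chr1", start = 900, end = 1100, apex = 1000,
                        peak_id = "s1")
  hits <- data.frame(motif = "CACGTG", chrom = "chr1",
                     start = c(997, 947, 1047, 1200), end = NA, strand = "+")
  hits$end <- hits$start + 6L
  h <- spatial_distribution(summits, hits, bin = 10, window = 100)
  expect_equal(sum(h$count), 3)
  # motif midpoints at the apex fall in the central bin
  central <- h$count[h$offset == 5]
  expect_equal(central, 1)
  expect_equal(sum(h$frequency), 3)
})

test_that("topk coverage counts summits containing any listed motif", {
  g <- gen_genome(1, 50000, 0.5, seed = 10)
  planted <- plant_sites(g, c(CACGTG = 20), seed = 11)
  truth <- planted$truth
  summits <- data.frame(chrom = truth$chrom, start = truth$start - 50,
                        end = truth$start + 56, apex = truth$start + 3,
                        peak_id = sprintf("s%02d", seq_len(nrow(truth))))
  hits <- scan_motifs(planted$genome, "CACGTG")
  expect_equal(topk_coverage(summits, hits, "CACGTG"), 1)
  expect_equal(topk_coverage(summits, hits, character(0)), 0)
  far <- data.frame(chrom = "chr1", start = 0, end = 6, apex = 3,
                    peak_id = "tiny")
  expect_error(topk_coverage(far[0, ], hits, "CACGTG"), "empty")
})
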
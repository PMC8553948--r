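test_that("per-locus directional values match hand-worked cases", {
  # identical homozygotes: (2 - 2p)/(2 - 2p) = 1 for any p
  for (p in c(0.1, 0.5, 0.9))
    expect_equal(rxy_locus("A", "A", "A", "A", c(A = p, G = 1 - p)), 1)
  # full mismatch at p = 0.5: (0 - 1)/(2 - 1) = -1
  expect_equal(rxy_locus("A", "A", "G", "G", c(A = 0.5, G = 0.5)), -1)
  # heterozygous x against homozygous y, both directions
  p <- c(A = 0.3, G = 0.2)
  expect_equal(rxy_locus("A", "G", "A", "A", p), 1.0)
  expect_equal(rxy_locus("A", "A", "A", "G", p), 2 / 7, tolerance = 1e-12)
})

test_that("general form agrees with an independent brute-force evaluation", {
  freqs <- c(A = 0.17, C = 0.28, G = 0.35, T = 0.20)
  combos <- expand.grid(a = names(freqs), b = names(freqs),
                        c = names(freqs), d = names(freqs),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    g <- combos[i, ]
    expect_equal(rxy_locus(g$a, g$b, g$c, g$d, freqs),
                 qg_brute(g$a, g$b, g$c, g$d, freqs), tolerance = 1e-12)
  }
})

test_that("multilocus HRC matches the pseudo-haploid hand reduction", {
  panel <- ag_panel(rep(0.5, 3))
  x <- calls_on(panel, c("A", "A", "A"))
  y <- calls_on(panel, c("A", "G", "A"))
  # per-locus symmetric values (1, -1, 1) -> mean 1/3
  expect_equal(pairwise_hrc(x, y, panel)$hrc, 1 / 3, tolerance = 1e-12)
  # both modes agree exactly when all loci share one frequency
  expect_equal(pairwise_hrc(x, y, panel, mode = "ratio_of_sums")$hrc, 1 / 3,
               tolerance = 1e-12)
})

test_that("identical call vectors give HRC = 1 exactly", {
  panel <- gen_freq_panel(1000, seed = 21)
  pr <- simulate_pair(panel, 0.3, seed = 22)
  for (mode in c("mean_of_ratios", "ratio_of_sums"))
    expect_equal(pairwise_hrc(pr$x, pr$x, panel, mode = mode)$hrc, 1)
})

test_that("the estimator is symmetric in the two individuals", {
  panel <- gen_freq_panel(2000, seed = 31)
  for (k in c(0, 0.125, 0.25)) {
    pr <- simulate_pair(panel, k, seed = 32 + round(1000 * k))
    for (mode in c("mean_of_ratios", "ratio_of_sums"))
      expect_equal(pairwise_hrc(pr$x, pr$y, panel, mode = mode)$hrc,
                   pairwise_hrc(pr$y, pr$x, panel, mode = mode)$hrc,
                   tolerance = 1e-12)
  }
})

test_that("relabeling allele1 and allele2 leaves HRC unchanged", {
  panel <- gen_freq_panel(2000, seed = 41)
  pr <- simulate_pair(panel, 0.125, seed = 42)
  flipped <- freq_panel(panel$chrom, panel$pos, panel$id,
                        panel$allele2, panel$allele1, 1 - panel$freq1)
  expect_equal(pairwise_hrc(pr$x, pr$y, panel)$hrc,
               pairwise_hrc(pr$x, pr$y, flipped)$hrc, tolerance = 1e-12)
})

test_that("missing calls are excluded and empty overlap is an error", {
  panel <- ag_panel(c(0.3, 0.4, 0.5, 0.6))
  x <- calls_on(panel, c("A", NA, "A", "A"))
  y <- calls_on(panel, c("A", "G", NA, "A"))
  res <- pairwise_hrc(x, y, panel)
  expect_equal(res$n_snps, 2L)
  x2 <- calls_on(panel, c("A", "A", NA, NA))
  y2 <- calls_on(panel, c(NA, NA, "A", "A"))
  expect_error(pairwise_hrc(x2, y2, panel), "no overlapping SNPs")
})

test_that("classification uses the mid-point thresholds", {
  expect_equal(classify_hrc(0.2595), "first_degree")
  expect_equal(classify_hrc(0.0962), "second_degree")
  expect_equal(classify_hrc(-0.01), "unrelated")
  expect_equal(classify_hrc(0.07), "second_or_third_degree")
  # boundaries assign to the more related class
  expect_equal(classify_hrc(0.1875), "first_degree")
  expect_equal(classify_hrc(0.0625), "second_or_third_degree")
  expect_equal(classify_hrc(0.090), "second_degree")
  expect_equal(classify_hrc(0.1875 - 1e-9), "second_degree")
  expect_equal(classify_hrc(0.0625 - 1e-9), "unrelated")
  expect_error(classify_hrc(NaN), "finite")
})

test_that("confidence tiers follow the shared-SNP-count regimes", {
  expect_equal(confidence_tier(18364), "high")
  expect_equal(confidence_tier(12000), "medium")
  expect_equal(confidence_tier(4059), "low")
  expect_equal(confidence_tier(c(1, 3999)),
               c("below_threshold", "below_threshold"))
  expect_equal(confidence_tier(c(18000, 11000, 4000)),
               c("high", "medium", "low"))
})

test_that("known-unrelated normalization subtracts the unrelated mean", {
  results <- data.frame(id_x = c("a", "a", "b"), id_y = c("b", "c", "c"),
                        n_snps = 5000L,
                        hrc = c(0.3131, 0.1149, 0.1149),
                        class_label = NA_character_,
                        confidence_tier = "low", stringsAsFactors = FALSE)
  results$class_label <- classify_hrc(results$hrc)
  ku <- data.frame(id_x = c("a", "b"), id_y = c("c", "c"))
  norm <- normalize_unrelated(results, ku)
  expect_equal(norm$hrc[norm$id_x == "a" & norm$id_y == "b"], 0.1982,
               tolerance = 1e-12)
  expect_equal(norm$class_label[norm$id_x == "a" & norm$id_y == "b"],
               "first_degree")
  # centering: corrected known-unrelated mean is zero by construction
  uk_rows <- norm$id_y == "c"
  expect_equal(mean(norm$hrc[uk_rows]), 0, tolerance = 1e-12)
  expect_equal(norm$hrc_raw, results$hrc)

  expect_error(normalize_unrelated(results, ku[0, ]), "at least one")
  bad <- data.frame(id_x = "a", id_y = "zz")
  expect_error(normalize_unrelated(results, bad), "not found")
})
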
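test_that("generated panels are valid, truncated and seeded", {
  for (spec in c("beta", "uniform")) {
    panel <- gen_freq_panel(500, spectrum = spec, seed = 111)
    expect_s3_class(panel, "freq_panel")
    expect_true(all(panel$freq1 >= 0.001 & panel$freq1 <= 0.999))
  }
  p1 <- gen_freq_panel(200, seed = 112)
  p2 <- gen_freq_panel(200, seed = 112)
  expect_identical(p1, p2)
  expect_error(gen_freq_panel(10, spectrum = "beta", shape1 = -1),
               "positive")
})

test_that("the beta spectrum is symmetric around one half", {
  panel <- gen_freq_panel(100000, spectrum = "beta", shape1 = 0.2,
                          shape2 = 0.2, seed = 113)
  # var of beta(0.2, 0.2) is ~0.1786 -> 3 SE at n = 1e5 is ~0.004
  expect_lt(abs(mean(panel$freq1) - 0.5), 0.004)
})

test_that("cohort truth propagates to the estimator", {
  panel <- gen_freq_panel(2000, seed = 121)
  pairs <- data.frame(id_x = "a", id_y = "b", k = 1)
  cohort <- gen_cohort(panel, pairs, seed = 122)
  expect_equal(pairwise_hrc(cohort$calls[, "a"], cohort$calls[, "b"],
                            panel)$hrc, 1)
  dup <- data.frame(id_x = c("a", "a"), id_y = c("b", "c"), k = c(0, 0.25))
  expect_error(gen_cohort(panel, dup, seed = 1), "contradictory")
})

test_that("independent missingness thins the pairwise overlap as expected", {
  n <- 4000
  panel <- gen_freq_panel(n, seed = 131)
  cohort <- gen_cohort(panel, data.frame(id_x = "a", id_y = "b", k = 0),
                       missing_rate = 0.5, seed = 132)
  overlap <- sum(!is.na(cohort$calls[, "a"]) & !is.na(cohort$calls[, "b"]))
  expect_lt(abs(overlap - 0.25 * n), 3 * sqrt(n * 0.25 * 0.75))
})

test_that("error-free pileups reproduce the generating calls", {
  panel <- gen_freq_panel(800, seed = 141)
  cohort <- gen_cohort(panel, data.frame(id_x = "a", id_y = "b", k = 0.25),
                       seed = 142)
  truth <- cohort$calls[, "a"]
  lines <- gen_pileup(truth, panel, depth_mean = 8, error_rate = 0,
                      seed = 143)
  called <- call_pileup(lines, panel, seed = 144)
  covered <- !is.na(called)
  expect_gt(mean(covered), 0.99)          # Poisson(8) leaves almost no gaps
  expect_identical(called[covered], truth[covered])
})

test_that("ultra-low depth leaves most loci missing", {
  panel <- gen_freq_panel(2000, seed = 151)
  cohort <- gen_cohort(panel, data.frame(id_x = "a", id_y = "b", k = 0),
                       seed = 152)
  lines <- gen_pileup(cohort$calls[, "a"], panel, depth_mean = 0.05,
                      seed = 153)
  called <- call_pileup(lines, panel, seed = 154)
  expect_gt(mean(is.na(called)), 0.9)
})

test_that("read errors produce the enumerated discordance rate", {
  err <- 0.1; dmean <- 5; n <- 10000
  panel <- gen_freq_panel(n, seed = 161)
  cohort <- gen_cohort(panel, data.frame(id_x = "a", id_y = "b", k = 0),
                       seed = 162)
  truth <- cohort$calls[, "a"]
  lines <- gen_pileup(truth, panel, depth_mean = dmean, error_rate = err,
                      seed = 163)
  called <- call_pileup(lines, panel, min_base_quality = 0, seed = 164)
  ok <- !is.na(called)
  disc <- mean(called[ok] != truth[ok])

  # independent enumeration: reads hit the true allele w.p. 1 - err, the
  # other panel allele w.p. err/3; the call picks uniformly among surviving
  # reads, so P(discordant | depth d, called) = E[n_other / (n_true+n_other)]
  p_t <- 1 - err; p_o <- err / 3
  num <- 0; den <- 0
  for (d in 1:25) {
    pd <- stats::dpois(d, dmean)
    for (nt in 0:d) for (no in 0:(d - nt)) {
      if (nt + no == 0) next
      pr <- stats::dmultinom(c(nt, no, d - nt - no), d,
                             c(p_t, p_o, 1 - p_t - p_o))
      num <- num + pd * pr * no / (nt + no)
      den <- den + pd * pr
    }
  }
  expected <- num / den
  expect_lt(abs(disc - expected),
            3 * sqrt(expected * (1 - expected) / sum(ok)))
})

test_that("fixture outputs parse through the standard readers cleanly", {
  panel <- gen_freq_panel(300, seed = 171)
  cohort <- gen_cohort(panel, data.frame(id_x = "a", id_y = "b", k = 0.125),
                       missing_rate = 0.1, seed = 172)
  dir <- withr::local_tempdir()
  expect_no_warning({
    write_freq_panel(panel, file.path(dir, "p.frq"))
    back <- read_freq_panel(file.path(dir, "p.frq"))
    write_tped(cohort$calls, panel, file.path(dir, "coh"))
    plink <- read_plink(file.path(dir, "coh"), panel)
    lines <- gen_pileup(cohort$calls[, "a"], panel, seed = 173)
    call_pileup(lines, panel)
  })
  expect_equal(nrow(back), 300L)
  expect_equal(ncol(plink), 2L)
})
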
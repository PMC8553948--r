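# Monte-Carlo calibration: simulated pseudo-haploid pairs at fixed IBD
# sharing, class distributions per SNP count, false-positive rates and
# posterior probabilities.
#
# Pair model: per locus, individual x's single allele is allele1 with
# probability freq1; with probability k (the IBD-copy probability) y copies
# x's allele, otherwise y draws independently from the same frequency. Under
# pseudo-haploid sampling k equals the realized kinship coefficient, so the
# expected HRC is exactly k: 0.25 for 1st-degree pairs, 0.125 for 2nd-degree,
# 0 for unrelated.

SIM_CLASSES <- c(0, 0.125, 0.25)

class_of_k <- function(k) {
  c("0" = "unrelated", "0.125" = "second_degree",
    "0.25" = "first_degree")[as.character(k)]
}

# One simulated pair on the allele1-indicator scale. f: vector of allele1
# frequencies. Returns logicals x1, y1 (TRUE = carries allele1).
sim_pair_flags <- function(f, k) {
  n <- length(f)
  x1 <- stats::runif(n) < f
  copy <- stats::runif(n) < k
  y1 <- ifelse(copy, x1, stats::runif(n) < f)
  list(x1 = x1, y1 = y1)
}

# HRC straight from indicator vectors, avoiding character alleles.
hrc_from_flags <- function(x1, y1, f, mode = "mean_of_ratios") {
  px <- ifelse(x1, f, 1 - f)
  py <- ifelse(y1, f, 1 - f)
  hrc_combine(x1 == y1, px, py, mode)
}

#' Simulate one pseudo-haploid pair at a fixed IBD-copy probability
#'
#' @param panel a [freq_panel()] supplying per-locus allele frequencies and
#'   allele labels.
#' @param k IBD-copy probability in `[0, 1]`: per locus, the second
#'   individual copies the first's allele with probability `k`, otherwise
#'   draws independently from the population frequency. `k = 0.25`
#'   corresponds to a 1st-degree pair on the HRC scale, `0.125` to
#'   2nd-degree, `0` to unrelated.
#' @param seed optional integer seed.
#' @return list of two named character vectors `x` and `y` (alleles over the
#'   panel's loci).
#' @export
simulate_pair <- function(panel, k, seed = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > 1)
    stop("k must be a single probability in [0, 1]", call. = FALSE)
  with_seed(seed, {
    fl <- sim_pair_flags(panel$freq1, k)
    list(x = stats::setNames(ifelse(fl$x1, panel$allele1, panel$allele2),
                             panel$id),
         y = stats::setNames(ifelse(fl$y1, panel$allele1, panel$allele2),
                             panel$id))
  })
}

#' Simulate HRC class distributions across SNP counts
#'
#' For each SNP count, simulates `n_pairs` pseudo-haploid pairs per
#' relatedness class (unrelated k = 0, 2nd-degree k = 0.125, 1st-degree
#' k = 0.25), each pair on a fresh random locus subset of the panel, computes
#' every pair's HRC, and fits a normal distribution per class. The fitted
#' curves are the basis for false-positive rates ([false_positive_rate()])
#' and posterior probabilities ([posterior_hrc()]).
#'
#' @param panel a [freq_panel()].
#' @param snp_counts integer vector of loci-per-pair values; each must not
#'   exceed the panel size.
#' @param n_pairs simulated pairs per class per SNP count (>= 2).
#' @param seed optional integer seed; fixed seed gives bit-identical samples.
#' @param classes IBD-copy probabilities to simulate.
#' @param mode multilocus combination passed to the estimator.
#' @return object of class `class_distributions`: list with `snp_counts`,
#'   `n_pairs`, `samples` (nested list `[[snp_count]][[k]]` of HRC vectors)
#'   and `fitted` (data frame `snp_count`, `k`, `class_label`, `mean`, `sd`).
#' @export
build_distributions <- function(panel, snp_counts, n_pairs = 500,
                                seed = NULL, classes = SIM_CLASSES,
                                mode = "mean_of_ratios") {
  stopifnot(inherits(panel, "freq_panel"), n_pairs >= 2)
  snp_counts <- as.integer(snp_counts)
  if (any(snp_counts > nrow(panel)))
    stop("snp_count ", max(snp_counts), " exceeds panel size ", nrow(panel),
         call. = FALSE)
  if (any(snp_counts < 1L)) stop("snp_counts must be >= 1", call. = FALSE)
  f_all <- panel$freq1
  samples <- list()
  fitted <- list()
  with_seed(seed, {
    for (sc in snp_counts) {
      per_class <- list()
      for (k in classes) {
        hrc <- vapply(seq_len(n_pairs), function(i) {
          f <- f_all[sample.int(length(f_all), sc)]
          fl <- sim_pair_flags(f, k)
          hrc_from_flags(fl$x1, fl$y1, f, mode)
        }, numeric(1L))
        per_class[[as.character(k)]] <- hrc
        fitted[[length(fitted) + 1L]] <-
          data.frame(snp_count = sc, k = k,
                     class_label = unname(class_of_k(k)),
                     mean = mean(hrc), sd = stats::sd(hrc),
                     stringsAsFactors = FALSE)
      }
      samples[[as.character(sc)]] <- per_class
    }
  })
  structure(list(snp_counts = snp_counts, n_pairs = n_pairs,
                 classes = classes, samples = samples,
                 fitted = do.call(rbind, fitted)),
            class = "class_distributions")
}

# Own-class HRC band under the hard thresholds; used for threshold-crossing
# (false positive) rates.
class_band <- function(k, t_unrelated = 0.0625, t_first = 0.1875) {
  switch(as.character(k),
         "0" = c(-Inf, t_unrelated),
         "0.125" = c(t_unrelated, t_first),
         "0.25" = c(t_first, Inf),
         stop("no hard-threshold band for class k = ", k, call. = FALSE))
}

#' Threshold-crossing (false positive) rate of a simulated class
#'
#' Fraction of a class's simulated HRC values falling outside its own
#' hard-threshold band: unrelated below 0.0625, 2nd degree in
#' [0.0625, 0.1875), 1st degree at or above 0.1875. The 2nd-degree rate is
#' the usual summary, as that class can cross into both neighbours.
#'
#' @param dist a [build_distributions()] result.
#' @param class_k the class's IBD-copy probability (0, 0.125 or 0.25).
#' @param snp_count which simulated SNP count to evaluate; default all.
#' @return named numeric vector of rates, one per SNP count.
#' @export
false_positive_rate <- function(dist, class_k, snp_count = NULL) {
  stopifnot(inherits(dist, "class_distributions"))
  counts <- snp_count %||% dist$snp_counts
  band <- class_band(class_k)
  vapply(as.character(counts), function(sc) {
    hrc <- dist$samples[[sc]][[as.character(class_k)]]
    if (is.null(hrc))
      stop("class k = ", class_k, " not simulated at ", sc, " SNPs",
           call. = FALSE)
    mean(hrc < band[1L] | hrc >= band[2L])
  }, numeric(1L))
}

#' Posterior class probabilities for an HRC estimate
#'
#' Evaluates the normal fit of each simulated class at the estimate and
#' normalizes across classes (equal priors by default). The simulated SNP
#' count nearest to the pair's actual count is used, with a message when they
#' differ.
#'
#' @param hrc the pair's HRC estimate.
#' @param n_snps the pair's shared-SNP count.
#' @param dist a [build_distributions()] result covering all three classes.
#' @param priors prior class probabilities, named by class `k` values or in
#'   `dist$classes` order; default equal.
#' @return named numeric vector of posterior probabilities (names are class
#'   labels); sums to 1.
#' @export
posterior_hrc <- function(hrc, n_snps, dist, priors = NULL) {
  stopifnot(inherits(dist, "class_distributions"))
  sc <- dist$snp_counts[which.min(abs(dist$snp_counts - n_snps))]
  if (sc != n_snps)
    message("using nearest simulated SNP count ", sc, " for a pair with ",
            n_snps, " SNPs")
  fit <- dist$fitted[dist$fitted$snp_count == sc, ]
  priors <- priors %||% rep(1 / nrow(fit), nrow(fit))
  dens <- stats::dnorm(hrc, fit$mean, fit$sd) * priors
  if (!any(dens > 0))
    stop("estimate outside simulated range: no class curve covers hrc = ",
         format(hrc), " at ", sc, " SNPs", call. = FALSE)
  stats::setNames(dens / sum(dens), fit$class_label)
}
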
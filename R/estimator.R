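# Queller-Goodnight pairwise relatedness on the halved (pseudo-haploid)
# scale, classification and known-unrelated normalization.
#
# Per locus and direction, with individual x carrying alleles (a, b) and
# individual y carrying (c, d), and p the population frequency of each
# allele:
#
#   r_xy = (0.5 (Iac + Iad + Ibc + Ibd) - pa - pb) / (1 + Iab - pa - pb)
#
# where the I terms are allele-identity indicators. The symmetric per-locus
# value is (r_xy + r_yx) / 2, each direction using its own individual's
# allele frequencies. For pseudo-haploid calls (a = b, c = d) the direction
# reduces to (I - p_a) / (1 - p_a); this is the vectorized hot path, with
# the general four-allele form kept for diploid input and as an oracle.
# Expectations under pseudo-haploid sampling are 0.25 for 1st-degree pairs,
# 0.125 for 2nd-degree and 0 for unrelated ("halved relatedness
# coefficients", HRC).

#' Per-locus Queller-Goodnight value, one direction
#'
#' The general four-allele form: individual x carries alleles `a`,`b`,
#' individual y carries `c`,`d`. Pseudo-haploid calls are the special case
#' `a == b`, `c == d`.
#'
#' @param a,b alleles of individual x (single bases).
#' @param c,d alleles of individual y.
#' @param p named numeric vector of population allele frequencies; must be
#'   defined and strictly inside (0, 1) for every allele present.
#' @return the directional per-locus value `r_xy`.
#' @export
rxy_locus <- function(a, b, c, d, p) {
  al <- c(a, b, c, d)
  if (!all(al %in% names(p)))
    stop("frequency missing for allele(s): ",
         paste(setdiff(al, names(p)), collapse = ", "), call. = FALSE)
  pa <- p[[a]]; pb <- p[[b]]
  if (any(c(pa, pb, p[[c]], p[[d]]) <= 0) ||
      any(c(pa, pb, p[[c]], p[[d]]) >= 1))
    stop("allele frequencies must be strictly inside (0, 1)", call. = FALSE)
  num <- 0.5 * ((a == c) + (a == d) + (b == c) + (b == d)) - pa - pb
  den <- 1 + (a == b) - pa - pb
  if (den == 0)
    stop("zero denominator at locus; frequencies too close to bounds",
         call. = FALSE)
  num / den
}

# Vectorized symmetric per-locus pieces for pseudo-haploid data.
# px, py: frequency of each individual's own allele; I: identity indicator.
# Returns numerators and denominators of the unreduced directional forms
# (numerator 2(I - p), denominator 2(1 - p)), so both combination modes can
# be built from the same pieces.
ph_locus_terms <- function(ident, px, py) {
  list(num_x = 2 * (ident - px), den_x = 2 * (1 - px),
       num_y = 2 * (ident - py), den_y = 2 * (1 - py))
}

#' Pairwise HRC between two pseudo-haploid individuals
#'
#' Intersects the loci non-missing in both individuals, attaches each
#' individual's own allele frequency from the panel, and combines the
#' per-locus directional values into a single halved relatedness coefficient
#' (HRC).
#'
#' Two multilocus combinations are available: `mean_of_ratios` (default)
#' averages the symmetric per-locus value (r_xy + r_yx)/2 across loci;
#' `ratio_of_sums` accumulates numerators and denominators separately per
#' direction, forms the two multilocus ratios and averages them (the
#' SPAGeDI-style estimator).
#'
#' @param x,y named character vectors of single-allele calls (`NA` missing),
#'   names being panel SNP ids.
#' @param panel a [freq_panel()].
#' @param mode multilocus combination, `"mean_of_ratios"` or
#'   `"ratio_of_sums"`.
#' @param id_x,id_y individual identifiers carried into the result.
#' @return a one-row data frame (`id_x`, `id_y`, `n_snps`, `hrc`,
#'   `class_label`, `confidence_tier`).
#' @export
pairwise_hrc <- function(x, y, panel,
                         mode = c("mean_of_ratios", "ratio_of_sums"),
                         id_x = "x", id_y = "y") {
  stopifnot(inherits(panel, "freq_panel"))
  mode <- match.arg(mode)
  shared <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  shared <- shared[shared %in% panel$id]
  if (length(shared) == 0L)
    stop("no overlapping SNPs between ", id_x, " and ", id_y, call. = FALSE)
  pidx <- match(shared, panel$id)
  ax <- x[shared]; ay <- y[shared]
  px <- allele_freq(panel, pidx, ax)
  py <- allele_freq(panel, pidx, ay)
  if (anyNA(px) || anyNA(py))
    stop("call allele not among the panel's two alleles at ",
         shared[which(is.na(px) | is.na(py))[1L]], call. = FALSE)
  hrc <- hrc_combine(ax == ay, px, py, mode)
  data.frame(id_x = id_x, id_y = id_y, n_snps = length(shared), hrc = hrc,
             class_label = classify_hrc(hrc),
             confidence_tier = confidence_tier(length(shared)),
             stringsAsFactors = FALSE)
}

hrc_combine <- function(ident, px, py, mode) {
  t <- ph_locus_terms(ident, px, py)
  if (mode == "mean_of_ratios") {
    mean((t$num_x / t$den_x + t$num_y / t$den_y) / 2)
  } else {
    (sum(t$num_x) / sum(t$den_x) + sum(t$num_y) / sum(t$den_y)) / 2
  }
}

#' Classify an HRC value into a relatedness class
#'
#' Hard thresholds sit at the mid-points between the expected class means
#' (0.25 for 1st degree, 0.125 for 2nd, 0 for unrelated): 0.1875 between 1st
#' and 2nd degree, 0.0625 between 2nd degree and unrelated. Because
#' 3rd-degree relatives (expected HRC 0.0625) overlap the bottom of the
#' 2nd-degree band, values in [0.0625, 0.090) are labelled
#' `second_or_third_degree`. Boundary values go to the more related class.
#'
#' @param hrc numeric vector of halved relatedness coefficients.
#' @param t_unrelated threshold below which a pair is unrelated.
#' @param t_third upper edge of the 2nd-or-3rd-degree caveat band.
#' @param t_first threshold at and above which a pair is 1st degree.
#' @return character vector of class labels.
#' @export
classify_hrc <- function(hrc, t_unrelated = 0.0625, t_third = 0.090,
                         t_first = 0.1875) {
  stopifnot(0 < t_unrelated, t_unrelated < t_third, t_third < t_first)
  if (any(!is.finite(hrc))) stop("hrc must be finite", call. = FALSE)
  ifelse(hrc >= t_first, "first_degree",
         ifelse(hrc >= t_third, "second_degree",
                ifelse(hrc >= t_unrelated, "second_or_third_degree",
                       "unrelated")))
}

#' Confidence tier from the number of shared SNPs
#'
#' Tiers follow the SNP-count regimes where error behaviour changes:
#' from ~18,000 shared SNPs misassignment is rare (`high`); between 11,000
#' and 18,000 no false-positive related calls are expected though false
#' negatives remain possible (`medium`); from 4,000 SNPs true 1st-degree
#' relatives are detectable as related, if not always at the right degree
#' (`low`); below that estimates are reported but flagged
#' (`below_threshold`).
#'
#' @param n_snps integer vector of shared-SNP counts.
#' @return character vector of tiers.
#' @export
confidence_tier <- function(n_snps) {
  stopifnot(all(n_snps >= 1))
  ifelse(n_snps >= 18000, "high",
         ifelse(n_snps >= 11000, "medium",
                ifelse(n_snps >= 4000, "low", "below_threshold")))
}

#' Normalize HRC estimates against known-unrelated pairs
#'
#' When the frequency panel poorly matches the test population's ancestry,
#' all HRC estimates shift upward together. Subtracting the mean HRC of
#' pairs known to be unrelated re-centres the estimates on their expected
#' ranges; classification is re-run on the corrected values and the original
#' estimates are retained in `hrc_raw`.
#'
#' @param results a pairwise report data frame (as from [run_relate()] or
#'   rows of [pairwise_hrc()]).
#' @param known_unrelated data frame with columns `id_x`, `id_y` naming the
#'   known-unrelated pairs (order within a pair is ignored).
#' @return `results` with `hrc_raw` added, `hrc` replaced by the corrected
#'   value and `class_label` reclassified.
#' @export
normalize_unrelated <- function(results, known_unrelated) {
  if (is.null(known_unrelated) || nrow(known_unrelated) == 0L)
    stop("known_unrelated must name at least one pair", call. = FALSE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  rk <- key(results$id_x, results$id_y)
  uk <- key(known_unrelated$id_x, known_unrelated$id_y)
  hit <- match(uk, rk)
  if (anyNA(hit))
    stop("known-unrelated pair not found in results: ",
         uk[is.na(hit)][1L], call. = FALSE)
  shift <- mean(results$hrc[hit], na.rm = TRUE)
  results$hrc_raw <- results$hrc
  results$hrc <- results$hrc - shift
  ok <- !is.na(results$hrc)
  results$class_label[ok] <- classify_hrc(results$hrc[ok])
  results
}
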
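# Synthetic-data generators: frequency panels, pedigreed cohorts with known
# truth, and pileup text. These make the whole pipeline testable without any
# external download and double as a simulation workbench.

#' Generate a synthetic allele-frequency panel
#'
#' Draws per-locus allele frequencies from a chosen spectrum and assigns two
#' distinct random bases per locus. The default uniform spectrum emulates the
#' effective frequency spectrum of the usable genome-wide panel SNPs: the
#' per-locus variance it induces in the relatedness estimator reproduces the
#' published error-rate-versus-SNP-count behaviour of real
#' frequency panels. The U-shaped beta spectrum (default beta(0.2, 0.2)),
#' with most mass near the frequency bounds, is a heavy-tailed stress case:
#' it roughly doubles the per-locus estimator noise, so class distributions
#' stay wide even at high SNP counts. Class means are unaffected by the
#' spectrum (the estimator is frequency-corrected). Frequencies are truncated
#' to [0.001, 0.999] so no locus is fixed.
#'
#' @param n_loci number of loci (>= 1).
#' @param spectrum `"uniform"` or `"beta"`.
#' @param shape1,shape2 beta parameters (ignored for uniform).
#' @param seed optional integer seed; same seed, same panel.
#' @return a [freq_panel()].
#' @export
gen_freq_panel <- function(n_loci, spectrum = c("uniform", "beta"),
                           shape1 = 0.2, shape2 = 0.2, seed = NULL) {
  spectrum <- match.arg(spectrum)
  stopifnot(n_loci >= 1)
  if (spectrum == "beta" && (shape1 <= 0 || shape2 <= 0))
    stop("beta spectrum parameters must be positive", call. = FALSE)
  with_seed(seed, {
    f <- if (spectrum == "beta") stats::rbeta(n_loci, shape1, shape2)
         else stats::runif(n_loci)
    f <- pmin(pmax(f, 0.001), 0.999)
    a1 <- sample(VALID_BASES, n_loci, replace = TRUE)
    shift <- sample.int(3L, n_loci, replace = TRUE)
    a2 <- VALID_BASES[(match(a1, VALID_BASES) - 1L + shift) %% 4L + 1L]
    chrom <- as.character(sort(sample.int(22L, n_loci, replace = TRUE)))
    pos <- stats::ave(seq_len(n_loci), chrom, FUN = function(i)
      cumsum(sample.int(10000L, length(i), replace = TRUE)))
    freq_panel(chrom, pos, paste(chrom, pos, sep = "_"), a1, a2, f)
  })
}

#' Generate a pseudo-haploid cohort with known relatedness truth
#'
#' Builds single-allele genotypes over a panel for a set of individuals.
#' Pairs listed in `pairs` are generated with [simulate_pair()] semantics at
#' their specified IBD-copy probability `k`; `extra_ids` individuals (and
#' each pair's first member) draw independently from the panel frequencies.
#' Calls are then masked to missing independently per individual at
#' `missing_rate`.
#'
#' @param panel a [freq_panel()].
#' @param pairs data frame with columns `id_x`, `id_y`, `k`; an individual
#'   may appear in at most one pair (a repeated pair or id with conflicting
#'   `k` is contradictory and rejected).
#' @param extra_ids additional unrelated singleton individual ids.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return list with `calls` (character matrix, loci x individuals), `truth`
#'   (the `pairs` data frame) and `panel`.
#' @export
gen_cohort <- function(panel, pairs, extra_ids = character(),
                       missing_rate = 0, seed = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("id_x", "id_y", "k") %in% names(pairs)))
  ids <- c(rbind(pairs$id_x, pairs$id_y), extra_ids)
  if (anyDuplicated(ids))
    stop("contradictory pair spec: individual listed more than once: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  with_seed(seed, {
    calls <- matrix(NA_character_, nrow(panel), length(ids),
                    dimnames = list(panel$id, ids))
    for (i in seq_len(nrow(pairs))) {
      fl <- sim_pair_flags(panel$freq1, pairs$k[i])
      calls[, pairs$id_x[i]] <- ifelse(fl$x1, panel$allele1, panel$allele2)
      calls[, pairs$id_y[i]] <- ifelse(fl$y1, panel$allele1, panel$allele2)
    }
    for (id in extra_ids) {
      x1 <- stats::runif(nrow(panel)) < panel$freq1
      calls[, id] <- ifelse(x1, panel$allele1, panel$allele2)
    }
    if (missing_rate > 0)
      calls[matrix(stats::runif(length(calls)) < missing_rate,
                   nrow(calls))] <- NA_character_
    list(calls = calls, truth = pairs, panel = panel)
  })
}

#' Generate samtools-mpileup-style text for one individual
#'
#' Emits one pileup line per covered panel locus: read depth is
#' Poisson(`depth_mean`); each read's base equals the individual's call
#' except with probability `error_rate`, in which case it is a uniformly
#' random other base. The panel's `allele1` plays the reference base, so
#' matching reads are written as `.`, mismatches as explicit letters. Base
#' qualities are fixed at Q41 (above any conventional floor); loci with zero
#' reads or a missing call produce no line, mimicking real ultra-low-coverage
#' pileups.
#'
#' @param calls named character vector of one individual's calls (`NA`
#'   missing), names being panel SNP ids.
#' @param panel a [freq_panel()].
#' @param depth_mean mean read depth per locus (> 0).
#' @param error_rate per-read base error probability in `[0, 0.25]`.
#' @param seed optional integer seed.
#' @return character vector of pileup lines.
#' @export
gen_pileup <- function(calls, panel, depth_mean = 1, error_rate = 0,
                       seed = NULL) {
  stopifnot(inherits(panel, "freq_panel"), depth_mean > 0,
            error_rate >= 0, error_rate <= 0.25)
  pidx <- match(names(calls), panel$id)
  if (anyNA(pidx)) stop("calls contain loci absent from the panel",
                        call. = FALSE)
  with_seed(seed, {
    depth <- stats::rpois(length(calls), depth_mean)
    depth[is.na(calls)] <- 0L
    out <- character(0)
    for (i in which(depth > 0L)) {
      ref <- panel$allele1[pidx[i]]
      bases <- rep(calls[[i]], depth[i])
      err <- stats::runif(depth[i]) < error_rate
      if (any(err))
        bases[err] <- vapply(bases[err], function(b)
          sample(setdiff(VALID_BASES, b), 1L), character(1L))
      txt <- ifelse(bases == ref, ".", bases)
      out <- c(out, paste(panel$chrom[pidx[i]], panel$pos[pidx[i]], ref,
                          depth[i], paste(txt, collapse = ""),
                          strrep("J", depth[i]), sep = "\t"))
    }
    out
  })
}
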
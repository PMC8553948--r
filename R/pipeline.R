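# End-to-end orchestration: calling (if starting from pileups), exhaustive
# pairwise estimation, classification, tiering, optional normalization and
# posteriors, TSV report.

#' Run the full pairwise-relatedness pipeline
#'
#' Resolves per-individual pseudo-haploid calls (from pileup files, a PLINK
#' text prefix, or an in-memory call matrix — PLINK or matrix input skips the
#' calling stage entirely), then estimates the HRC for every pair of
#' individuals, classifies it and attaches a confidence tier. Optionally
#' normalizes against known-unrelated pairs and attaches posterior class
#' probabilities from simulated distributions. Pairs with zero overlapping
#' SNPs are reported as `NA` with a warning; the run continues.
#'
#' @param pileups named character vector of pileup file paths (names are
#'   individual ids); mutually exclusive with `plink` / `calls`.
#' @param plink PLINK text path prefix (.ped/.map or .tped/.tfam).
#' @param calls character matrix of calls (loci x individuals).
#' @param panel a [freq_panel()] or path to a .frq file.
#' @param mode multilocus combination, see [pairwise_hrc()].
#' @param min_base_quality phred floor for pileup calling.
#' @param seed integer seed covering calling randomness; recorded in the
#'   report header.
#' @param known_unrelated optional data frame (`id_x`, `id_y`) of pairs known
#'   to be unrelated, for [normalize_unrelated()].
#' @param distributions optional [build_distributions()] result; when given,
#'   posterior class probabilities are appended per pair.
#' @param out optional report path; the TSV body is preceded by `#` header
#'   lines recording seed and panel size.
#' @return the report data frame, sorted by `hrc` descending (`NA` rows
#'   last), invisibly when `out` is given.
#' @export
run_relate <- function(pileups = NULL, plink = NULL, calls = NULL, panel,
                       mode = "mean_of_ratios", min_base_quality = 30,
                       seed = NULL, known_unrelated = NULL,
                       distributions = NULL, out = NULL) {
  if (is.character(panel)) panel <- read_freq_panel(panel)
  stopifnot(inherits(panel, "freq_panel"))
  if (sum(!vapply(list(pileups, plink, calls), is.null, logical(1L))) != 1L)
    stop("provide exactly one of pileups, plink or calls", call. = FALSE)
  if (!is.null(pileups)) {
    if (is.null(names(pileups)) || any(!nzchar(names(pileups))))
      stop("pileups must be a named vector (names are individual ids)",
           call. = FALSE)
    calls <- with_seed(seed, {
      m <- vapply(pileups, function(p)
        call_pileup(p, panel, min_base_quality), character(nrow(panel)))
      rownames(m) <- panel$id
      m
    })
  } else if (!is.null(plink)) {
    calls <- read_plink(plink, panel, seed = seed)
  }
  ids <- colnames(calls)
  if (length(ids) < 2L)
    stop("need at least 2 individuals, got ", length(ids), call. = FALSE)

  combos <- utils::combn(ids, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(j) {
    ix <- combos[1L, j]; iy <- combos[2L, j]
    tryCatch(
      pairwise_hrc(calls[, ix], calls[, iy], panel, mode = mode,
                   id_x = ix, id_y = iy),
      error = function(e) {
        warning("pair ", ix, "-", iy, ": ", conditionMessage(e),
                call. = FALSE)
        data.frame(id_x = ix, id_y = iy, n_snps = 0L, hrc = NA_real_,
                   class_label = NA_character_,
                   confidence_tier = NA_character_,
                   stringsAsFactors = FALSE)
      })
  })
  report <- do.call(rbind, rows)
  report <- report[order(-report$hrc, report$id_x, report$id_y,
                         na.last = TRUE), , drop = FALSE]
  rownames(report) <- NULL
  if (!is.null(known_unrelated))
    report <- normalize_unrelated(report, known_unrelated)
  if (!is.null(distributions)) {
    post <- t(vapply(seq_len(nrow(report)), function(i) {
      if (is.na(report$hrc[i])) return(rep(NA_real_, 3L))
      suppressMessages(
        posterior_hrc(report$hrc[i], report$n_snps[i], distributions))
    }, numeric(3L)))
    colnames(post) <- paste0("p_", c("unrelated", "second_degree",
                                     "first_degree"))
    report <- cbind(report, post)
  }
  if (!is.null(out)) {
    con <- file(out, "w")
    on.exit(close(con))
    writeLines(c(paste0("# lcrelate pairwise report"),
                 paste0("# seed: ", seed %||% "none"),
                 paste0("# panel_loci: ", nrow(panel))), con)
    utils::write.table(report, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(report))
  }
  report
}
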
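# PLINK text genotype input/output and pseudo-haploidization.
#
# Supported layouts: .ped/.map (one row per individual) and .tped/.tfam
# (one row per locus). Genotypes may be diploid; "0" is the missing code.
# Homozygous genotypes collapse to one allele; heterozygous genotypes are
# pseudo-haploidized by a seeded random single-allele draw (count reported).
# Alleles that match neither panel allele at a locus become missing.

#' Read PLINK text genotypes as pseudo-haploid calls
#'
#' @param prefix path prefix: `<prefix>.ped` + `<prefix>.map`, or
#'   `<prefix>.tped` + `<prefix>.tfam` (auto-detected, tped preferred).
#' @param panel a [freq_panel()]; loci absent from the panel are dropped with
#'   a message, alleles foreign to the panel's two become missing.
#' @param seed optional seed for heterozygote resolution.
#' @return character matrix of single-allele calls, loci (panel ids) in rows,
#'   individuals in columns; `NA` is missing.
#' @export
read_plink <- function(prefix, panel, seed = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  if (file.exists(paste0(prefix, ".tped"))) {
    g <- read_tped_raw(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    g <- read_ped_raw(prefix)
  } else {
    stop("no .tped or .ped file found for prefix: ", prefix, call. = FALSE)
  }
  in_panel <- g$loci %in% panel$id
  if (any(!in_panel))
    message(sum(!in_panel), " loci absent from the panel dropped")
  if (!any(in_panel)) stop("no loci shared with the panel", call. = FALSE)
  a1 <- g$a1[in_panel, , drop = FALSE]
  a2 <- g$a2[in_panel, , drop = FALSE]
  loci <- g$loci[in_panel]
  pidx <- match(loci, panel$id)

  with_seed(seed, {
    miss <- a1 == "0" | a2 == "0"
    het <- !miss & a1 != a2
    if (any(het)) {
      message(sum(het), " heterozygous genotypes pseudo-haploidized at random")
      take1 <- matrix(stats::runif(length(a1)) < 0.5, nrow(a1))
      a1[het & !take1] <- a2[het & !take1]
    }
    calls <- a1
    calls[miss] <- NA_character_
    ok <- calls == panel$allele1[pidx] | calls == panel$allele2[pidx]
    calls[!is.na(calls) & !ok] <- NA_character_
    rownames(calls) <- loci
    colnames(calls) <- g$ids
    calls
  })
}

read_tped_raw <- function(prefix) {
  tped <- readLines(paste0(prefix, ".tped"), warn = FALSE)
  tfam <- read_ws_table(paste0(prefix, ".tfam"))
  ids <- tfam[[2L]]
  rows <- strsplit(trimws(tped[nzchar(tped)]), "[ \t]+")
  nfield <- lengths(rows)
  expect <- 4L + 2L * length(ids)
  if (any(nfield != expect))
    stop("tped line ", which(nfield != expect)[1L],
         ": expected 2 alleles per individual per locus (",
         expect, " fields, got ", nfield[nfield != expect][1L], ")",
         call. = FALSE)
  m <- t(vapply(rows, identity, character(expect)))
  ai <- 4L + seq_len(length(ids)) * 2L - 1L
  list(loci = m[, 2L], ids = ids,
       a1 = toupper(m[, ai, drop = FALSE]),
       a2 = toupper(m[, ai + 1L, drop = FALSE]))
}

read_ped_raw <- function(prefix) {
  map <- read_ws_table(paste0(prefix, ".map"))
  loci <- map[[2L]]
  ped <- readLines(paste0(prefix, ".ped"), warn = FALSE)
  rows <- strsplit(trimws(ped[nzchar(ped)]), "[ \t]+")
  expect <- 6L + 2L * length(loci)
  nfield <- lengths(rows)
  if (any(nfield != expect))
    stop("ped line ", which(nfield != expect)[1L],
         ": expected 2 alleles per locus per individual (",
         expect, " fields, got ", nfield[nfield != expect][1L], ")",
         call. = FALSE)
  m <- t(vapply(rows, identity, character(expect)))
  ai <- 6L + seq_along(loci) * 2L - 1L
  list(loci = loci, ids = m[, 2L],
       a1 = t(toupper(m[, ai, drop = FALSE])),
       a2 = t(toupper(m[, ai + 1L, drop = FALSE])))
}

read_ws_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Write pseudo-haploid calls as PLINK transposed text (.tped/.tfam)
#'
#' Pseudo-haploid calls are written as homozygous diploid genotypes (the
#' conventional encoding); missing calls as `0 0`. Only panel loci present in
#' the call matrix are written.
#'
#' @param calls character matrix (loci x individuals) as from [read_plink()]
#'   or [call_pileup()] columns; or a named vector for one individual.
#' @param panel a [freq_panel()] supplying chrom/pos per locus.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_tped <- function(calls, panel, prefix) {
  stopifnot(inherits(panel, "freq_panel"))
  if (is.null(dim(calls)))
    calls <- matrix(calls, ncol = 1L,
                    dimnames = list(names(calls), "IND1"))
  pidx <- match(rownames(calls), panel$id)
  if (anyNA(pidx)) stop("call matrix contains loci absent from the panel",
                        call. = FALSE)
  geno <- calls
  geno[is.na(geno)] <- "0"
  pairs <- matrix("", nrow(geno), 2L * ncol(geno))
  pairs[, seq_len(ncol(geno)) * 2L - 1L] <- geno
  pairs[, seq_len(ncol(geno)) * 2L] <- geno
  body <- cbind(panel$chrom[pidx], rownames(calls), "0",
                as.character(panel$pos[pidx]), pairs)
  writeLines(apply(body, 1L, paste, collapse = " "),
             paste0(prefix, ".tped"))
  fam <- cbind(colnames(calls), colnames(calls), "0", "0", "0", "-9")
  writeLines(apply(fam, 1L, paste, collapse = " "),
             paste0(prefix, ".tfam"))
  invisible(prefix)
}

#' Randomly subsample an individual's non-missing calls
#'
#' Keeps a uniformly random subset (without replacement) of `n` of the
#' non-missing calls and sets all other loci to missing. Deterministic per
#' seed. Used to emulate lower-coverage versions of an individual.
#'
#' @param calls named character vector of single-allele calls (`NA` missing).
#' @param n number of calls to keep; must not exceed the non-missing count.
#' @param seed optional integer seed.
#' @return vector of the same length and names with only `n` calls retained.
#' @export
subsample_loci <- function(calls, n, seed = NULL) {
  nm <- which(!is.na(calls))
  if (n > length(nm))
    stop("cannot keep ", n, " calls: only ", length(nm), " are non-missing",
         call. = FALSE)
  keep <- with_seed(seed, nm[sample.int(length(nm), n)])
  out <- calls
  out[setdiff(nm, keep)] <- NA_character_
  out
}
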
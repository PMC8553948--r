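#' Construct a frequency panel
#'
#' A frequency panel is the population reference for the relatedness
#' estimator: a set of strictly biallelic, non-fixed SNPs with the population
#' frequency of one of the two alleles. It is stored as a data frame with
#' columns `chrom`, `pos`, `id`, `allele1`, `allele2`, `freq1` and class
#' `freq_panel`.
#'
#' @param chrom chromosome labels.
#' @param pos 1-based positions.
#' @param id SNP identifier strings, unique within the panel.
#' @param allele1,allele2 single bases in A/C/G/T; must differ per locus.
#' @param freq1 frequency of `allele1`, strictly inside (0, 1).
#' @return a `freq_panel` data frame.
#' @export
freq_panel <- function(chrom, pos, id, allele1, allele2, freq1) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   id = as.character(id),
                   allele1 = as.character(allele1),
                   allele2 = as.character(allele2),
                   freq1 = as.numeric(freq1),
                   stringsAsFactors = FALSE)
  validate_panel(df)
}

validate_panel <- function(df) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) stop("empty panel", call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate SNP id in panel: ",
         paste(utils::head(unique(df$id[duplicated(df$id)]), 3L),
               collapse = ", "), call. = FALSE)
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) in panel", call. = FALSE)
  bad_allele <- !(df$allele1 %in% VALID_BASES) |
    !(df$allele2 %in% VALID_BASES) | df$allele1 == df$allele2
  if (any(bad_allele))
    stop(sum(bad_allele), " loci are not strictly biallelic SNPs",
         call. = FALSE)
  if (any(!is.finite(df$freq1)) || any(df$freq1 <= 0) || any(df$freq1 >= 1))
    stop("freq1 must be strictly inside (0, 1) for every retained locus",
         call. = FALSE)
  class(df) <- c("freq_panel", "data.frame")
  df
}

#' Read a PLINK-style .frq allele-frequency file
#'
#' Expects whitespace-delimited columns `CHR SNP A1 A2 MAF NCHROBS` (the
#' PLINK .frq dialect; `NCHROBS` optional), where `MAF` is interpreted as the
#' frequency of `A1`. Loci that are fixed (frequency 0 or 1) or whose alleles
#' are not single A/C/G/T bases (e.g. indel codes `I`/`D`) are dropped with a
#' message reporting how many were removed. Positions are taken from a `POS`
#' column when present, otherwise parsed from SNP ids of the form
#' `<chrom>_<pos>`; ids in any other shape get `NA` positions (such a panel
#' still works for PLINK-format input, but not for pileup calling, which
#' matches sites by chromosome and position).
#'
#' @param path path to the .frq file.
#' @return a [freq_panel()] of the retained loci.
#' @export
read_freq_panel <- function(path) {
  if (!file.exists(path)) stop("frequency file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("frequency file has no data rows: ", path,
                               call. = FALSE)
  header <- toupper(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
  need <- c("CHR", "SNP", "A1", "A2", "MAF")
  if (!all(need %in% header))
    stop("frequency file header must contain columns ",
         paste(need, collapse = " "), call. = FALSE)
  idx <- match(need, header)
  pos_col <- match("POS", header)
  rows <- strsplit(trimws(lines[-1L]), "[ \t]+")
  nfield <- lengths(rows)
  bad <- which(nfield < max(c(idx, pos_col), na.rm = TRUE))
  if (length(bad))
    stop("malformed frequency line ", bad[1L] + 1L, ": ",
         lines[bad[1L] + 1L], call. = FALSE)
  cols <- c(idx, if (!is.na(pos_col)) pos_col)
  mat <- t(vapply(rows, function(r) r[cols], character(length(cols))))
  chrom <- mat[, 1L]
  id <- mat[, 2L]
  a1 <- toupper(mat[, 3L])
  a2 <- toupper(mat[, 4L])
  freq1 <- suppressWarnings(as.numeric(mat[, 5L]))
  if (anyNA(freq1)) {
    bad <- which(is.na(freq1))[1L]
    stop("malformed frequency line ", bad + 1L, ": non-numeric MAF",
         call. = FALSE)
  }
  if (anyDuplicated(id))
    stop("duplicate SNP id in frequency file: ",
         id[duplicated(id)][1L], call. = FALSE)
  if (!is.na(pos_col)) {
    pos <- suppressWarnings(as.integer(mat[, 6L]))
  } else {
    pos <- suppressWarnings(as.integer(sub("^.*_([0-9]+)$", "\\1", id)))
    pos[!grepl("^.+_[0-9]+$", id)] <- NA_integer_
  }

  snp_ok <- a1 %in% VALID_BASES & a2 %in% VALID_BASES & a1 != a2
  if (any(!snp_ok))
    message(sum(!snp_ok), " non-biallelic-SNP loci dropped from panel")
  fixed <- snp_ok & (freq1 <= 0 | freq1 >= 1)
  if (any(fixed))
    message(sum(fixed), " fixed loci (freq 0 or 1) dropped from panel")
  keep <- snp_ok & !fixed
  if (!any(keep)) stop("no loci left in panel after filtering", call. = FALSE)
  validate_panel(data.frame(chrom = chrom[keep], pos = pos[keep],
                            id = id[keep], allele1 = a1[keep],
                            allele2 = a2[keep], freq1 = freq1[keep],
                            stringsAsFactors = FALSE))
}

#' Write a frequency panel as a PLINK-style .frq file
#'
#' Columns written are `CHR SNP A1 A2 MAF NCHROBS`, with `MAF` the frequency
#' of `A1` and a nominal `NCHROBS`. Reading the file back with
#' [read_freq_panel()] recovers the panel exactly (positions round-trip
#' through `<chrom>_<pos>` SNP ids; for other id shapes a `POS` column is
#' added).
#'
#' @param panel a [freq_panel()].
#' @param path output path.
#' @param nchrobs nominal observed-chromosome count column.
#' @return `path`, invisibly.
#' @export
write_freq_panel <- function(panel, path, nchrobs = 1000L) {
  stopifnot(inherits(panel, "freq_panel"))
  encodes_pos <- all(!is.na(panel$pos)) &&
    all(panel$id == paste(panel$chrom, panel$pos, sep = "_"))
  df <- data.frame(CHR = panel$chrom, SNP = panel$id, A1 = panel$allele1,
                   A2 = panel$allele2, MAF = panel$freq1,
                   NCHROBS = nchrobs, stringsAsFactors = FALSE)
  if (!encodes_pos) df$POS <- panel$pos
  utils::write.table(df, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Frequencies of arbitrary alleles at given loci: freq1 for allele1 carriers,
# 1 - freq1 for allele2 carriers, NA otherwise.
allele_freq <- function(panel, locus_idx, allele) {
  f <- ifelse(allele == panel$allele1[locus_idx], panel$freq1[locus_idx],
              ifelse(allele == panel$allele2[locus_idx],
                     1 - panel$freq1[locus_idx], NA_real_))
  f
}
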
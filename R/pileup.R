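# samtools mpileup text handling and random pseudo-haploid calling.
#
# A pileup line is: chrom, 1-based pos, ref base, depth, base string, quality
# string (tab-separated). The base string uses "." / "," for reference
# matches, explicit letters for mismatches, "^X" read starts (X is mapping
# quality, skipped), "$" read ends, "+n<seq>"/"-n<seq>" indels (skipped), and
# "*"/"#" deletion placeholders (consume a quality, never called).

# Decode one base-column string into per-read bases aligned with quality
# characters. Returns uppercase bases; deletion placeholders become NA.
decode_pileup_bases <- function(bases, ref) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                      # caret + mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len                     # skip inserted/deleted sequence
    } else if (ch == "." || ch == ",") {
      out <- c(out, toupper(ref)); i <- i + 1L
    } else if (ch %in% c("*", "#")) {
      out <- c(out, NA_character_); i <- i + 1L
    } else {
      out <- c(out, toupper(ch)); i <- i + 1L
    }
  }
  out
}

parse_pileup_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 6L)
    stop("unparseable pileup line: ", line, call. = FALSE)
  depth <- suppressWarnings(as.integer(f[4L]))
  pos <- suppressWarnings(as.integer(f[2L]))
  if (is.na(depth) || is.na(pos))
    stop("unparseable pileup line: ", line, call. = FALSE)
  list(chrom = f[1L], pos = pos, ref = f[3L], depth = depth,
       bases = f[5L], quals = f[6L])
}

#' Random pseudo-haploid call from one pileup line
#'
#' Decodes the read bases, drops those below the base-quality floor or not
#' matching either panel allele at the site, and picks one survivor uniformly
#' at random as the individual's single-allele (pseudo-haploid) call.
#'
#' @param pileup_line one line of samtools mpileup text.
#' @param panel a [freq_panel()]; the site is matched by (chrom, pos), with a
#'   warning if the ref base matches neither panel allele.
#' @param min_base_quality phred floor below which read bases are discarded.
#' @param seed optional integer seed for the uniform pick.
#' @return a list with `id` (panel SNP id) and `allele` (single base, or
#'   `NA` when no read survives filtering); `NULL` when the position is not
#'   in the panel.
#' @export
call_pseudo_haploid <- function(pileup_line, panel, min_base_quality = 30,
                                seed = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  rec <- parse_pileup_line(pileup_line)
  hit <- which(panel$chrom == rec$chrom & panel$pos == rec$pos)
  if (length(hit) == 0L) return(NULL)
  hit <- hit[1L]
  with_seed(seed, call_at_site(rec, panel, hit, min_base_quality))
}

call_at_site <- function(rec, panel, hit, min_base_quality) {
  alleles <- c(panel$allele1[hit], panel$allele2[hit])
  if (rec$depth == 0L || !nzchar(rec$bases))
    return(list(id = panel$id[hit], allele = NA_character_))
  b <- decode_pileup_bases(rec$bases, rec$ref)
  q <- utf8ToInt(rec$quals) - 33L
  if (length(b) != length(q))
    stop("unparseable pileup line (base/quality length mismatch): ",
         paste(rec$chrom, rec$pos), call. = FALSE)
  keep <- !is.na(b) & q >= min_base_quality & b %in% alleles
  if (!any(keep)) return(list(id = panel$id[hit], allele = NA_character_))
  surv <- b[keep]
  pick <- if (length(surv) == 1L) surv else surv[sample.int(length(surv), 1L)]
  list(id = panel$id[hit], allele = pick)
}

#' Pseudo-haploid calling over a whole pileup file
#'
#' Applies [call_pseudo_haploid()] to every line of a pileup file (or a
#' character vector of lines) and assembles the calls into a vector over the
#' panel's loci. Positions not in the panel are skipped silently; panel loci
#' with no covered line are `NA` (missing).
#'
#' @inheritParams call_pseudo_haploid
#' @param pileup path to a pileup text file, or a character vector of lines.
#' @return named character vector over `panel$id`: the called allele or `NA`.
#' @export
call_pileup <- function(pileup, panel, min_base_quality = 30, seed = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  lines <- if (length(pileup) == 1L && file.exists(pileup))
    readLines(pileup, warn = FALSE) else pileup
  lines <- lines[nzchar(lines)]
  calls <- stats::setNames(rep(NA_character_, nrow(panel)), panel$id)
  site_key <- paste(panel$chrom, panel$pos)
  with_seed(seed, {
    for (ln in lines) {
      rec <- parse_pileup_line(ln)
      hit <- match(paste(rec$chrom, rec$pos), site_key)
      if (is.na(hit)) next
      res <- call_at_site(rec, panel, hit, min_base_quality)
      calls[[res$id]] <- res$allele
    }
  })
  calls
}
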
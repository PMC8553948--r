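# Small deterministic panels and call vectors used across test files.

# Panel with fixed alleles A (allele1) / G (allele2) at every locus.
ag_panel <- function(freqs) {
  n <- length(freqs)
  freq_panel(chrom = rep("1", n), pos = seq_len(n),
             id = paste0("1_", seq_len(n)),
             allele1 = rep("A", n), allele2 = rep("G", n), freq1 = freqs)
}

# Named call vector over a panel's loci.
calls_on <- function(panel, alleles) {
  stats::setNames(as.character(alleles), panel$id[seq_along(alleles)])
}

# Brute-force Queller-Goodnight per-locus value, written independently of
# the package's implementation (indicator sums spelled out).
qg_brute <- function(a, b, c, d, p) {
  I <- function(u, v) as.numeric(u == v)
  num <- 0.5 * (I(a, c) + I(a, d) + I(b, c) + I(b, d)) - p[[a]] - p[[b]]
  den <- 1 + I(a, b) - p[[a]] - p[[b]]
  num / den
}

write_frq_lines <- function(path, lines) {
  writeLines(c("CHR SNP A1 A2 MAF NCHROBS", lines), path)
  path
}
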
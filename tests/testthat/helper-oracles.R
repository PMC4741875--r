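# Independent brute-force oracles, deliberately naive: each one literally
# constructs the object the implementation only reasons about.

# CpG classification by building both trinucleotide strings and searching
# for the literal "CG".
oracle_classify <- function(left, allele_a, allele_b, right) {
  has <- function(center) grepl("CG", paste0(left, center, right),
                                fixed = TRUE)
  a <- has(allele_a); b <- has(allele_b)
  if (a && b) "CG_SHIFT" else if (a || b) "CG_POLYMORPHIC" else "NON_CG"
}

# Per-base distance scan over a toy chromosome. islands: data.frame with
# 0-based half-open start/end. Returns one label per position 0..(len-1).
oracle_region_scan <- function(islands, len, shore_width) {
  labels <- rep("OPEN_SEA", len)
  for (pos in 0:(len - 1L)) {
    d <- Inf
    for (i in seq_len(nrow(islands))) {
      s <- islands$start[i]; e <- islands$end[i]
      d <- min(d, if (pos >= s && pos < e) 0 else if (pos < s) s - pos
               else pos - (e - 1L))
    }
    labels[pos + 1L] <- if (d == 0) "ISLAND" else if (d <= shore_width)
      "SHORE" else "OPEN_SEA"
  }
  labels
}

# Bernoulli log-likelihood of the enrichment model, for a generic-optimizer
# cross-check of the glm fit.
enrichment_loglik <- function(beta, y, x_cgsnpt, x_maf, x_tags) {
  lp <- beta[1] + beta[2] * x_cgsnpt + beta[3] * x_maf + beta[4] * x_tags
  sum(y * lp - log1p(exp(lp)))
}

# Small fully in-memory fixture builders --------------------------------

make_snp_row <- function(snp_id = "rs1", chrom = "chr1", pos = 100L,
                         strand = "+", allele_a = "C", allele_b = "T",
                         ancestral = "C", maf = 0.2,
                         flank5 = "AAAAC", flank3 = "GAAAA") {
  data.table::data.table(snp_id = snp_id, chrom = chrom, pos = pos,
                         strand = strand, allele_a = allele_a,
                         allele_b = allele_b, ancestral = ancestral,
                         maf = maf, flank5 = flank5, flank3 = flank3)
}

# reverse-complement an entire SNP record (alleles, ancestral, flanks
# complemented; flanks swapped)
rc_snp_row <- function(row) {
  out <- data.table::copy(row)
  out$allele_a <- complement_bases(row$allele_a)
  out$allele_b <- complement_bases(row$allele_b)
  out$ancestral <- ifelse(is.na(row$ancestral), NA_character_,
                          complement_bases(row$ancestral))
  out$flank5 <- reverse_complement(row$flank3)
  out$flank3 <- reverse_complement(row$flank5)
  out$strand <- ifelse(row$strand == "+", "-", "+")
  out
}
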
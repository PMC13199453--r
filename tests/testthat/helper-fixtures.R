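# Hand-built fixtures used across test files.

# A deterministic panel: `spans` is a list of per-locus SNP position vectors,
# `chroms` the chromosome of each locus; uniform map at `cm_per_mb` unless a
# map is supplied.
toy_panel <- function(spans, chroms, cm_per_mb = 1, genetic_map = NULL,
                      chrom_len = 30e6) {
  n <- length(spans)
  loci <- data.frame(
    locus_id = sprintf("L%04d", seq_len(n)),
    chrom = as.integer(chroms),
    start = vapply(spans, function(p) as.integer(min(p)), integer(1)),
    end = vapply(spans, function(p) as.integer(max(p)), integer(1)),
    n_snps = vapply(spans, length, integer(1)))
  snps <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(locus_id = loci$locus_id[i], chrom = loci$chrom[i],
               pos = as.integer(spans[[i]]),
               oceanic_allele = "A", freshwater_allele = "T")
  }))
  if (is.null(genetic_map)) {
    genetic_map <- do.call(rbind, lapply(unique(loci$chrom), function(ch) {
      data.frame(chrom = ch, pos = c(1, chrom_len),
                 cM = c(0, chrom_len * cm_per_mb / 1e6))
    }))
  }
  new_locus_panel(loci, snps, genetic_map)
}

# dosage matrix wrapped as a complete genotype_matrix over a panel
toy_matrix <- function(dosage, panel, samples = NULL) {
  m <- as.matrix(dosage)
  storage.mode(m) <- "integer"
  rownames(m) <- if (is.null(samples)) sprintf("s%02d", seq_len(nrow(m)))
                 else samples
  colnames(m) <- panel$loci$locus_id[seq_len(ncol(m))]
  structure(m, class = c("genotype_matrix", class(m)))
}

# brute-force three-state likelihood of a set of per-SNP read counts,
# multiplying per-read emission probabilities directly (no logs, no
# count shortcuts): the independent oracle for the caller
oracle_call <- function(counts, e_b, min_snps = 3L) {
  # counts: data.frame n_fw, n_oc, n_other (one row per SNP)
  lik <- vapply(c(0, 1, 2), function(g) {
    p_fw <- (g / 2) * (1 - e_b) + (1 - g / 2) * (e_b / 3)
    p_oc <- (g / 2) * (e_b / 3) + (1 - g / 2) * (1 - e_b)
    prod(vapply(seq_len(nrow(counts)), function(i) {
      p_fw^counts$n_fw[i] * p_oc^counts$n_oc[i] * (e_b / 3)^counts$n_other[i]
    }, numeric(1)))
  }, numeric(1))
  covered <- sum(rowSums(counts) > 0)
  if (covered < min_snps) return(NA_character_)
  top <- which(lik == max(lik))
  if (length(top) != 1L) return(NA_character_)
  c("OO", "HET", "FF")[top]
}
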
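#' Simulate low-coverage per-SNP pileups
#'
#' Emulates the read data behind sparse (~0.4-1.8x) whole-genome sequencing
#' at panel SNPs. Per individual and SNP the read count is
#' Poisson(`mean_coverage`); each read carries the freshwater allele with
#' probability g/2 for truth dosage g, and is then perturbed by a four-base
#' error model: the emitted base equals the carried allele with probability
#' 1 - e and each of the three other bases with probability e/3 (so reads
#' matching neither panel allele appear with probability 2e/3 and are
#' recorded as "other"). Phred base and mapping qualities are emitted per
#' read class so caller-side quality filters are exercised; an optional
#' fraction of reads is emitted as a low-quality class (BQ 10, MQ 20,
#' generated at its own higher error rate) that default filters remove.
#'
#' @param truth a `truth_genotypes`.
#' @param panel the `locus_panel` the truth was generated over.
#' @param mean_coverage mean reads per SNP per individual (> 0).
#' @param base_error per-base error probability of good reads, in (0, 1);
#'   emitted BQ is its phred equivalent.
#' @param mapping_error mapping error probability of good reads, in (0, 1);
#'   emitted MQ is its phred equivalent.
#' @param low_qual_frac fraction of reads emitted in the low-quality class.
#' @param low_qual_base_error base-error rate of the low-quality class.
#' @param seed integer seed.
#' @return data.frame pileup dialect: sample, locus_id, chrom, pos, n_fw,
#'   n_oc, n_other, BQ, MQ (one row per individual x SNP x quality class
#'   with at least one read).
#' @export
simulate_pileups <- function(truth, panel, mean_coverage = 1,
                             base_error = 0.001, mapping_error = 1e-4,
                             low_qual_frac = 0, low_qual_base_error = 0.1,
                             seed = 1L) {
  stopifnot(mean_coverage > 0,
            base_error > 0, base_error < 1,
            mapping_error > 0, mapping_error < 1,
            low_qual_frac >= 0, low_qual_frac < 1)
  if (!identical(colnames(truth$dosage), panel$loci$locus_id))
    stop("truth loci do not match the panel")
  set.seed(seed)
  snps <- panel$snps
  n_ind <- nrow(truth$dosage)
  n_snp <- nrow(snps)
  locus_col <- match(snps$locus_id, panel$loci$locus_id)

  # expand to the individual x SNP grid
  ind <- rep(seq_len(n_ind), each = n_snp)
  snp <- rep(seq_len(n_snp), times = n_ind)
  g <- truth$dosage[cbind(ind, locus_col[snp])]
  n_reads <- stats::rpois(length(g), mean_coverage)

  emit_class <- function(n, g, e) {
    # reads carrying fw allele ~ Binomial(n, g/2); each read then kept or
    # perturbed under the four-base model
    fw_src <- stats::rbinom(length(n), n, g / 2)
    oc_src <- n - fw_src
    # a fw-source read is observed as fw w.p. 1-e, as oc w.p. e/3, other 2e/3
    fw_keep <- stats::rbinom(length(n), fw_src, 1 - e)
    fw_to_oc <- stats::rbinom(length(n), fw_src - fw_keep, 1 / 3)
    oc_keep <- stats::rbinom(length(n), oc_src, 1 - e)
    oc_to_fw <- stats::rbinom(length(n), oc_src - oc_keep, 1 / 3)
    data.frame(n_fw = fw_keep + oc_to_fw, n_oc = oc_keep + fw_to_oc,
               n_other = n - fw_keep - oc_to_fw - oc_keep - fw_to_oc)
  }

  n_low <- if (low_qual_frac > 0) stats::rbinom(length(n_reads), n_reads, low_qual_frac)
           else integer(length(n_reads))
  n_good <- n_reads - n_low

  base <- data.frame(sample = rownames(truth$dosage)[ind],
                     locus_id = snps$locus_id[snp], chrom = snps$chrom[snp],
                     pos = snps$pos[snp], stringsAsFactors = FALSE)
  phred <- function(p) as.integer(round(-10 * log10(p)))
  good <- cbind(base, emit_class(n_good, g, base_error),
                BQ = phred(base_error), MQ = phred(mapping_error))
  out <- good[n_good > 0, , drop = FALSE]
  if (any(n_low > 0)) {
    low <- cbind(base, emit_class(n_low, g, low_qual_base_error),
                 BQ = 10L, MQ = 20L)
    out <- rbind(out, low[n_low > 0, , drop = FALSE])
  }
  rownames(out) <- NULL
  out[order(out$sample, out$chrom, out$pos, out$BQ), ]
}

#' Read and write pileup tables
#'
#' The flat pileup dialect round-trips exactly through TSV. A minimal VCF
#' rendering with per-sample AD (allele depth, freshwater then oceanic then
#' other) is also provided for interoperability; reading it back requires
#' the vcfR package.
#'
#' @param pileups pileup data.frame from [simulate_pileups()].
#' @param path file path.
#' @export
write_pileups <- function(pileups, path) {
  utils::write.table(pileups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileups
#' @export
read_pileups <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname write_pileups
#' @param panel the `locus_panel` (for allele labels).
#' @export
write_pileups_vcf <- function(pileups, panel, path) {
  key <- paste(pileups$chrom, pileups$pos)
  snp_key <- paste(panel$snps$chrom, panel$snps$pos)
  samples <- sort(unique(pileups$sample))
  agg <- function(col) {
    m <- matrix(0L, length(snp_key), length(samples),
                dimnames = list(snp_key, samples))
    s <- rowsum(pileups[[col]], paste(key, pileups$sample))
    ks <- strsplit(rownames(s), " ")
    i <- match(paste(vapply(ks, `[`, "", 1), vapply(ks, `[`, "", 2)), snp_key)
    j <- match(vapply(ks, `[`, "", 3), samples)
    m[cbind(i, j)] <- as.integer(s[, 1])
    m
  }
  fw <- agg("n_fw"); oc <- agg("n_oc"); ot <- agg("n_other")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (fw,oc,other)\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(snp_key), function(i) {
    ad <- paste(fw[i, ], oc[i, ], ot[i, ], sep = ",")
    paste(c(panel$snps$chrom[i], panel$snps$pos[i], ".",
            panel$snps$freshwater_allele[i], panel$snps$oceanic_allele[i],
            ".", "PASS", paste0("LOCUS=", panel$snps$locus_id[i]), "AD", ad),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_pileups
#' @param BQ,MQ quality values to stamp on rows read from VCF (the AD field
#'   carries no per-read qualities; VCF input is assumed pre-filtered).
#' @export
read_pileups_vcf <- function(path, panel, BQ = 30L, MQ = 60L) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF pileups requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  chrom <- as.integer(v@fix[, "CHROM"])
  pos <- as.integer(v@fix[, "POS"])
  locus <- sub("^LOCUS=", "", v@fix[, "INFO"])
  out <- do.call(rbind, lapply(colnames(ad), function(s) {
    parts <- do.call(rbind, lapply(strsplit(ad[, s], ","), as.integer))
    data.frame(sample = s, locus_id = locus, chrom = chrom, pos = pos,
               n_fw = parts[, 1], n_oc = parts[, 2], n_other = parts[, 3],
               BQ = BQ, MQ = MQ, stringsAsFactors = FALSE)
  }))
  out <- out[out$n_fw + out$n_oc + out$n_other > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
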
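#' Approximate genotype-likelihood calling of multi-SNP loci
#'
#' The caller assigns each individual a diploid state at each panel locus --
#' homozygous oceanic (OO), heterozygous (HET) or homozygous freshwater (FF)
#' -- from sparse per-SNP read counts. Per-SNP genotype likelihoods follow
#' the standard low-coverage model: a read base b under freshwater-allele
#' dosage g has probability
#' \deqn{P(b | g) = (g/2) P(b | fw) + (1 - g/2) P(b | oc),}
#' with \eqn{P(b | a) = 1 - e} when b matches allele a and \eqn{e/3}
#' otherwise (four-base error model). Because the SNPs within a locus are
#' tightly correlated, per-SNP log-likelihoods are summed across the locus in
#' panel orientation (allele 1 = freshwater everywhere) to give approximate
#' likelihoods of the three locus states.
#'
#' @name caller
NULL

.STATES <- c("OO", "HET", "FF")

#' Per-SNP genotype log-likelihoods from filtered read counts
#'
#' @param n_fw,n_oc,n_other read counts supporting the freshwater allele, the
#'   oceanic allele, or neither (vectors of equal length).
#' @param e_b base-call error probability of the counted reads (scalar or
#'   vector).
#' @return matrix with columns `OO`, `HET`, `FF` of log-likelihoods for
#'   dosage g = 0, 1, 2; a SNP with zero reads has the flat triple (0, 0, 0).
#' @export
snp_genotype_log_likelihoods <- function(n_fw, n_oc, n_other = 0, e_b = 0.001) {
  n <- max(length(n_fw), length(n_oc), length(n_other))
  n_fw <- rep_len(n_fw, n); n_oc <- rep_len(n_oc, n)
  n_other <- rep_len(n_other, n); e <- rep_len(e_b, n)
  stopifnot(all(n_fw >= 0), all(n_oc >= 0), all(n_other >= 0),
            all(e > 0), all(e < 1))
  ll <- sapply(c(0, 1, 2), function(g) {
    p_fw <- (g / 2) * (1 - e) + (1 - g / 2) * (e / 3)
    p_oc <- (g / 2) * (e / 3) + (1 - g / 2) * (1 - e)
    # bases matching neither allele contribute e/3 under both alleles
    n_fw * log(p_fw) + n_oc * log(p_oc) + n_other * log(e / 3)
  })
  ll <- matrix(ll, nrow = n, dimnames = list(NULL, .STATES))
  ll[n_fw + n_oc + n_other == 0, ] <- 0
  ll
}

#' Locus log-likelihoods from per-SNP triples
#'
#' @param snp_ll matrix of per-SNP log-likelihood triples (columns OO, HET,
#'   FF), all SNPs oriented to the freshwater allele.
#' @param has_reads logical per SNP (>= 1 passing read); defaults to SNPs
#'   with a non-flat triple.
#' @return a `locus_likelihoods` list: `ll` (named triple),
#'   `n_snps_with_reads`.
#' @export
locus_log_likelihoods <- function(snp_ll, has_reads = NULL) {
  snp_ll <- matrix(snp_ll, ncol = 3)
  if (is.null(has_reads)) has_reads <- rowSums(snp_ll != 0) > 0
  structure(list(ll = stats::setNames(colSums(snp_ll), .STATES),
                 n_snps_with_reads = sum(has_reads)),
            class = "locus_likelihoods")
}

#' Call one locus from its likelihood triple
#'
#' The state is the argmax of the triple, provided at least `min_snps` SNPs
#' in the locus had passing reads; an exact tie among the maxima is returned
#' as missing (no evidence to prefer a state).
#'
#' @param ll a `locus_likelihoods` (or bare named triple with attribute
#'   handling via `n_snps`).
#' @param min_snps minimum number of SNPs with reads (default 3).
#' @return `"OO"`, `"HET"`, `"FF"` or `NA_character_`.
#' @export
call_locus <- function(ll, min_snps = 3L) {
  triple <- if (inherits(ll, "locus_likelihoods")) ll$ll else ll
  n <- if (inherits(ll, "locus_likelihoods")) ll$n_snps_with_reads else min_snps
  if (n < min_snps) return(NA_character_)
  m <- max(triple)
  top <- which(triple == m)
  if (length(top) != 1L) return(NA_character_)
  .STATES[top]
}

#' Call the full sample-by-locus genotype matrix
#'
#' Applies the read filters (drop read classes with mapping or base phred
#' quality below `mq_min`/`bq_min`, the phred equivalents of mapping error
#' < 0.001 and base error < 0.01), computes per-SNP likelihoods with the
#' per-class base-error probability implied by BQ, sums within loci, and
#' calls each (sample, locus) cell; cells with fewer than `min_snps` covered
#' SNPs, or with tied likelihoods, are missing.
#'
#' @param pileups pileup data.frame (sample, locus_id, chrom, pos, n_fw,
#'   n_oc, n_other, BQ, MQ).
#' @param panel the `locus_panel`.
#' @param samples character vector fixing the row set (defaults to samples
#'   present in `pileups`).
#' @param min_snps minimum SNPs with reads per called locus (default 3).
#' @param bq_min,mq_min phred quality filters (defaults 20 and 30).
#' @return a `genotype_matrix`: integer dosage matrix (0/1/2, NA missing)
#'   with attributes `states` available via [genotype_states()] and a
#'   `filter_log` attribute recording read-filter counts.
#' @export
call_matrix <- function(pileups, panel, samples = NULL, min_snps = 3L,
                        bq_min = 20, mq_min = 30) {
  need <- c("sample", "locus_id", "pos", "n_fw", "n_oc", "n_other", "BQ", "MQ")
  if (!all(need %in% names(pileups)))
    stop("pileups must have columns: ", paste(need, collapse = ", "))
  if (!all(pileups$locus_id %in% panel$loci$locus_id))
    stop("pileups reference loci absent from the panel")
  if (is.null(samples)) samples <- sort(unique(pileups$sample))
  if (!all(pileups$sample %in% samples))
    stop("pileups contain samples outside the requested sample set")
  loci <- panel$loci$locus_id

  keep <- pileups$BQ >= bq_min & pileups$MQ >= mq_min
  n_reads_all <- pileups$n_fw + pileups$n_oc + pileups$n_other
  filter_log <- list(reads_total = sum(n_reads_all),
                     reads_failed_quality = sum(n_reads_all[!keep]),
                     rows_total = nrow(pileups), rows_kept = sum(keep))
  p <- pileups[keep & n_reads_all > 0, , drop = FALSE]

  out <- matrix(NA_integer_, length(samples), length(loci),
                dimnames = list(samples, loci))
  if (nrow(p) > 0) {
    e_b <- 10^(-p$BQ / 10)
    ll <- snp_genotype_log_likelihoods(p$n_fw, p$n_oc, p$n_other, e_b)
    cell <- paste(p$sample, p$locus_id, sep = "\r")
    ll_cell <- rowsum(ll, cell)
    # SNPs with reads per cell: count distinct positions
    snp_key <- paste(cell, p$pos, sep = "\r")
    first <- !duplicated(snp_key)
    n_snps <- rowsum(as.integer(first), cell)[, 1]
    n_snps <- n_snps[rownames(ll_cell)]
    best <- max.col(ll_cell, ties.method = "first")
    maxv <- ll_cell[cbind(seq_len(nrow(ll_cell)), best)]
    tied <- rowSums(ll_cell == maxv) > 1L
    g <- ifelse(n_snps >= min_snps & !tied, best - 1L, NA_integer_)
    ids <- strsplit(rownames(ll_cell), "\r", fixed = TRUE)
    ri <- match(vapply(ids, `[`, "", 1), samples)
    ci <- match(vapply(ids, `[`, "", 2), loci)
    out[cbind(ri, ci)] <- g
  }
  structure(out, class = c("genotype_matrix", class(out)),
            filter_log = filter_log)
}

#' State view of a genotype matrix
#'
#' @param matrix a `genotype_matrix` (integer dosage, NA = missing).
#' @return character matrix of "OO"/"HET"/"FF"/NA.
#' @export
genotype_states <- function(matrix) {
  s <- matrix(.STATES[as.vector(matrix) + 1L], nrow(matrix), ncol(matrix),
              dimnames = dimnames(matrix))
  s
}

#' Per-locus missingness of a genotype matrix
#'
#' @param matrix a `genotype_matrix`.
#' @return named numeric vector, fraction missing per locus.
#' @export
locus_missingness <- function(matrix) {
  colMeans(is.na(matrix))
}

#' Retain only loci called in every individual
#'
#' @param matrix a `genotype_matrix`.
#' @return the matrix restricted to columns with zero missing entries.
#' @export
filter_complete_loci <- function(matrix) {
  keep <- !apply(is.na(matrix), 2, any)
  out <- matrix[, keep, drop = FALSE]
  structure(out, class = class(matrix), filter_log = attr(matrix, "filter_log"))
}

#' Validate calls against cross pedigrees
#'
#' For each offspring and locus where both parents are called, checks the
#' offspring call against the Mendelian support of the parental pair (for
#' example OO x FF admits only HET; OO x HET admits OO or HET). Loci where a
#' parent is uncalled, or the offspring itself is uncalled, are excluded
#' from the denominator (uncalled offspring are tallied separately).
#'
#' @param calls a `genotype_matrix` covering parents and offspring.
#' @param pedigree data.frame with columns offspring, parentA, parentB
#'   (sample ids in `calls`).
#' @return data.frame per parental-pair class: n_checked, n_consistent,
#'   consistency, n_offspring_missing.
#' @export
validate_with_crosses <- function(calls, pedigree) {
  ids <- unlist(pedigree[, c("offspring", "parentA", "parentB")])
  if (!all(ids %in% rownames(calls)))
    stop("pedigree references samples absent from the call matrix")
  support <- list("0x0" = 0L, "0x1" = c(0L, 1L), "0x2" = 1L,
                  "1x1" = c(0L, 1L, 2L), "1x2" = c(1L, 2L), "2x2" = 2L)
  rows <- list()
  for (r in seq_len(nrow(pedigree))) {
    off <- calls[pedigree$offspring[r], ]
    pa <- calls[pedigree$parentA[r], ]
    pb <- calls[pedigree$parentB[r], ]
    ok_parents <- !is.na(pa) & !is.na(pb)
    cls <- paste(pmin(pa, pb), pmax(pa, pb), sep = "x")
    for (k in names(support)) {
      idx <- which(ok_parents & cls == k)
      if (!length(idx)) next
      checked <- idx[!is.na(off[idx])]
      rows[[paste(r, k)]] <- data.frame(
        pair_class = k, n_checked = length(checked),
        n_consistent = sum(off[checked] %in% support[[k]]),
        n_offspring_missing = sum(is.na(off[idx])))
    }
  }
  if (!length(rows))
    return(data.frame(pair_class = character(0), n_checked = integer(0),
                      n_consistent = integer(0), consistency = numeric(0),
                      n_offspring_missing = integer(0)))
  agg <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(agg, agg$pair_class), function(d) {
    data.frame(pair_class = d$pair_class[1], n_checked = sum(d$n_checked),
               n_consistent = sum(d$n_consistent),
               n_offspring_missing = sum(d$n_offspring_missing))
  }))
  out$consistency <- ifelse(out$n_checked > 0,
                            out$n_consistent / out$n_checked, NA_real_)
  rownames(out) <- NULL
  out[, c("pair_class", "n_checked", "n_consistent", "consistency",
          "n_offspring_missing")]
}

#' Read and write genotype matrices
#'
#' TSV with samples as rows and loci as columns, dosage values 0/1/2 or NA.
#'
#' @param matrix a `genotype_matrix`.
#' @param path file path.
#' @export
write_genotype_matrix <- function(matrix, path) {
  d <- data.frame(sample = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d$sample
  structure(m, class = c("genotype_matrix", class(m)))
}
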
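#' Freshwater content and haploblocks
#'
#' Freshwater content is the fraction of an individual's alleles at complete
#' adaptive loci that are freshwater (allele count / 2L). A haploblock is a
#' maximal run of consecutive panel loci (same chromosome) at which the
#' individual carries at least one freshwater allele; physical span is
#' measured from the first SNP of the first member locus to the last SNP of
#' the last, genetic span by interpolating the genetic map at those SNPs.
#' Runs of a single locus are counted as singletons and excluded from
#' block-length distributions.
#'
#' @name haploblocks
NULL

#' Per-individual freshwater content
#'
#' @param matrix a complete `genotype_matrix` (no missing entries; apply
#'   [filter_complete_loci()] first).
#' @param timepoint optional per-sample label carried into the output.
#' @return data.frame: sample, n_fw_alleles, n_loci, content, timepoint.
#' @export
freshwater_content <- function(matrix, timepoint = NULL) {
  if (anyNA(matrix))
    stop("matrix has missing calls; apply filter_complete_loci() first")
  L <- ncol(matrix)
  cnt <- rowSums(matrix)
  data.frame(sample = rownames(matrix), n_fw_alleles = cnt, n_loci = L,
             content = cnt / (2 * L),
             timepoint = if (is.null(timepoint)) NA_character_
                         else rep_len(timepoint, nrow(matrix)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find haploblocks of freshwater-carrying loci
#'
#' @param matrix a complete `genotype_matrix` over the panel's loci (columns
#'   must be a subset of panel loci, in panel order).
#' @param panel the `locus_panel`.
#' @param max_gap_bp optional maximum gap between the last SNP of one member
#'   locus and the first SNP of the next; a larger gap splits the run
#'   (the headline analysis uses 0.8e6, twice the largest locus size).
#' @return list with `blocks` (data.frame: sample, chrom, first_locus,
#'   last_locus, n_loci, start_bp, end_bp, span_bp, span_cM) containing runs
#'   of >= 2 loci, and `singletons` (data.frame: sample, n_singletons).
#' @export
find_haploblocks <- function(matrix, panel, max_gap_bp = NULL) {
  if (anyNA(matrix))
    stop("matrix has missing calls; apply filter_complete_loci() first")
  li <- match(colnames(matrix), panel$loci$locus_id)
  if (anyNA(li)) stop("matrix columns are not panel loci")
  if (is.unsorted(li, strictly = TRUE)) stop("matrix columns must be in panel order")
  chrom <- panel$loci$chrom[li]
  # first and last SNP position of each (retained) locus
  sp <- split(panel$snps$pos, factor(panel$snps$locus_id,
                                     levels = panel$loci$locus_id))
  first_snp <- vapply(sp, min, numeric(1))[li]
  last_snp <- vapply(sp, max, numeric(1))[li]

  blocks <- list()
  singles <- integer(nrow(matrix))
  for (s in seq_len(nrow(matrix))) {
    carry <- matrix[s, ] >= 1L
    if (!any(carry)) next
    # breaks: not carrying, chromosome change, or gap over threshold
    idx <- which(carry)
    new_run <- c(TRUE, diff(idx) != 1L | chrom[idx[-1]] != chrom[idx[-length(idx)]])
    if (!is.null(max_gap_bp) && length(idx) > 1) {
      gap <- first_snp[idx[-1]] - last_snp[idx[-length(idx)]]
      new_run[-1] <- new_run[-1] | gap > max_gap_bp
    }
    run <- cumsum(new_run)
    for (r in unique(run)) {
      mem <- idx[run == r]
      if (length(mem) < 2L) { singles[s] <- singles[s] + 1L; next }
      start_bp <- first_snp[mem[1]]
      end_bp <- last_snp[mem[length(mem)]]
      cm <- interpolate_cm(panel$genetic_map, chrom[mem[1]],
                           c(start_bp, end_bp))
      blocks[[length(blocks) + 1L]] <- data.frame(
        sample = rownames(matrix)[s], chrom = chrom[mem[1]],
        first_locus = colnames(matrix)[mem[1]],
        last_locus = colnames(matrix)[mem[length(mem)]],
        n_loci = length(mem), start_bp = start_bp, end_bp = end_bp,
        span_bp = end_bp - start_bp, span_cM = cm[2] - cm[1],
        stringsAsFactors = FALSE)
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks)
            else data.frame(sample = character(0), chrom = integer(0),
                            first_locus = character(0), last_locus = character(0),
                            n_loci = integer(0), start_bp = numeric(0),
                            end_bp = numeric(0), span_bp = numeric(0),
                            span_cM = numeric(0))
  list(blocks = blocks,
       singletons = data.frame(sample = rownames(matrix),
                               n_singletons = singles, row.names = NULL))
}

#' Genetic span of a haploblock
#'
#' @param block one row of the blocks table from [find_haploblocks()], or any
#'   list with chrom, start_bp, end_bp.
#' @param genetic_map data.frame chrom/pos/cM.
#' @return span in cM (monotone linear interpolation).
#' @export
genetic_span <- function(block, genetic_map) {
  cm <- interpolate_cm(genetic_map, block$chrom, c(block$start_bp, block$end_bp))
  cm[2] - cm[1]
}

#' Summaries of block lengths by group
#'
#' Per-group mean, standard deviation and quantiles of a span column, plus
#' pairwise Welch t-tests and Cohen's D (with bootstrap CI) for all group
#' pairs. Empty groups are dropped with a message.
#'
#' @param blocks blocks data.frame with a grouping column.
#' @param group name of the grouping column (e.g. a timepoint label added by
#'   the caller).
#' @param span name of the span column (`"span_bp"` or `"span_cM"`).
#' @param n_boot bootstrap replicates for the Cohen's D CI.
#' @param seed integer seed for the bootstrap.
#' @return list with `summary` (per group) and `comparisons` (per pair;
#'   NULL when fewer than two groups).
#' @export
block_length_summary <- function(blocks, group = "timepoint",
                                 span = "span_bp", n_boot = 1000L, seed = 1L) {
  g <- blocks[[group]]
  x <- blocks[[span]]
  keep <- !is.na(g)
  g <- g[keep]; x <- x[keep]
  groups <- split(x, g)
  empty <- vapply(groups, length, integer(1)) == 0
  if (any(empty)) {
    message("dropping empty groups: ", paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  summ <- do.call(rbind, lapply(names(groups), function(k) {
    v <- groups[[k]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75))
    data.frame(group = k, n = length(v), mean = mean(v), sd = stats::sd(v),
               q25 = q[1], median = q[2], q75 = q[3], row.names = NULL)
  }))
  comparisons <- NULL
  if (length(groups) >= 2) {
    pairs <- utils::combn(names(groups), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
      a <- groups[[pairs[1, p]]]; b <- groups[[pairs[2, p]]]
      wt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      cd <- cohens_d(a, b, n_boot = n_boot, seed = seed + p)
      data.frame(group1 = pairs[1, p], group2 = pairs[2, p],
                 welch_t = if (is.null(wt)) NA_real_ else unname(wt$statistic),
                 welch_p = if (is.null(wt)) NA_real_ else wt$p.value,
                 cohens_d = cd$d, d_ci_lo = cd$ci[1], d_ci_hi = cd$ci[2])
    }))
  }
  list(summary = summ, comparisons = comparisons)
}

#' Write a blocks table
#'
#' @param blocks blocks data.frame.
#' @param path file path.
#' @export
write_blocks <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
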
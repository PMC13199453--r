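#' Truth genotype matrices
#'
#' A `truth_genotypes` object holds the ground-truth diploid state of every
#' individual at every panel locus as a freshwater-allele dosage matrix
#' (0 = homozygous oceanic, 1 = heterozygous, 2 = homozygous freshwater),
#' plus an ancestry label per individual. Synthetic truth is the reference
#' the caller is validated against.
#'
#' @param dosage integer matrix individuals x loci with values in 0:2.
#' @param sample_ids character vector of row names.
#' @param locus_ids character vector of column names.
#' @param ancestry character vector per individual (founder class,
#'   pedigree id, ...).
#' @return a `truth_genotypes` object.
#' @export
new_truth_genotypes <- function(dosage, sample_ids = rownames(dosage),
                                locus_ids = colnames(dosage),
                                ancestry = rep("unknown", nrow(dosage))) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(all(dosage %in% 0:2), length(ancestry) == nrow(dosage))
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%04d", seq_len(nrow(dosage)))
  if (is.null(locus_ids)) locus_ids <- sprintf("L%04d", seq_len(ncol(dosage)))
  dimnames(dosage) <- list(sample_ids, locus_ids)
  structure(list(dosage = dosage, ancestry = ancestry),
            class = "truth_genotypes")
}

#' @export
print.truth_genotypes <- function(x, ...) {
  cat("truth_genotypes:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "loci; mean freshwater content",
      signif(mean(x$dosage) / 2, 3), "\n")
  invisible(x)
}

#' Per-individual freshwater content of a truth matrix
#'
#' @param truth a `truth_genotypes`.
#' @return numeric vector, `rowSums(dosage) / (2 * n_loci)`.
#' @export
truth_content <- function(truth) {
  rowSums(truth$dosage) / (2 * ncol(truth$dosage))
}

#' Simulate a population sample with bimodal freshwater content
#'
#' Emulates the structure of lake timepoint samples: each individual's target
#' freshwater content is drawn from a Gaussian mixture on [0, 1] (typically a
#' low-content mode near 0 and a jackpot mode around 0.3), and freshwater
#' alleles are then laid down in contiguous runs of consecutive panel loci so
#' that jackpot individuals carry haploblocks rather than scattered alleles.
#'
#' @param panel a `locus_panel`.
#' @param n_individuals sample size.
#' @param mode_weights,mode_means,mode_sds mixture parameters (recycled to a
#'   common length); weights are normalized. Means must lie in [0, 1].
#' @param block_mean_loci mean run length (loci) of a freshwater run.
#' @param p_ff probability that a run is homozygous freshwater rather than
#'   heterozygous.
#' @param seed integer seed.
#' @return a `truth_genotypes`; ancestry records the mixture mode drawn.
#' @export
simulate_population_sample <- function(panel, n_individuals,
                                       mode_weights = c(0.5, 0.5),
                                       mode_means = c(0.005, 0.33),
                                       mode_sds = c(0.004, 0.05),
                                       block_mean_loci = 8,
                                       p_ff = 0.1,
                                       seed = 1L) {
  k <- max(length(mode_weights), length(mode_means), length(mode_sds))
  mode_weights <- rep_len(mode_weights, k)
  mode_means <- rep_len(mode_means, k)
  mode_sds <- rep_len(mode_sds, k)
  if (any(mode_means < 0 | mode_means > 1))
    stop("mode means must define contents in [0, 1]")
  if (sum(mode_weights) <= 0) stop("mode weights must sum to a positive value")
  set.seed(seed)
  w <- mode_weights / sum(mode_weights)
  L <- nrow(panel$loci)
  modes <- sample.int(k, n_individuals, replace = TRUE, prob = w)
  content <- stats::rnorm(n_individuals, mode_means[modes], mode_sds[modes])
  content <- pmin(pmax(content, 0), 1)

  chrom <- panel$loci$chrom
  dosage <- matrix(0L, n_individuals, L)
  for (i in seq_len(n_individuals)) {
    target <- round(content[i] * 2 * L)
    guard <- 0L
    while (target > 0 && guard < 10L * L) {
      start <- sample.int(L, 1L)
      len <- 1L + stats::rpois(1L, block_mean_loci - 1)
      d <- if (stats::runif(1) < p_ff) 2L else 1L
      j <- start
      while (len > 0 && j <= L && chrom[j] == chrom[start] && target > 0) {
        room <- min(d, 2L - dosage[i, j])
        add <- min(room, target)
        dosage[i, j] <- dosage[i, j] + add
        target <- target - add
        j <- j + 1L
        len <- len - 1L
      }
      guard <- guard + 1L
    }
  }
  new_truth_genotypes(dosage,
                      sample_ids = sprintf("ind%04d", seq_len(n_individuals)),
                      locus_ids = panel$loci$locus_id,
                      ancestry = sprintf("mode%d", modes))
}

# Phase a dosage vector into two haplotypes. Contiguous heterozygous runs
# (within a chromosome) are placed on one randomly chosen haplotype per run,
# mirroring the haploblock origin of heterozygous stretches.
phase_dosage <- function(dosage, chrom) {
  L <- length(dosage)
  h1 <- as.integer(dosage == 2L)
  h2 <- h1
  het <- dosage == 1L
  if (any(het)) {
    run_break <- c(TRUE, diff(het) != 0 | diff(chrom) != 0)
    run_id <- cumsum(run_break)
    for (r in unique(run_id[het])) {
      pick <- stats::runif(1) < 0.5
      idx <- which(run_id == r & het)
      if (pick) h1[idx] <- 1L else h2[idx] <- 1L
    }
  }
  list(h1 = h1, h2 = h2)
}

#' Simulate a cross between two parents
#'
#' Offspring are produced by Mendelian transmission: each parent's dosage
#' vector is phased into two haplotypes (contiguous heterozygous runs on one
#' haplotype), and each offspring receives one recombinant gamete per parent.
#' Crossovers follow a no-interference Poisson process on the panel's genetic
#' map, realized as independent per-interval switches at the Haldane
#' recombination fractions; `recombination = FALSE` transmits whole parental
#' haplotype sets per chromosome (intervals within a chromosome get r = 0).
#'
#' @param panel a `locus_panel`.
#' @param parentA,parentB dosage vectors over `panel` loci (values 0/1/2), or
#'   single-row `truth_genotypes`.
#' @param n_offspring number of offspring.
#' @param recombination logical; see above.
#' @param seed integer seed.
#' @return a `truth_genotypes` of the offspring (ancestry `"cross"`).
#' @export
simulate_cross <- function(panel, parentA, parentB, n_offspring,
                           recombination = TRUE, seed = 1L) {
  as_dosage_row <- function(p) {
    if (inherits(p, "truth_genotypes")) {
      if (nrow(p$dosage) != 1L) stop("parent must be a single row")
      p <- p$dosage[1L, ]
    }
    p <- as.integer(p)
    if (length(p) != nrow(panel$loci))
      stop("parent dosage length does not match the panel")
    if (!all(p %in% 0:2)) stop("parent dosages must be 0, 1 or 2")
    p
  }
  a <- as_dosage_row(parentA)
  b <- as_dosage_row(parentB)
  set.seed(seed)
  chrom <- panel$loci$chrom
  L <- length(chrom)
  rec <- recombination_fractions(panel)
  if (!recombination && L > 1) rec[chrom[-1] == chrom[-L]] <- 0
  pa <- phase_dosage(a, chrom)
  pb <- phase_dosage(b, chrom)
  idx <- rep(1L, n_offspring)
  g1 <- cpp_make_gametes(matrix(pa$h1, ncol = 1), matrix(pa$h2, ncol = 1),
                         idx, rec)
  g2 <- cpp_make_gametes(matrix(pb$h1, ncol = 1), matrix(pb$h2, ncol = 1),
                         idx, rec)
  new_truth_genotypes(t(g1 + g2),
                      sample_ids = sprintf("off%05d", seq_len(n_offspring)),
                      locus_ids = panel$loci$locus_id,
                      ancestry = rep("cross", n_offspring))
}

#' Mean content expectations for standard cross designs
#'
#' Utility for pedigree construction: starting from a homozygous-oceanic and
#' a homozygous-freshwater founder, F1 individuals are heterozygous at every
#' locus (content 1/2), first-generation backcrosses to oceanic average 1/4,
#' and second-generation backcrosses 1/8.
#'
#' @param panel a `locus_panel`.
#' @param cross one of "F1", "BC1", "BC2".
#' @param n_offspring offspring count for the terminal generation.
#' @param seed integer seed.
#' @return a `truth_genotypes` of the terminal generation.
#' @export
simulate_standard_cross <- function(panel, cross = c("F1", "BC1", "BC2"),
                                    n_offspring = 100L, seed = 1L) {
  cross <- match.arg(cross)
  L <- nrow(panel$loci)
  oo <- rep(0L, L); ff <- rep(2L, L)
  f1 <- rep(1L, L)  # OO x FF offspring are HET everywhere by construction
  if (cross == "F1")
    return(simulate_cross(panel, oo, ff, n_offspring, seed = seed))
  if (cross == "BC1")
    return(simulate_cross(panel, f1, oo, n_offspring, seed = seed))
  # BC2: each BC1 offspring is backcrossed to an all-oceanic parent once,
  # so the terminal generation descends from n_offspring distinct BC1 fish
  bc1 <- simulate_cross(panel, f1, oo, n_offspring, seed = seed)
  simulate_cross_each(panel, bc1, oo, seed = seed + 1L)
}

#' Cross every individual of a truth matrix to a common parent
#'
#' Produces one offspring per row of `parents`: a recombinant gamete from
#' that individual plus a recombinant gamete from `other`.
#'
#' @param panel a `locus_panel`.
#' @param parents a `truth_genotypes`.
#' @param other dosage vector of the common parent.
#' @param seed integer seed.
#' @return a `truth_genotypes` with `nrow(parents$dosage)` offspring.
#' @export
simulate_cross_each <- function(panel, parents, other, seed = 1L) {
  stopifnot(inherits(parents, "truth_genotypes"))
  other <- as.integer(other)
  if (length(other) != nrow(panel$loci))
    stop("parent dosage length does not match the panel")
  set.seed(seed)
  chrom <- panel$loci$chrom
  rec <- recombination_fractions(panel)
  n <- nrow(parents$dosage)
  L <- ncol(parents$dosage)
  H1 <- matrix(0L, L, n); H2 <- matrix(0L, L, n)
  for (i in seq_len(n)) {
    ph <- phase_dosage(parents$dosage[i, ], chrom)
    H1[, i] <- ph$h1; H2[, i] <- ph$h2
  }
  g1 <- cpp_make_gametes(H1, H2, seq_len(n), rec)
  po <- phase_dosage(other, chrom)
  g2 <- cpp_make_gametes(matrix(po$h1, ncol = 1), matrix(po$h2, ncol = 1),
                         rep(1L, n), rec)
  new_truth_genotypes(t(g1 + g2),
                      sample_ids = sprintf("off%05d", seq_len(n)),
                      locus_ids = panel$loci$locus_id,
                      ancestry = rep("cross", n))
}

#' Read and write truth genotype matrices
#'
#' TSV with samples as rows and loci as columns; first column `sample`,
#' second `ancestry`, remaining columns dosages 0/1/2.
#'
#' @param truth a `truth_genotypes`.
#' @param path file path.
#' @export
write_truth_genotypes <- function(truth, path) {
  d <- data.frame(sample = rownames(truth$dosage), ancestry = truth$ancestry,
                  truth$dosage, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_genotypes
#' @export
read_truth_genotypes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  new_truth_genotypes(m, sample_ids = d$sample,
                      locus_ids = colnames(d)[-(1:2)], ancestry = d$ancestry)
}
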
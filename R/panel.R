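#' Locus panels of multi-SNP freshwater-adaptive haplotypes
#'
#' A locus panel describes the freshwater-adaptive loci used throughout the
#' pipeline: each locus is a set of tightly correlated SNPs on one chromosome,
#' every SNP labelled with its oceanic and freshwater allele, together with a
#' per-chromosome genetic map (bp to cM). Panels are the coordinate system for
#' genotype calling, haploblock detection and the forward simulator.
#'
#' @name locus_panel
NULL

.CHROMS <- 21L
.BASES <- c("A", "C", "G", "T")

#' Generate a synthetic locus panel
#'
#' Draws `n_loci` non-overlapping multi-SNP loci across 21 chromosomes.
#' SNP counts per locus are sampled log-uniformly within
#' `snps_per_locus_range` (the adaptive-locus panels this emulates have from
#' 3 to several thousand correlated SNPs per locus), locus physical spans are
#' log-normal around `median_span_bp`, and SNPs are placed uniformly inside
#' the span. A linear genetic map at `cm_per_mb` is attached per chromosome.
#'
#' @param n_loci number of loci (default 344, the size of the adaptive panel).
#' @param snps_per_locus_range integer length-2, inclusive range of SNPs per
#'   locus (default `c(3, 3658)`).
#' @param chromosome_lengths named or unnamed numeric vector of chromosome
#'   lengths in bp; default 21 chromosomes of 20 Mb.
#' @param median_span_bp median physical span of a locus (default 27300 bp).
#' @param cm_per_mb recombination rate of the linear genetic map (default 1).
#' @param min_gap_bp minimum gap enforced between adjacent loci (default 5e4).
#' @param seed integer seed; the panel is deterministic given the seed.
#' @return A `locus_panel` object: list with `loci` (data.frame: locus_id,
#'   chrom, start, end, n_snps), `snps` (data.frame: locus_id, chrom, pos,
#'   oceanic_allele, freshwater_allele) and `genetic_map` (data.frame: chrom,
#'   pos, cM).
#' @export
generate_locus_panel <- function(n_loci = 344L,
                                 snps_per_locus_range = c(3L, 3658L),
                                 chromosome_lengths = rep(20e6, 21),
                                 median_span_bp = 27300,
                                 cm_per_mb = 1,
                                 min_gap_bp = 5e4,
                                 seed = 1L) {
  stopifnot(n_loci >= 1L,
            length(snps_per_locus_range) == 2L,
            snps_per_locus_range[1] >= 1L,
            snps_per_locus_range[2] <= 4000L,
            snps_per_locus_range[1] <= snps_per_locus_range[2],
            all(chromosome_lengths > 0))
  set.seed(seed)
  n_chrom <- length(chromosome_lengths)
  chrom_of <- sort(sample.int(n_chrom, n_loci, replace = TRUE,
                              prob = chromosome_lengths / sum(chromosome_lengths)))

  # log-uniform SNP counts; log-normal spans clipped to >= n_snps bases
  lo <- log(snps_per_locus_range[1]); hi <- log(snps_per_locus_range[2] + 1)
  n_snps <- pmin(snps_per_locus_range[2],
                 pmax(snps_per_locus_range[1], floor(exp(stats::runif(n_loci, lo, hi)))))
  spans <- round(stats::rlnorm(n_loci, meanlog = log(median_span_bp), sdlog = 0.9))
  spans <- pmax(spans, n_snps * 2)

  loci <- vector("list", n_loci)
  snps <- vector("list", n_loci)
  k <- 0L
  for (ch in unique(chrom_of)) {
    idx <- which(chrom_of == ch)
    need <- sum(spans[idx]) + (length(idx) + 1) * min_gap_bp
    if (need > chromosome_lengths[ch]) {
      stop("chromosome ", ch, " too short (", chromosome_lengths[ch],
           " bp) to host ", length(idx), " loci spanning ", need, " bp")
    }
    # place loci left to right with random slack distributed between them
    slack <- chromosome_lengths[ch] - sum(spans[idx]) - (length(idx) + 1) * min_gap_bp
    cuts <- sort(stats::runif(length(idx), 0, slack))
    gaps <- diff(c(0, cuts))
    pos <- min_gap_bp
    for (j in seq_along(idx)) {
      i <- idx[j]
      start <- as.integer(round(pos + gaps[j]) + 1)
      end <- as.integer(start + spans[i] - 1)
      pos <- end + min_gap_bp
      k <- k + 1L
      p <- sort(sample.int(spans[i], n_snps[i])) + start - 1L
      oc <- sample(.BASES, n_snps[i], replace = TRUE)
      fw <- vapply(oc, function(b) sample(setdiff(.BASES, b), 1L), character(1))
      loci[[k]] <- data.frame(locus_id = NA_character_, chrom = ch,
                              start = start, end = end,
                              n_snps = as.integer(n_snps[i]))
      snps[[k]] <- data.frame(locus_id = NA_character_, chrom = ch, pos = p,
                              oceanic_allele = oc, freshwater_allele = unname(fw))
    }
  }
  loci <- do.call(rbind, loci)
  ord <- order(loci$chrom, loci$start)
  loci <- loci[ord, , drop = FALSE]
  loci$locus_id <- sprintf("L%04d", seq_len(n_loci))
  snps <- do.call(rbind, snps[ord])
  snps$locus_id <- rep(loci$locus_id, loci$n_snps)
  rownames(loci) <- rownames(snps) <- NULL

  gm <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    data.frame(chrom = ch, pos = c(1, chromosome_lengths[ch]),
               cM = c(0, chromosome_lengths[ch] * cm_per_mb / 1e6))
  }))
  new_locus_panel(loci, snps, gm)
}

#' Construct a locus panel from its component tables
#'
#' @param loci data.frame with locus_id, chrom, start, end, n_snps.
#' @param snps data.frame with locus_id, chrom, pos, oceanic_allele,
#'   freshwater_allele.
#' @param genetic_map data.frame with chrom, pos, cM (cM non-decreasing in pos
#'   within each chromosome).
#' @return a validated `locus_panel`.
#' @export
new_locus_panel <- function(loci, snps, genetic_map) {
  panel <- structure(list(loci = loci, snps = snps, genetic_map = genetic_map),
                     class = "locus_panel")
  validate_locus_panel(panel)
  panel
}

#' @rdname new_locus_panel
#' @param panel a `locus_panel`.
#' @export
validate_locus_panel <- function(panel) {
  loci <- panel$loci; snps <- panel$snps; gm <- panel$genetic_map
  stopifnot(is.data.frame(loci), is.data.frame(snps), is.data.frame(gm),
            nrow(loci) >= 1)
  if (any(duplicated(loci$locus_id))) stop("duplicated locus ids")
  if (!all(snps$locus_id %in% loci$locus_id)) stop("snps reference unknown loci")
  # snp positions strictly increasing within locus, consistent chromosome
  sp <- split(snps, factor(snps$locus_id, levels = loci$locus_id))
  ns <- vapply(sp, nrow, integer(1))
  if (any(ns < 1)) stop("every locus needs >= 1 SNP")
  ok <- vapply(sp, function(d) all(diff(d$pos) > 0) && length(unique(d$chrom)) == 1,
               logical(1))
  if (!all(ok)) stop("snp positions must be strictly increasing on one chromosome")
  # loci sorted and non-overlapping per chromosome
  if (is.unsorted(order(loci$chrom, loci$start))) stop("loci must be sorted")
  for (ch in unique(loci$chrom)) {
    d <- loci[loci$chrom == ch, ]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping loci on chromosome ", ch)
  }
  bad <- vapply(split(gm, gm$chrom),
                function(d) is.unsorted(d$pos, strictly = TRUE) || is.unsorted(d$cM),
                logical(1))
  if (any(bad)) stop("genetic map must be strictly sorted in pos with non-decreasing cM")
  invisible(panel)
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("locus_panel:", nrow(x$loci), "loci,", nrow(x$snps), "SNPs on",
      length(unique(x$loci$chrom)), "chromosomes;",
      sum(callable_loci(x)), "callable (>= 3 SNPs)\n")
  invisible(x)
}

#' Which panel loci are callable (at least 3 SNPs)
#'
#' @param panel a `locus_panel`.
#' @param min_snps minimum SNPs for callability (default 3).
#' @return logical vector along `panel$loci`.
#' @export
callable_loci <- function(panel, min_snps = 3L) {
  panel$loci$n_snps >= min_snps
}

#' Interpolate genetic-map position
#'
#' Monotone linear interpolation of the cM coordinate at physical positions.
#' Positions beyond the mapped range are extrapolated at the terminal segment
#' rate, with a warning.
#'
#' @param genetic_map data.frame chrom/pos/cM.
#' @param chrom chromosome (scalar).
#' @param pos numeric vector of bp positions.
#' @return numeric vector of cM values.
#' @export
interpolate_cm <- function(genetic_map, chrom, pos) {
  d <- genetic_map[genetic_map$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0) stop("genetic map does not cover chromosome ", chrom)
  if (nrow(d) == 1) return(rep(d$cM, length(pos)))
  if (any(pos < min(d$pos) | pos > max(d$pos)))
    warning("position outside genetic map range on chromosome ", chrom,
            "; extrapolating at terminal rate")
  # linear interpolation with linear extrapolation using terminal slopes
  out <- stats::approx(d$pos, d$cM, xout = pos, rule = 2)$y
  lo <- pos < d$pos[1]
  hi <- pos > d$pos[nrow(d)]
  if (any(lo)) {
    r <- (d$cM[2] - d$cM[1]) / (d$pos[2] - d$pos[1])
    out[lo] <- d$cM[1] + (pos[lo] - d$pos[1]) * r
  }
  if (any(hi)) {
    n <- nrow(d)
    r <- (d$cM[n] - d$cM[n - 1]) / (d$pos[n] - d$pos[n - 1])
    out[hi] <- d$cM[n] + (pos[hi] - d$pos[n]) * r
  }
  out
}

#' Inter-locus recombination fractions along the panel
#'
#' For the forward simulator and the cross simulator: the probability of an
#' odd number of crossovers between the midpoints of consecutive panel loci,
#' from the genetic map via Haldane's function r = (1 - exp(-2d))/2 with d in
#' Morgans. Consecutive loci on different chromosomes get r = 0.5
#' (independent assortment). Under a no-interference Poisson crossover
#' process, inheritance switches across intervals are independent Bernoulli
#' draws with exactly these fractions.
#'
#' @param panel a `locus_panel`.
#' @return numeric vector of length `nrow(panel$loci) - 1`.
#' @export
recombination_fractions <- function(panel) {
  loci <- panel$loci
  n <- nrow(loci)
  if (n < 2) return(numeric(0))
  mid <- (loci$start + loci$end) / 2
  cm <- numeric(n)
  for (ch in unique(loci$chrom)) {
    i <- loci$chrom == ch
    cm[i] <- interpolate_cm(panel$genetic_map, ch, mid[i])
  }
  r <- numeric(n - 1)
  same <- loci$chrom[-1] == loci$chrom[-n]
  d <- (cm[-1] - cm[-n]) / 100  # Morgans
  r[same] <- (1 - exp(-2 * d[same])) / 2
  r[!same] <- 0.5
  r
}

# ---- panel IO ----------------------------------------------------------

#' Read and write locus panels
#'
#' The panel serializes to three plain-text files in `dir`: `panel.tsv`
#' (locus_id, chrom, pos, oceanic_allele, freshwater_allele; 1-based
#' positions), `panel.bed` (0-based half-open locus extents) and
#' `genetic_map.tsv` (chrom, pos, cM). Writing then reading round-trips
#' exactly.
#'
#' @param panel a `locus_panel`.
#' @param dir output directory (created if absent).
#' @return `write_locus_panel` returns `dir` invisibly; `read_locus_panel`
#'   returns a `locus_panel`.
#' @export
write_locus_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(panel$snps, file.path(dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = panel$loci$chrom, start = panel$loci$start - 1L,
                    end = panel$loci$end, name = panel$loci$locus_id)
  utils::write.table(bed, file.path(dir, "panel.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(panel$genetic_map, file.path(dir, "genetic_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_locus_panel
#' @export
read_locus_panel <- function(dir) {
  snps <- utils::read.table(file.path(dir, "panel.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  bed <- utils::read.table(file.path(dir, "panel.bed"), sep = "\t",
                           header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  gm <- utils::read.table(file.path(dir, "genetic_map.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  n_snps <- as.integer(table(factor(snps$locus_id, levels = bed$name)))
  loci <- data.frame(locus_id = bed$name, chrom = bed$chrom,
                     start = bed$start + 1L, end = bed$end, n_snps = n_snps)
  new_locus_panel(loci, snps, gm)
}
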
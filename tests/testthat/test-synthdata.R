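test_that("generated panels satisfy the structural invariants", {
  p <- generate_locus_panel(n_loci = 344, snps_per_locus_range = c(3, 3658),
                            seed = 11)
  expect_equal(nrow(p$loci), 344)
  expect_true(all(p$loci$n_snps >= 3 & p$loci$n_snps <= 3658))
  expect_true(all(callable_loci(p)))
  expect_true(all(p$loci$chrom %in% 1:21))
  # strictly increasing SNP positions within loci, non-overlapping loci
  expect_silent(validate_locus_panel(p))
  # alleles differ at every SNP
  expect_true(all(p$snps$oceanic_allele != p$snps$freshwater_allele))
})

test_that("a minimal one-locus panel is valid", {
  p <- generate_locus_panel(n_loci = 1, snps_per_locus_range = c(3, 3),
                            seed = 2)
  expect_equal(nrow(p$loci), 1)
  expect_equal(p$loci$n_snps, 3L)
})

test_that("panel generation is seed-deterministic and files round-trip", {
  p1 <- generate_locus_panel(n_loci = 30, snps_per_locus_range = c(3, 40),
                             seed = 5)
  p2 <- generate_locus_panel(n_loci = 30, snps_per_locus_range = c(3, 40),
                             seed = 5)
  expect_identical(p1, p2)
  d1 <- file.path(tempdir(), "pan1"); d2 <- file.path(tempdir(), "pan2")
  write_locus_panel(p1, d1); write_locus_panel(p2, d2)
  for (f in c("panel.tsv", "panel.bed", "genetic_map.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  p3 <- read_locus_panel(d1)
  expect_identical(p3$loci, p1$loci)
  expect_equal(p3$snps$pos, p1$snps$pos)
  expect_equal(p3$genetic_map$cM, p1$genetic_map$cM)
})

test_that("impossible panel sizing errors out", {
  expect_error(
    generate_locus_panel(n_loci = 50, snps_per_locus_range = c(3, 5),
                         chromosome_lengths = rep(1e5, 2), seed = 1),
    "too short")
})

test_that("population samples hit their content targets", {
  p <- generate_locus_panel(n_loci = 60, snps_per_locus_range = c(3, 10),
                            seed = 3)
  # degenerate single mode at zero content
  t0 <- simulate_population_sample(p, 25, mode_weights = c(1, 0),
                                   mode_means = c(0, 0.3),
                                   mode_sds = c(0, 0.01), seed = 4)
  expect_true(all(t0$dosage == 0L))
  expect_true(all(truth_content(t0) == 0))
  # realized content equals the (clipped, rounded) mixture draw
  tb <- simulate_population_sample(p, 80, seed = 6)
  expect_true(all(truth_content(tb) >= 0 & truth_content(tb) <= 1))
  expect_identical(tb$dosage,
                   simulate_population_sample(p, 80, seed = 6)$dosage)
  # infeasible mode mean rejected
  expect_error(simulate_population_sample(p, 5, mode_means = c(0, 1.4)),
               "in \\[0, 1\\]")
})

test_that("bimodal population samples fail the dip test of unimodality", {
  p <- generate_locus_panel(n_loci = 120, snps_per_locus_range = c(3, 8),
                            seed = 8)
  tb <- simulate_population_sample(p, 300, mode_weights = c(0.5, 0.5),
                                   mode_means = c(0.005, 0.33),
                                   mode_sds = c(0.004, 0.05), seed = 9)
  dt <- dip_test(truth_content(tb), n_boot = 500, seed = 10)
  expect_lt(dt$p_value, 0.01)
})

test_that("cross offspring respect Mendelian support", {
  p <- generate_locus_panel(n_loci = 40, snps_per_locus_range = c(3, 6),
                            seed = 12)
  L <- nrow(p$loci)
  oo <- rep(0L, L); ff <- rep(2L, L)
  f1 <- simulate_cross(p, oo, ff, 50, seed = 13)
  expect_true(all(f1$dosage == 1L))
  expect_true(all(truth_content(f1) == 0.5))
  # OO x OO yields only OO
  expect_true(all(simulate_cross(p, oo, oo, 20, seed = 14)$dosage == 0L))
  # HET x OO offspring are OO or HET only
  bc <- simulate_cross(p, rep(1L, L), oo, 200, seed = 15)
  expect_true(all(bc$dosage %in% 0:1))
  # mismatched panel errors
  expect_error(simulate_cross(p, rep(0L, L - 1), ff, 5), "does not match")
})

test_that("backcross generations halve the expected freshwater content", {
  p <- generate_locus_panel(n_loci = 300, snps_per_locus_range = c(3, 10),
                            seed = 16)
  bc1 <- simulate_standard_cross(p, "BC1", 4000, seed = 17)
  c1 <- truth_content(bc1)
  expect_lt(abs(mean(c1) - 0.25), 3 * stats::sd(c1) / sqrt(length(c1)))
  bc2 <- simulate_standard_cross(p, "BC2", 4000, seed = 18)
  c2 <- truth_content(bc2)
  expect_lt(abs(mean(c2) - 0.125), 3 * stats::sd(c2) / sqrt(length(c2)))
})

test_that("pileups follow the read-count and error model", {
  p <- generate_locus_panel(n_loci = 30, snps_per_locus_range = c(3, 8),
                            seed = 20)
  tr <- simulate_population_sample(p, 10, mode_weights = c(0.4, 0.6),
                                   mode_means = c(0.02, 0.4), seed = 21)
  pu <- simulate_pileups(tr, p, mean_coverage = 30, base_error = 0.001,
                         seed = 22)
  expect_identical(pu, simulate_pileups(tr, p, mean_coverage = 30,
                                        base_error = 0.001, seed = 22))
  # HET truth: freshwater-read fraction near 1/2 overall
  het_loci <- colnames(tr$dosage)[tr$dosage[1, ] == 1L]
  rows <- pu$sample == rownames(tr$dosage)[1] & pu$locus_id %in% het_loci
  if (sum(rows) > 0) {
    n_fw <- sum(pu$n_fw[rows]); n_tot <- sum(pu$n_fw[rows] + pu$n_oc[rows])
    if (n_tot > 50)
      expect_lt(abs(n_fw / n_tot - 0.5), 3 * sqrt(0.25 / n_tot))
  }
  # error-model composition: "other" reads appear at about 2e/3
  pu_e <- simulate_pileups(tr, p, mean_coverage = 20, base_error = 0.05,
                           seed = 23)
  tot <- sum(pu_e$n_fw + pu_e$n_oc + pu_e$n_other)
  frac_other <- sum(pu_e$n_other) / tot
  expect_lt(abs(frac_other - 2 * 0.05 / 3), 3 * sqrt(0.033 / tot))
  # parameter validation
  expect_error(simulate_pileups(tr, p, mean_coverage = 0), "coverage")
  # round-trip
  f <- tempfile(fileext = ".tsv")
  write_pileups(pu, f)
  expect_equal(read_pileups(f), pu, ignore_attr = TRUE)
})

test_that("pileups round-trip through VCF with per-sample allele depths", {
  skip_if_not_installed("vcfR")
  p <- generate_locus_panel(n_loci = 5, snps_per_locus_range = c(3, 4),
                            seed = 30)
  tr <- simulate_population_sample(p, 4, mode_weights = c(0.3, 0.7),
                                   mode_means = c(0.1, 0.5), seed = 31)
  pu <- simulate_pileups(tr, p, mean_coverage = 8, seed = 32)
  f <- tempfile(fileext = ".vcf")
  write_pileups_vcf(pu, p, f)
  back <- read_pileups_vcf(f, p)
  # aggregate counts per sample x SNP agree
  key <- function(d) paste(d$sample, d$chrom, d$pos)
  agg <- function(d) {
    s <- rowsum(cbind(d$n_fw, d$n_oc, d$n_other), key(d))
    s[order(rownames(s)), , drop = FALSE]
  }
  expect_equal(agg(back), agg(pu))
})

test_that("relatedness graphs have the requested structure", {
  g0 <- generate_relatedness_graph(96, c(0, 0, 0), seed = 1)
  expect_equal(nrow(g0), 0)
  g <- generate_relatedness_graph(96, c(30, 20, 10), seed = 2)
  expect_equal(nrow(g), 60)
  expect_true(all(g$i < g$j))
  expect_false(any(duplicated(paste(g$i, g$j))))
  expect_equal(as.integer(table(g$degree)), c(30, 20, 10))
  expect_identical(g, generate_relatedness_graph(96, c(30, 20, 10), seed = 2))
  expect_error(generate_relatedness_graph(5, c(20, 0, 0)), "only")
})
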
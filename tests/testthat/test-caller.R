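test_that("per-SNP log-likelihoods match the closed form", {
  e <- 0.01
  # pure freshwater support
  ll <- snp_genotype_log_likelihoods(5, 0, 0, e)
  expect_equal(unname(ll[1, "FF"] - ll[1, "OO"]),
               5 * (log(1 - e) - log(e / 3)))
  expect_equal(which.max(ll[1, ]), c(FF = 3L))
  # balanced support favors the heterozygote
  ll2 <- snp_genotype_log_likelihoods(3, 3, 0, e)
  expect_equal(which.max(ll2[1, ]), c(HET = 2L))
  # explicit values for one read of each kind
  ll3 <- snp_genotype_log_likelihoods(1, 0, 0, e)
  expect_equal(unname(ll3[1, ]),
               log(c(e / 3, 0.5 * (1 - e) + 0.5 * e / 3, 1 - e)))
  # zero reads: flat triple
  expect_equal(unname(snp_genotype_log_likelihoods(0, 0, 0, e)[1, ]),
               c(0, 0, 0))
  # "other" bases shift all three states equally
  ll4 <- snp_genotype_log_likelihoods(2, 1, 3, e)
  ll5 <- snp_genotype_log_likelihoods(2, 1, 0, e)
  expect_equal(ll4[1, ] - ll5[1, ], rep(3 * log(e / 3), 3),
               ignore_attr = TRUE)
})

test_that("locus likelihoods are additive over SNPs", {
  e <- 0.005
  a <- snp_genotype_log_likelihoods(c(4, 0), c(0, 1), c(0, 0), e)
  one <- locus_log_likelihoods(a[1, , drop = FALSE])
  expect_equal(one$ll, a[1, ])
  both <- locus_log_likelihoods(a)
  expect_equal(both$ll, colSums(a))
  expect_equal(both$n_snps_with_reads, 2L)
  # conflicting pure-fw and pure-oc SNPs of equal depth favor HET
  conf <- snp_genotype_log_likelihoods(c(3, 0), c(0, 3), c(0, 0), e)
  expect_equal(call_locus(locus_log_likelihoods(conf), min_snps = 2),
               "HET")
})

test_that("fw/oc label swap mirrors the likelihood triple", {
  e <- 0.02
  ll <- snp_genotype_log_likelihoods(c(5, 1), c(2, 2), c(1, 0), e)
  sw <- snp_genotype_log_likelihoods(c(2, 2), c(5, 1), c(1, 0), e)
  expect_equal(ll[, "OO"], sw[, "FF"])
  expect_equal(ll[, "FF"], sw[, "OO"])
  expect_equal(ll[, "HET"], sw[, "HET"])
})

test_that("locus calls follow the min-SNP and tie rules", {
  ll <- structure(list(ll = c(OO = -10, HET = -2, FF = -5),
                       n_snps_with_reads = 2L),
                  class = "locus_likelihoods")
  expect_identical(call_locus(ll, min_snps = 3), NA_character_)
  ll$n_snps_with_reads <- 3L
  expect_identical(call_locus(ll, min_snps = 3), "HET")
  flat <- structure(list(ll = c(OO = 0, HET = 0, FF = 0),
                         n_snps_with_reads = 4L),
                    class = "locus_likelihoods")
  expect_identical(call_locus(flat), NA_character_)
})

test_that("argmax calls equal exhaustive enumeration on small pileups", {
  e <- 0.01
  set.seed(41)
  for (rep in 1:250) {
    n_snp <- sample(1:3, 1)
    counts <- data.frame(n_fw = integer(n_snp), n_oc = integer(n_snp),
                         n_other = integer(n_snp))
    n_reads <- sample(0:6, 1)
    if (n_reads > 0) {
      snp <- sample(n_snp, n_reads, replace = TRUE)
      kind <- sample(c("n_fw", "n_oc", "n_other"), n_reads, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1))
      for (r in seq_len(n_reads))
        counts[snp[r], kind[r]] <- counts[snp[r], kind[r]] + 1L
    }
    ll <- snp_genotype_log_likelihoods(counts$n_fw, counts$n_oc,
                                       counts$n_other, e)
    got <- call_locus(locus_log_likelihoods(
      ll, has_reads = rowSums(counts) > 0), min_snps = 3)
    expect_identical(got, oracle_call(counts, e, min_snps = 3),
                     label = paste("rep", rep))
  }
})

test_that("the call matrix recovers truth at saturating coverage", {
  p <- generate_locus_panel(n_loci = 25, snps_per_locus_range = c(3, 8),
                            seed = 50)
  tr <- simulate_population_sample(p, 12, mode_weights = c(0.4, 0.6),
                                   mode_means = c(0.03, 0.4), seed = 51)
  pu <- simulate_pileups(tr, p, mean_coverage = 30, base_error = 0.001,
                         seed = 52)
  m <- call_matrix(pu, p)
  expect_equal(dim(m), dim(tr$dosage))
  expect_false(anyNA(m))
  expect_true(all(m == tr$dosage))
  # empty pileups give an all-missing matrix on the requested grid
  m0 <- call_matrix(pu[0, ], p, samples = rownames(tr$dosage))
  expect_true(all(is.na(m0)))
  expect_equal(dim(m0), dim(tr$dosage))
})

test_that("quality filters drop low-quality read classes", {
  p <- generate_locus_panel(n_loci = 10, snps_per_locus_range = c(3, 5),
                            seed = 53)
  tr <- simulate_population_sample(p, 6, mode_weights = c(1, 0),
                                   mode_means = c(0, 0), mode_sds = c(0, 0),
                                   seed = 54)
  pu <- simulate_pileups(tr, p, mean_coverage = 10, low_qual_frac = 0.4,
                         seed = 55)
  m <- call_matrix(pu, p)
  lg <- attr(m, "filter_log")
  expect_gt(lg$reads_failed_quality, 0)
  expect_lt(lg$rows_kept, lg$rows_total)
  # with every read low-quality nothing is callable
  pu_bad <- pu
  pu_bad$BQ <- 10L
  expect_true(all(is.na(call_matrix(pu_bad, p))))
})

test_that("complete-locus filtering matches a brute-force column scan", {
  p <- generate_locus_panel(n_loci = 40, snps_per_locus_range = c(3, 6),
                            seed = 56)
  tr <- simulate_population_sample(p, 8, seed = 57)
  pu <- simulate_pileups(tr, p, mean_coverage = 2, seed = 58)
  m <- call_matrix(pu, p)
  mc <- filter_complete_loci(m)
  keep_oracle <- colnames(m)[colSums(is.na(m)) == 0]
  expect_gt(length(keep_oracle), 0)
  expect_lt(length(keep_oracle), ncol(m))
  expect_identical(colnames(mc), keep_oracle)
  expect_false(anyNA(mc))
  # no missingness: identity
  full <- toy_matrix(matrix(1L, 3, 5), p)
  expect_identical(colnames(filter_complete_loci(full)), colnames(full))
  # single missing entry drops exactly that locus
  one <- toy_matrix(matrix(1L, 3, 5), p)
  one[2, 3] <- NA_integer_
  expect_identical(colnames(filter_complete_loci(one)),
                   colnames(one)[-3])
})

test_that("cross validation scores Mendelian consistency", {
  p <- generate_locus_panel(n_loci = 20, snps_per_locus_range = c(3, 6),
                            seed = 60)
  L <- nrow(p$loci)
  oo <- new_truth_genotypes(matrix(0L, 1, L), "pa", p$loci$locus_id)
  ff <- new_truth_genotypes(matrix(2L, 1, L), "pb", p$loci$locus_id)
  off <- simulate_cross(p, oo, ff, 8, seed = 61)
  all_truth <- new_truth_genotypes(
    rbind(oo$dosage, ff$dosage, off$dosage),
    c("pa", "pb", rownames(off$dosage)), p$loci$locus_id)
  pu <- simulate_pileups(all_truth, p, mean_coverage = 30, seed = 62)
  calls <- call_matrix(pu, p)
  ped <- data.frame(offspring = rownames(off$dosage),
                    parentA = "pa", parentB = "pb")
  rep <- validate_with_crosses(calls, ped)
  r02 <- rep[rep$pair_class == "0x2", ]
  expect_equal(r02$consistency, 1)
  expect_equal(r02$n_checked, 8 * L)
  # a locus with an uncalled parent leaves the denominator
  calls2 <- calls
  calls2["pa", 1] <- NA_integer_
  rep2 <- validate_with_crosses(calls2, ped)
  expect_equal(sum(rep2$n_checked), 8 * (L - 1))
  expect_error(validate_with_crosses(calls, data.frame(
    offspring = "nope", parentA = "pa", parentB = "pb")), "absent")
})

test_that("genotype matrices round-trip through TSV", {
  p <- generate_locus_panel(n_loci = 8, snps_per_locus_range = c(3, 4),
                            seed = 63)
  m <- toy_matrix(matrix(c(0L, 1L, 2L, NA, 1L, 0L, 2L, 1L), 2, 4), p)
  f <- tempfile(fileext = ".tsv")
  write_genotype_matrix(m, f)
  back <- read_genotype_matrix(f)
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(m))
})
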
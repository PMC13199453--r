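#!/usr/bin/env Rscript
# Stage 1: synthesize the study inputs -- the adaptive locus panel, truth
# genotypes for a time series of lake samples (with a rising jackpot-carrier
# fraction), low-coverage pileups, an experimental cross family, and a
# relatedness graph. Everything downstream runs from the files written here.

suppressPackageStartupMessages(library(sticklejack))
dir.create("results", showWarnings = FALSE)
dir.create("results/cohort", showWarnings = FALSE)

panel <- generate_locus_panel(n_loci = 344, snps_per_locus_range = c(3, 30),
                              seed = 1001)
write_locus_panel(panel, "results/cohort/panel")
cat("panel:", nrow(panel$loci), "loci,", nrow(panel$snps), "SNPs\n")

# timepoints emulate the sampled years: jackpot-carrier weight rises from
# ~1% two years after founding to 100% by year six
timepoints <- list(
  RS2019 = list(n = 96, w = c(0.99, 0.01)),
  SC2013 = list(n = 96, w = c(0.99, 0.01)),
  SC2014 = list(n = 47, w = c(0.52, 0.48)),
  SC2015 = list(n = 96, w = c(0.12, 0.88)),
  SC2017 = list(n = 96, w = c(0.00, 1.00)),
  SC2020 = list(n = 20, w = c(0.00, 1.00)))

for (tp in names(timepoints)) {
  spec <- timepoints[[tp]]
  truth <- simulate_population_sample(
    panel, spec$n, mode_weights = spec$w,
    mode_means = c(0.005, 0.33), mode_sds = c(0.004, 0.05),
    seed = 2000 + match(tp, names(timepoints)))
  rownames(truth$dosage) <- paste0(tp, "_", rownames(truth$dosage))
  write_truth_genotypes(truth, sprintf("results/cohort/truth_%s.tsv", tp))
  pu <- simulate_pileups(truth, panel, mean_coverage = 1.2,
                         base_error = 0.001, low_qual_frac = 0.05,
                         seed = 3000 + match(tp, names(timepoints)))
  write_pileups(pu, sprintf("results/cohort/pileups_%s.tsv", tp))
  cat(sprintf("%s: %d individuals, mean true content %.4f\n",
              tp, spec$n, mean(truth_content(truth))))
}

# an oceanic x freshwater cross family for caller validation
L <- nrow(panel$loci)
oo <- new_truth_genotypes(matrix(0L, 1, L), "cross_pa", panel$loci$locus_id)
ff <- new_truth_genotypes(matrix(2L, 1, L), "cross_pb", panel$loci$locus_id)
off <- simulate_cross(panel, oo, ff, 24, seed = 4001)
rownames(off$dosage) <- paste0("cross_", rownames(off$dosage))
fam <- new_truth_genotypes(rbind(oo$dosage, ff$dosage, off$dosage),
                           c("cross_pa", "cross_pb", rownames(off$dosage)),
                           panel$loci$locus_id)
write_truth_genotypes(fam, "results/cohort/truth_cross.tsv")
write_pileups(simulate_pileups(fam, panel, mean_coverage = 1.2, seed = 4002),
              "results/cohort/pileups_cross.tsv")
cat("cross family:", nrow(fam$dosage), "fish (2 parents + 24 offspring)\n")

# relatedness fixture: a closed network of related carriers inside SC2017
graph <- generate_relatedness_graph(96, c(5, 25, 30), seed = 5001)
write_pair_graph(graph, "results/cohort/relatedness_SC2017.tsv")
cat("relatedness graph:", nrow(graph), "labeled pairs\n")
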
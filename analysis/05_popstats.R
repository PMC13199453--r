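#!/usr/bin/env Rscript
# Stage 5: population-genetic summaries -- neutral SFS with theta/pi and
# Tajima's D, LD decay across the adaptive loci per timepoint, binomial
# carrier-sampling probabilities, and the relatedness permutation test.

suppressPackageStartupMessages(library(sticklejack))

panel <- read_locus_panel("results/cohort/panel")
complete <- read_genotype_matrix("results/calls_complete_loci.tsv")
tp_of <- sub("_.*$", "", rownames(complete))

# neutral baseline: stationary single-deme runs, folded SFS projected to 40
neut <- do.call(rbind, lapply(1:8, function(s) {
  deme <- neutral_stationary_deme(50, n_loci_pool = 1500, u_genome = 0.5,
                                  generations = 250, seed = 500 + s)
  k <- deme_allele_counts(deme)
  k <- k[k > 0 & k < 100]
  sf <- folded_projected_sfs(k, 100, 40)
  st <- theta_pi_tajima(sf, L_sites = 1500)
  data.frame(replicate = s, S = round(st$S, 1), theta_w = st$theta_w,
             pi = st$pi, tajimas_d = st$tajimas_d)
}))
write.table(neut, "results/neutral_sfs_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("neutral stationary replicates (N = 50, projected to 40 chromosomes):\n")
print(neut, row.names = FALSE, digits = 3)
cat(sprintf("Tajima's D across replicates: mean %.3f, range [%.3f, %.3f]\n\n",
            mean(neut$tajimas_d), min(neut$tajimas_d), max(neut$tajimas_d)))

# LD decay per timepoint over the complete adaptive loci (marine coding)
for (tp in c("SC2013", "SC2014", "SC2017")) {
  dos <- 2L - complete[tp_of == tp, , drop = FALSE]
  ld <- tryCatch(
    ld_decay(dos, panel, n_boot = 200, seed = 51),
    error = function(e) NULL)
  if (is.null(ld)) { cat(tp, ": too little dosage variance for LD\n"); next }
  write.table(ld, sprintf("results/ld_decay_%s.tsv", tp), sep = "\t",
              quote = FALSE, row.names = FALSE)
  near <- ld$mean_r2[1]
  far <- ld$mean_r2[nrow(ld)]
  cat(sprintf("%s: mean r2 %.3f in nearest bin vs %.3f in farthest (%d bins)\n",
              tp, near, far, nrow(ld)))
}

# binomial sampling probabilities for jackpot carriers at 0.1% frequency
tab <- data.frame(
  n = c(96, 3000, 3000, 3000, 3000), k_min = c(1, 1, 5, 7, 10))
tab$probability <- mapply(function(n, k) jackpot_sampling_prob(n, 0.001, k),
                          tab$n, tab$k_min)
write.table(tab, "results/jackpot_sampling_probs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nP(>= k carriers | frequency 0.1%):\n")
print(tab, row.names = FALSE, digits = 3)

# relatedness enrichment: observed pairs vs random 20-fish subsamples
graph <- read_pair_graph("results/cohort/relatedness_SC2017.tsv")
perm <- relatedness_permutation(graph, 96, n_sub = 20, reps = 1000, seed = 52)
cat(sprintf("\nrelatedness permutation (60 pairs among 96): mean %.2f pairs per 20-fish subsample (expected %.2f), range %d-%d, %d of 1000 reps with none\n",
            perm$mean, perm$expected, perm$min, perm$max, perm$n_zero_reps))
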
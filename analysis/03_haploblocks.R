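#!/usr/bin/env Rscript
# Stage 3: per-individual freshwater content over the complete loci, and
# haploblock detection with and without the 0.8 Mb maximum-gap threshold.

suppressPackageStartupMessages(library(sticklejack))

panel <- read_locus_panel("results/cohort/panel")
complete <- read_genotype_matrix("results/calls_complete_loci.tsv")
tp_of <- sub("_.*$", "", rownames(complete))

ct <- freshwater_content(complete, timepoint = tp_of)
write.table(ct, "results/content.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("freshwater content by timepoint (called loci only):\n")
print(aggregate(content ~ timepoint, ct, function(x)
  c(mean = round(mean(x), 4), max = round(max(x), 3))), row.names = FALSE)

for (gap in list(c("none", NA), c("0.8Mb", 0.8e6))) {
  g <- if (is.na(gap[2])) NULL else as.numeric(gap[2])
  hb <- find_haploblocks(complete, panel, max_gap_bp = g)
  blocks <- hb$blocks
  blocks$timepoint <- sub("_.*$", "", blocks$sample)
  write_blocks(blocks, sprintf("results/haploblocks_gap_%s.tsv", gap[1]))
  summ <- block_length_summary(blocks, group = "timepoint",
                               span = "span_bp", n_boot = 200, seed = 31)
  cat(sprintf("\nhaploblocks (gap threshold: %s): %d blocks, %d singletons\n",
              gap[1], nrow(blocks), sum(hb$singletons$n_singletons)))
  print(summ$summary, row.names = FALSE, digits = 3)
  if (!is.null(summ$comparisons)) {
    keep <- summ$comparisons[abs(summ$comparisons$cohens_d) > 0.2, ]
    if (nrow(keep)) {
      cat("group pairs with |Cohen's D| > 0.2:\n")
      print(keep, row.names = FALSE, digits = 3)
    }
  }
}
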
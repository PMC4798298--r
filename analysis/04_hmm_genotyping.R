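#!/usr/bin/env Rscript
# Individually sequence the HS segregants of each backcross at ~1X,
# exclude individuals under 1.02X mean coverage, decode each genome with
# the two-state HMM, and drop segregants that turn out to carry the
# wild-type IRA2 haplotype. Accuracy is measured against the simulation
# truth, which real data does not offer.

library(gxemap)
set.seed(2018)
dir.create("results", showWarnings = FALSE)

map <- default_genome_map()
for (bc in c("BY", "3S")) {
  design <- backcross_design(map, bc)
  panel <- simulate_panel(design, map, 80, target_class = "HS")
  obs <- lapply(seq_len(80), function(i)
    simulate_individual_reads(panel$genomes[i, ], map, 1.1))
  names(obs) <- sprintf("seg%04d", seq_len(80))
  keep <- vapply(obs, coverage_filter, TRUE, map = map)
  cat(sprintf("%s backcross: %d of 80 HS segregants pass the 1.02X filter\n",
              bc, sum(keep)))
  obs <- obs[keep]
  write_observations(obs, sprintf("results/observations_%s.tsv", bc))
  calls <- lapply(obs, genotype_hmm, map = map, design = design)
  carriers <- mutation_carriers(calls, map)
  cat(sprintf("  %d decoded individuals carry the ira2 mutation (all should)\n",
              sum(carriers)))
  G <- genotype_matrix(calls[carriers], design)
  write_genotypes(G, sprintf("results/genotypes_%s.tsv", bc))
  seg <- which(design$segregating)
  truth <- t(panel$genomes[keep, seg][carriers, ] >= 1L) + 0L
  acc <- mean(G == truth, na.rm = TRUE)
  called <- mean(!is.na(G))
  cat(sprintf("  HMM accuracy %.2f%% at %.0f%% of SNPs confidently called\n",
              100 * acc, 100 * called))
}
cat("wrote results/observations_*.tsv, genotypes_*.tsv\n")
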
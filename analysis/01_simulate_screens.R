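#!/usr/bin/env Rscript
# Simulate the 21 C screens of both backcrosses on the desk-scale map and
# write the raw artifacts (SNP map, replicate colony scores, truth
# records). Both backcrosses of the rough focal segregant are screened at
# 21 C because every temperature-sensitivity class expresses there.

library(gxemap)
set.seed(2016)
dir.create("results", showWarnings = FALSE)

map <- default_genome_map()
write_snp_map(map, "results/snp_map.tsv")
write_rule_set(default_rule_set(), "results/ruleset.json")

for (bc in c("BY", "3S")) {
  design <- backcross_design(map, bc)
  panel <- simulate_panel(design, map, 150, screen_temperature = 21)
  scores <- simulate_panel_scores(panel, replicates = 3)
  write_phenotypes(scores, sprintf("results/phenotypes_%s.tsv", bc))
  write_truth(truth_record(panel), sprintf("results/truth_%s.json", bc))
  cat(sprintf("%s backcross: %d rough segregants collected from %d examined\n",
              bc, length(panel$class), panel$examined))
  print(table(panel$class))
}
cat("wrote results/snp_map.tsv, phenotypes_*.tsv, truth_*.json\n")
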
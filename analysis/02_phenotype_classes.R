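#!/usr/bin/env Rscript
# Turn replicate 0-5 colony scores into per-temperature smooth/rough
# states (median in [0,1] or [4,5]) and temperature-sensitivity classes,
# then compare the calls with the simulation truth.

library(gxemap)

for (bc in c("BY", "3S")) {
  scores <- read_phenotypes(sprintf("results/phenotypes_%s.tsv", bc))
  calls <- classify_phenotypes(scores)
  write_class_calls(calls, sprintf("results/class_calls_%s.tsv", bc))
  truth <- read_truth(sprintf("results/truth_%s.json", bc))
  agree <- mean(calls$class == truth$individuals$class)
  cat(sprintf("%s backcross: %.1f%% classified; %.1f%% agree with truth\n",
              bc, 100 * attr(calls, "fraction_classified"), 100 * agree))
  print(table(calls$class))
}
cat("wrote results/class_calls_*.tsv\n")
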
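#!/usr/bin/env Rscript
# Scan the 3S-backcross HS panel for genotypic heterogeneity: collapse
# SNPs into segregating regions, chi-square every inter-chromosomal
# region pair, threshold at Storey q <= 0.01, and dissect the detected
# focal locus by partitioning the panel at MSS11. The panel emulates a
# 70/30 mixture of the MSS11^BY- and MSS11^3S-dependent HS genotypes.

library(gxemap)
set.seed(2019)
dir.create("results", showWarnings = FALSE)

map <- default_genome_map()
design <- backcross_design(map, "3S")
panel <- simulate_panel(design, map, 90, target_class = "HS",
                        mixture_locus = "MSS11",
                        mixture_props = c(BY = 0.7, "3S" = 0.3))
G <- panel_genotype_matrix(panel)
regions <- exclude_telomeric(collapse_regions(G), map)
cat(sprintf("%d segregating regions after the 20 kb telomere exclusion\n",
            length(regions)))
utils::write.table(regions_table(regions), "results/regions_3S_HS.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
tests <- pairwise_chi2(regions)
tests$q <- compute_qvalues(tests$p)
utils::write.table(tests, "results/pair_tests_3S_HS.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
sig <- significant_pairs(tests, q_threshold = 0.01)
cat(sprintf("%d of %d inter-chromosomal pairs significant at q <= 0.01\n",
            nrow(sig), nrow(tests)))
locus_of <- function(id) {
  r <- regions[[id]]
  h <- map$loci$locus[map$loci$chrom == r$chrom &
                        map$loci$pos >= r$start & map$loci$pos <= r$end]
  if (length(h)) h[1] else sprintf("%s:%d-%d", r$chrom, r$start, r$end)
}
if (nrow(sig)) {
  sig$locusA <- vapply(sig$regionA, locus_of, "")
  sig$locusB <- vapply(sig$regionB, locus_of, "")
  print(utils::head(sig[, c("locusA", "locusB", "chi2", "q")], 10))
}

# partition at the MSS11-containing region and call skewed loci
mss11 <- map$loci[map$loci$locus == "MSS11", ]
focal <- Find(function(r) r$chrom == mss11$chrom && r$start <= mss11$pos &&
                r$end >= mss11$pos, regions)
part <- partition_and_call(G, focal)
for (a in names(part)) {
  calls <- part[[a]]$calls
  calls$locus <- vapply(seq_len(nrow(calls)), function(i) {
    h <- map$loci$locus[map$loci$chrom == calls$chrom[i] &
                          map$loci$pos >= calls$start[i] &
                          map$loci$pos <= calls$end[i]]
    if (length(h)) h[1] else NA_character_
  }, "")
  cat(sprintf("MSS11^%s subgroup (n = %d) calls: %s\n", a, part[[a]]$n,
              paste(stats::na.omit(paste0(calls$locus, "^", calls$allele)[
                !is.na(calls$locus)]), collapse = " ")))
  utils::write.table(calls, sprintf("results/partition_calls_MSS11%s.tsv", a),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote results/regions_3S_HS.tsv, pair_tests_3S_HS.tsv, partition_calls_*.tsv\n")
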
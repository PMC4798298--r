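# Backcross meiosis, screen, and sequencing simulators.

test_that("the Haldane map function behaves at its landmarks", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(1e9), 0.5, tolerance = 1e-6)
  # 1 cM at the study's 3,300 bp/cM scale
  expect_equal(haldane_r(3300), (1 - exp(-0.02)) / 2)
  expect_equal(haldane_r(3300), 0.009901, tolerance = 1e-4)
})

test_that("adjacent-SNP recombinant fractions match the Haldane fraction", {
  map <- genome_map(data.frame(chrom = "c1", length = 20000),
                    data.frame(chrom = "c1", pos = c(5000, 8300, 18200)))
  des <- cross_design(map, rep(1L, 3), rep(0L, 3))
  set.seed(11)
  g <- simulate_gametes(des, map, 1e4)
  for (j in 1:2) {
    d <- diff(map$snps$pos)[j]
    r <- haldane_r(d)
    obs <- mean(g[, j] != g[, j + 1])
    se <- sqrt(r * (1 - r) / 1e4)
    expect_lt(abs(obs - r), 3 * se + 1e-9)
  }
  # first-SNP origin is a fair coin
  expect_lt(abs(mean(g[, 1]) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("fixed regions are invariant across all segregants of a backcross", {
  set.seed(12)
  map <- default_genome_map()
  des <- backcross_design(map, "BY")
  g <- simulate_gametes(des, map, 40)
  fixed <- !des$segregating
  expect_true(all(g[, fixed] == matrix(des$focal[fixed], 40, sum(fixed),
                                       byrow = TRUE)))
})

test_that("simulating gametes on an empty map errors", {
  map <- genome_map(data.frame(chrom = "c1", length = 1000),
                    data.frame(chrom = character(0), pos = numeric(0)))
  des <- cross_design(map, integer(0), integer(0))
  expect_error(simulate_gametes(des, map, 5), "empty")
})

test_that("screens collect only individuals expressing at the screen temperature", {
  set.seed(13)
  map <- default_genome_map()
  des <- backcross_design(map, "BY")
  p37 <- simulate_panel(des, map, 30, screen_temperature = 37)
  # only the NS genotype is rough at 37 C
  expect_true(all(p37$class == "NS"))
  # a design with no satisfiable rule errors up front
  all_by <- cross_design(map, rep(0L, nrow(map$snps)), rep(0L, nrow(map$snps)))
  expect_error(simulate_panel(all_by, map, 5), "no rule")
})

test_that("screened class composition matches exact enumeration of the rules", {
  set.seed(14)
  map <- default_genome_map()
  des <- backcross_design(map, "3S")
  # enumerate every causal-locus combination and its class
  dl <- des$loci
  cols <- lapply(seq_len(nrow(dl)), function(i) {
    if (dl$segregating[i]) c(dl$focal[i], dl$recurrent[i]) else dl$focal[i]
  })
  names(cols) <- dl$locus
  tab <- as.matrix(expand.grid(cols, stringsAsFactors = FALSE))
  cls <- apply(tab, 1, classify_genotype)
  rough21 <- cls != "SMOOTH"  # every class expresses at 21 C
  expected <- table(cls[rough21]) / sum(rough21)
  n <- 400
  panel <- simulate_panel(des, map, n, screen_temperature = 21)
  for (k in names(expected)) {
    p <- as.numeric(expected[k])
    obs <- mean(panel$class == k)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
  }
})

test_that("marginal allele frequency at unlinked SNPs is one half", {
  set.seed(15)
  map <- default_genome_map()
  des <- backcross_design(map, "BY")
  panel <- simulate_panel(des, map, 150, screen_temperature = 21)
  # chrX segregates in the BY backcross and carries no causal locus
  j <- which(map$snps$chrom == "chrX")[1]
  f <- mean(panel$genomes[, j] == 1L)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 150))
})

test_that("the mixture override fixes the focal-allele composition", {
  set.seed(16)
  map <- default_genome_map()
  des <- backcross_design(map, "3S")
  panel <- simulate_panel(des, map, 60, target_class = "HS",
                          mixture_locus = "MSS11",
                          mixture_props = c(BY = 0.7, "3S" = 0.3))
  expect_equal(sum(panel$genotypes[, "MSS11"] == "BY"), 42)
  expect_equal(sum(panel$genotypes[, "MSS11"] == "3S"), 18)
  expect_true(all(panel$class == "HS"))
})

test_that("pooled counts are binomial draws at the pool allele frequency", {
  map <- default_genome_map()
  des <- backcross_design(map, "3S")
  set.seed(17)
  g <- simulate_gametes(des, map, 40)
  # error-free: SNPs fixed 3S in the pool yield no BY reads
  counts0 <- simulate_pool_counts(g, map, 50, error_rate = 0)
  fixed3S <- which(colMeans(g >= 1L) == 1)
  expect_true(all(counts0$count_BY[fixed3S] == 0))
  # mean estimated frequency tracks the pool frequency over many sites
  f <- colMeans(g >= 1L)
  est <- counts0$count_3S / pmax(counts0$count_BY + counts0$count_3S, 1)
  resid <- est - f
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(length(resid)))
  # a coin-flip error rate erases all signal
  counts5 <- simulate_pool_counts(g, map, 50, error_rate = 0.5)
  est5 <- counts5$count_3S / pmax(counts5$count_BY + counts5$count_3S, 1)
  expect_lt(abs(mean(est5) - 0.5), 0.01)
})

test_that("individual read simulation respects Poisson coverage moments", {
  map <- default_genome_map()
  des <- backcross_design(map, "BY")
  set.seed(18)
  g <- simulate_gametes(des, map, 1)[1, ]
  obs0 <- simulate_individual_reads(g, map, 0)
  expect_equal(nrow(obs0), 0)
  obs1 <- simulate_individual_reads(g, map, 1)
  S <- nrow(map$snps)
  expect_lt(abs(attr(obs1, "mean_coverage") - 1), 3 * sqrt(1 / S))
  # deep error-free coverage: the majority allele equals the truth everywhere
  obs30 <- simulate_individual_reads(g, map, 30, error_rate = 0)
  i <- match(paste(obs30$chrom, obs30$pos), paste(map$snps$chrom, map$snps$pos))
  maj <- obs30$count_3S > obs30$count_BY
  expect_equal(maj, g[i] >= 1L)
})

test_that("phenotype scores place rough medians only at expressed temperatures", {
  set.seed(19)
  s_ns <- simulate_phenotype_scores("NS")
  med <- tapply(s_ns$score, s_ns$temperature, median)
  expect_true(all(med >= 4))
  s_hs <- simulate_phenotype_scores("HS")
  med <- tapply(s_hs$score, s_hs$temperature, median)
  expect_true(med["21"] >= 4)
  expect_true(all(med[c("30", "37")] <= 1))
})
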
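# Segregating regions, the pairwise chi-square scan, Storey q-values,
# and genotype partitioning.

mat <- function(rows, chrom = NULL, pos = NULL) {
  G <- do.call(rbind, rows)
  structure(G,
            snp_chrom = if (is.null(chrom)) rep("c1", nrow(G)) else chrom,
            snp_pos = if (is.null(pos)) seq_len(nrow(G)) * 1000 else pos)
}

test_that("identical inheritance patterns collapse into one region", {
  G <- mat(list(c(0, 1, 0, 1), c(0, 1, 0, 1), c(0, 1, 0, 1)))
  expect_length(collapse_regions(G), 1)
  G2 <- mat(list(c(0, 1, 0, 1), c(0, 1, 0, 1), c(1, 0, 1, 0), c(1, 0, 1, 0)))
  r <- collapse_regions(G2)
  expect_length(r, 2)
  expect_equal(r[[1]]$snps, 1:2)
  # a single mid-chromosome recombinant splits the run at its switch
  G3 <- mat(list(c(0, 1, 0, 0), c(0, 1, 0, 0), c(0, 1, 0, 1),
                 c(0, 1, 0, 1), c(0, 1, 0, 1)))
  r3 <- collapse_regions(G3)
  expect_length(r3, 2)
  expect_equal(r3[[1]]$snps, 1:2)
  expect_equal(r3[[2]]$snps, 3:5)
  expect_error(collapse_regions(matrix(integer(0), 0, 4),
                                chrom = character(0), pos = numeric(0)),
               "empty")
})

test_that("missing calls match anything and patterns accumulate", {
  G <- mat(list(c(0, NA, 0, 1), c(0, 1, NA, 1), c(NA, 1, 0, 1)))
  r <- collapse_regions(G)
  expect_length(r, 1)
  expect_equal(unname(r[[1]]$pattern), c(0, 1, 0, 1))
})

test_that("collapse is lossless and bounded by the SNP count", {
  set.seed(41)
  n_snp <- 60; n_ind <- 12
  G <- matrix(sample(c(0L, 1L, NA), n_snp * n_ind, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2)), n_snp, n_ind)
  attr(G, "snp_chrom") <- rep(c("c1", "c2"), each = 30)
  attr(G, "snp_pos") <- rep(seq_len(30) * 1000, 2)
  regions <- collapse_regions(G)
  expect_lte(length(regions), n_snp)
  for (r in regions) {
    for (j in r$snps) {
      ok <- !is.na(G[j, ])
      expect_equal(G[j, ok], r$pattern[ok])
    }
  }
  # alternating patterns leave every SNP its own region
  Galt <- mat(list(c(0, 0), c(1, 1), c(0, 0), c(1, 1)))
  expect_length(collapse_regions(Galt), 4)
})

test_that("telomeric regions are excluded by the 20 kb margin", {
  map <- genome_map(data.frame(chrom = "c1", length = 200e3),
                    data.frame(chrom = "c1", pos = c(5000, 100e3, 196e3)))
  G <- mat(list(c(0, 1), c(1, 0), c(0, 1)), chrom = rep("c1", 3),
           pos = map$snps$pos)
  regions <- collapse_regions(G)
  kept <- exclude_telomeric(regions, map)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$start, 100e3)
  expect_length(exclude_telomeric(regions, map, margin = 0), 3)
})

test_that("pairwise chi-square matches the 2x2 closed form and the oracle", {
  region <- function(chrom, pattern)
    structure(list(chrom = chrom, start = 1, end = 2, snps = 1,
                   pattern = pattern), class = "segregating_region")
  # independence: chi2 = 0, p = 1
  a <- region("c1", rep(c(0, 1), each = 50))
  b <- region("c2", rep(c(0, 1, 0, 1), 25))
  t0 <- pairwise_chi2(list(a, b))
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)
  # perfect association: chi2 = N
  t1 <- pairwise_chi2(list(a, region("c2", a$pattern)))
  expect_equal(t1$chi2, 100)
  # [[30,10],[10,30]] -> chi2 = 20
  x <- rep(c(0, 0, 1, 1), c(30, 10, 10, 30))
  y <- rep(c(0, 1, 0, 1), c(30, 10, 10, 30))
  t2 <- pairwise_chi2(list(region("c1", x), region("c2", y)))
  expect_equal(t2$chi2, 20)
  # oracle: agreement with stats::chisq.test on random patterns
  set.seed(42)
  for (i in 1:10) {
    p1 <- sample(0:1, 80, replace = TRUE)
    p2 <- sample(c(0L, 1L, NA), 80, replace = TRUE, prob = c(.45, .45, .1))
    tt <- pairwise_chi2(list(region("c1", p1), region("c2", p2)))
    keep <- !is.na(p1) & !is.na(p2)
    ref <- suppressWarnings(stats::chisq.test(table(p1[keep], p2[keep]),
                                              correct = FALSE))
    expect_equal(tt$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
  }
  # intra-chromosomal pairs are linkage, not epistasis: never tested
  t3 <- pairwise_chi2(list(a, region("c1", a$pattern), b))
  expect_true(all(t3$chromA != t3$chromB))
  # zero-margin pairs are skipped
  t4 <- pairwise_chi2(list(a, region("c2", rep(1, 100))))
  expect_equal(nrow(t4), 0)
})

test_that("Storey q-values match a brute-force implementation", {
  # fewer than 100 tests: pi0 = 1, pure rank formula
  set.seed(43)
  p <- round(runif(20), 3)
  q <- compute_qvalues(p)
  brute <- vapply(p, function(pi) {
    min(1, min(vapply(p[p >= pi], function(pj)
      length(p) * pj / sum(p <= pj), 0)))
  }, 0)
  expect_equal(as.numeric(q), brute, tolerance = 1e-12)
  expect_equal(attr(q, "pi0"), 1)
  # q is non-decreasing in p
  big <- runif(500)
  qb <- compute_qvalues(big)
  expect_true(all(diff(qb[order(big)]) >= -1e-12))
  # with many tests the same rank formula holds at the estimated pi0
  qb_brute <- vapply(big, function(pi) {
    min(1, min(vapply(big[big >= pi], function(pj)
      attr(qb, "pi0") * length(big) * pj / sum(big <= pj), 0)))
  }, 0)
  expect_equal(as.numeric(qb), qb_brute, tolerance = 1e-12)
  # degenerate inputs
  expect_equal(as.numeric(compute_qvalues(rep(1, 5))), rep(1, 5))
  expect_error(compute_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("significant pairs are thresholded on q and sorted", {
  tests <- data.frame(regionA = 1:4, regionB = 5:8,
                      chromA = "c1", chromB = "c2",
                      n = 90, chi2 = c(50, 2, 30, 1),
                      p = c(1e-12, 0.3, 1e-7, 0.9))
  sig <- significant_pairs(tests, q_threshold = 0.01)
  expect_equal(sig$chi2, c(50, 30))
  expect_equal(nrow(significant_pairs(tests, q_threshold = 0)), 0)
})

test_that("partitioning a mixed HS panel resolves the minority genotype's alleles", {
  set.seed(44)
  map <- default_genome_map()
  des <- backcross_design(map, "3S")
  panel <- simulate_panel(des, map, 60, target_class = "HS",
                          mixture_locus = "MSS11",
                          mixture_props = c(BY = 0.7, "3S" = 0.3))
  G <- panel_genotype_matrix(panel)
  regions <- collapse_regions(G)
  mss11 <- map$loci[map$loci$locus == "MSS11", ]
  focal <- Find(function(r) r$chrom == mss11$chrom &&
                  r$start <= mss11$pos && r$end >= mss11$pos, regions)
  part <- partition_and_call(G, focal)
  expect_equal(part[["3S"]]$n, 18)
  # the MSS11^3S subgroup requires XII^3S, END3^BY, MGA1^BY, SFL1^BY
  want <- data.frame(locus = c("XII", "END3", "MGA1", "SFL1"),
                     allele = c("3S", "BY", "BY", "BY"))
  calls <- part[["3S"]]$calls
  for (i in seq_len(nrow(want))) {
    li <- map$loci[map$loci$locus == want$locus[i], ]
    hit <- calls[calls$chrom == li$chrom & calls$start <= li$pos &
                   calls$end >= li$pos, ]
    expect_equal(nrow(hit), 1, info = want$locus[i])
    expect_equal(hit$allele, want$allele[i], info = want$locus[i])
  }
  # an unlinked chromosome in the larger subgroup stays uncalled
  expect_false(any(part[["BY"]]$calls$chrom == "chrVIII"))
  # a subgroup with no carriers errors by allele name
  mono <- structure(list(chrom = "c9", start = 1, end = 2, snps = 1,
                         pattern = rep(1, ncol(G))),
                    class = "segregating_region")
  expect_error(partition_and_call(G, mono), "BY")
})
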
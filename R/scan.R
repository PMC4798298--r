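# Genotypic-heterogeneity scan: collapse linked SNPs with identical
# inheritance patterns into segregating regions, chi-square test every
# inter-chromosomal region pair for correlated allele states, control the
# false discovery rate with Storey q-values, and dissect detected pairs
# by partitioning the panel at a focal region.

#' Collapse linked SNPs into segregating regions
#'
#' Greedy left-to-right grouping within each chromosome: a SNP joins the
#' current region iff its inheritance pattern equals the region's pattern
#' at every individual where both are non-missing (missing-tolerant
#' equality — low-coverage data has missing calls); otherwise a new
#' region starts. A region's pattern accumulates the non-missing values
#' of its members.
#'
#' @param genotypes SNP x individual matrix in `{0, 1, NA}` over
#'   segregating SNPs, as from [genotype_matrix()] (attributes
#'   `snp_chrom`, `snp_pos`), or with `chrom`/`pos` supplied explicitly.
#' @param chrom,pos per-SNP coordinates (defaults taken from the matrix
#'   attributes).
#' @return list of `segregating_region` objects: `chrom`, `start`, `end`,
#'   `snps` (row indices), `pattern` (vector over individuals).
#' @export
collapse_regions <- function(genotypes, chrom = attr(genotypes, "snp_chrom"),
                             pos = attr(genotypes, "snp_pos")) {
  if (!nrow(genotypes)) stop("empty genotype matrix")
  stopifnot(length(chrom) == nrow(genotypes), length(pos) == nrow(genotypes))
  regions <- list()
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pat <- genotypes[idx[1], ]
    members <- idx[1]
    flush <- function() {
      regions[[length(regions) + 1L]] <<- structure(
        list(chrom = cc, start = pos[members[1]],
             end = pos[members[length(members)]],
             snps = members, pattern = pat),
        class = "segregating_region")
    }
    for (j in idx[-1]) {
      g <- genotypes[j, ]
      both <- !is.na(g) & !is.na(pat)
      if (all(g[both] == pat[both])) {
        members <- c(members, j)
        fill <- is.na(pat) & !is.na(g)
        pat[fill] <- g[fill]
      } else {
        flush()
        pat <- g; members <- j
      }
    }
    flush()
  }
  regions
}

#' Drop regions near chromosome ends
#'
#' Regions overlapping the first or last `margin` bases of their
#' chromosome are excluded (short-read mapping is unreliable near
#' telomeres).
#'
#' @param regions list from [collapse_regions()].
#' @param map the `genome_map` (chromosome lengths).
#' @param margin bp (default 20000).
#' @return filtered region list.
#' @export
exclude_telomeric <- function(regions, map, margin = 20000) {
  L <- setNames(map$chromosomes$length, map$chromosomes$chrom)
  keep <- vapply(regions, function(r) {
    r$start > margin && r$end <= L[r$chrom] - margin
  }, TRUE)
  regions[keep]
}

#' Chi-square tests for all inter-chromosomal region pairs
#'
#' For every pair of regions on different chromosomes, the 2x2 table of
#' joint allele states over individuals non-missing at both regions is
#' scored with the Pearson chi-square statistic (no continuity
#' correction, df = 1, upper-tail p). Pairs with any zero table margin
#' are skipped (their p is undefined). The statistic is computed in
#' closed form over all pairs at once via matrix products.
#'
#' @param regions list from [collapse_regions()].
#' @return data.frame of `pair_test`s: `regionA`, `regionB` (indices into
#'   `regions`), `chromA`, `chromB`, `n`, `chi2`, `p`.
#' @export
pairwise_chi2 <- function(regions) {
  R <- length(regions)
  if (R < 2) stop("need at least two regions")
  chrom <- vapply(regions, `[[`, "", "chrom")
  if (length(unique(chrom)) < 2) stop("need regions on at least two chromosomes")
  P <- do.call(rbind, lapply(regions, `[[`, "pattern"))
  B1 <- P == 1; B1[is.na(B1)] <- FALSE
  B0 <- P == 0; B0[is.na(B0)] <- FALSE
  n11 <- B1 %*% t(B1); n10 <- B1 %*% t(B0)
  n01 <- B0 %*% t(B1); n00 <- B0 %*% t(B0)
  ut <- which(upper.tri(n11) & outer(chrom, chrom, "!="), arr.ind = TRUE)
  a <- n00[ut]; b <- n01[ut]; c_ <- n10[ut]; d <- n11[ut]
  N <- a + b + c_ + d
  m1 <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  ok <- m1 > 0
  chi2 <- ifelse(ok, N * (a * d - b * c_)^2 / m1, NA_real_)
  out <- data.frame(regionA = ut[, 1], regionB = ut[, 2],
                    chromA = chrom[ut[, 1]], chromB = chrom[ut[, 2]],
                    n = N, chi2 = chi2,
                    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Storey q-values
#'
#' The proportion of true nulls pi0 is estimated on the lambda grid
#' 0.05, 0.10, ..., 0.95 and smoothed with a cubic spline evaluated at
#' the largest lambda; the estimate falls back to 1 (plain
#' Benjamini-Hochberg behavior) when it exceeds 1, is non-positive, or
#' fewer than 100 tests are available. q_i is the minimum over
#' p_j >= p_i of pi0 * m * p_j / rank(p_j), capped at 1.
#'
#' @param p p-values in \[0, 1\].
#' @return q-values in the input order, with attribute `pi0`.
#' @export
compute_qvalues <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- 1
  if (m >= 100) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    est <- stats::predict(fit, x = max(lambda))$y
    if (is.finite(est) && est > 0 && est <= 1) pi0 <- est
  }
  o <- order(p)
  r <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- pmin(rev(cummin(rev(r))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Select significant region pairs at a q-value threshold
#'
#' @param tests data.frame from [pairwise_chi2()]; a `q` column is added
#'   (via [compute_qvalues()]) if absent.
#' @param q_threshold point-wise FDR (default 0.01, the study's 1% rule).
#' @return significant rows sorted by q then decreasing chi2.
#' @export
significant_pairs <- function(tests, q_threshold = 0.01) {
  if (!"q" %in% names(tests)) tests$q <- compute_qvalues(tests$p)
  out <- tests[tests$q <= q_threshold, , drop = FALSE]
  out <- out[order(out$q, -out$chi2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition a panel at a focal region and call skewed loci
#'
#' Splits individuals by their allele at the focal region, computes each
#' subgroup's per-SNP 3S-allele frequency smoothed over `window` SNPs,
#' and calls loci wherever the smoothed frequency falls below `low` or
#' above `high`; adjacent called SNPs merge into intervals. This is the
#' step that resolves which alleles each multi-locus genotype requires
#' once a heterogeneous class has been split at its focal locus.
#'
#' @param genotypes SNP x individual matrix as in [collapse_regions()].
#' @param focal a `segregating_region` (its pattern defines the split).
#' @param chrom,pos per-SNP coordinates (defaults from attributes).
#' @param window smoothing window in SNPs (default 25).
#' @param low,high calling thresholds on the smoothed frequency
#'   (defaults 0.10 / 0.90).
#' @return list with one element per focal allele (`"BY"`, `"3S"`), each
#'   holding `n`, `track` (chrom, pos, freq, freq_smooth) and `calls`
#'   (chrom, start, end, allele — the enriched parental allele).
#' @export
partition_and_call <- function(genotypes, focal,
                               chrom = attr(genotypes, "snp_chrom"),
                               pos = attr(genotypes, "snp_pos"),
                               window = 25, low = 0.10, high = 0.90) {
  stopifnot(low > 0, high < 1, low < high)
  groups <- list("BY" = which(focal$pattern == 0),
                 "3S" = which(focal$pattern == 1))
  out <- list()
  for (a in names(groups)) {
    cols <- groups[[a]]
    if (!length(cols))
      stop("no individuals carry the ", a, " allele at the focal region")
    G <- genotypes[, cols, drop = FALSE]
    freq <- rowMeans(G, na.rm = TRUE)
    freq[is.nan(freq)] <- NA_real_
    track <- data.frame(chrom = chrom, pos = pos, freq = freq)
    track$freq_smooth <- moving_average_by(track$freq, track$chrom, window)
    called <- !is.na(track$freq_smooth) &
      (track$freq_smooth < low | track$freq_smooth > high)
    dir <- ifelse(track$freq_smooth > high, "3S", "BY")
    calls <- list()
    for (cc in unique(track$chrom)) {
      idx <- which(track$chrom == cc)
      grp <- paste(called[idx], ifelse(called[idx], dir[idx], ""))
      r <- rle(grp)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (i in seq_along(r$lengths)) {
        if (!startsWith(r$values[i], "TRUE")) next
        b <- idx[starts[i]:ends[i]]
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = cc, start = pos[b[1]], end = pos[b[length(b)]],
          allele = dir[b[1]], stringsAsFactors = FALSE)
      }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
      data.frame(chrom = character(0), start = numeric(0),
                 end = numeric(0), allele = character(0))
    out[[a]] <- list(n = length(cols), track = track, calls = calls)
  }
  out
}

#' Summarize segregating regions as a data.frame
#'
#' @param regions list from [collapse_regions()].
#' @return data.frame `region`, `chrom`, `start`, `end`, `n_snps`.
#' @export
regions_table <- function(regions) {
  data.frame(region = seq_along(regions),
             chrom = vapply(regions, `[[`, "", "chrom"),
             start = vapply(regions, `[[`, 0, "start"),
             end = vapply(regions, `[[`, 0, "end"),
             n_snps = vapply(regions, function(r) length(r$snps), 0L))
}
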
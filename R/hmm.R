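# HMM haplotype inference for low-coverage individually sequenced
# segregants. Two hidden states (focal vs recurrent parental origin),
# Haldane transition probabilities between adjacent segregating SNPs,
# per-read emissions with a symmetric allele error, log-space
# throughout. Hard calls come from Viterbi (ties broken toward the
# previous SNP's state, preserving segments); per-SNP confidences from
# forward-backward.

#' Mean per-site coverage of a set of site observations
#'
#' @param observations a `site_observations` data.frame.
#' @param map the `genome_map` (total SNP count is the denominator).
#' @return total reads / total map SNPs.
#' @export
mean_site_coverage <- function(observations, map) {
  sum(observations$count_BY + observations$count_3S) / n_snps(map)
}

#' Coverage filter for individually sequenced segregants
#'
#' Individuals with average per-site coverage below `min_coverage`
#' (default 1.02X, the study's exclusion rule) are dropped; coverage
#' exactly at the threshold is kept.
#'
#' @inheritParams mean_site_coverage
#' @param min_coverage threshold in reads/site.
#' @return logical: keep this individual?
#' @export
coverage_filter <- function(observations, map, min_coverage = 1.02) {
  mean_site_coverage(observations, map) >= min_coverage
}

log_sum_exp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

#' Infer per-SNP parental origin for one segregant
#'
#' Decodes the haplotype of a low-coverage individual over the SNPs that
#' segregate in its cross; fixed regions are filled in from the design.
#' States are the focal and recurrent parental haplotypes, with initial
#' distribution (1/2, 1/2), Haldane transitions, and per-read emissions
#' that report the true allele with probability `1 - error_rate`.
#'
#' @param observations a `site_observations` data.frame (`chrom`, `pos`,
#'   `count_BY`, `count_3S`).
#' @param map the `genome_map`.
#' @param design the `cross_design` of the individual's backcross.
#' @param error_rate per-read allele error (default 0.005).
#' @return A `haplotype_call` data.frame over all map SNPs: `chrom`,
#'   `pos`, `origin` (`"focal"`/`"recurrent"`), `allele` (`"BY"`, `"3S"`
#'   or `"MUT"`), `posterior` (forward-backward probability of the called
#'   state; 1 at fixed SNPs), `segregating`, `low_confidence`
#'   (posterior < 0.75).
#' @export
genotype_hmm <- function(observations, map, design, error_rate = 0.005) {
  S <- n_snps(map)
  if (!any(design$segregating)) stop("design has no segregating SNPs")
  kBY <- kS <- rep(0, S)
  key <- paste(observations$chrom, observations$pos)
  i <- match(key, paste(map$snps$chrom, map$snps$pos))
  if (anyNA(i)) stop("observations contain SNPs absent from the map")
  kBY[i] <- observations$count_BY
  kS[i] <- observations$count_3S
  origin <- ifelse(design$segregating, NA_character_, "fixed")
  posterior <- rep(1, S)
  le <- log(error_rate); lc <- log1p(-error_rate)
  for (cc in unique(map$snps$chrom)) {
    idx <- which(map$snps$chrom == cc & design$segregating)
    m <- length(idx)
    if (!m) next
    # read-space allele of each state at each SNP (MUT reads as 3S)
    foc3 <- design$focal[idx] >= 1L
    rec3 <- design$recurrent[idx] >= 1L
    eF <- ifelse(foc3, kS[idx], kBY[idx]) * lc +
          ifelse(foc3, kBY[idx], kS[idx]) * le
    eR <- ifelse(rec3, kS[idx], kBY[idx]) * lc +
          ifelse(rec3, kBY[idx], kS[idx]) * le
    r <- haldane_r(diff(map$snps$pos[idx]), map$map_scale)
    lr <- log(r); ls <- log1p(-r)
    # Viterbi
    vF <- vR <- numeric(m); ptrF <- ptrR <- integer(m)
    vF[1] <- log(0.5) + eF[1]; vR[1] <- log(0.5) + eR[1]
    if (m > 1) for (j in 2:m) {
      stayF <- vF[j - 1] + ls[j - 1]; swF <- vR[j - 1] + lr[j - 1]
      ptrF[j] <- if (stayF >= swF) 1L else 2L
      vF[j] <- max(stayF, swF) + eF[j]
      stayR <- vR[j - 1] + ls[j - 1]; swR <- vF[j - 1] + lr[j - 1]
      ptrR[j] <- if (stayR >= swR) 2L else 1L
      vR[j] <- max(stayR, swR) + eR[j]
    }
    path <- integer(m)
    path[m] <- if (vF[m] >= vR[m]) 1L else 2L
    if (m > 1) for (j in m:2) path[j - 1] <- if (path[j] == 1L) ptrF[j] else ptrR[j]
    # forward-backward
    aF <- aR <- bF <- bR <- numeric(m)
    aF[1] <- log(0.5) + eF[1]; aR[1] <- log(0.5) + eR[1]
    if (m > 1) for (j in 2:m) {
      aF[j] <- log_sum_exp2(aF[j - 1] + ls[j - 1], aR[j - 1] + lr[j - 1]) + eF[j]
      aR[j] <- log_sum_exp2(aR[j - 1] + ls[j - 1], aF[j - 1] + lr[j - 1]) + eR[j]
    }
    bF[m] <- 0; bR[m] <- 0
    if (m > 1) for (j in (m - 1):1) {
      bF[j] <- log_sum_exp2(ls[j] + eF[j + 1] + bF[j + 1],
                            lr[j] + eR[j + 1] + bR[j + 1])
      bR[j] <- log_sum_exp2(ls[j] + eR[j + 1] + bR[j + 1],
                            lr[j] + eF[j + 1] + bF[j + 1])
    }
    gF <- aF + bF; gR <- aR + bR
    z <- log_sum_exp2(gF, gR)
    pF <- exp(gF - z)
    origin[idx] <- ifelse(path == 1L, "focal", "recurrent")
    posterior[idx] <- ifelse(path == 1L, pF, 1 - pF)
  }
  allele <- allele_label(ifelse(origin == "recurrent", design$recurrent,
                                design$focal))
  structure(data.frame(chrom = map$snps$chrom, pos = map$snps$pos,
                       origin = origin, allele = allele,
                       posterior = posterior,
                       segregating = design$segregating,
                       low_confidence = posterior < 0.75,
                       stringsAsFactors = FALSE),
            class = c("haplotype_call", "data.frame"))
}

#' Build a SNP x individual genotype matrix from haplotype calls
#'
#' Segregating SNPs only; alleles coded 0 (BY) / 1 (3S, with MUT
#' collapsed onto its carrier 3S haplotype); low-confidence calls become
#' `NA` (missing, written as `N` on disk).
#'
#' @param calls named list of `haplotype_call` data.frames.
#' @param design the shared `cross_design`.
#' @return integer matrix (segregating SNPs x individuals) with
#'   `chrom`/`pos` kept in attributes `snp_chrom` / `snp_pos`.
#' @export
genotype_matrix <- function(calls, design) {
  seg <- which(design$segregating)
  cols <- lapply(calls, function(cl) {
    a <- ifelse(cl$allele[seg] == "BY", 0L, 1L)
    a[cl$low_confidence[seg]] <- NA_integer_
    a
  })
  G <- do.call(cbind, cols)
  colnames(G) <- names(calls)
  structure(G, snp_chrom = design$map$snps$chrom[seg],
            snp_pos = design$map$snps$pos[seg])
}

#' Flag segregants that lack the ira2 mutation
#'
#' Individuals whose decoded origin at the mutation SNP is the recurrent
#' (wild-type) haplotype carry a functional IRA2 and are excluded from
#' downstream analyses of the mutant background (the study dropped 16
#' such individuals from its BY backcross).
#'
#' @param calls named list of `haplotype_call` data.frames.
#' @param map the `genome_map` (needs an IRA2 locus).
#' @return logical vector: carries the mutation?
#' @export
mutation_carriers <- function(calls, map) {
  snp <- map$loci$snp[map$loci$locus == "IRA2"]
  if (!length(snp)) stop("map has no IRA2 locus")
  vapply(calls, function(cl) cl$allele[snp] == "MUT", TRUE)
}
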
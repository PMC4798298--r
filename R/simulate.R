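# Backcross meiosis, phenotype screen, and sequencing simulators.
#
# Randomness uses R's global RNG; seed with set.seed() (the pipeline and
# the analysis drivers do this once, up front).

#' Simulate backcross gametes
#'
#' Meiosis in the focal x recurrent diploid is a Markov walk along each
#' chromosome: the first SNP's transmitted haplotype is Bernoulli(1/2)
#' and adjacent SNPs recombine with the Haldane fraction
#' `haldane_r(d_bp, map_scale)`. SNPs where the parents share an allele
#' come out fixed; the rest report the transmitted parent's allele.
#'
#' @param design a `cross_design`.
#' @param map the `genome_map` the design was built on.
#' @param n number of gametes.
#' @return integer matrix (`n` x SNPs) of allele codes (0 = BY, 1 = 3S,
#'   2 = MUT).
#' @export
simulate_gametes <- function(design, map, n) {
  S <- n_snps(map)
  if (S == 0) stop("empty genome map")
  stopifnot(n >= 1)
  H <- matrix(0L, n, S)  # 1 = focal haplotype transmitted
  for (cc in unique(map$snps$chrom)) {
    idx <- which(map$snps$chrom == cc)
    r <- haldane_r(diff(map$snps$pos[idx]), map$map_scale)
    h <- matrix(0L, n, length(idx))
    h[, 1] <- as.integer(runif(n) < 0.5)
    if (length(idx) > 1) {
      for (j in 2:length(idx)) {
        sw <- runif(n) < r[j - 1]
        h[, j] <- ifelse(sw, 1L - h[, j - 1], h[, j - 1])
      }
    }
    H[, idx] <- h
  }
  foc <- matrix(design$focal, n, S, byrow = TRUE)
  rec <- matrix(design$recurrent, n, S, byrow = TRUE)
  out <- ifelse(H == 1L, foc, rec)
  storage.mode(out) <- "integer"
  out
}

#' Genotype vectors at the map's named loci
#'
#' @param genomes integer allele matrix from [simulate_gametes()].
#' @param map a `genome_map` with a `loci` table.
#' @return character matrix (individuals x loci) of allele labels.
#' @export
genotypes_at_loci <- function(genomes, map) {
  if (is.null(map$loci)) stop("map carries no loci table")
  g <- genomes[, map$loci$snp, drop = FALSE]
  out <- matrix(allele_label(g), nrow(g), ncol(g))
  colnames(out) <- map$loci$locus
  out
}

# vectorized rule evaluation over a genotype matrix; returns a logical
# matrix individuals x rules
satisfaction_matrix <- function(genotypes, rules) {
  rl <- unclass(rules)
  sat <- matrix(FALSE, nrow(genotypes), length(rl),
                dimnames = list(NULL, names(rl)))
  for (k in seq_along(rl)) {
    req <- rl[[k]]$requirements
    m <- genotypes[, names(req), drop = FALSE] ==
      matrix(req, nrow(genotypes), length(req), byrow = TRUE)
    sat[, k] <- rowSums(m) == length(req)
  }
  sat
}

classify_matrix <- function(genotypes, rules) {
  sat <- satisfaction_matrix(genotypes, rules)
  rl <- unclass(rules)
  t21 <- t30 <- t37 <- rep(FALSE, nrow(genotypes))
  for (k in seq_along(rl)) {
    tm <- rl[[k]]$temperatures
    if (21 %in% tm) t21 <- t21 | sat[, k]
    if (30 %in% tm) t30 <- t30 | sat[, k]
    if (37 %in% tm) t37 <- t37 | sat[, k]
  }
  cls <- rep("SMOOTH", nrow(genotypes))
  cls[t21 & !t30 & !t37] <- "HS"
  cls[t21 & t30 & !t37] <- "MS"
  cls[t21 & t30 & t37] <- "NS"
  bad <- (!t21 & (t30 | t37)) | (t21 & !t30 & t37)
  if (any(bad)) stop("rule set produced a temperature set outside the three classes")
  list(class = cls, t21 = t21, t30 = t30, t37 = t37, satisfied = sat)
}

#' Simulate a phenotypic screen of backcross segregants
#'
#' Draws gametes until `n` individuals expressing the rough phenotype at
#' `screen_temperature` (per the rule set) have been collected, attaching
#' each individual's temperature-sensitivity class. Optionally restricts
#' the collection to one class (`target_class`) and/or fixes the mixture
#' of alleles at a focal locus among the collected individuals
#' (`mixture_locus`/`mixture_props`), the override used when emulating
#' screens whose genotype composition deviates from Mendelian
#' expectation.
#'
#' @param design a `cross_design`.
#' @param map the matching `genome_map` (needs a `loci` table).
#' @param n individuals to collect.
#' @param rules a `rule_set`.
#' @param screen_temperature 21, 30 or 37.
#' @param target_class optionally one of `"HS"`, `"MS"`, `"NS"`.
#' @param mixture_locus,mixture_props optional focal locus name and named
#'   proportion vector over its alleles (e.g. `c(BY = 0.7, "3S" = 0.3)`).
#' @param misclass probability that a collected individual's class label
#'   is replaced by a uniform draw over HS/MS/NS (default 0,
#'   deterministic labels).
#' @param max_draws safety cap on examined individuals.
#' @return A `segregant_panel`: list with `genomes` (n x SNP allele
#'   matrix), `genotypes` (n x loci), `class`, `examined`, `design`,
#'   `map`.
#' @export
simulate_panel <- function(design, map, n, rules = default_rule_set(),
                           screen_temperature = 21, target_class = NULL,
                           mixture_locus = NULL, mixture_props = NULL,
                           misclass = 0, max_draws = 2e6) {
  stopifnot(n >= 1, screen_temperature %in% TEMPERATURES)
  freqs <- vapply(unclass(rules), expected_frequency, 0, design = design)
  if (all(freqs == 0))
    stop("no rule can be satisfied under this cross design")
  want_mix <- !is.null(mixture_locus)
  if (want_mix) {
    stopifnot(!is.null(mixture_props), !is.null(names(mixture_props)))
    target_counts <- round(n * mixture_props / sum(mixture_props))
    target_counts[1] <- n - sum(target_counts[-1])
  }
  kept_g <- list(); kept_cls <- character(0); kept_gt <- list()
  examined <- 0L
  block <- max(500L, ceiling(4 * n / max(sum(freqs), 1e-3)))
  mix_have <- if (want_mix) setNames(rep(0L, length(mixture_props)),
                                     names(mixture_props))
  repeat {
    g <- simulate_gametes(design, map, block)
    examined <- examined + block
    gt <- genotypes_at_loci(g, map)
    cm <- classify_matrix(gt, rules)
    expr <- switch(as.character(screen_temperature),
                   "21" = cm$t21, "30" = cm$t30, "37" = cm$t37)
    keep <- expr
    if (!is.null(target_class)) keep <- keep & cm$class == target_class
    if (any(keep)) {
      ki <- which(keep)
      if (want_mix) {
        alle <- gt[ki, mixture_locus]
        take <- integer(0)
        for (a in names(mix_have)) {
          need <- target_counts[a] - mix_have[a]
          ai <- ki[alle == a]
          if (need > 0 && length(ai)) {
            ai <- ai[seq_len(min(need, length(ai)))]
            take <- c(take, ai)
            mix_have[a] <- mix_have[a] + length(ai)
          }
        }
        ki <- take
      }
      if (length(ki)) {
        kept_g[[length(kept_g) + 1L]] <- g[ki, , drop = FALSE]
        kept_gt[[length(kept_gt) + 1L]] <- gt[ki, , drop = FALSE]
        kept_cls <- c(kept_cls, cm$class[ki])
      }
    }
    done <- if (want_mix) all(mix_have >= target_counts) else length(kept_cls) >= n
    if (done) break
    if (examined >= max_draws)
      stop("screen exhausted max_draws before collecting ", n, " individuals")
  }
  genomes <- do.call(rbind, kept_g)
  genotypes <- do.call(rbind, kept_gt)
  if (!want_mix && length(kept_cls) > n) {
    genomes <- genomes[seq_len(n), , drop = FALSE]
    genotypes <- genotypes[seq_len(n), , drop = FALSE]
    kept_cls <- kept_cls[seq_len(n)]
  }
  if (misclass > 0) {
    flip <- runif(length(kept_cls)) < misclass
    kept_cls[flip] <- sample(c("HS", "MS", "NS"), sum(flip), replace = TRUE)
  }
  structure(list(genomes = genomes, genotypes = genotypes,
                 class = kept_cls, examined = examined,
                 design = design, map = map),
            class = "segregant_panel")
}

#' @export
print.segregant_panel <- function(x, ...) {
  cat("segregant_panel:", nrow(x$genomes), "individuals (",
      x$examined, "examined ) from", x$design$name, "\n")
  print(table(x$class))
  invisible(x)
}

#' Simulate replicate colony scores for one individual
#'
#' Temperatures in the class's expressed set draw from the rough score
#' distribution (uniform on 4-5), the others from the smooth distribution
#' (uniform on 0-1). With probability `noise`, a replicate is replaced by
#' a uniform draw on 0-5.
#'
#' @param class one of `"HS"`, `"MS"`, `"NS"`, `"SMOOTH"`.
#' @param replicates biological replicates per temperature (default 3).
#' @param noise replicate corruption probability (default 0).
#' @return data.frame with columns `temperature`, `replicate`, `score`.
#' @export
simulate_phenotype_scores <- function(class, replicates = 3, noise = 0) {
  stopifnot(replicates >= 1)
  expressed <- switch(class, HS = 21L, MS = c(21L, 30L),
                      NS = c(21L, 30L, 37L), SMOOTH = integer(0),
                      stop("unknown class: ", class))
  out <- expand.grid(temperature = TEMPERATURES,
                     replicate = seq_len(replicates))
  rough <- out$temperature %in% expressed
  out$score <- ifelse(rough, sample(4:5, nrow(out), replace = TRUE),
                      sample(0:1, nrow(out), replace = TRUE))
  if (noise > 0) {
    swap <- runif(nrow(out)) < noise
    out$score[swap] <- sample(0:5, sum(swap), replace = TRUE)
  }
  out[order(out$temperature, out$replicate), c("temperature", "replicate", "score")]
}

#' Simulate phenotype scores for a whole panel
#'
#' @param panel a `segregant_panel`.
#' @inheritParams simulate_phenotype_scores
#' @return data.frame with columns `individual`, `temperature`,
#'   `replicate`, `score`.
#' @export
simulate_panel_scores <- function(panel, replicates = 3, noise = 0) {
  out <- lapply(seq_along(panel$class), function(i) {
    s <- simulate_phenotype_scores(panel$class[i], replicates, noise)
    cbind(individual = sprintf("seg%04d", i), s)
  })
  do.call(rbind, out)
}

#' Simulate pooled sequencing of a panel
#'
#' Per SNP the read depth is Poisson(`mean_depth`); each read comes from
#' a uniformly random pool member and reports that member's allele,
#' flipped with probability `error_rate`. MUT collapses to 3S in read
#' space (the mutation sits on a 3S chromosome). The uniform-member model
#' reduces to a single binomial draw per site at the pool allele
#' frequency, which is what is drawn.
#'
#' @param genomes allele matrix (individuals x SNPs) of the pooled panel.
#' @param map the `genome_map`.
#' @param mean_depth mean reads per site (the study pools were >= ~114X).
#' @param error_rate per-read allele error (default 0.005).
#' @return A `pool_counts` data.frame: `chrom`, `pos`, `count_BY`,
#'   `count_3S`.
#' @export
simulate_pool_counts <- function(genomes, map, mean_depth, error_rate = 0.005) {
  stopifnot(nrow(genomes) >= 1, mean_depth > 0)
  f <- colMeans(genomes >= 1L)  # pool frequency of the 3S-side allele
  p <- f * (1 - error_rate) + (1 - f) * error_rate
  depth <- rpois(length(f), mean_depth)
  k3 <- rbinom(length(f), depth, p)
  structure(data.frame(chrom = map$snps$chrom, pos = map$snps$pos,
                       count_BY = depth - k3, count_3S = k3),
            class = c("pool_counts", "data.frame"))
}

#' Simulate low-coverage individual sequencing
#'
#' Per-SNP depth is Poisson(`mean_coverage`); each read reports the true
#' parental-origin allele (MUT reads as 3S), flipped with probability
#' `error_rate`.
#'
#' @param genome one individual's allele vector over map SNPs.
#' @param map the `genome_map`.
#' @param mean_coverage mean reads per site (the study's individuals were
#'   sequenced at about 1X).
#' @param error_rate per-read allele error (default 0.005).
#' @return A `site_observations` data.frame (`chrom`, `pos`, `count_BY`,
#'   `count_3S`, covered sites only) with attribute `mean_coverage` =
#'   total reads / total SNPs.
#' @export
simulate_individual_reads <- function(genome, map, mean_coverage,
                                      error_rate = 0.005) {
  stopifnot(mean_coverage >= 0)
  S <- n_snps(map)
  depth <- rpois(S, mean_coverage)
  covered <- which(depth > 0)
  truth3 <- genome[covered] >= 1L
  p <- ifelse(truth3, 1 - error_rate, error_rate)
  k3 <- rbinom(length(covered), depth[covered], p)
  obs <- data.frame(chrom = map$snps$chrom[covered],
                    pos = map$snps$pos[covered],
                    count_BY = depth[covered] - k3, count_3S = k3)
  structure(obs, class = c("site_observations", "data.frame"),
            mean_coverage = sum(depth) / S)
}

#' True genotype matrix of a panel over its segregating SNPs
#'
#' The error-free counterpart of [genotype_matrix()]: SNP x individual
#' matrix in `{0, 1}` (MUT collapsed onto its carrier 3S haplotype) over
#' the SNPs that segregate in the panel's cross, ready for
#' [collapse_regions()].
#'
#' @param panel a `segregant_panel`.
#' @return integer matrix with `snp_chrom`/`snp_pos` attributes.
#' @export
panel_genotype_matrix <- function(panel) {
  genomes_to_genotype_matrix(panel$genomes, panel$design)
}

#' @rdname panel_genotype_matrix
#' @param genomes individuals x SNP allele matrix from
#'   [simulate_gametes()].
#' @param design the matching `cross_design`.
#' @export
genomes_to_genotype_matrix <- function(genomes, design) {
  seg <- which(design$segregating)
  G <- t(genomes[, seg, drop = FALSE] >= 1L) + 0L
  colnames(G) <- sprintf("seg%04d", seq_len(ncol(G)))
  structure(G, snp_chrom = design$map$snps$chrom[seg],
            snp_pos = design$map$snps$pos[seg])
}

#' Machine-readable truth record for a simulated panel
#'
#' Captures the causal locus positions, the cross design's per-locus
#' segregation, and each individual's multi-locus genotype and class, for
#' consumption by downstream evaluation.
#'
#' @param panel a `segregant_panel`.
#' @return list ready for [write_truth()].
#' @export
truth_record <- function(panel) {
  map <- panel$map
  list(design = panel$design$name,
       causal_loci = cbind(map$loci[, c("locus", "chrom", "pos")],
                           panel$design$loci[, c("focal", "recurrent", "segregating")]),
       n_examined = panel$examined,
       individuals = data.frame(
         individual = sprintf("seg%04d", seq_along(panel$class)),
         class = panel$class,
         genotype = apply(panel$genotypes, 1, function(g)
           paste(colnames(panel$genotypes), g, sep = "^", collapse = " ")),
         stringsAsFactors = FALSE))
}
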
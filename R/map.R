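# Genome maps and cross designs.
#
# Allele codes used throughout: 0 = BY, 1 = 3S, 2 = MUT (the ira2
# frameshift allele, which arose on a 3S chromosome and reads as 3S in
# short-read data).

ALLELES <- c("BY", "3S", "MUT")

allele_code <- function(x) {
  i <- match(x, ALLELES)
  if (anyNA(i)) stop("unknown allele label(s): ", paste(unique(x[is.na(i)]), collapse = ", "))
  i - 1L
}

allele_label <- function(code) ALLELES[code + 1L]

#' Construct a genome map
#'
#' A genome map holds chromosome lengths, SNP positions, the bp-per-cM
#' scale used by the Haldane map function, and (optionally) the table of
#' named causal loci anchored to map SNPs.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length` (bp).
#' @param snps data.frame with columns `chrom` and `pos` (1-based bp);
#'   positions must be strictly increasing within each chromosome.
#' @param map_scale base pairs per centimorgan (default 3300).
#' @param loci optional data.frame with columns `locus`, `chrom`, `pos`;
#'   each locus is snapped to the nearest map SNP.
#' @return An object of class `genome_map`.
#' @export
genome_map <- function(chromosomes, snps, map_scale = 3300, loci = NULL) {
  stopifnot(is.data.frame(chromosomes), all(c("chrom", "length") %in% names(chromosomes)))
  stopifnot(is.data.frame(snps), all(c("chrom", "pos") %in% names(snps)))
  if (map_scale <= 0) stop("map_scale must be > 0")
  chromosomes$chrom <- as.character(chromosomes$chrom)
  snps$chrom <- as.character(snps$chrom)
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome ids")
  bad <- setdiff(unique(snps$chrom), chromosomes$chrom)
  if (length(bad)) stop("unknown chromosome in snps: ", paste(bad, collapse = ", "))
  # keep snps in chromosome order, check monotone positions and bounds
  snps <- snps[order(match(snps$chrom, chromosomes$chrom), snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  for (cc in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == cc]
    L <- chromosomes$length[chromosomes$chrom == cc]
    if (any(diff(p) <= 0)) stop("SNP positions not strictly increasing on ", cc)
    if (any(p < 1 | p > L)) stop("SNP position outside chromosome ", cc)
  }
  m <- structure(list(chromosomes = chromosomes, snps = snps,
                      map_scale = map_scale, loci = NULL),
                 class = "genome_map")
  if (!is.null(loci)) {
    stopifnot(all(c("locus", "chrom", "pos") %in% names(loci)))
    if (anyDuplicated(loci$locus)) stop("locus names must be unique")
    idx <- vapply(seq_len(nrow(loci)), function(i) {
      on_chrom <- which(snps$chrom == loci$chrom[i])
      if (!length(on_chrom)) stop("locus ", loci$locus[i], " on chromosome without SNPs")
      on_chrom[which.min(abs(snps$pos[on_chrom] - loci$pos[i]))]
    }, integer(1))
    loci$snp <- idx
    loci$pos <- snps$pos[idx]
    m$loci <- loci
  }
  m
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$snps), "SNPs,", x$map_scale, "bp/cM\n")
  if (!is.null(x$loci)) cat("loci:", paste(x$loci$locus, collapse = ", "), "\n")
  invisible(x)
}

n_snps <- function(map) nrow(map$snps)

#' Desk-scale default genome map
#'
#' Sixteen chromosomes of 50-150 kb with SNPs every `spacing` bp
#' (about 2,000 SNPs in total at the default spacing) and the nine causal
#' loci placed mid-chromosome on distinct chromosomes. Gene-to-chromosome
#' assignments follow the real yeast genome where the distinct-chromosome
#' constraint allows. The full-genome scale (36,756 SNPs) is reached by
#' shrinking `spacing` and growing the lengths; all analysis code is
#' scale-free.
#'
#' @param spacing distance between adjacent SNPs in bp (default 800).
#' @param map_scale bp per centimorgan (default 3300).
#' @return A `genome_map` with a `loci` table.
#' @export
default_genome_map <- function(spacing = 800, map_scale = 3300) {
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
             "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")
  chroms <- data.frame(chrom = paste0("chr", roman),
                       length = round(seq(50e3, 150e3, length.out = 16)))
  snps <- do.call(rbind, lapply(seq_len(16), function(i) {
    data.frame(chrom = chroms$chrom[i],
               pos = seq(spacing %/% 2 + 1, chroms$length[i], by = spacing))
  }))
  mids <- setNames(round(chroms$length / 2), chroms$chrom)
  loci <- data.frame(
    locus = c("IRA2", "TRR1", "FLO8", "MGA1", "FLO11",
              "XII", "MSS11", "END3", "SFL1"),
    chrom = c("chrII", "chrIV", "chrV", "chrVII", "chrIX",
              "chrXII", "chrXIII", "chrXIV", "chrXV"),
    stringsAsFactors = FALSE)
  loci$pos <- unname(mids[loci$chrom])
  genome_map(chroms, snps, map_scale = map_scale, loci = loci)
}

#' Default focal-parent genotype
#'
#' Per-SNP allele vector (codes 0 = BY, 1 = 3S, 2 = MUT) of the rough
#' recombinant parent used in both backcrosses, modeled as a
#' chromosome-level mosaic. Causal chromosomes carry the allele that the
#' parent's rough genotype requires (END3 BY, FLO8 3S, FLO11 3S, IRA2 MUT,
#' MGA1 BY, MSS11 BY, SFL1 BY, TRR1 3S, XII BY); the remaining chromosomes
#' alternate BY/3S so roughly half the genome segregates in each backcross.
#' The MUT allele sits only at the IRA2 SNP, on an otherwise 3S chromosome.
#'
#' @param map a `genome_map` with a `loci` table containing IRA2.
#' @return integer vector over map SNPs.
#' @export
default_focal_parent <- function(map) {
  focal_chrom <- c(chrII = "3S", chrIV = "3S", chrV = "3S", chrVII = "BY",
                   chrIX = "3S", chrXII = "BY", chrXIII = "BY",
                   chrXIV = "BY", chrXV = "BY",
                   chrI = "BY", chrIII = "3S", chrVI = "3S", chrVIII = "BY",
                   chrX = "3S", chrXI = "3S", chrXVI = "3S")
  alleles <- focal_chrom[map$snps$chrom]
  if (anyNA(alleles)) stop("default_focal_parent needs the default 16-chromosome map")
  v <- allele_code(unname(alleles))
  ira2 <- map$loci$snp[map$loci$locus == "IRA2"]
  if (!length(ira2)) stop("map has no IRA2 locus")
  v[ira2] <- 2L
  v
}

#' Construct a backcross design
#'
#' A cross design pairs the focal recombinant parent's per-SNP genotype
#' with a recurrent parent (BY or 3S). SNPs where the two parents carry
#' the same allele are fixed in the offspring; the rest segregate 1:1.
#'
#' @param map a `genome_map`.
#' @param backcross_to `"BY"` or `"3S"`, the recurrent parent.
#' @param focal per-SNP allele codes of the focal parent
#'   (default [default_focal_parent()]).
#' @return An object of class `cross_design` with elements `focal`,
#'   `recurrent` (per-SNP codes), `segregating` (logical), and — when the
#'   map carries loci — a `loci` table with per-locus segregation status.
#' @export
backcross_design <- function(map, backcross_to = c("BY", "3S"),
                             focal = default_focal_parent(map)) {
  backcross_to <- match.arg(backcross_to)
  recurrent <- rep(allele_code(backcross_to), n_snps(map))
  cross_design(map, focal, recurrent, name = paste0(backcross_to, "-backcross"))
}

#' Construct a cross design from explicit parental haplotypes
#'
#' @param map a `genome_map`.
#' @param focal,recurrent per-SNP allele code vectors for the two
#'   haplotypes of the cross.
#' @param name label for reporting.
#' @return A `cross_design`.
#' @export
cross_design <- function(map, focal, recurrent, name = "cross") {
  S <- n_snps(map)
  stopifnot(length(focal) == S, length(recurrent) == S)
  focal <- as.integer(focal); recurrent <- as.integer(recurrent)
  stopifnot(all(focal %in% 0:2), all(recurrent %in% 0:2))
  d <- structure(list(map = map, focal = focal, recurrent = recurrent,
                      segregating = focal != recurrent, name = name),
                 class = "cross_design")
  if (!is.null(map$loci)) {
    li <- map$loci$snp
    d$loci <- data.frame(
      locus = map$loci$locus,
      focal = allele_label(focal[li]),
      recurrent = allele_label(recurrent[li]),
      segregating = focal[li] != recurrent[li],
      stringsAsFactors = FALSE)
  }
  d
}

#' The original cross, in which every locus segregates
#'
#' Design for the BYx3S cross carrying the ira2 mutation on its 3S
#' chromosome: one haplotype all BY, the other all 3S with MUT at the IRA2
#' SNP, so every SNP (and every causal locus) segregates 1:1. Used for
#' Mendelian genotype-frequency calculations at the scale of the original
#' screen.
#'
#' @param map a `genome_map` with an IRA2 locus.
#' @return A `cross_design`.
#' @export
f2_design <- function(map) {
  focal <- rep(1L, n_snps(map))
  ira2 <- map$loci$snp[map$loci$locus == "IRA2"]
  if (!length(ira2)) stop("map has no IRA2 locus")
  focal[ira2] <- 2L
  cross_design(map, focal, rep(0L, n_snps(map)), name = "BYx3S")
}

#' @export
print.cross_design <- function(x, ...) {
  cat("cross_design '", x$name, "': ", sum(x$segregating), "/",
      length(x$segregating), " SNPs segregating\n", sep = "")
  if (!is.null(x$loci)) print(x$loci)
  invisible(x)
}

#' Haldane recombination fraction
#'
#' Converts a physical distance to a recombination fraction through the
#' Haldane map function r = (1 - exp(-2 d)) / 2 with d in Morgans,
#' d = bp / map_scale / 100.
#'
#' @param d_bp distance in base pairs (vectorized).
#' @param map_scale bp per centimorgan.
#' @return recombination fraction(s) in \[0, 0.5).
#' @export
haldane_r <- function(d_bp, map_scale = 3300) {
  (1 - exp(-2 * (d_bp / map_scale) / 100)) / 2
}
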
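# Bulk segregant mapping: allele-frequency tracks, a kernel-pooled
# binomial LOD scan over 100-bp bins, and locus calling with 2-LOD
# support intervals.
#
# The LOD scan is a deliberate surrogate for MULTIPOOL's dynamic Bayesian
# network: reads are aggregated into bins, pooled under a Gaussian kernel
# (default scale 10 cM = 33 kb at 3,300 bp/cM), and scored with the
# log10 binomial likelihood ratio of the local MLE frequency against the
# null 0.5. The calling rules (LOD >= 5 over >= 20 kb, 2-LOD drop
# intervals) operate on any LOD track and are preserved exactly.

#' Restrict pool counts to the regions that segregate in a cross
#'
#' @param counts a `pool_counts` data.frame (`chrom`, `pos`, `count_BY`,
#'   `count_3S`).
#' @param design a `cross_design`; SNPs in fixed regions are removed.
#' @return filtered `pool_counts`.
#' @export
subset_segregating <- function(counts, design) {
  map <- design$map
  key <- paste(counts$chrom, counts$pos)
  mkey <- paste(map$snps$chrom, map$snps$pos)
  i <- match(key, mkey)
  if (anyNA(i)) stop("pool counts contain SNPs absent from the design's map")
  out <- counts[design$segregating[i], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP allele-frequency track
#'
#' @param counts a `pool_counts` data.frame.
#' @return data.frame `chrom`, `pos`, `depth`, `freq` — frequency of the
#'   3S allele, `NA` at zero-depth SNPs.
#' @export
estimate_frequencies <- function(counts) {
  depth <- counts$count_BY + counts$count_3S
  freq <- ifelse(depth > 0, counts$count_3S / depth, NA_real_)
  data.frame(chrom = counts$chrom, pos = counts$pos,
             depth = depth, freq = freq)
}

# centered moving average of `x` within groups, truncated at group ends,
# NAs excluded from numerator and denominator
moving_average_by <- function(x, group, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  h <- (window - 1) %/% 2
  out <- rep(NA_real_, length(x))
  for (g in unique(group)) {
    idx <- which(group == g)
    v <- x[idx]
    ok <- !is.na(v)
    cs <- cumsum(c(0, ifelse(ok, v, 0)))
    cn <- cumsum(c(0, as.integer(ok)))
    n <- length(v)
    lo <- pmax(1, seq_len(n) - h); hi <- pmin(n, seq_len(n) + h)
    num <- cs[hi + 1] - cs[lo]
    den <- cn[hi + 1] - cn[lo]
    out[idx] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

#' Smooth an allele-frequency track
#'
#' Centered moving average over `window` SNPs within each chromosome,
#' truncated (not padded) at chromosome ends; missing frequencies are
#' skipped in both numerator and denominator.
#'
#' @param track data.frame from [estimate_frequencies()].
#' @param window odd window size in SNPs (default 25, the scale used for
#'   the study's frequency plots).
#' @return `track` with an added `freq_smooth` column.
#' @export
smooth_track <- function(track, window = 25) {
  track$freq_smooth <- moving_average_by(track$freq, track$chrom, window)
  track
}

#' Binomial LOD of pooled counts against the null frequency 0.5
#'
#' @param k reads supporting the 3S allele.
#' @param n total reads.
#' @return log10 likelihood ratio at the MLE `k/n` versus p = 0.5
#'   (vectorized); 0 where `n` is 0.
#' @export
binomial_lod <- function(k, n) {
  p <- ifelse(n > 0, k / n, 0.5)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  lod <- (k * log(p) + (n - k) * log(1 - p) - n * log(0.5)) / log(10)
  ifelse(n > 0, lod, 0)
}

#' Kernel-pooled binomial LOD scan
#'
#' Reads are aggregated into `bin_size`-bp bins; at every bin the counts
#' of nearby bins are pooled under a Gaussian kernel of scale
#' `kernel_scale` and scored with [binomial_lod()]. When `pool_size` is
#' given, pooled counts are first capped at `2 * pool_size` effective
#' reads so the LOD cannot outgrow the information a finite pool of
#' segregants carries.
#'
#' @param counts a `pool_counts` data.frame.
#' @param map the `genome_map` (for chromosome lengths).
#' @param bin_size bin width in bp (default 100).
#' @param kernel_scale Gaussian kernel scale in bp (default 33000,
#'   i.e. 10 cM at 3,300 bp/cM).
#' @param pool_size number of pooled individuals, or `NULL` for no cap.
#' @return A `lod_track` data.frame: `chrom`, `start`, `end`, `center`,
#'   `k`, `n`, `lod`, `enriched` (`"BY"`/`"3S"`/`NA`).
#' @export
lod_scan <- function(counts, map, bin_size = 100, kernel_scale = 33000,
                     pool_size = NULL) {
  if (!nrow(counts)) stop("empty pool counts")
  cap <- if (is.null(pool_size)) Inf else 2 * pool_size
  out <- lapply(intersect(map$chromosomes$chrom, unique(counts$chrom)), function(cc) {
    d <- counts[counts$chrom == cc, ]
    L <- map$chromosomes$length[map$chromosomes$chrom == cc]
    nb <- ceiling(L / bin_size)
    bin <- (d$pos - 1) %/% bin_size + 1
    kb <- rowsum(d$count_3S, bin)
    ntot <- rowsum(d$count_BY + d$count_3S, bin)
    data_bins <- as.integer(rownames(kb))
    centers <- (seq_len(nb) - 0.5) * bin_size
    W <- exp(-outer(centers, centers[data_bins], "-")^2 / (2 * kernel_scale^2))
    k <- as.vector(W %*% kb)
    n <- as.vector(W %*% ntot)
    shrink <- pmin(1, cap / pmax(n, 1e-12))
    k <- k * shrink; n <- n * shrink
    p <- ifelse(n > 0, k / n, 0.5)
    data.frame(chrom = cc,
               start = (seq_len(nb) - 1) * bin_size + 1,
               end = pmin(seq_len(nb) * bin_size, L),
               center = centers, k = k, n = n,
               lod = binomial_lod(k, n),
               enriched = ifelse(p > 0.5, "3S", ifelse(p < 0.5, "BY", NA)),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("lod_track", "data.frame"))
}

#' Call significant loci from a LOD track
#'
#' Maximal runs of contiguous bins with LOD at or above `threshold` and a
#' consistent enriched parent are candidate loci; runs spanning less than
#' `min_span` bp are discarded. Each surviving run yields one call at its
#' argmax bin (leftmost on ties), with a support interval extending from
#' the peak over the contiguous bins whose LOD stays above
#' `max LOD - drop` (to the chromosome end if it never falls that far).
#'
#' @param lod a `lod_track` from [lod_scan()].
#' @param threshold minimum peak LOD (default 5).
#' @param min_span minimum run length in bp (default 20000).
#' @param drop LOD drop defining the support interval (default 2).
#' @return data.frame of locus calls: `chrom`, `peak`, `max_lod`,
#'   `enriched`, `start`, `end`.
#' @export
call_loci <- function(lod, threshold = 5, min_span = 20000, drop = 2) {
  stopifnot(threshold > 0, min_span > 0, drop > 0)
  calls <- list()
  for (cc in unique(lod$chrom)) {
    d <- lod[lod$chrom == cc, ]
    sig <- d$lod >= threshold & !is.na(d$enriched)
    grp <- paste(sig, ifelse(sig, d$enriched, ""))
    r <- rle(grp)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in seq_along(r$lengths)) {
      if (!startsWith(r$values[i], "TRUE")) next
      b <- starts[i]:ends[i]
      span <- d$end[ends[i]] - d$start[starts[i]] + 1
      if (span < min_span) next
      peak <- b[which.max(d$lod[b])]
      lim <- d$lod[peak] - drop
      lo <- peak; while (lo > 1 && d$lod[lo - 1] > lim) lo <- lo - 1
      hi <- peak; while (hi < nrow(d) && d$lod[hi + 1] > lim) hi <- hi + 1
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = cc, peak = d$center[peak], max_lod = d$lod[peak],
        enriched = d$enriched[peak], start = d$start[lo], end = d$end[hi],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(chrom = character(0), peak = numeric(0),
                      max_lod = numeric(0), enriched = character(0),
                      start = numeric(0), end = numeric(0)))
  do.call(rbind, calls)
}
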
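# On-disk formats: headered TSV for tabular artifacts, JSON for nested
# ones. All coordinates are 1-based inclusive, on disk and in memory.

check_nonempty_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  check_nonempty_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  for (cl in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !(df[[cl]] %in% c("NA", "")))
    if (length(bad))
      stop(path, ": malformed value in column '", cl, "' at line ",
           bad[1] + 1L)
    df[[cl]] <- v
  }
  df
}

#' Write / read a SNP map
#'
#' `snp_map.tsv` columns: `chrom`, `chrom_length`, `pos` (1-based bp).
#' The chromosome table is reconstructed from the per-SNP lengths.
#'
#' @param map a `genome_map`.
#' @param path TSV path.
#' @return the path (write) or a `genome_map` (read; causal loci are not
#'   stored in the TSV and can be re-attached via [genome_map()]).
#' @export
write_snp_map <- function(map, path) {
  L <- setNames(map$chromosomes$length, map$chromosomes$chrom)
  write_tsv(data.frame(chrom = map$snps$chrom,
                       chrom_length = L[map$snps$chrom],
                       pos = map$snps$pos), path)
}

#' @rdname write_snp_map
#' @param map_scale bp per centimorgan for the reconstructed map.
#' @export
read_snp_map <- function(path, map_scale = 3300) {
  df <- read_tsv_checked(path, c("chrom", "chrom_length", "pos"),
                         c("chrom_length", "pos"))
  chroms <- unique(df[, c("chrom", "chrom_length")])
  genome_map(data.frame(chrom = chroms$chrom, length = chroms$chrom_length),
             df[, c("chrom", "pos")], map_scale = map_scale)
}

#' Write / read pooled allele counts
#'
#' `pool_counts.tsv` columns: `chrom`, `pos`, `count_BY`, `count_3S`.
#'
#' @param counts a `pool_counts` data.frame.
#' @param path TSV path.
#' @export
write_pool_counts <- function(counts, path) write_tsv(counts, path)

#' @rdname write_pool_counts
#' @export
read_pool_counts <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "count_BY", "count_3S"),
                         c("pos", "count_BY", "count_3S"))
  if (any(df$count_BY < 0 | df$count_3S < 0)) stop(path, ": negative counts")
  structure(df, class = c("pool_counts", "data.frame"))
}

#' Write / read per-individual site observations
#'
#' `observations.tsv` columns: `individual`, `chrom`, `pos`, `count_BY`,
#' `count_3S` (covered sites only).
#'
#' @param obs named list of `site_observations` data.frames.
#' @param path TSV path.
#' @return the path (write); a named list of data.frames (read).
#' @export
write_observations <- function(obs, path) {
  rows <- lapply(names(obs), function(id) cbind(individual = id, obs[[id]]))
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- read_tsv_checked(path, c("individual", "chrom", "pos", "count_BY",
                                 "count_3S"),
                         c("pos", "count_BY", "count_3S"))
  split(df[, c("chrom", "pos", "count_BY", "count_3S")], df$individual)
}

#' Write / read a genotype matrix
#'
#' `genotypes.tsv`: `chrom`, `pos`, then one column per individual with
#' `B` (BY), `S` (3S) or `N` (missing).
#'
#' @param genotypes SNP x individual matrix in `{0, 1, NA}` with
#'   `snp_chrom`/`snp_pos` attributes (see [genotype_matrix()]).
#' @param path TSV path.
#' @export
write_genotypes <- function(genotypes, path) {
  codes <- matrix(c("B", "S")[genotypes + 1L], nrow(genotypes))
  codes[is.na(genotypes)] <- "N"
  df <- data.frame(chrom = attr(genotypes, "snp_chrom"),
                   pos = attr(genotypes, "snp_pos"))
  colnames(codes) <- colnames(genotypes)
  write_tsv(cbind(df, codes), path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos"), "pos")
  ind <- setdiff(names(df), c("chrom", "pos"))
  G <- as.matrix(df[, ind, drop = FALSE])
  bad <- !(G %in% c("B", "S", "N"))
  if (any(bad)) {
    row <- which(rowSums(matrix(bad, nrow(G))) > 0)[1]
    stop(path, ": invalid genotype code at line ", row + 1L)
  }
  out <- matrix(ifelse(G == "B", 0L, ifelse(G == "S", 1L, NA_integer_)),
                nrow(G), dimnames = list(NULL, ind))
  structure(out, snp_chrom = df$chrom, snp_pos = df$pos)
}

#' Write / read phenotype score tables
#'
#' `phenotypes.tsv` columns: `individual`, `temperature`, `replicate`,
#' `score`; `class_calls.tsv` columns: `individual`, `state21`,
#' `state30`, `state37`, `class`.
#'
#' @param phenotypes data.frame as produced by [simulate_panel_scores()].
#' @param path TSV path.
#' @export
write_phenotypes <- function(phenotypes, path) write_tsv(phenotypes, path)

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read_tsv_checked(path, c("individual", "temperature", "replicate", "score"),
                   c("temperature", "replicate", "score"))
}

#' @rdname write_phenotypes
#' @param calls class-call data.frame from [classify_phenotypes()].
#' @export
write_class_calls <- function(calls, path) write_tsv(calls, path)

#' @rdname write_phenotypes
#' @export
read_class_calls <- function(path) {
  read_tsv_checked(path, c("individual", "state21", "state30", "state37",
                           "class"))
}

#' Write / read a simulation truth record
#'
#' @param truth list from [truth_record()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  check_nonempty_file(path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Import a haploid genotype matrix from a VCF
#'
#' Optional convenience for real data: haploid GT fields (`0` reference /
#' BY, `1` alternate / 3S, `.` missing) become a SNP x individual matrix
#' in the same shape as [read_genotypes()]. Requires the vcfR package.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @return matrix in `{0, 1, NA}` with `snp_chrom`/`snp_pos` attributes.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf requires the vcfR package")
  check_nonempty_file(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  first <- substr(gt, 1, 1)
  G <- matrix(ifelse(first == "0", 0L, ifelse(first == "1", 1L, NA_integer_)),
              nrow(gt), dimnames = list(NULL, colnames(gt)))
  structure(G, snp_chrom = unname(v@fix[, "CHROM"]),
            snp_pos = as.integer(v@fix[, "POS"]))
}
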
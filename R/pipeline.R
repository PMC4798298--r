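# End-to-end orchestration: simulate -> screen -> classify -> pools ->
# bulk mapping -> individual sequencing -> HMM -> heterogeneity scan,
# with all artifacts and a JSON summary written to an output directory.

#' Pipeline configuration
#'
#' Collects every numeric setting of the analysis with the study's
#' Methods values as defaults. Thresholds must be positive; invalid
#' fields are reported together by [run_pipeline()].
#'
#' @param seed RNG seed.
#' @param out_dir output directory.
#' @param snp_spacing SNP spacing of the desk-scale map in bp.
#' @param n_rough rough individuals collected per backcross in the
#'   21 degree screen.
#' @param pool_size maximum individuals per class pool.
#' @param pool_depth mean pooled coverage (reads/site).
#' @param indiv_coverage mean individual coverage (reads/site).
#' @param read_error per-read allele error rate.
#' @param replicates phenotype replicates per temperature.
#' @param score_noise phenotype replicate corruption probability.
#' @param lod_threshold,min_span,lod_drop locus-calling rules
#'   (LOD >= 5 over >= 20 kb; 2-LOD-drop intervals).
#' @param kernel_scale LOD-scan kernel scale in bp.
#' @param window frequency smoothing window in SNPs.
#' @param q_threshold point-wise FDR for the pair scan.
#' @param telomere_margin bp excluded at chromosome ends.
#' @param freq_low,freq_high partition calling thresholds.
#' @param min_coverage individual coverage filter (reads/site).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("gxemap_run_"),
                            snp_spacing = 800, n_rough = 150,
                            pool_size = 100, pool_depth = 150,
                            indiv_coverage = 1.0, read_error = 0.005,
                            replicates = 3, score_noise = 0,
                            lod_threshold = 5, min_span = 20000,
                            lod_drop = 2, kernel_scale = 33000,
                            window = 25, q_threshold = 0.01,
                            telomere_margin = 20000,
                            freq_low = 0.10, freq_high = 0.90,
                            min_coverage = 1.02) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  bad <- character(0)
  pos <- c("snp_spacing", "n_rough", "pool_size", "pool_depth",
           "replicates", "lod_threshold", "min_span", "lod_drop",
           "kernel_scale", "window", "q_threshold", "min_coverage")
  for (f in pos) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) bad <- c(bad, f)
  nonneg <- c("indiv_coverage", "read_error", "score_noise", "telomere_margin")
  for (f in nonneg) if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) bad <- c(bad, f)
  if (!is.numeric(cfg$freq_low) || !is.numeric(cfg$freq_high) ||
      cfg$freq_low <= 0 || cfg$freq_high >= 1 || cfg$freq_low >= cfg$freq_high)
    bad <- c(bad, "freq_low/freq_high")
  if (cfg$window %% 2 != 1) bad <- c(bad, "window (must be odd)")
  if (length(bad))
    stop("invalid pipeline config field(s): ", paste(unique(bad), collapse = ", "))
  invisible(cfg)
}

# match locus calls to causal loci: a call hits a locus if the locus
# position lies inside the call's support interval on its chromosome
match_calls_to_loci <- function(calls, loci) {
  if (!nrow(calls)) return(character(0))
  hits <- character(0)
  for (i in seq_len(nrow(calls))) {
    j <- which(loci$chrom == calls$chrom[i] &
               loci$pos >= calls$start[i] & loci$pos <= calls$end[i])
    hits <- c(hits, loci$locus[j])
  }
  unique(hits)
}

#' Run the full analysis pipeline on simulated screens
#'
#' Simulates the 21-degree screens of both backcrosses, phenotypes and
#' classifies the collected rough segregants, bulk-maps each
#' backcross x class pool, individually sequences and HMM-genotypes the
#' HS individuals, scans for correlated region pairs, and partitions at
#' the most implicated focal region. All artifacts plus `summary.json`
#' (config, seed, package version, detected loci per pool, significant
#' pairs, partition calls, and an evaluation block against the simulation
#' truth) are written to `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly; the JSON on disk is the contract.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  map <- default_genome_map(spacing = config$snp_spacing)
  rules <- default_rule_set()
  write_snp_map(map, file.path(config$out_dir, "snp_map.tsv"))
  write_rule_set(rules, file.path(config$out_dir, "ruleset.json"))
  summary <- list(package = "gxemap",
                  version = as.character(utils::packageVersion("gxemap")),
                  seed = config$seed,
                  config = unclass(config)[setdiff(names(config), "out_dir")],
                  backcrosses = list())
  for (bc in c("BY", "3S")) {
    design <- backcross_design(map, bc)
    panel <- simulate_panel(design, map, config$n_rough, rules,
                            screen_temperature = 21)
    truth <- truth_record(panel)
    write_truth(truth, file.path(config$out_dir, sprintf("truth_%s.json", bc)))
    scores <- simulate_panel_scores(panel, config$replicates, config$score_noise)
    write_phenotypes(scores, file.path(config$out_dir,
                                       sprintf("phenotypes_%s.tsv", bc)))
    calls <- classify_phenotypes(scores)
    write_class_calls(calls, file.path(config$out_dir,
                                       sprintf("class_calls_%s.tsv", bc)))
    bc_sum <- list(n_rough = length(panel$class),
                   n_examined = panel$examined,
                   fraction_classified = attr(calls, "fraction_classified"),
                   class_counts = as.list(table(calls$class)),
                   pools = list())
    # ---- bulk segregant mapping of each called class ----
    for (cls in c("HS", "MS", "NS")) {
      members <- which(calls$class == cls)
      if (length(members) < 2) next
      members <- members[seq_len(min(length(members), config$pool_size))]
      counts <- simulate_pool_counts(panel$genomes[members, , drop = FALSE],
                                     map, config$pool_depth, config$read_error)
      counts <- subset_segregating(counts, design)
      write_pool_counts(counts, file.path(
        config$out_dir, sprintf("pool_counts_%s_%s.tsv", bc, cls)))
      track <- smooth_track(estimate_frequencies(counts), config$window)
      write_tsv(track, file.path(config$out_dir,
                                 sprintf("freq_track_%s_%s.tsv", bc, cls)))
      lt <- lod_scan(counts, map, kernel_scale = config$kernel_scale,
                     pool_size = length(members))
      loci <- call_loci(lt, config$lod_threshold, config$min_span,
                        config$lod_drop)
      write_tsv(loci, file.path(config$out_dir,
                                sprintf("loci_%s_%s.tsv", bc, cls)))
      causal <- map$loci[design$loci$segregating, ]
      fixed_in_class <- vapply(seq_len(nrow(causal)), function(i) {
        length(unique(panel$genotypes[members, causal$locus[i]])) == 1
      }, TRUE)
      bc_sum$pools[[cls]] <- list(
        n_pooled = length(members),
        detected_loci = loci,
        detected_causal = match_calls_to_loci(loci, map$loci),
        expected_causal = causal$locus[fixed_in_class])
    }
    # ---- individual sequencing + HMM + heterogeneity scan of HS ----
    hs <- which(calls$class == "HS")
    scan_sum <- list(n_hs = length(hs))
    if (length(hs) >= 10) {
      obs <- lapply(hs, function(i)
        simulate_individual_reads(panel$genomes[i, ], map,
                                  config$indiv_coverage, config$read_error))
      names(obs) <- sprintf("seg%04d", hs)
      keep <- vapply(obs, coverage_filter, TRUE, map = map,
                     min_coverage = config$min_coverage)
      obs <- obs[keep]
      write_observations(obs, file.path(config$out_dir,
                                        sprintf("observations_%s.tsv", bc)))
      hcalls <- lapply(obs, genotype_hmm, map = map, design = design,
                       error_rate = config$read_error)
      carriers <- mutation_carriers(hcalls, map)
      scan_sum$n_low_coverage_excluded <- sum(!keep)
      scan_sum$n_wildtype_excluded <- sum(!carriers)
      hcalls <- hcalls[carriers]
      G <- genotype_matrix(hcalls, design)
      write_genotypes(G, file.path(config$out_dir,
                                   sprintf("genotypes_%s.tsv", bc)))
      regions <- collapse_regions(G)
      regions <- exclude_telomeric(regions, map, config$telomere_margin)
      write_tsv(regions_table(regions),
                file.path(config$out_dir, sprintf("regions_%s.tsv", bc)))
      scan_sum$n_regions <- length(regions)
      tests <- pairwise_chi2(regions)
      tests$q <- compute_qvalues(tests$p)
      write_tsv(tests, file.path(config$out_dir,
                                 sprintf("pair_tests_%s.tsv", bc)))
      sig <- significant_pairs(tests, config$q_threshold)
      scan_sum$n_tests <- nrow(tests)
      scan_sum$significant_pairs <- sig
      if (nrow(sig)) {
        focal_id <- as.integer(names(sort(table(c(sig$regionA, sig$regionB)),
                                          decreasing = TRUE))[1])
        part <- partition_and_call(G, regions[[focal_id]],
                                   window = config$window,
                                   low = config$freq_low,
                                   high = config$freq_high)
        pc <- do.call(rbind, lapply(names(part), function(a)
          cbind(focal_allele = a, part[[a]]$calls)))
        write_tsv(pc, file.path(config$out_dir,
                                sprintf("partition_calls_%s.tsv", bc)))
        scan_sum$focal_region <- regions_table(regions[focal_id])
        scan_sum$partition_calls <- pc
      }
    }
    bc_sum$heterogeneity_scan <- scan_sum
    summary$backcrosses[[bc]] <- bc_sum
  }
  # ---- evaluation against truth: union of causal loci detected ----
  detected <- unique(unlist(lapply(summary$backcrosses, function(b)
    lapply(b$pools, `[[`, "detected_causal"))))
  summary$evaluation <- list(
    detected_causal_union = sort(detected),
    n_detected_causal_union = length(detected))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(summary)
}
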
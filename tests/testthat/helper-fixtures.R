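# Shared fixtures: reference genotypes from the worked examples and a
# tiny map for fast unit tests.

ns_genotype <- function() {
  c(END3 = "BY", FLO8 = "3S", FLO11 = "3S", IRA2 = "MUT", MGA1 = "BY",
    MSS11 = "BY", SFL1 = "BY", TRR1 = "3S", XII = "BY")
}

# the MSS11^3S-dependent HS genotype, with the loci fixed 3S in the 3S
# backcross filled in
hsb_genotype <- function() {
  c(XII = "3S", END3 = "BY", FLO8 = "3S", FLO11 = "3S", IRA2 = "MUT",
    MGA1 = "BY", MSS11 = "3S", SFL1 = "BY", TRR1 = "3S")
}

swap <- function(genotype, ...) {
  repl <- c(...)
  genotype[names(repl)] <- repl
  genotype
}

# small map: 3 chromosomes, SNPs every 1 kb, IRA2 present so designs work
tiny_map <- function(n_chrom = 3, length_bp = 60e3, spacing = 1000) {
  chroms <- data.frame(chrom = paste0("c", seq_len(n_chrom)),
                       length = length_bp)
  snps <- do.call(rbind, lapply(chroms$chrom, function(cc)
    data.frame(chrom = cc, pos = seq(500, length_bp, by = spacing))))
  loci <- data.frame(locus = "IRA2", chrom = "c1", pos = length_bp / 2)
  genome_map(chroms, snps, loci = loci)
}

# design over a tiny map where every SNP segregates 3S (MUT at IRA2) vs BY
tiny_design <- function(map = tiny_map()) {
  f2_design(map)
}
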
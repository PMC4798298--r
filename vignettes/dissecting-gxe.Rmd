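---
title: "Dissecting temperature-dependent GxE into multi-locus genotypes"
author: "gxemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting temperature-dependent GxE into multi-locus genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxemap)
```

## The biological problem

A spontaneous frameshift in *IRA2* (here the third allele `MUT` of that
locus) lets some haploid segregants of a BY x 3S yeast cross express a
"rough" colony morphology that the cross otherwise never shows. Whether a
given segregant is rough — and at which temperatures (21, 30, 37 °C) — is
controlled by combinations of alleles at a handful of loci, not by any
single locus. Segregants fall into three temperature-sensitivity classes:
highly sensitive (HS, rough at 21 °C only), moderately sensitive (MS,
rough at 21 and 30 °C) and non-sensitive (NS, rough at all three). This
is genotype-by-environment interaction expressed at the resolution of
multi-locus genotypes, and the same property that makes it interesting
makes it hard to map: when two different allele combinations produce the
same phenotype ("genotypic heterogeneity"), each combination's private
loci are diluted in pooled mapping data and can disappear entirely.

gxemap packages the full analytical strategy for this problem:

1. a deterministic **rule engine** encoding the five predominant
   multi-locus genotypes and their permissive temperature sets;
2. a **backcross simulator** (meiosis, phenotype screens, pooled and
   low-coverage individual sequencing) that generates data with the
   statistical structure the analysis assumes, plus a truth record;
3. **phenotype classification** from replicate 0–5 colony scores;
4. **bulk segregant mapping**: allele-frequency tracks, a binned LOD
   scan, locus calls with 2-LOD support intervals;
5. **HMM haplotype inference** for ~1X individually sequenced segregants;
6. a **pairwise chi-square heterogeneity scan** over collapsed
   segregating regions with Storey q-value FDR control, followed by
   genotype partitioning at the implicated focal locus.

## The rule engine

The default rule set holds the five predominant genotypes. Every rule
requires the generally required pair FLO8^3S and IRA2^MUT; the remaining
requirements determine temperature sensitivity:

```{r rules}
default_rule_set()
```

A genotype expresses the union of the permissive temperature sets of all
rules it satisfies. Because the requirement sets of `HS-MSS11BY` ⊂
`MS-END3BY` ⊂ `NS` are nested, the union rule coincides with a
"most-specific rule wins" reading: adding the alleles that extend the
temperature range never removes a temperature. An empty union means
smooth at every temperature. Under the default rules only the four
temperature sets {}, {21}, {21,30} and {21,30,37} can arise; the
classifier treats any other set (possible only with user-supplied rules)
as an error rather than silently inventing a class.

Two modelling choices deserve mention. First, penetrance is 1 — the
classes are reported deterministically, matching how the phenotype is
scored; a misclassification probability exists on the simulator for
robustness experiments but defaults to 0. Second, IRA2 is a three-allele
locus {BY, 3S, MUT}: the frameshift arose on a 3S chromosome, so in read
space MUT is indistinguishable from 3S, but only MUT satisfies rules.
The locus called "XII" has no resolved gene; it behaves exactly like the
named genes.

Two open points are resolved as drawn in the genotype diagram: FLO11 and
MGA1 are left unconstrained in the `MS-END33S` genotype, and temperature
patterns outside the three classes are treated as impossible only under
the default rules, with no claim about their biological possibility.

`temperature_modifiers()` derives the environmentally responsive loci
from a rule set: loci required by at least one rule, minus loci required
with the same allele by *every* rule (those are generally required, like
FLO8 and IRA2, and do not modify sensitivity). On the default set this
yields the seven loci XII, END3, FLO11, MGA1, MSS11, SFL1 and TRR1.

`expected_frequency()` gives the Mendelian probability of a genotype in
a cross: 1/2 per segregating required locus, 1 or 0 for fixed loci. In
the full cross the END3^3S-dependent MS genotype needs six segregating
alleles against five for the END3^BY-dependent one, so it is expected
half as often — the package verifies this both in closed form and by
brute-force enumeration of the 2^k genotype table.

## What the simulator emulates — and what it does not

`simulate_gametes()` models backcross meiosis as a Markov walk along each
chromosome with Haldane recombination fractions
r(d) = (1 − exp(−2 d_cM/100))/2 at 3,300 bp/cM. A backcross fixes the
SNPs where the focal recombinant parent matches the recurrent parent;
roughly half the genome segregates in each backcross.

The focal parent's genotype is not printed anywhere in the source
material; the default (END3^BY FLO8^3S FLO11^3S IRA2^MUT MGA1^BY
MSS11^BY SFL1^BY TRR1^3S XII^BY, as a chromosome-level mosaic) is the
inference that reproduces the observed segregation pattern — FLO8,
FLO11, TRR1 and IRA2 segregate against BY; END3, MGA1, MSS11, SFL1, XII
and IRA2 against 3S — and it is configurable per SNP.

The desk-scale default map has 16 chromosomes of 50–150 kb with SNPs
every 800 bp (~2,000 SNPs) and the causal loci mid-chromosome on distinct
chromosomes, following the real gene-to-chromosome assignments where
that constraint allows (IRA2 is placed on chrII because its real
chromosome already hosts SFL1). All analysis code is scale-free up to
the full 36,756-SNP genome; the desk scale keeps every simulation in the
package's tests and scripts in the seconds-to-minutes range. The sizes
used throughout — pools of ~100 individuals at 150X, HS panels of 90 at
~1X, screens of 150 rough segregants — are the package's stated study
conditions, chosen to match the real screens' pool sizes (51–126
individuals, ≥114X pools, ~1X individuals).

Pooled sequencing draws per-site depth from Poisson(mean depth) and
assigns each read to a uniformly random pool member with a symmetric
allele error (default 0.005). That uniform-member model collapses to one
binomial draw per site at the pool allele frequency, which is what the
code samples. A beta-binomial overdispersion hook exists because finite
pools bound the information per site, but the default pools (≥50
individuals) do not need it; the same concern is handled analytically in
the LOD scan by the effective-depth cap described below.

The simulator does **not** model read-level artifacts (no FASTQ/BAM),
selection markers beyond the screen filter, or the segregation-distorting
locus linked to END3 that real screens experience; the mixture override
on `simulate_panel()` exists precisely because real class compositions
deviate from Mendelian expectation for reasons the data do not resolve.
Consequently, passing tests demonstrate correctness of the *analysis*
under Mendelian segregation plus sequencing noise — not robustness to
alignment bias, coverage heterogeneity along the genome, or segregation
distortion. One visible consequence of deterministic rules: in a
simulated 3S-backcross HS panel, every MSS11^BY individual must carry
END3^3S (otherwise it would be MS), so the MSS11^BY subgroup of the
partition analysis calls END3^3S — a correlation that the real panels,
with their non-Mendelian composition, did not show.

## Phenotype classification

Each individual is scored 0–5 in three replicates at each temperature;
the per-temperature state is the median, called smooth in [0, 1] and
rough in [4, 5], both bounds inclusive (the verbal rule does not state
open or closed; inclusive is the documented choice). Intermediate
"bumpy" medians are ambiguous, and any ambiguous temperature makes the
individual unclassified — only individuals that clearly and consistently
show smooth or rough colonies enter the mapping panels. The fraction
classified is a report field (1.0 on noise-free simulations; the real
screens classified 78.4%), never an assertion.

## Bulk segregant mapping

Allele frequencies are per-SNP read ratios, missing at zero depth, and
smoothed with a 25-SNP centered moving average truncated at chromosome
ends. The scan proper is a deliberate surrogate for the MULTIPOOL
dynamic-Bayesian-network model: reads aggregate into 100-bp bins, each
evaluation bin pools nearby counts under a Gaussian kernel (default
scale 33,000 bp = 10 cM), and the statistic is the log10 binomial
likelihood ratio of the pooled counts at their MLE frequency against the
null 0.5. The published calling rules operate unchanged on this track:
a locus needs LOD ≥ 5 sustained over a run of at least 20 kb ("span"
is read as the length of the contiguous supra-threshold run, the stricter
of the two possible readings), one call per run at the leftmost argmax
bin, and a support interval spanning the contiguous bins within 2 LOD of
the peak. Pooled counts are capped at 2 × pool size effective reads
before the likelihood ratio, so deep sequencing cannot claim more
information than a finite pool of segregants carries — a pool of n
individuals can never exceed LOD = 2n·log10(2), which is also why pools
far smaller than the study's 51–126 individuals legitimately call
nothing. The two-pool "replicates mode" of the original tool is not
reproduced; each pool is scanned independently and calls are compared
downstream.

## HMM genotyping

Low-coverage individuals (mean ≥ 1.02X after the coverage filter, with
the boundary kept) are decoded chromosome by chromosome with a two-state
HMM over the segregating SNPs: uniform start, Haldane transitions from
the physical map, and per-read emissions that report the true allele
with probability 1 − error. The error rate default (0.005) is a
decision, not a published value, and is exposed in the configuration.
All recursions are in log space (a 36k-SNP chromosome underflows
otherwise). Hard calls come from Viterbi with ties broken toward the
previous SNP's state to preserve segments; forward–backward posteriors
provide per-SNP confidence, and calls under 0.75 posterior are flagged
and treated as missing in the genotype matrix. Individuals whose decoded
state at the IRA2 SNP is the wild-type haplotype are flagged for
exclusion — the analysis concerns the mutant background only. On matched
desk-scale simulations the decoder is ≥95% accurate at 1X, and accuracy
rises monotonically with coverage; the exact threshold was fixed from a
pilot run and then frozen.

## The heterogeneity scan

Linked SNPs with the same inheritance pattern collapse greedily (left to
right per chromosome) into segregating regions, the unit that keeps the
number of tests manageable. Pattern equality is missing-tolerant — at 1X
many calls are absent, and `N` matches anything — with the region pattern
accumulating non-missing values as it grows; collapse is lossless where
data exist. Regions within 20 kb of chromosome ends are excluded.

Every inter-chromosomal region pair (intra-chromosomal correlation is
linkage, not epistasis) is tested with Pearson's chi-square on the 2x2
table of joint allele states over mutually non-missing individuals, no
continuity correction, df = 1; pairs with a zero margin are skipped
rather than assigned p = 1. The statistic is computed in closed form for
all pairs at once via matrix products — at desk scale a panel yields
~10^5 pairs — and agrees with `stats::chisq.test()` to 1e-12 in tests.

Q-values follow Storey's procedure: pi0 estimated on the lambda grid
0.05…0.95, spline-smoothed and read at the largest lambda, falling back
to 1 (pure Benjamini–Hochberg) when the estimate leaves (0, 1] or fewer
than 100 tests exist. Pairs at q ≤ 0.01 are significant. On 50 null
panels (no phenotypic selection) the pooled significant-pair proportion
stays below 1%; on panels mixing two HS genotypes 70/30 at n = 90 the
scan implicates the focal locus reliably. "Recovery" in the power check
means at least one significant pair joins the MSS11-containing region to
a region containing a true partner locus — the decision the scan feeds,
namely which locus to partition on. The weakest true pair (MSS11–XII,
expected chi-square ≈ 21 at n = 90) is not individually guaranteed to
clear q ≤ 0.01 among ~10^5 tests, and the real data's own pair list was
asymmetric in ways Mendelian simulation cannot reproduce, so no test
asserts the exact pair identities.

After the scan, the panel splits by allele at the focal region and each
subgroup's smoothed allele frequencies (25-SNP windows) are called where
they leave the [10%, 90%] band, merging adjacent called SNPs into
intervals. In the simulated mixture, the MSS11^3S subgroup calls XII^3S,
END3^BY, MGA1^BY and SFL1^BY — the full allele set of the
MSS11^3S-dependent genotype.

## Numerical and interface conventions

* Coordinates are 1-based inclusive everywhere, on disk and in memory.
* Randomness uses R's global RNG; every driver and the pipeline seed it
  once up front, and a fixed seed makes `run_pipeline()` byte-identical.
* Tabular artifacts are headered TSV; nested artifacts (rule sets, truth
  records, run summaries) are JSON. A haploid-VCF importer is provided
  for real genotype matrices (vcfR, optional).
* Ties at LOD argmax break leftmost; HMM ties toward the previous state;
  frequency estimates at zero depth are missing, never 0/0.
* Degenerate inputs error early and name the offending field: empty
  maps, genotypes missing a required locus, designs under which no rule
  is satisfiable, subgroups with no carriers, malformed TSV rows (with
  their line number).

## Worked example

```{r example}
set.seed(1)
map <- default_genome_map()
design <- backcross_design(map, "BY")
panel <- simulate_panel(design, map, 100, target_class = "NS")
counts <- subset_segregating(simulate_pool_counts(panel$genomes, map, 150),
                             design)
call_loci(lod_scan(counts, map, pool_size = 100))
```

The four loci fixed in the NS class of the BY backcross (FLO8, IRA2,
TRR1, FLO11 — on chrV, chrII, chrIV and chrIX of the desk map) are
called with support intervals covering the planted positions; the other
segregating chromosomes stay silent.

## Known limitations

* The LOD surrogate preserves the published calling semantics but not
  MULTIPOOL's exact posterior machinery; absolute LOD values are not
  comparable between the two, only the calls are.
* Deterministic rules concentrate class compositions at their Mendelian
  expectations; real screens deviate (selection, linked advantage loci),
  which is why headline counts from the real data are report fields.
* The chi-square scan tests pairs only; three-way interactions and
  segregation-distortion scans are out of scope.
* No diploid/heterozygous states in the HMM; the material is haploid.
```
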
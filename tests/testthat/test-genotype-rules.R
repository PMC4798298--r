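# Rule engine: multi-locus genotypes -> temperature sets -> classes.

test_that("expressed temperatures reproduce the allele-swap outcomes", {
  # the NS genotype is rough at every examined temperature
  expect_equal(expressed_temperatures(ns_genotype()), c(21L, 30L, 37L))
  # swapping FLO11 to BY in the NS background removes 37 C only
  expect_equal(expressed_temperatures(swap(ns_genotype(), FLO11 = "BY")),
               c(21L, 30L))
  # swapping MGA1 to 3S in the NS background removes 37 C only
  expect_equal(expressed_temperatures(swap(ns_genotype(), MGA1 = "3S")),
               c(21L, 30L))
  # each swap in the MSS11^3S-dependent HS genotype abolishes the trait
  for (sw in list(c(END3 = "3S"), c(MGA1 = "3S"), c(SFL1 = "3S"))) {
    expect_equal(expressed_temperatures(swap(hsb_genotype(), sw)),
                 integer(0))
  }
  # without the ira2 mutation nothing is expressed
  allBY <- setNames(rep("BY", 9), names(ns_genotype()))
  expect_equal(expressed_temperatures(allBY), integer(0))
})

test_that("classification maps temperature sets onto the three classes", {
  expect_equal(classify_genotype(ns_genotype()), "NS")
  expect_equal(classify_genotype(swap(ns_genotype(), FLO11 = "BY",
                                      MGA1 = "3S")), "MS")
  # MSS11^BY individuals need only FLO8^3S and the mutation at 21 C
  g <- setNames(rep("3S", 9), names(ns_genotype()))
  g[c("FLO8", "IRA2", "MSS11")] <- c("3S", "MUT", "BY")
  expect_equal(classify_genotype(g), "HS")
  allBY <- setNames(rep("BY", 9), names(ns_genotype()))
  expect_equal(classify_genotype(allBY), "SMOOTH")
})

test_that("a genotype missing a required locus raises a named error", {
  g <- ns_genotype()[-match("MSS11", names(ns_genotype()))]
  expect_error(expressed_temperatures(g), "MSS11")
  expect_error(classify_genotype(g), "MSS11")
})

test_that("the default rules name the seven environmentally responsive loci", {
  expect_setequal(temperature_modifiers(default_rule_set()),
                  c("XII", "END3", "FLO11", "MGA1", "MSS11", "SFL1", "TRR1"))
  # a single rule has no modifiers: every required allele is uniform
  one <- rule_set(list(genotype_rule(
    "only", c(FLO8 = "3S", IRA2 = "MUT", MSS11 = "BY"), 21)))
  expect_equal(temperature_modifiers(one), character(0))
  # two rules differing at a single locus implicate exactly that locus
  two <- rule_set(list(
    genotype_rule("a", c(FLO8 = "3S", IRA2 = "MUT", MSS11 = "BY"), 21),
    genotype_rule("b", c(FLO8 = "3S", IRA2 = "MUT", MSS11 = "3S"), 21)))
  expect_equal(temperature_modifiers(two), "MSS11")
})

test_that("requirement sets nest: HS-a within MS-a within NS", {
  rs <- default_rule_set()
  req <- lapply(rs, `[[`, "requirements")
  is_subset <- function(a, b) all(names(a) %in% names(b)) &&
    all(b[names(a)] == a)
  expect_true(is_subset(req[["HS-MSS11BY"]], req[["MS-END3BY"]]))
  expect_true(is_subset(req[["MS-END3BY"]], req[["NS"]]))
  # consequence: a genotype satisfying NS satisfies both nested rules and
  # the union classifies it NS
  expect_true(satisfies_rule(ns_genotype(), rs[["HS-MSS11BY"]]))
  expect_true(satisfies_rule(ns_genotype(), rs[["MS-END3BY"]]))
  expect_equal(classify_genotype(ns_genotype()), "NS")
})

test_that("expressed temperatures grow monotonically with satisfied rules", {
  rs <- default_rule_set()
  set.seed(42)
  loci <- names(ns_genotype())
  for (i in 1:50) {
    g <- setNames(sample(c("BY", "3S"), 9, replace = TRUE), loci)
    g["IRA2"] <- sample(c("BY", "MUT"), 1)
    full <- expressed_temperatures(g, rs)
    part <- expressed_temperatures(g, rule_set(unclass(rs)[1:3]))
    expect_true(all(part %in% full))
  }
})

test_that("expected genotype frequencies follow Mendelian products", {
  map <- default_genome_map()
  f2 <- f2_design(map)
  rs <- default_rule_set()
  # five segregating required alleles
  expect_equal(expected_frequency(rs[["MS-END3BY"]], f2), 1 / 32)
  # a six-allele genotype occurs half as often as a five-allele one
  expect_equal(expected_frequency(rs[["MS-END33S"]], f2) /
                 expected_frequency(rs[["MS-END3BY"]], f2), 0.5)
  # fixed mismatching allele kills the genotype: END3 is fixed BY in the
  # BY backcross, so the END3^3S-dependent genotype cannot occur there
  by <- backcross_design(map, "BY")
  expect_equal(expected_frequency(rs[["MS-END33S"]], by), 0)
  # locus absent from the design errors
  r <- genotype_rule("x", c(FLO8 = "3S", IRA2 = "MUT", NOVEL1 = "BY"), 21)
  expect_error(expected_frequency(r, f2), "NOVEL1")
})

test_that("expected frequencies equal brute-force enumeration over genotype tables", {
  map <- default_genome_map()
  rs <- default_rule_set()
  for (design in list(f2_design(map), backcross_design(map, "BY"),
                      backcross_design(map, "3S"))) {
    dl <- design$loci
    cols <- lapply(seq_len(nrow(dl)), function(i) {
      if (dl$segregating[i]) c(dl$focal[i], dl$recurrent[i]) else dl$focal[i]
    })
    names(cols) <- dl$locus
    tab <- as.matrix(expand.grid(cols, stringsAsFactors = FALSE))
    for (r in unclass(rs)) {
      frac <- mean(apply(tab, 1, satisfies_rule, rule = r))
      expect_equal(frac, expected_frequency(r, design), info = r$name)
    }
  }
})

test_that("rule sets serialize to JSON and back unchanged", {
  rs <- default_rule_set()
  path <- withr::local_tempfile(fileext = ".json")
  write_rule_set(rs, path)
  expect_equal(read_rule_set(path), rs)
  shipped <- system.file("extdata", "default_ruleset.json", package = "gxemap")
  expect_equal(read_rule_set(shipped), rs)
})

test_that("rule-set construction enforces the generally required pair", {
  expect_error(rule_set(list(genotype_rule("bad", c(MSS11 = "BY"), 21))),
               "FLO8")
  expect_error(genotype_rule("bad", c(FLO8 = "3S", IRA2 = "MUT"), 25),
               "temperatures")
  expect_error(genotype_rule("bad", character(0), 21), "non-empty")
})
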
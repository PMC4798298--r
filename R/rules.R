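# Multi-locus genotype -> temperature-sensitivity rule engine.
#
# A rule names the alleles that a multi-locus genotype must carry and the
# set of temperatures (deg C) at which carriers express the rough colony
# phenotype. The default rule set encodes the five predominant genotypes
# underlying the highly sensitive (HS), moderately sensitive (MS) and
# non-sensitive (NS) classes. Every rule requires FLO8^3S together with
# the ira2 frameshift (allele "MUT"), the generally required pair.

TEMPERATURES <- c(21L, 30L, 37L)

#' Construct a genotype rule
#'
#' @param name rule identifier.
#' @param requirements named character vector, locus -> required allele in
#'   `{"BY", "3S", "MUT"}`.
#' @param temperatures permissive temperatures, a subset of `c(21, 30, 37)`.
#' @return An object of class `genotype_rule`.
#' @export
genotype_rule <- function(name, requirements, temperatures) {
  if (!length(requirements)) stop("requirements must be non-empty")
  if (is.null(names(requirements)) || any(names(requirements) == ""))
    stop("requirements must be a named vector (locus -> allele)")
  if (anyDuplicated(names(requirements))) stop("duplicated locus in requirements")
  if (!all(requirements %in% ALLELES))
    stop("alleles must be in {", paste(ALLELES, collapse = ", "), "}")
  temperatures <- sort(unique(as.integer(temperatures)))
  if (!length(temperatures) || !all(temperatures %in% TEMPERATURES))
    stop("temperatures must be a non-empty subset of {21, 30, 37}")
  structure(list(name = name,
                 requirements = requirements[order(names(requirements))],
                 temperatures = temperatures),
            class = "genotype_rule")
}

#' Construct a rule set
#'
#' @param rules list of [genotype_rule()] objects with unique names. Each
#'   rule must require the generally required pair FLO8^3S and IRA2^MUT.
#' @return An object of class `rule_set`.
#' @export
rule_set <- function(rules) {
  stopifnot(length(rules) >= 1, all(vapply(rules, inherits, TRUE, "genotype_rule")))
  nm <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("rule names must be unique")
  for (r in rules) {
    req <- r$requirements
    if (!identical(unname(req["FLO8"]), "3S") || !identical(unname(req["IRA2"]), "MUT"))
      stop("rule '", r$name, "' must require FLO8=3S and IRA2=MUT")
  }
  structure(setNames(rules, nm), class = "rule_set")
}

#' The five predominant multi-locus genotypes
#'
#' Default rule set: two HS genotypes (rough at 21 deg C only), two MS
#' genotypes (21 and 30), and the single NS genotype (21, 30 and 37).
#' The MSS11^BY-dependent HS genotype needs only FLO8^3S and the ira2
#' mutation besides MSS11^BY; the MSS11^3S-dependent HS genotype
#' additionally requires XII^3S, END3^BY, MGA1^BY and SFL1^BY.
#'
#' @return A `rule_set` of five rules named `HS-MSS11BY`, `HS-MSS113S`,
#'   `MS-END3BY`, `MS-END33S`, `NS`.
#' @export
default_rule_set <- function() {
  rule_set(list(
    genotype_rule("HS-MSS11BY",
                  c(FLO8 = "3S", IRA2 = "MUT", MSS11 = "BY"),
                  21),
    genotype_rule("HS-MSS113S",
                  c(XII = "3S", END3 = "BY", FLO8 = "3S", IRA2 = "MUT",
                    MGA1 = "BY", MSS11 = "3S", SFL1 = "BY"),
                  21),
    genotype_rule("MS-END3BY",
                  c(END3 = "BY", FLO8 = "3S", IRA2 = "MUT", MSS11 = "BY",
                    TRR1 = "3S"),
                  c(21, 30)),
    genotype_rule("MS-END33S",
                  c(END3 = "3S", FLO8 = "3S", IRA2 = "MUT", MGA1 = "BY",
                    MSS11 = "BY", SFL1 = "BY"),
                  c(21, 30)),
    genotype_rule("NS",
                  c(END3 = "BY", FLO8 = "3S", FLO11 = "3S", IRA2 = "MUT",
                    MGA1 = "BY", MSS11 = "BY", SFL1 = "BY", TRR1 = "3S"),
                  c(21, 30, 37))
  ))
}

rule_loci <- function(rules) {
  unique(unlist(lapply(unclass(rules), function(r) names(r$requirements))))
}

check_genotype_covers <- function(genotype, rules) {
  missing <- setdiff(rule_loci(rules), names(genotype))
  if (length(missing))
    stop("genotype is missing locus/loci: ", paste(missing, collapse = ", "))
}

#' Does a genotype satisfy a rule?
#'
#' @param genotype named character vector, locus -> allele.
#' @param rule a `genotype_rule`.
#' @return logical.
#' @export
satisfies_rule <- function(genotype, rule) {
  req <- rule$requirements
  missing <- setdiff(names(req), names(genotype))
  if (length(missing))
    stop("genotype is missing locus/loci: ", paste(missing, collapse = ", "))
  all(genotype[names(req)] == req)
}

#' Temperatures at which a genotype expresses the rough phenotype
#'
#' The union of the permissive temperature sets of all satisfied rules;
#' an empty result means the genotype is smooth at every temperature.
#' Overlaps are resolved by union, which with the default (nested) rule
#' set coincides with the most-specific-rule reading.
#'
#' @param genotype named character vector covering every locus the rule
#'   set names.
#' @param rules a `rule_set` (default [default_rule_set()]).
#' @return sorted integer vector, a subset of `c(21, 30, 37)`.
#' @export
expressed_temperatures <- function(genotype, rules = default_rule_set()) {
  check_genotype_covers(genotype, rules)
  temps <- integer(0)
  for (r in unclass(rules))
    if (satisfies_rule(genotype, r)) temps <- union(temps, r$temperatures)
  sort(temps)
}

#' Classify a genotype into a temperature-sensitivity class
#'
#' Maps the expressed temperature set to `"HS"` (21 only), `"MS"` (21 and
#' 30), `"NS"` (all three) or `"SMOOTH"` (none). Any other temperature
#' set is impossible under the default rule set and raises an error.
#'
#' @inheritParams expressed_temperatures
#' @return one of `"HS"`, `"MS"`, `"NS"`, `"SMOOTH"`.
#' @export
classify_genotype <- function(genotype, rules = default_rule_set()) {
  temps <- expressed_temperatures(genotype, rules)
  if (!length(temps)) return("SMOOTH")
  key <- paste(temps, collapse = ",")
  cls <- c("21" = "HS", "21,30" = "MS", "21,30,37" = "NS")
  if (!key %in% names(cls))
    stop("temperature set {", key, "} has no class under this rule set")
  unname(cls[key])
}

#' Loci that modify temperature sensitivity
#'
#' Loci appearing in at least one rule's requirements, excluding loci
#' required with an identical allele in every rule of the set (those,
#' like FLO8^3S and IRA2^MUT, are generally required for the trait and do
#' not modify its temperature sensitivity).
#'
#' @param rules a `rule_set`.
#' @return character vector of locus names (possibly empty).
#' @export
temperature_modifiers <- function(rules = default_rule_set()) {
  rl <- unclass(rules)
  loci <- rule_loci(rules)
  uniform <- vapply(loci, function(l) {
    alle <- vapply(rl, function(r) {
      if (l %in% names(r$requirements)) unname(r$requirements[l]) else NA_character_
    }, "")
    !anyNA(alle) && length(unique(alle)) == 1
  }, TRUE)
  sort(loci[!uniform])
}

#' Expected Mendelian frequency of a multi-locus genotype
#'
#' Product over the rule's required loci of 1/2 where the locus segregates
#' for the required allele, 1 where it is fixed at the required allele,
#' and 0 where it is fixed at (or segregates only between) other alleles.
#'
#' @param rule a `genotype_rule`.
#' @param design a `cross_design` whose map names every required locus.
#' @return probability in \[0, 1\].
#' @export
expected_frequency <- function(rule, design) {
  if (is.null(design$loci)) stop("design carries no locus table")
  dl <- design$loci
  p <- 1
  for (l in names(rule$requirements)) {
    i <- match(l, dl$locus)
    if (is.na(i)) stop("locus ", l, " absent from design")
    a <- unname(rule$requirements[l])
    if (dl$segregating[i]) {
      p <- p * if (a %in% c(dl$focal[i], dl$recurrent[i])) 0.5 else 0
    } else {
      p <- p * as.numeric(a == dl$focal[i])
    }
  }
  p
}

#' @export
print.rule_set <- function(x, ...) {
  for (r in unclass(x)) {
    cat(sprintf("%-12s {%s} -> {%s}\n", r$name,
                paste(names(r$requirements), r$requirements, sep = "^", collapse = " "),
                paste(r$temperatures, collapse = ",")))
  }
  invisible(x)
}

#' Write a rule set to JSON
#'
#' Serialized as a list of `{name, requirements, temperatures}` objects;
#' the packaged default rule set lives at
#' `system.file("extdata", "default_ruleset.json", package = "gxemap")`.
#'
#' @param rules a `rule_set`.
#' @param path output file.
#' @export
write_rule_set <- function(rules, path) {
  obj <- lapply(unclass(rules), function(r)
    list(name = r$name, requirements = as.list(r$requirements),
         temperatures = r$temperatures))
  jsonlite::write_json(unname(obj), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a rule set from JSON
#'
#' @param path file written by [write_rule_set()].
#' @return A `rule_set`.
#' @export
read_rule_set <- function(path) {
  check_nonempty_file(path)
  obj <- jsonlite::read_json(path)
  rule_set(lapply(obj, function(o)
    genotype_rule(o$name, unlist(o$requirements), unlist(o$temperatures))))
}
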
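# Replicate colony scores -> per-temperature states -> class calls.

#' Median of replicate colony scores
#'
#' @param scores numeric scores on the 0-5 scale.
#' @return the median (even counts average the central pair).
#' @export
median_score <- function(scores) {
  if (!length(scores)) stop("no scores")
  if (any(scores < 0 | scores > 5)) stop("scores must lie in [0, 5]")
  stats::median(scores)
}

#' Call the colony state from a median score
#'
#' Medians in \[0, 1\] are called smooth and in \[4, 5\] rough (bounds
#' inclusive); anything between is ambiguous ("bumpy" colonies have no
#' class semantics).
#'
#' @param median_value median score in \[0, 5\].
#' @return one of `"smooth"`, `"rough"`, `"ambiguous"`.
#' @export
call_state <- function(median_value) {
  if (is.na(median_value) || median_value < 0 || median_value > 5)
    stop("median score out of range [0, 5]")
  if (median_value <= 1) "smooth" else if (median_value >= 4) "rough" else "ambiguous"
}

#' Call the temperature-sensitivity class from per-temperature states
#'
#' (rough, smooth, smooth) at (21, 30, 37) is HS; (rough, rough, smooth)
#' MS; (rough, rough, rough) NS. Every other combination — including any
#' ambiguous state — is unclassified: only individuals that clearly and
#' consistently show smooth or rough colonies are classified.
#'
#' @param state21,state30,state37 states from [call_state()].
#' @return one of `"HS"`, `"MS"`, `"NS"`, `"unclassified"`.
#' @export
call_class <- function(state21, state30, state37) {
  key <- paste(state21, state30, state37, sep = "/")
  switch(key,
         "rough/smooth/smooth" = "HS",
         "rough/rough/smooth" = "MS",
         "rough/rough/rough" = "NS",
         "unclassified")
}

#' Classify a table of replicate phenotype scores
#'
#' @param phenotypes data.frame with columns `individual`, `temperature`
#'   (21/30/37), `replicate`, `score`.
#' @return data.frame with one row per individual: `individual`,
#'   `state21`, `state30`, `state37`, `class`, plus attribute
#'   `fraction_classified` (HS+MS+NS over all individuals).
#' @export
classify_phenotypes <- function(phenotypes) {
  stopifnot(all(c("individual", "temperature", "replicate", "score") %in%
                names(phenotypes)))
  ids <- unique(phenotypes$individual)
  rows <- lapply(ids, function(id) {
    d <- phenotypes[phenotypes$individual == id, ]
    st <- vapply(TEMPERATURES, function(tt) {
      sc <- d$score[d$temperature == tt]
      if (!length(sc)) stop("individual ", id, " has no scores at ", tt, " C")
      call_state(median_score(sc))
    }, "")
    data.frame(individual = id, state21 = st[1], state30 = st[2],
               state37 = st[3], class = call_class(st[1], st[2], st[3]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction_classified") <- mean(out$class != "unclassified")
  out
}
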
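#' Population state
#'
#' Frequencies of the four genotypes: `XXn` (hermaphrodites), `XYn` (males
#' without CMS), `XXc` (females, i.e. CMS hermaphrodites) and `XYc` (CMS
#' males). Frequencies must be non-negative and sum to 1 (to within 1e-12).
#'
#' @param XXn,XYn,XXc,XYc Genotype frequencies.
#' @return A named numeric vector of class `population_state`.
#' @examples
#' population_state(0.8, 0.2, 0, 0)
#' pure_hermaphrodites()
#' @export
population_state <- function(XXn, XYn = 0, XXc = 0, XYc = 0) {
  f <- c(XXn = XXn, XYn = XYn, XXc = XXc, XYc = XYc)
  validate_state(f)
  structure(f, class = "population_state")
}

#' @rdname population_state
#' @export
pure_hermaphrodites <- function() population_state(1, 0, 0, 0)

validate_state <- function(f) {
  if (!is.numeric(f) || length(f) != 4L || anyNA(f))
    stop("a population state is 4 genotype frequencies", call. = FALSE)
  if (any(f < 0))
    stop("genotype frequencies must be non-negative", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-12)
    stop("genotype frequencies must sum to 1 (|sum - 1| = ",
         format(abs(sum(f) - 1)), ")", call. = FALSE)
  invisible(f)
}

as_state <- function(f) {
  structure(setNames(as.numeric(f), GENOTYPES), class = "population_state")
}

#' @export
print.population_state <- function(x, digits = 6, ...) {
  cat("Population state (genotype frequencies):\n")
  print(round(unclass(x), digits))
  cat(sprintf("  hermaphrodites %.4g | males %.4g | females %.4g | CMS %.4g\n",
              x[["XXn"]], x[["XYn"]] + x[["XYc"]], x[["XXc"]],
              x[["XXc"]] + x[["XYc"]]))
  invisible(x)
}

#' Phenotype and cytotype summaries of a state
#'
#' Helpers aggregating genotype frequencies into the three sexual phenotypes
#' (hermaphrodites `XXn`; males `XYn + XYc`; females `XXc`) and the CMS
#' cytotype frequency (`XXc + XYc`).
#'
#' @param state A [population_state()].
#' @return A single frequency ([male_frequency()], [female_frequency()],
#'   [cms_frequency()]) or a named length-3 vector ([phenotype_frequencies()]).
#' @export
male_frequency <- function(state) unname(state[["XYn"]] + state[["XYc"]])

#' @rdname male_frequency
#' @export
female_frequency <- function(state) unname(state[["XXc"]])

#' @rdname male_frequency
#' @export
cms_frequency <- function(state) unname(state[["XXc"]] + state[["XYc"]])

#' @rdname male_frequency
#' @export
phenotype_frequencies <- function(state) {
  c(hermaphrodite = unname(state[["XXn"]]),
    male = male_frequency(state),
    female = female_frequency(state))
}
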
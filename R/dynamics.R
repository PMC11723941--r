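#' Introduce a genotype at low frequency
#'
#' Set the named genotype to frequency `freq` and rescale the remaining
#' genotypes proportionally so the frequencies still sum to 1. This is the
#' standard invasion protocol: a mutant enters at a rare frequency (1e-6 in
#' the invasion scenarios) without disturbing the residents' relative
#' proportions.
#'
#' @param state A [population_state()].
#' @param genotype One of `"XXn"`, `"XYn"`, `"XXc"`, `"XYc"`.
#' @param freq Introduction frequency in `[0, 1)`; `freq = 0` returns the
#'   state unchanged.
#' @return The perturbed [population_state()].
#' @examples
#' introduce(pure_hermaphrodites(), "XYn", 1e-6)
#' @export
introduce <- function(state, genotype, freq = 1e-6) {
  validate_state(state)
  genotype <- match.arg(genotype, GENOTYPES)
  if (freq < 0 || freq >= 1)
    stop("'freq' must lie in [0, 1)", call. = FALSE)
  if (freq == 0) return(state)
  f <- as.numeric(state)
  names(f) <- GENOTYPES
  rest <- sum(f[setdiff(GENOTYPES, genotype)])
  if (rest <= 0)
    stop("cannot introduce into a state whose other frequencies are all zero",
         call. = FALSE)
  f[setdiff(GENOTYPES, genotype)] <-
    f[setdiff(GENOTYPES, genotype)] * (1 - freq) / rest
  f[genotype] <- freq
  as_state(f)
}

#' Iterate the recursion to equilibrium
#'
#' Repeatedly apply the one-generation map until the genotype frequencies
#' stop changing: the run is deemed converged when the L-infinity difference
#' between states `window` generations apart falls below `tol`
#' (default: less than 1e-10 over 20 generations). Runs end early on
#' extinction (no viable zygotes) or, optionally, when the CMS cytotype
#' frequency reaches `stop_at_cms` (used by the rescue protocol of
#' [run_scenario()]).
#'
#' @param state Initial [population_state()].
#' @param params A [cms_params()] object.
#' @param tol Convergence tolerance on the change over `window` generations.
#' @param window Number of generations over which change is measured.
#' @param max_gen Generation cap; reaching it returns `converged = FALSE`
#'   with the last state rather than an error (near-threshold dynamics are
#'   slow).
#' @param stop_at_cms If non-`NULL`, stop as soon as the CMS frequency
#'   reaches this value.
#' @param eps Presence threshold passed to [classify()].
#' @return An object of class `equilibrium_result`: a list with fields
#'   `state`, `generations`, `converged`, `extinct`, `stopped_at_cms` and
#'   `classification`.
#' @examples
#' p <- cms_params(alpha = 4)
#' res <- iterate_to_equilibrium(introduce(pure_hermaphrodites(), "XYn"), p)
#' res$classification              # androdioecy
#' male_frequency(res$state)       # 1/3 (alpha = 4, s = 0)
#' @export
iterate_to_equilibrium <- function(state, params, tol = 1e-10, window = 20,
                                   max_gen = 2e6, stop_at_cms = NULL,
                                   eps = 1e-4) {
  validate_state(state)
  res <- cpp_iterate(as.numeric(state), params_vector(params),
                     as.numeric(max_gen), tol, as.integer(window),
                     if (is.null(stop_at_cms)) -1 else stop_at_cms)
  out <- list(state = as_state(res$state),
              generations = res$generations,
              converged = res$converged,
              extinct = res$extinct,
              stopped_at_cms = res$stopped_at_cms)
  out$classification <- classify(out$state, params, eps = eps,
                                 converged = res$converged,
                                 extinct = res$extinct)
  structure(out, class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  status <- if (x$extinct) "extinct"
            else if (x$converged) "converged"
            else if (x$stopped_at_cms) "stopped at CMS threshold"
            else "generation cap reached"
  cat(sprintf("Equilibrium run: %s after %.0f generations -> %s\n",
              status, x$generations, x$classification))
  print(x$state)
  invisible(x)
}

#' Classify the sexual system of a state
#'
#' Map the pattern of phenotypes present — hermaphrodites (`XXn`), males
#' (`XYn + XYc`), females (`XXc`) — to one of the six sexual-system labels.
#' A phenotype counts as present when its frequency exceeds `eps`. States in
#' which no seed parent remains (only males, only females with no viable
#' outcome, or an extinction flag from the dynamics) are labelled
#' `extinction`.
#'
#' @param state A [population_state()].
#' @param params A [cms_params()] object (reserved for classification rules
#'   that depend on the mating-system variant).
#' @param eps Presence threshold; chosen well above the 1e-6 introduction
#'   frequency and far above the 1e-10 convergence tolerance.
#' @param converged Whether the state comes from a converged run; if not,
#'   the label carries attribute `provisional = TRUE`.
#' @param extinct Whether the dynamics flagged extinction.
#' @return A character scalar: one of `"hermaphroditism"`, `"androdioecy"`,
#'   `"gynodioecy"`, `"trioecy"`, `"dioecy"`, `"extinction"`.
#' @examples
#' classify(population_state(0.7, 0.3), cms_params(alpha = 4))
#' @export
classify <- function(state, params, eps = 1e-4, converged = TRUE,
                     extinct = FALSE) {
  if (extinct) {
    label <- "extinction"
  } else {
    h <- state[["XXn"]] > eps
    m <- male_frequency(state) > eps
    fe <- female_frequency(state) > eps
    label <-
      if (h && m && fe) "trioecy"
      else if (h && m) "androdioecy"
      else if (h && fe) "gynodioecy"
      else if (h) "hermaphroditism"
      else if (m && fe) "dioecy"
      else "extinction"  # only males, or only females: no persisting population
  }
  if (!converged) attr(label, "provisional") <- TRUE
  label
}

#' Run an invasion-order scenario
#'
#' Reproduce the two invasion protocols of the model. `males_first`: start
#' from pure hermaphrodites, introduce `XY,n` males at `intro_freq`, iterate
#' to equilibrium (the androdioecious resident), then introduce `XX,c`
#' females and iterate to the final equilibrium. `females_first`: introduce
#' `XX,c` first; if the CMS frequency reaches `rescue_at` before convergence
#' (CMS destined to fix, which without pollen limitation means extinction),
#' males are introduced at `intro_freq` at that generation and the run
#' continues; if instead the first phase converges, males are introduced at
#' the (gynodioecious or hermaphroditic) equilibrium. `none`: simply
#' equilibrate `start`.
#'
#' @param params A [cms_params()] object.
#' @param order `"males_first"`, `"females_first"` or `"none"`.
#' @param intro_freq Introduction frequency for each invading genotype.
#' @param rescue_at CMS frequency triggering male introduction in the
#'   `females_first` protocol.
#' @param start Initial state (default pure hermaphrodites).
#' @param ... Passed to [iterate_to_equilibrium()] (`tol`, `window`,
#'   `max_gen`, `eps`).
#' @return An object of class `scenario_result`: a list with `stages` (named
#'   list of `equilibrium_result`s in order), `final` (the last stage) and
#'   `classification`.
#' @examples
#' p <- cms_params(g = 1.1, alpha = 5, s = 0.4, d = 0.1, e_m = 0.8)
#' run_scenario(p, "males_first")$classification   # trioecy
#' @export
run_scenario <- function(params, order = c("males_first", "females_first",
                                           "none"),
                         intro_freq = 1e-6, rescue_at = 0.99,
                         start = pure_hermaphrodites(), ...) {
  order <- match.arg(order)
  stages <- list()
  if (order == "none") {
    stages$equilibrium <- iterate_to_equilibrium(start, params, ...)
  } else if (order == "males_first") {
    stages$androdioecy <-
      iterate_to_equilibrium(introduce(start, "XYn", intro_freq), params, ...)
    if (!stages$androdioecy$extinct) {
      stages$cms_invasion <-
        iterate_to_equilibrium(introduce(stages$androdioecy$state, "XXc",
                                         intro_freq), params, ...)
    }
  } else {
    first <- iterate_to_equilibrium(introduce(start, "XXc", intro_freq),
                                    params, stop_at_cms = rescue_at, ...)
    stages$cms_first <- first
    if (!first$extinct) {
      # males enter either at the converged (gyno)dioecious equilibrium or,
      # when CMS is destined to fix, as a rescue at CMS frequency rescue_at
      stages$male_invasion <-
        iterate_to_equilibrium(introduce(first$state, "XYn", intro_freq),
                               params, ...)
    }
  }
  final <- stages[[length(stages)]]
  structure(list(stages = stages, final = final,
                 classification = final$classification,
                 order = order),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Invasion scenario (%s), %d stage(s) -> %s\n", x$order,
              length(x$stages), x$classification))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-14s %8.0f generations, %s\n", nm, st$generations,
                st$classification))
  }
  print(x$final$state)
  invisible(x)
}

#' Locate a threshold by bisection on full simulations
#'
#' A numerical oracle for the closed-form thresholds: bisect a single
#' parameter between `lo` and `hi`, where `predicate(params)` runs a
#' simulation and reports a qualitative outcome (e.g. "CMS is present at
#' equilibrium"). The predicate must differ between the two endpoints.
#'
#' @param params Baseline [cms_params()]; the varied field is overwritten.
#' @param vary Name of the parameter to vary (`"g"`, `"alpha"`, `"s"`,
#'   `"d"` or `"e_m"`).
#' @param lo,hi Bracketing interval.
#' @param predicate Function of a `cms_params` object returning `TRUE` or
#'   `FALSE`.
#' @param tol Interval width at which to stop; the midpoint is returned.
#' @return The boundary value of the varied parameter.
#' @examples
#' \donttest{
#' p <- cms_params(model = 1)
#' invades_males <- function(pp) {
#'   res <- iterate_to_equilibrium(introduce(pure_hermaphrodites(), "XYn"),
#'                                 pp, max_gen = 1e5)
#'   male_frequency(res$state) > 1e-5
#' }
#' bisect_threshold(p, "alpha", 1.2, 3, invades_males, tol = 1e-4)  # 2
#' }
#' @export
bisect_threshold <- function(params, vary, lo, hi, predicate, tol = 1e-6) {
  vary <- match.arg(vary, c("g", "alpha", "s", "d", "e_m"))
  at <- function(v) { p <- params; p[[vary]] <- v; predicate(p) }
  p_lo <- at(lo); p_hi <- at(hi)
  if (identical(p_lo, p_hi))
    stop("predicate does not change sign across [lo, hi]", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(at(mid), p_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-generation trajectory
#'
#' Record the genotype frequencies for a fixed number of generations, for
#' plotting and for the `simulate` CLI subcommand.
#'
#' @inheritParams iterate_to_equilibrium
#' @param n_gen Number of generations to record.
#' @return A data frame with columns `generation`, the four genotype
#'   frequencies, `CMS_freq`, `male_freq` and `female_freq`. Truncated at
#'   extinction.
#' @examples
#' p <- cms_params(alpha = 4)
#' head(trajectory(introduce(pure_hermaphrodites(), "XYn", 0.01), p, 50))
#' @export
trajectory <- function(state, params, n_gen) {
  validate_state(state)
  m <- cpp_trajectory(as.numeric(state), params_vector(params),
                      as.integer(n_gen))
  colnames(m) <- paste0("f_", GENOTYPES)
  data.frame(generation = seq_len(nrow(m)) - 1L, m,
             CMS_freq = m[, 3] + m[, 4],
             male_freq = m[, 2] + m[, 4],
             female_freq = m[, 3])
}
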
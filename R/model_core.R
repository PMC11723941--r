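#' Per-generation gamete pools
#'
#' Compute, for a population state, the pollen pool, the proportions of X- and
#' Y-bearing pollen, and the fertilized-ovule classes that drive the
#' genotype-frequency recursion: outcrossed ovules by maternal genotype
#' (`O_XXn`, `O_XXc`), prior-selfed ovules (`S1_XXn`), delayed-selfed ovules
#' (`S2_XXn`, model 3 only), and the total number of viable zygotes `N_S`.
#'
#' Pollen: hermaphrodites contribute `P_h` each, males `alpha * P_h`, CMS
#' males `(1 - e_m) * alpha * P_h`, females none. Half of male pollen carries
#' Y. Ovules: hermaphrodites `G_h`, females `g * G_h`, males none.
#' Hermaphrodites prior-self a fraction `s` of their ovules irrespective of
#' pollen availability; the rest are outcrossed with probability 1 (model 1)
#' or `min(1, P / P_h)` (models 2 and 3) where `P` is the mean per-capita
#' pollen production. In model 3, hermaphrodite ovules that are neither
#' prior-selfed nor outcrossed are fertilized by delayed selfing; females'
#' unfertilized ovules always abort. A fraction `d` of all selfed zygotes
#' dies, so `N_S = O_XXn + O_XXc + (S1 + S2) * (1 - d)`.
#'
#' When the population produces no pollen at all (only females present),
#' outcross fertilization is zero in all three models and `P_X = P_Y = 0`.
#'
#' @param state A [population_state()].
#' @param params A [cms_params()] object.
#' @return An object of class `gamete_pools`: a named list with fields
#'   `P_bar`, `P_X`, `P_Y`, `O_XXn`, `O_XXc`, `S1_XXn`, `S2_XXn`, `N_S`.
#' @examples
#' p <- cms_params(alpha = 5, s = 0.4, d = 0.1)
#' gamete_pools(population_state(0.5, 0.5), p)
#' @export
gamete_pools <- function(state, params) {
  validate_state(state)
  gp <- gamete_pools_raw(as.numeric(state), params)
  structure(gp, class = "gamete_pools")
}

# unvalidated workhorse; also the analytic extension used by the Jacobian
# (tolerates slightly negative frequencies from finite-difference probes)
gamete_pools_raw <- function(f, params) {
  with(params, {
    pol_h <- f[1] * P_h
    pol_m <- f[2] * alpha * P_h + f[4] * (1 - e_m) * alpha * P_h
    P_bar <- pol_h + pol_m
    if (P_bar > 0) {
      P_X <- (pol_h + 0.5 * pol_m) / P_bar
      P_Y <- 1 - P_X
      outx <- if (model == 1L) 1 else min(1, P_bar / P_h)
    } else {
      P_X <- P_Y <- 0
      outx <- 0
    }
    S1 <- s * G_h * f[1]
    O_XXn <- outx * (1 - s) * G_h * f[1]
    O_XXc <- outx * g * G_h * f[3]
    S2 <- if (model == 3L) (1 - outx) * (1 - s) * G_h * f[1] else 0
    list(P_bar = P_bar, P_X = P_X, P_Y = P_Y,
         O_XXn = O_XXn, O_XXc = O_XXc, S1_XXn = S1, S2_XXn = S2,
         N_S = O_XXn + O_XXc + (S1 + S2) * (1 - d))
  })
}

#' @export
print.gamete_pools <- function(x, digits = 6, ...) {
  cat("Gamete pools (per capita, units of P_h / G_h):\n")
  print(round(unlist(x), digits))
  invisible(x)
}

#' One generation of the genotype-frequency recursion
#'
#' Apply the deterministic one-generation map. Writing `O`, `S1`, `S2` for the
#' fertilized-ovule classes of [gamete_pools()] and `P_X`, `P_Y` for the
#' pollen haplotype proportions, the next-generation frequencies are
#' proportional to
#' \deqn{f'_{XX,n} \propto O_{XX,n} P_X + (S1 + S2)(1 - d), \quad
#'       f'_{XY,n} \propto O_{XX,n} P_Y,}
#' \deqn{f'_{XX,c} \propto O_{XX,c} P_X, \quad
#'       f'_{XY,c} \propto O_{XX,c} P_Y,}
#' normalized by the total viable zygote count `N_S`. The cytotype is
#' strictly maternal: pollen never transmits CMS, and all selfed seed of
#' hermaphrodites is `XX,n`.
#'
#' Frequencies below 1e-15 after the step are clamped to zero and the state
#' renormalized, so long runs do not accumulate denormal tails.
#'
#' @inheritParams gamete_pools
#' @return The next [population_state()].
#' @section Extinction: if no viable zygote is produced (`N_S = 0`, e.g. an
#'   all-female population), a condition of class `population_extinct` is
#'   signalled; its `state` field carries the pre-step state.
#' @examples
#' p <- cms_params(alpha = 5)
#' step_generation(population_state(0.8, 0.2), p)
#' @export
step_generation <- function(state, params) {
  validate_state(state)
  f <- as.numeric(state)
  gp <- gamete_pools_raw(f, params)
  if (gp$N_S <= 0) {
    cond <- structure(
      class = c("population_extinct", "error", "condition"),
      list(message = "population produced no viable zygotes (N_S = 0)",
           call = sys.call(), state = as_state(f)))
    stop(cond)
  }
  nxt <- step_raw(f, params, gp)
  nxt[nxt < 1e-15] <- 0
  as_state(nxt / sum(nxt))
}

# the unnormalized-then-normalized map without clamping; gp optional
step_raw <- function(f, params, gp = gamete_pools_raw(f, params)) {
  num <- c(gp$O_XXn * gp$P_X + (gp$S1_XXn + gp$S2_XXn) * (1 - params$d),
           gp$O_XXn * gp$P_Y,
           gp$O_XXc * gp$P_X,
           gp$O_XXc * gp$P_Y)
  num / gp$N_S
}
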
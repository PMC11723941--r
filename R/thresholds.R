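#' Closed-form invasion and fixation thresholds
#'
#' Analytical criteria for the invasion of males and of the CMS cytotype and
#' for the fixation of CMS, expressed as thresholds on the relative
#' fecundities `alpha` (male pollen production) and `g` (female seed
#' production).
#'
#' * [male_invasion_alpha()]: males invade a hermaphroditic population iff
#'   `alpha > 2 (1 - s d) / (1 - s)`. At `s = 0` males must be at least twice
#'   as successful at siring as hermaphrodites; under complete selfing
#'   (`s = 1`) the threshold is infinite.
#' * [cms_invasion_g_herm()]: CMS invades a pure hermaphroditic population
#'   iff `g > 1 - s d`.
#' * [cms_invasion_g_andro()]: in an androdioecious resident population the
#'   criterion becomes `g > 1 - s + s (1 - d) / P_X0`, where `P_X0` is the
#'   fraction of X-bearing pollen at the androdioecious equilibrium. Males act
#'   as a CMS sink (they are sired by Y pollen but never transmit the
#'   cytotype), so `P_X0 < 1` makes invasion harder. With no males
#'   (`P_X0 = 1`) the criterion reduces to `1 - s d`.
#' * [cms_fixation_g()]: with males present and no pollen limitation
#'   (model 1), CMS fixes — the population becomes dioecious — iff
#'   `g >= 1 + s - 2 s d`, the invasion criterion evaluated at the dioecious
#'   limit `P_X0 = 0.5`. The gap between the androdioecious invasion
#'   threshold and this fixation threshold is the band in which trioecy is
#'   maintained by negative frequency-dependent selection.
#'
#' @param s Prior selfing rate in `[0, 1]`.
#' @param d Inbreeding depression in `[0, 1]`.
#' @param alpha Relative male pollen production.
#' @return A single numeric threshold. `male_invasion_alpha()` returns `Inf`
#'   at `s = 1`.
#' @examples
#' male_invasion_alpha(0, 0.1)        # 2: twice the siring success
#' cms_invasion_g_herm(0.4, 0.1)      # 0.96
#' cms_invasion_g_andro(0.4, 0.1, 5)  # > 0.96: males hinder CMS invasion
#' cms_fixation_g(0.4, 0.1)           # 1.32
#' @seealso [androdioecy_equilibrium()], [trioecy_upper_g()],
#'   [bisect_threshold()] for the simulation-based counterpart.
#' @export
male_invasion_alpha <- function(s, d) {
  if (s >= 1) return(Inf)
  2 * (1 - s * d) / (1 - s)
}

#' @rdname male_invasion_alpha
#' @export
cms_invasion_g_herm <- function(s, d) 1 - s * d

#' @rdname male_invasion_alpha
#' @export
cms_invasion_g_andro <- function(s, d, alpha) {
  P_X0 <- androdioecy_equilibrium(s, d, alpha)$P_X0
  1 - s + s * (1 - d) / P_X0
}

#' @rdname male_invasion_alpha
#' @export
cms_fixation_g <- function(s, d) 1 + s - 2 * s * d

#' Androdioecious equilibrium before CMS arrives
#'
#' The stable male/hermaphrodite equilibrium of the CMS-free system. The
#' equilibrium male frequency is
#' \deqn{f^0_{XY,n} = \frac{\alpha (1 - s) - 2 (1 - s d)}
#'                         {2 (\alpha - 1)(1 - s d)},}
#' clipped to `[0, 0.5)`: it is 0 whenever `alpha` does not exceed
#' [male_invasion_alpha()]. The fraction of X-bearing pollen at that
#' equilibrium is the pollen-weighted
#' \deqn{P^0_X = \frac{f^0_{XX,n} + 0.5\,\alpha f^0_{XY,n}}
#'                    {f^0_{XX,n} + \alpha f^0_{XY,n}},}
#' which lies in `[0.5, 1]` (half of male pollen carries Y).
#'
#' @inheritParams male_invasion_alpha
#' @return A list of class `androdioecy_equilibrium` with fields `f0_XYn`
#'   and `P_X0`.
#' @examples
#' androdioecy_equilibrium(0, 0, 4)  # f0 = 1/3, P_X0 = 2/3
#' @export
androdioecy_equilibrium <- function(s, d, alpha) {
  thr <- male_invasion_alpha(s, d)
  if (alpha <= 1 || alpha <= thr) {
    f0 <- 0
  } else {
    f0 <- (alpha * (1 - s) - 2 * (1 - s * d)) / (2 * (alpha - 1) * (1 - s * d))
    f0 <- min(max(f0, 0), 0.5 - .Machine$double.eps)
  }
  h0 <- 1 - f0
  P_X0 <- if (f0 > 0) (h0 + 0.5 * alpha * f0) / (h0 + alpha * f0) else 1
  structure(list(f0_XYn = f0, P_X0 = P_X0), class = "androdioecy_equilibrium")
}

#' @export
print.androdioecy_equilibrium <- function(x, ...) {
  cat(sprintf("Androdioecious equilibrium: male frequency %.6g, P_X0 %.6g\n",
              x$f0_XYn, x$P_X0))
  invisible(x)
}

#' Pollen-limited bound on CMS fixation (trioecy upper boundary)
#'
#' Under pollen limitation the fixation of CMS is blocked — and trioecy can
#' persist — when female seed production lies below a bound that depends on
#' how much pollen a CMS-male population can still produce:
#' `g < 1 - s + 4 s (1 - d) / (alpha (1 - e_m))` when unfertilized ovules
#' abort (model 2), and
#' `g < (1 - s)(2 d - 1) + 4 (1 - d) / (alpha (1 - e_m))` when hermaphrodites
#' recover them by delayed selfing (model 3, a broader band). The bounds only
#' bite when a dioecious population would actually be pollen-limited, i.e.
#' when its mean per-capita pollen production `alpha (1 - e_m) / 2` is below
#' `P_h` (here 1); otherwise the attribute `applicable` is `FALSE` and the
#' model-1 fixation criterion alone decides. At `e_m = 1` the bound is
#' infinite: fully sterile CMS males leave a "dioecious" end state without
#' pollen, so CMS can never fix.
#'
#' @inheritParams male_invasion_alpha
#' @param e_m Fraction of a CMS male's pollen aborted.
#' @param model Pollen-limitation variant, 2 or 3 (model 1 has no such
#'   bound and is an error).
#' @return The numeric bound (possibly `Inf`), with logical attribute
#'   `applicable`.
#' @examples
#' trioecy_upper_g(0.4, 0.1, 5, 0.8, model = 2)  # 2.04
#' trioecy_upper_g(0.4, 0.1, 5, 0.8, model = 3)  # 3.12
#' @export
trioecy_upper_g <- function(s, d, alpha, e_m, model) {
  if (model == 1)
    stop("no pollen-limitation bound in model 1", call. = FALSE)
  if (!model %in% c(2, 3)) stop("'model' must be 2 or 3", call. = FALSE)
  if (e_m >= 1) {
    bound <- Inf
    applicable <- TRUE
  } else {
    bound <- if (model == 2) {
      1 - s + 4 * s * (1 - d) / (alpha * (1 - e_m))
    } else {
      (1 - s) * (2 * d - 1) + 4 * (1 - d) / (alpha * (1 - e_m))
    }
    applicable <- alpha * (1 - e_m) / 2 < 1
  }
  structure(bound, applicable = applicable)
}

#' All applicable thresholds for a parameter set
#'
#' Evaluate every closed-form threshold at the given parameters, for the
#' `threshold` CLI subcommand and for overlaying threshold curves on phase
#' tables.
#'
#' @param params A [cms_params()] object.
#' @return A data frame with columns `quantity`, `value`, `applicable`.
#' @export
threshold_report <- function(params) {
  rows <- list(
    c("male_invasion_alpha", male_invasion_alpha(params$s, params$d), TRUE),
    c("cms_invasion_g_herm", cms_invasion_g_herm(params$s, params$d), TRUE),
    c("cms_invasion_g_andro",
      cms_invasion_g_andro(params$s, params$d, params$alpha), TRUE),
    c("cms_fixation_g", cms_fixation_g(params$s, params$d), TRUE),
    c("androdioecy_male_freq",
      androdioecy_equilibrium(params$s, params$d, params$alpha)$f0_XYn, TRUE),
    c("P_X0",
      androdioecy_equilibrium(params$s, params$d, params$alpha)$P_X0, TRUE))
  if (params$model %in% c(2, 3)) {
    b <- trioecy_upper_g(params$s, params$d, params$alpha, params$e_m,
                         params$model)
    rows <- c(rows, list(c("trioecy_upper_g", as.numeric(b),
                           attr(b, "applicable"))))
  }
  data.frame(quantity = vapply(rows, `[[`, "", 1),
             value = as.numeric(vapply(rows, `[[`, "", 2)),
             applicable = as.logical(vapply(rows, `[[`, "", 3)))
}
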
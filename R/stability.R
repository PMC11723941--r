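#' Numerical Jacobian of the one-generation map at a fixed point
#'
#' Central finite differences of the normalized map with respect to each
#' genotype frequency. Each probe `state +/- h * e_j` is renormalized onto
#' the simplex before stepping, and the unclamped analytic form of the map is
#' used so the derivative is well defined at boundary equilibria where some
#' frequencies are exactly zero.
#'
#' The input must actually be a fixed point: the one-step residual is
#' checked against 1e-9 and a violation is an error (use
#' [boundary_equilibrium()] or [iterate_to_equilibrium()] with a tight
#' tolerance to obtain one).
#'
#' @param state A fixed point of the map for `params`.
#' @param params A [cms_params()] object.
#' @param h Finite-difference step.
#' @return A 4x4 matrix of partial derivatives, rows and columns in genotype
#'   order `XXn, XYn, XXc, XYc`.
#' @examples
#' p <- cms_params(g = 1.2, s = 0.4, d = 0.1)
#' J <- jacobian_at(pure_hermaphrodites(), p)
#' J["XXc", "XXc"]  # growth factor of rare CMS: g / (1 - s d)
#' @export
jacobian_at <- function(state, params, h = 1e-7) {
  f <- as.numeric(state)
  map <- function(x) step_raw(x / sum(x), params)
  residual <- max(abs(map(f) - f))
  if (residual > 1e-9)
    stop("state is not a fixed point of the map (one-step residual ",
         format(residual, digits = 3), " > 1e-9)", call. = FALSE)
  J <- matrix(0, 4, 4, dimnames = list(GENOTYPES, GENOTYPES))
  for (j in 1:4) {
    up <- dn <- f
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    J[, j] <- (map(up) - map(dn)) / (2 * h)
  }
  J
}

#' Leading-eigenvalue invasion verdict at a boundary equilibrium
#'
#' Local stability analysis of a boundary equilibrium against a set of
#' invading genotypes. The Jacobian of the map is evaluated at the
#' equilibrium and restricted to the block of the invading genotypes (which
#' must be absent from the equilibrium); the rare types then grow or decay
#' geometrically at the rate of the block's spectral radius. The verdict is
#' `can_invade` when the leading modulus exceeds `1 + tol_margin`,
#' `cannot_invade` below `1 - tol_margin`, and `marginal` in between
#' (finite-difference noise makes verdicts within the margin unreliable).
#'
#' To test whether CMS *fixation* is stable, invert the roles: at the
#' dioecious (CMS-fixed) equilibrium, take the non-CMS genotypes
#' `c("XXn", "XYn")` as the invaders; `cannot_invade` then means CMS stays
#' fixed.
#'
#' @param equilibrium A fixed point excluding the invading genotypes
#'   (their frequencies must be below 1e-9).
#' @param params A [cms_params()] object.
#' @param invading Character vector of genotype names, a non-empty subset of
#'   `XXn, XYn, XXc, XYc`.
#' @param h Finite-difference step for [jacobian_at()].
#' @param tol_margin Half-width of the `marginal` band around 1.
#' @return An object of class `stability_report`: a list with fields
#'   `equilibrium`, `jacobian`, `leading_modulus`, `verdict` and `invading`.
#' @examples
#' p <- cms_params(alpha = 3, s = 0, d = 0)   # above the threshold alpha = 2
#' invasion_verdict(pure_hermaphrodites(), p, "XYn")$verdict  # can_invade
#' @export
invasion_verdict <- function(equilibrium, params, invading, h = 1e-7,
                             tol_margin = 1e-3) {
  invading <- match.arg(invading, GENOTYPES, several.ok = TRUE)
  if (length(invading) == 0) stop("'invading' must be non-empty", call. = FALSE)
  if (any(as.numeric(equilibrium)[match(invading, GENOTYPES)] > 1e-9))
    stop("equilibrium must exclude the invading genotypes", call. = FALSE)
  J <- jacobian_at(equilibrium, params, h = h)
  block <- J[invading, invading, drop = FALSE]
  lead <- max(Mod(eigen(block, only.values = TRUE)$values))
  verdict <- if (lead > 1 + tol_margin) "can_invade"
             else if (lead < 1 - tol_margin) "cannot_invade"
             else "marginal"
  structure(list(equilibrium = equilibrium, jacobian = J,
                 leading_modulus = lead, verdict = verdict,
                 invading = invading),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, digits = 6, ...) {
  cat("Stability report: invading {", paste(x$invading, collapse = ", "),
      "}\n", sep = "")
  cat("Jacobian:\n")
  print(round(x$jacobian, digits))
  cat(sprintf("Leading modulus of invading block: %.6g -> %s\n",
              x$leading_modulus, x$verdict))
  invisible(x)
}

#' Named boundary equilibria
#'
#' Construct the boundary fixed points at which invasion is analysed:
#' `"hermaphrodite"` is the pure-hermaphrodite point `(1, 0, 0, 0)`;
#' `"dioecy"` is the CMS-fixed point `(0, 0, 0.5, 0.5)` (an exact fixed
#' point whenever CMS males retain some pollen, `e_m < 1`); `"androdioecy"`
#' and `"gynodioecy"` are obtained by simulating the corresponding
#' single-invader dynamics to a tight tolerance.
#'
#' @param params A [cms_params()] object.
#' @param boundary One of `"hermaphrodite"`, `"androdioecy"`,
#'   `"gynodioecy"`, `"dioecy"`.
#' @param ... Passed to [iterate_to_equilibrium()] for the simulated
#'   boundaries.
#' @return A [population_state()].
#' @export
boundary_equilibrium <- function(params,
                                 boundary = c("hermaphrodite", "androdioecy",
                                              "gynodioecy", "dioecy"), ...) {
  boundary <- match.arg(boundary)
  switch(boundary,
    hermaphrodite = pure_hermaphrodites(),
    dioecy = population_state(0, 0, 0.5, 0.5),
    androdioecy = iterate_to_equilibrium(
      introduce(pure_hermaphrodites(), "XYn", 1e-3), params,
      tol = 1e-14, ...)$state,
    gynodioecy = iterate_to_equilibrium(
      introduce(pure_hermaphrodites(), "XXc", 1e-3), params,
      tol = 1e-14, ...)$state)
}
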
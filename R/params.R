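#' Model parameters
#'
#' Bundle the parameters of the CMS trioecy model: the fecundities of the
#' unisexual phenotypes relative to hermaphrodites, the mating-system
#' parameters, and the choice of pollen-limitation variant.
#'
#' The phenotypes are determined jointly by an XY sex-determination locus and
#' a maternally transmitted cytotype (n = normal, c = CMS). `XX,n` individuals
#' are hermaphrodites producing `G_h` ovules and `P_h` pollen grains; `XY,n`
#' are males producing `alpha * P_h` pollen; `XX,c` are females (CMS
#' hermaphrodites) producing `g * G_h` ovules and no pollen; `XY,c` are males
#' whose pollen production is partially restored by the Y-linked restorer,
#' producing `(1 - e_m) * alpha * P_h` pollen.
#'
#' Three mating-system variants are supported:
#' * `model = 1`: no pollen limitation; all non-prior-selfed ovules are
#'   outcrossed.
#' * `model = 2`: the probability that a non-prior-selfed ovule is outcrossed
#'   is `min(1, P / P_h)` where `P` is mean per-capita pollen production;
#'   unfertilized ovules abort.
#' * `model = 3`: as model 2, but hermaphrodites fertilize their unoutcrossed
#'   ovules by delayed selfing; females' unfertilized ovules still abort.
#'
#' @param g Seed production of a female relative to a hermaphrodite
#'   (`g >= 0`).
#' @param alpha Pollen production of a male relative to a hermaphrodite.
#'   Values below 1 are permitted (with a warning) but contradict the
#'   sex-allocation trade-off the model assumes.
#' @param s Prior selfing rate of hermaphrodites, in `[0, 1]`.
#' @param d Inbreeding depression: fraction of self-fertilized zygotes
#'   (prior or delayed) that die, in `[0, 1]`.
#' @param e_m Fraction of a CMS male's pollen aborted, in `[0, 1]`
#'   (0 = full restoration, 1 = CMS males fully sterile).
#' @param G_h,P_h Absolute ovule and pollen production of a hermaphrodite.
#'   The recursions depend only on ratios, so the defaults of 1 set the
#'   natural scale; both must be positive.
#' @param model Pollen-limitation variant, one of 1, 2, 3.
#'
#' @return An object of class `cms_params`: a named list of the validated
#'   parameters.
#' @examples
#' p <- cms_params(g = 1.1, alpha = 5, s = 0.4, d = 0.1, e_m = 0.8)
#' p
#' @export
cms_params <- function(g = 1, alpha = 1, s = 0, d = 0, e_m = 0,
                       G_h = 1, P_h = 1, model = 1) {
  for (nm in c("g", "alpha", "s", "d", "e_m", "G_h", "P_h", "model")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (g < 0) stop("'g' must be >= 0", call. = FALSE)
  if (alpha < 1) warning("'alpha' < 1 contradicts the male sex-allocation trade-off")
  for (nm in c("s", "d", "e_m")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (G_h <= 0 || P_h <= 0) stop("'G_h' and 'P_h' must be positive", call. = FALSE)
  if (!model %in% c(1, 2, 3)) stop("'model' must be 1, 2 or 3", call. = FALSE)
  structure(
    list(g = as.numeric(g), alpha = as.numeric(alpha), s = as.numeric(s),
         d = as.numeric(d), e_m = as.numeric(e_m), G_h = as.numeric(G_h),
         P_h = as.numeric(P_h), model = as.integer(model)),
    class = "cms_params"
  )
}

#' @export
print.cms_params <- function(x, ...) {
  cat("CMS trioecy model parameters (model ", x$model, ")\n", sep = "")
  cat(sprintf("  g = %g  alpha = %g  s = %g  d = %g  e_m = %g\n",
              x$g, x$alpha, x$s, x$d, x$e_m))
  if (x$G_h != 1 || x$P_h != 1)
    cat(sprintf("  G_h = %g  P_h = %g\n", x$G_h, x$P_h))
  invisible(x)
}

# parameter vector handed to the compiled core, in its fixed order
params_vector <- function(params) {
  c(params$g, params$alpha, params$s, params$d, params$e_m,
    params$G_h, params$P_h, params$model)
}
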
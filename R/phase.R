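#' Phase sweep over a (g, alpha) grid
#'
#' Classify the sexual system at equilibrium over a grid of relative female
#' seed production `g` and relative male pollen production `alpha`, at fixed
#' `(s, d, e_m, model)` and a fixed invasion order. Each cell runs a full
#' [run_scenario()]; the closed-form threshold curves are evaluated on the
#' same axes and attached for overlay.
#'
#' Cells that fail to converge within `max_gen` keep their provisional label
#' and are flagged `converged = FALSE`; the sweep continues.
#'
#' @param params Baseline [cms_params()]; `g` and `alpha` are overwritten
#'   per cell.
#' @param g_values,alpha_values Grid axes. The default ranges bracket the
#'   invasion and fixation thresholds for moderate selfing rates.
#' @param order Invasion order, as in [run_scenario()].
#' @param max_gen Generation cap per stage of each cell's scenario.
#' @param ... Further arguments to [run_scenario()].
#' @return A data frame of class `phase_table` with one row per cell:
#'   `g`, `alpha`, `label`, `f_XXn`, `f_XYn`, `f_XXc`, `f_XYc`, `converged`.
#'   Attributes: `params`, `order`, and `threshold_curves` (a data frame
#'   with, per `alpha`, the applicable threshold values of `g` plus the
#'   constant male-invasion threshold on `alpha`).
#' @examples
#' \donttest{
#' p <- cms_params(s = 0.4, d = 0.1, e_m = 0.8, model = 1)
#' tab <- sweep_phase(p, g_values = seq(0.9, 1.6, length.out = 8),
#'                    alpha_values = seq(1, 8, length.out = 8))
#' table(tab$label)
#' }
#' @export
sweep_phase <- function(params,
                        g_values = seq(0.8, 2.5, length.out = 50),
                        alpha_values = seq(1, 10, length.out = 50),
                        order = "males_first", max_gen = 5e5, ...) {
  if (length(g_values) > 500 || length(alpha_values) > 500)
    stop("grid resolution is capped at 500 x 500", call. = FALSE)
  if (any(g_values < 0) || any(alpha_values <= 0))
    stop("grid bounds must be positive", call. = FALSE)
  grid <- expand.grid(g = g_values, alpha = alpha_values,
                      KEEP.OUT.ATTRS = FALSE)
  run_cell <- function(g, alpha) {
    p <- params; p$g <- g; p$alpha <- alpha
    sc <- run_scenario(p, order = order, max_gen = max_gen, ...)
    st <- sc$final$state
    list(label = as.character(sc$classification),
         f = as.numeric(st),
         converged = sc$final$converged || sc$final$extinct)
  }
  cells <- Map(run_cell, grid$g, grid$alpha)
  fmat <- do.call(rbind, lapply(cells, `[[`, "f"))
  out <- data.frame(
    g = grid$g, alpha = grid$alpha,
    label = vapply(cells, `[[`, "", "label"),
    f_XXn = fmat[, 1], f_XYn = fmat[, 2], f_XXc = fmat[, 3],
    f_XYc = fmat[, 4],
    converged = vapply(cells, `[[`, NA, "converged"))
  attr(out, "params") <- params
  attr(out, "order") <- order
  attr(out, "threshold_curves") <- threshold_curves(params, alpha_values)
  class(out) <- c("phase_table", class(out))
  out
}

# threshold curves on the sweep axes, for overlay
threshold_curves <- function(params, alpha_values) {
  s <- params$s; d <- params$d
  curves <- data.frame(
    alpha = alpha_values,
    alpha_male_invasion = male_invasion_alpha(s, d),
    g_cms_invasion_herm = cms_invasion_g_herm(s, d),
    g_cms_invasion_andro = vapply(alpha_values, cms_invasion_g_andro,
                                  0, s = s, d = d),
    g_cms_fixation = cms_fixation_g(s, d))
  if (params$model %in% c(2, 3)) {
    curves$g_trioecy_upper <- vapply(alpha_values, function(a) {
      b <- trioecy_upper_g(s, d, a, params$e_m, params$model)
      if (attr(b, "applicable")) as.numeric(b) else NA_real_
    }, 0)
  }
  curves
}

#' Write and read phase tables and sweep configurations
#'
#' `write_phase_table()` writes one CSV row per grid cell (columns `g`,
#' `alpha`, `label`, the four genotype frequencies, `converged`); an empty
#' table yields a header-only file. `load_config()` reads a flat YAML (or
#' JSON, a YAML subset) configuration with any of the keys `g`, `alpha`,
#' `s`, `d`, `e_m`, `G_h`, `P_h`, `model`, `order`, `grid`; unknown keys are
#' an error. `grid` is either a mapping with `g_min/g_max/g_n` and
#' `alpha_min/alpha_max/alpha_n` or a compact string
#' `"gmin:gmax:n,amin:amax:n"`.
#'
#' @param table A `phase_table` from [sweep_phase()].
#' @param path File path.
#' @return `write_phase_table()` returns `path` invisibly; `load_config()`
#'   returns a list with elements `params` (a [cms_params()]), `order`, and
#'   `g_values`/`alpha_values` (or `NULL` when no grid is given).
#' @export
write_phase_table <- function(table, path) {
  cols <- c("g", "alpha", "label", "f_XXn", "f_XYn", "f_XXc", "f_XYc",
            "converged")
  df <- as.data.frame(table)[, cols, drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phase_table
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  par_keys <- c("g", "alpha", "s", "d", "e_m", "G_h", "P_h", "model")
  known <- c(par_keys, "order", "grid")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(cms_params, cfg[intersect(names(cfg), par_keys)])
  order <- if (is.null(cfg$order)) "males_first" else
    match.arg(gsub("-", "_", cfg$order),
              c("males_first", "females_first", "none"))
  g_values <- alpha_values <- NULL
  if (!is.null(cfg$grid)) {
    gr <- parse_grid(cfg$grid)
    g_values <- gr$g_values
    alpha_values <- gr$alpha_values
  }
  list(params = params, order = order, g_values = g_values,
       alpha_values = alpha_values)
}

parse_grid <- function(grid) {
  if (is.character(grid)) {
    parts <- strsplit(strsplit(grid, ",")[[1]], ":")
    if (length(parts) != 2 || any(lengths(parts) != 3))
      stop("grid string must be 'gmin:gmax:n,amin:amax:n'", call. = FALSE)
    g <- as.numeric(parts[[1]]); a <- as.numeric(parts[[2]])
    list(g_values = seq(g[1], g[2], length.out = g[3]),
         alpha_values = seq(a[1], a[2], length.out = a[3]))
  } else {
    need <- c("g_min", "g_max", "g_n", "alpha_min", "alpha_max", "alpha_n")
    missing <- setdiff(need, names(grid))
    if (length(missing) > 0)
      stop("grid mapping lacks keys: ", paste(missing, collapse = ", "),
           call. = FALSE)
    list(g_values = seq(grid$g_min, grid$g_max, length.out = grid$g_n),
         alpha_values = seq(grid$alpha_min, grid$alpha_max,
                            length.out = grid$alpha_n))
  }
}

#' Plot a phase table
#'
#' Colored raster of sexual-system labels over the (alpha, g) plane with the
#' closed-form threshold curves overlaid. Requires ggplot2; the CSV written
#' by [write_phase_table()] is the canonical output, plots are convenience.
#'
#' @param x A `phase_table`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot.phase_table <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
  curves <- attr(x, "threshold_curves")
  pal <- c(hermaphroditism = "#999999", androdioecy = "#56B4E9",
           gynodioecy = "#E69F00", trioecy = "#009E73",
           dioecy = "#CC79A7", extinction = "#000000")
  gg <- ggplot2::ggplot(as.data.frame(x),
                        ggplot2::aes(x = alpha, y = g)) +
    ggplot2::geom_tile(ggplot2::aes(fill = label)) +
    ggplot2::scale_fill_manual(values = pal, name = "sexual system") +
    ggplot2::geom_vline(xintercept = curves$alpha_male_invasion[1],
                        linetype = 2) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = g_cms_invasion_andro),
                       color = "red") +
    ggplot2::geom_hline(yintercept = curves$g_cms_fixation[1],
                        color = "darkgreen") +
    ggplot2::labs(x = expression(alpha), y = "g")
  if (!is.null(curves$g_trioecy_upper))
    gg <- gg + ggplot2::geom_line(data = curves,
                                  ggplot2::aes(y = g_trioecy_upper),
                                  color = "darkgreen", linetype = 3,
                                  na.rm = TRUE)
  gg
}
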
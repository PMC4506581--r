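#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_colour_viridis_c theme_minimal geom_raster geom_path
#'   scale_fill_gradient coord_equal geom_errorbar
#' @importFrom rlang .data
#' @export
ggplot2::autoplot

#' Plot density profiles from the Fisher-Kolmogorov solver
#'
#' @param object An `fk_profiles` tibble from [solve_fk()].
#' @param ... Unused.
#' @return A ggplot: density versus position, coloured by time.
#' @method autoplot fk_profiles
#' @export
autoplot.fk_profiles <- function(object, ...) {
  ggplot(object, aes(x = .data$x_um, y = .data$density,
                     colour = .data$t_h, group = .data$t_h)) +
    geom_line() +
    scale_colour_viridis_c(name = "t (h)") +
    labs(x = "x (μm)", y = expression(C(x, t) ~ "(cells/" * mu * m^2 * ")"),
         title = "Cell density profiles") +
    theme_minimal()
}

#' Plot a leading-edge half-width series
#'
#' @param series Tibble with `t_h`, `le_um` and optionally
#'   `replicate_id`.
#' @param model Optional model series (same columns) drawn as a line.
#' @return A ggplot of half-width versus time.
#' @export
plot_leading_edge <- function(series, model = NULL) {
  stopifnot(all(c("t_h", "le_um") %in% names(series)))
  grp <- if ("replicate_id" %in% names(series))
    factor(series$replicate_id) else factor(1)
  p <- ggplot(series, aes(x = .data$t_h, y = .data$le_um)) +
    geom_point(aes(colour = grp)) +
    labs(x = "t (h)", y = expression(L[E](t) ~ "(" * mu * m * ")"),
         colour = "replicate",
         title = "Scratch half-width") +
    theme_minimal()
  if (!is.null(model))
    p <- p + geom_line(data = model, aes(x = .data$t_h, y = .data$le_um),
                       linewidth = 0.8)
  p
}

#' Display an assay frame with the detected wound boundary
#'
#' @param image An [assay_image()].
#' @param region Optional `vacant_region` from [detect_vacant_region()]
#'   whose boundary polyline is overlaid.
#' @param downsample Integer pixel stride used when rasterising (keeps
#'   the plot light).
#' @return A ggplot raster of the frame.
#' @export
plot_frame <- function(image, region = NULL, downsample = 4L) {
  stopifnot(inherits(image, "assay_image"))
  px <- image$pixels
  rows <- seq(1, nrow(px), by = downsample)
  cols <- seq(1, ncol(px), by = downsample)
  df <- expand.grid(y = rows, x = cols)
  df$value <- px[cbind(df$y, df$x)]
  df$x_um <- (df$x - 0.5) * image$pixel_size
  df$y_um <- (df$y - 0.5) * image$pixel_size
  p <- ggplot(df, aes(x = .data$x_um, y = .data$y_um,
                      fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", guide = "none") +
    coord_equal(expand = FALSE) +
    labs(x = "x (μm)", y = "y (μm)",
         title = sprintf("t = %g h", image$t)) +
    theme_minimal()
  if (!is.null(region) && nrow(region$edge_polyline) > 0)
    p <- p + geom_path(data = region$edge_polyline,
                       aes(x = .data$x_um, y = .data$y_um,
                           group = .data$component),
                       colour = "green", inherit.aes = FALSE)
  p
}

#' Plot a logistic growth fit against observed subregion densities
#'
#' @param counts Count tibble (as in [fit_lambda()]).
#' @param fit A `lambda_fit`.
#' @param a_sr Subregion area (um^2).
#' @return A ggplot of density versus time with the fitted curve.
#' @export
plot_growth_fit <- function(counts, fit, a_sr = 3.789e4) {
  stopifnot(inherits(fit, "lambda_fit"))
  counts <- check_counts(counts)
  obs <- dplyr::summarise(
    dplyr::group_by(counts, .data$t_h),
    density = mean(.data$n_cells) / a_sr, .groups = "drop")
  tt <- seq(0, max(obs$t_h), length.out = 200)
  curve <- tibble::tibble(
    t_h = tt, density = logistic_solution(fit$c0, fit$k, fit$lam_mean, tt))
  ggplot(obs, aes(x = .data$t_h, y = .data$density)) +
    geom_point(shape = 4, size = 2) +
    geom_line(data = curve) +
    labs(x = "t (h)", y = expression(C(t) ~ "(cells/" * mu * m^2 * ")"),
         title = sprintf("Logistic fit: lambda = %.3g /h", fit$lam_mean)) +
    theme_minimal()
}
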
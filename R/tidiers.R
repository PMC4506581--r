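#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a proliferation-rate fit
#'
#' @param x A `lambda_fit` from [fit_lambda()].
#' @param ... Unused.
#' @return A tibble with one row per replicate plus the pooled estimate
#'   identified by `replicate_id = NA`.
#' @method tidy lambda_fit
#' @export
tidy.lambda_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$replicates, term = "lambda", .before = 1),
    tibble::tibble(term = "lambda", replicate_id = NA,
                   lambda = x$lam_mean, sse = NA_real_,
                   n_times = NA_integer_))
}

#' @rdname tidy.lambda_fit
#' @method glance lambda_fit
#' @export
glance.lambda_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lam_mean, lambda_sd = x$lam_sd,
                 k = x$k, c0 = x$c0, n_replicates = nrow(x$replicates))
}

#' Tidy a diffusivity fit
#'
#' @param x A `diffusivity_fit` from [fit_D()].
#' @param ... Unused.
#' @return A tibble with one row per replicate and threshold fraction.
#' @method tidy diffusivity_fit
#' @export
tidy.diffusivity_fit <- function(x, ...) {
  dplyr::mutate(x$replicates, term = "D", .before = 1)
}

#' @rdname tidy.diffusivity_fit
#' @method glance diffusivity_fit
#' @export
glance.diffusivity_fit <- function(x, ...) {
  tibble::tibble(d = x$d_mean, d_sd = x$d_sd, d_low = x$d_low,
                 d_high = x$d_high, fraction = x$fraction)
}

#' Tidy a sequential condition summary
#'
#' @param x A `condition_summary` from [sequential_estimate()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`K`, `C0`, `lambda`,
#'   `D`, `t_d`) carrying the estimate and its spread (sd for the
#'   count-based parameters, the detection-threshold interval for `D`).
#' @method tidy condition_summary
#' @export
tidy.condition_summary <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    term = c("K", "C0", "lambda", "D", "t_d"),
    estimate = c(x$k$mean, x$c0$mean, x$lambda_fit$lam_mean,
                 x$d_fit$d_mean, x$t_d),
    spread_low = c(x$k$mean - x$k$sd, x$c0$mean - x$c0$sd,
                   x$lambda_fit$lam_mean - x$lambda_fit$lam_sd,
                   x$d_fit$d_low, NA),
    spread_high = c(x$k$mean + x$k$sd, x$c0$mean + x$c0$sd,
                    x$lambda_fit$lam_mean + x$lambda_fit$lam_sd,
                    x$d_fit$d_high, NA),
    unit = c("cells/um^2", "cells/um^2", "/h", "um^2/h", "h"))
}

#' @rdname tidy.condition_summary
#' @method glance condition_summary
#' @export
glance.condition_summary <- function(x, ...) {
  tibble::tibble(condition = x$condition, K = x$k$mean, C0 = x$c0$mean,
                 lambda = x$lambda_fit$lam_mean, D = x$d_fit$d_mean,
                 t_d = x$t_d)
}
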
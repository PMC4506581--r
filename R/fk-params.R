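#' Fisher-Kolmogorov model parameters
#'
#' Bundles the mechanistic triple of the Fisher-Kolmogorov (FKPP) model —
#' cell diffusivity `D`, proliferation rate `lambda` and carrying-capacity
#' density `K` — together with the initial monolayer density `C0`.
#'
#' @param D Cell diffusivity (um^2/h), `>= 0`.
#' @param lambda Low-density per-capita proliferation rate (/h), `>= 0`.
#'   Doubling time is `log(2)/lambda`.
#' @param K Carrying-capacity density (cells/um^2), `> 0`.
#' @param C0 Initial monolayer density (cells/um^2), in `[0, K]`.
#'
#' @return An object of class `fk_params` (named list).
#' @examples
#' fk_params(D = 132, lambda = 5.07e-2, K = 1.13e-3, C0 = 6.84e-4)
#' @export
fk_params <- function(D, lambda, K, C0) {
  stopifnot(is.numeric(D), length(D) == 1, is.finite(D),
            is.numeric(lambda), length(lambda) == 1, is.finite(lambda),
            is.numeric(K), length(K) == 1, is.finite(K),
            is.numeric(C0), length(C0) == 1, is.finite(C0))
  if (D < 0) stop("cell diffusivity `D` must be >= 0", call. = FALSE)
  if (lambda < 0) stop("proliferation rate `lambda` must be >= 0", call. = FALSE)
  if (K <= 0) stop("carrying capacity `K` must be > 0", call. = FALSE)
  if (C0 < 0 || C0 > K)
    stop("initial density `C0` must lie in [0, K]", call. = FALSE)
  structure(list(D = D, lambda = lambda, K = K, C0 = C0),
            class = "fk_params")
}

#' @export
print.fk_params <- function(x, ...) {
  cat("<fk_params>\n")
  cat(sprintf("  D      = %.4g um^2/h\n", x$D))
  cat(sprintf("  lambda = %.4g /h (doubling time %.3g h)\n",
              x$lambda, if (x$lambda > 0) log(2) / x$lambda else Inf))
  cat(sprintf("  K      = %.4g cells/um^2\n", x$K))
  cat(sprintf("  C0     = %.4g cells/um^2\n", x$C0))
  invisible(x)
}

#' Imaged-domain geometry
#'
#' Physical size of the imaged field of view and the position of the
#' scratch centre. Defaults correspond to a standard live-imaging
#' scratch-assay frame (1970 x 1430 um, vertical scratch centred at
#' x = 985 um).
#'
#' @param lx Horizontal width (um), `> 0`.
#' @param ly Vertical height (um), `> 0`.
#' @param x_centre Scratch centre (um), in `(0, lx)`.
#' @return An object of class `domain_geometry`.
#' @examples
#' domain_geometry()
#' @export
domain_geometry <- function(lx = 1970, ly = 1430, x_centre = lx / 2) {
  stopifnot(is.numeric(lx), length(lx) == 1, is.finite(lx),
            is.numeric(ly), length(ly) == 1, is.finite(ly),
            is.numeric(x_centre), length(x_centre) == 1, is.finite(x_centre))
  if (lx <= 0 || ly <= 0) stop("domain sides must be positive", call. = FALSE)
  if (x_centre <= 0 || x_centre >= lx)
    stop("scratch centre must lie strictly inside (0, lx)", call. = FALSE)
  structure(list(lx = lx, ly = ly, x_centre = x_centre),
            class = "domain_geometry")
}

#' Finite-difference solver settings
#'
#' Grid spacing, time step and Picard convergence control for the implicit
#' Fisher-Kolmogorov solver. The defaults (`dx` = 1 um, `dt` = 0.1 h,
#' `eps` = 1e-6) give grid-independent results over the parameter ranges
#' relevant to scratch assays.
#'
#' @param dx Spatial grid spacing (um), `> 0`.
#' @param dt Time step (h), `> 0`.
#' @param eps Absolute (max-norm) Picard convergence tolerance, `> 0`.
#' @param max_picard_iters Cap on Picard sweeps per time step (fail-fast).
#' @return An object of class `solver_config`.
#' @examples
#' solver_config()
#' @export
solver_config <- function(dx = 1, dt = 0.1, eps = 1e-6, max_picard_iters = 100L) {
  stopifnot(is.numeric(dx), dx > 0, is.numeric(dt), dt > 0,
            is.numeric(eps), eps > 0,
            is.numeric(max_picard_iters), max_picard_iters >= 1)
  structure(list(dx = dx, dt = dt, eps = eps,
                 max_picard_iters = as.integer(max_picard_iters)),
            class = "solver_config")
}
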
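#' Parameters of the single-cell clock oscillator
#'
#' Bundles the free parameters of the nondimensionalized clock model: the
#' activator concentration \code{A}, the degradation rates \code{d_M},
#' \code{d_P}, \code{d_R} of mRNA, cytoplasmic protein and nuclear repressor
#' (1/h), the light sensitivity \code{i} and the noise intensity \code{sigma}.
#' Production rates are fixed at 1 by the nondimensionalization.  When the
#' dissociation constant \code{K} is \code{NULL} (the default) the
#' protein-sequestration activation is evaluated in its K -> 0 piecewise
#' limit, which is indistinguishable from the full form for K <= 1e-4.
#'
#' @param A activator concentration (dimensionless, > 0).
#' @param d_M,d_P,d_R degradation rates (1/h, > 0).  \code{d_P} and \code{d_R}
#'   default to \code{d_M}, giving the equal-degradation parameterization used
#'   in the early fitting stages.
#' @param i light sensitivity (dimensionless, >= 0).
#' @param sigma noise intensity (dimensionless, >= 0).
#' @param K optional dissociation constant (>= 0); \code{NULL} selects the
#'   piecewise activation limit.
#' @return An object of class \code{clock_parameters}.
#' @examples
#' p <- clock_parameters(A = 1.5, d_M = 0.25, i = 0.3, sigma = 0.1)
#' p
#' @export
clock_parameters <- function(A, d_M, d_P = d_M, d_R = d_M, i = 0, sigma = 0,
                             K = NULL) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A))
  if (A <= 0) stop("activator concentration 'A' must be > 0")
  for (nm in c("d_M", "d_P", "d_R")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("degradation rate '", nm, "' must be a single positive number")
  }
  if (!is.numeric(i) || length(i) != 1L || !is.finite(i) || i < 0)
    stop("light sensitivity 'i' must be >= 0")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop("noise intensity 'sigma' must be >= 0")
  if (!is.null(K)) {
    if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K < 0)
      stop("dissociation constant 'K' must be >= 0 or NULL")
  }
  structure(list(A = A, d_M = d_M, d_P = d_P, d_R = d_R, i = i,
                 sigma = sigma, K = K),
            class = "clock_parameters")
}

#' @export
print.clock_parameters <- function(x, ...) {
  cat("Clock oscillator parameters\n")
  cat(sprintf("  A = %.4g, d_M = %.4g, d_P = %.4g, d_R = %.4g (1/h)\n",
              x$A, x$d_M, x$d_P, x$d_R))
  cat(sprintf("  light sensitivity i = %.4g, noise sigma = %.4g\n",
              x$i, x$sigma))
  cat(if (is.null(x$K)) "  activation: piecewise (K -> 0 limit)\n"
      else sprintf("  activation: sequestration, K = %.3g\n", x$K))
  invisible(x)
}

#' @export
as.double.clock_parameters <- function(x, ...) {
  c(A = x$A, d_M = x$d_M, d_P = x$d_P, d_R = x$d_R, i = x$i,
    sigma = x$sigma)
}

# Internal: parameter vector layout expected by the compiled integrators,
# with K < 0 as the piecewise-limit sentinel.
par_vec <- function(params) {
  c(params$A, params$d_M, params$d_P, params$d_R, params$i,
    if (is.null(params$K)) -1 else params$K)
}

#' Does a parameter set satisfy the equal-degradation constraint?
#'
#' The early fitting stages constrain all three degradation rates to a common
#' value \code{d}, which maximizes the chance of sustained oscillations.
#'
#' @param params a \code{\link{clock_parameters}} object.
#' @param tol relative tolerance for equality.
#' @return logical scalar.
#' @export
has_equal_degradation <- function(params, tol = 1e-10) {
  d <- c(params$d_M, params$d_P, params$d_R)
  diff(range(d)) <= tol * max(d)
}
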
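#' Protein-sequestration transcriptional activation
#'
#' Fraction of free activator when a repressor binds the activator with 1:1
#' stoichiometry and dissociation constant \code{K}:
#' \deqn{f(R, A, K) = \frac{A - R - K + \sqrt{(A - R - K)^2 + 4AK}}{2A}.}
#' The function is continuous in all arguments and lies in (0, 1] for
#' \code{R >= 0}, \code{K > 0}.  As \code{K -> 0} it converges pointwise to
#' \code{\link{piecewise_activation}}.
#'
#' @param R repressor level (any real; vectorized).
#' @param A activator concentration (> 0).
#' @param K dissociation constant (>= 0).
#' @return activation fraction(s), same length as \code{R}.
#' @seealso \code{\link{piecewise_activation}}
#' @export
sequestration_activation <- function(R, A, K) {
  if (!is.numeric(A) || length(A) != 1L || A <= 0)
    stop("activator concentration 'A' must be > 0")
  if (!is.numeric(K) || any(K < 0)) stop("'K' must be >= 0")
  q <- A - R - K
  (q + sqrt(q^2 + 4 * A * K)) / (2 * A)
}

#' Piecewise activation limit (K -> 0)
#'
#' The K -> 0 limit of \code{\link{sequestration_activation}}:
#' \code{1 - R/A} for \code{R/A <= 1} and 0 otherwise.  The model is run in
#' this limit throughout fitting, since for K <= 1e-4 the full form is
#' numerically indistinguishable from it.
#'
#' @inheritParams sequestration_activation
#' @return activation fraction(s).
#' @export
piecewise_activation <- function(R, A) {
  if (!is.numeric(A) || length(A) != 1L || A <= 0)
    stop("activator concentration 'A' must be > 0")
  r <- R / A
  ifelse(r <= 1, 1 - r, 0)
}

#' Deterministic drift of the clock model
#'
#' Right-hand side of the oscillator without the noise terms:
#' \code{dM/dt = f(R, A) - d_M M + i I}, \code{dP/dt = M - d_P P},
#' \code{dR/dt = P - d_R R}, where \code{I} is the binary light level.
#'
#' @param state numeric length-3 vector \code{c(M, P, R)}.
#' @param params a \code{\link{clock_parameters}} object.
#' @param light light level, 0 (dark) or 1 (light).
#' @return named numeric vector of rates \code{c(dM, dP, dR)}.
#' @export
clock_drift <- function(state, params, light = 0) {
  stopifnot(inherits(params, "clock_parameters"),
            is.numeric(state), length(state) == 3L)
  if (!light %in% c(0, 1)) stop("'light' must be 0 or 1")
  M <- state[[1]]; P <- state[[2]]; R <- state[[3]]
  f <- if (is.null(params$K)) piecewise_activation(R, params$A)
       else sequestration_activation(R, params$A, params$K)
  c(dM = f - params$d_M * M + params$i * light,
    dP = M - params$d_P * P,
    dR = P - params$d_R * R)
}
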
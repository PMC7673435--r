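#' Dimensionless model parameters
#'
#' Constructs and validates the dimensionless parameter triple governing the
#' activity--stiffness system: the activity threshold `q` at which the cell
#' switches from matrix production to enzymatic digestion, the digestion rate
#' `D`, and the baseline production rate `P`.
#'
#' `q` must lie strictly in (0, 1) because activity is a saturating variable
#' bounded by 1. `P = 0` is admitted only for the degenerate closed-form
#' special case (the fixed point then loses its dependence on `D`); the full
#' model requires `P > 0`.
#'
#' @param q Dimensionless activity threshold, in (0, 1).
#' @param D Dimensionless digestion rate, > 0.
#' @param P Dimensionless production rate, >= 0 (0 only for the degenerate
#'   special case).
#' @return An object of class `selfheal_params`: a named list with elements
#'   `q`, `D`, `P`.
#' @examples
#' model_params()                     # baseline q = 0.2, D = 0.32, P = 0.1
#' model_params(q = 0.4, D = 0.08, P = 0.08 * 8 / 15)
#' @export
model_params <- function(q = 0.2, D = 0.32, P = 0.1) {
  stopifnot(is.numeric(q), length(q) == 1L, is.finite(q),
            is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(P), length(P) == 1L, is.finite(P))
  if (q <= 0 || q >= 1) {
    stop("`q` must lie strictly in (0, 1); got ", q, call. = FALSE)
  }
  if (D <= 0) stop("`D` must be > 0; got ", D, call. = FALSE)
  if (P < 0) stop("`P` must be >= 0; got ", P, call. = FALSE)
  structure(list(q = q, D = D, P = P), class = "selfheal_params")
}

#' @export
print.selfheal_params <- function(x, ...) {
  cat("<selfheal_params> q =", format(x$q), " D =", format(x$D),
      " P =", format(x$P), "\n")
  invisible(x)
}

#' Dimensional model parameters
#'
#' The dimensional form of the model carries an activity relaxation rate
#' `alpha` (1/time), an activity saturation level `A`, the stiffness `Q` at
#' which activation is half-maximal, an activity threshold `q_prime`, a
#' digestion coefficient `D_prime` (1/(activity x time)) and a production rate
#' `P_prime` (stiffness/time). All must be positive, and `q_prime < A` so that
#' the dimensionless threshold stays below 1.
#'
#' @param alpha Activity relaxation rate (1/time).
#' @param A Activity saturation level.
#' @param Q Stiffness at half-maximal activation.
#' @param q_prime Activity threshold (activity units), must be `< A`.
#' @param D_prime Digestion coefficient (1/(activity x time)).
#' @param P_prime Production rate (stiffness/time).
#' @return An object of class `selfheal_dim_params`.
#' @seealso [nondimensionalize()]
#' @export
dimensional_params <- function(alpha = 1, A = 1, Q = 1,
                               q_prime = 0.2, D_prime = 0.32, P_prime = 0.1) {
  vals <- c(alpha = alpha, A = A, Q = Q, q_prime = q_prime,
            D_prime = D_prime, P_prime = P_prime)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all dimensional parameters must be finite and > 0", call. = FALSE)
  }
  if (q_prime >= A) {
    stop("`q_prime` must be < `A` (dimensionless threshold q = q'/A < 1)",
         call. = FALSE)
  }
  structure(as.list(vals), class = "selfheal_dim_params")
}

#' Reduce dimensional parameters to the dimensionless triple
#'
#' Applies the nondimensionalization t = alpha * t', a = a'/A, k = k'/Q,
#' under which the six dimensional parameters collapse to three:
#' `q = q'/A`, `D = A * D'/alpha`, `P = P'/(alpha * Q)`.
#'
#' @param dp A [dimensional_params()] object.
#' @return A [model_params()] object.
#' @examples
#' nondimensionalize(dimensional_params())  # unit alpha, A, Q: q=0.2, D=0.32, P=0.1
#' @export
nondimensionalize <- function(dp) {
  stopifnot(inherits(dp, "selfheal_dim_params"))
  model_params(q = dp$q_prime / dp$A,
               D = dp$A * dp$D_prime / dp$alpha,
               P = dp$P_prime / (dp$alpha * dp$Q))
}

#' Production rate that pins the stiffness fixed point
#'
#' Solves the stationarity condition of the stiffness equation,
#' dk/dt = -D k (a - q) + P = 0, at a prescribed stiffness fixed point
#' `k_star` (with the activity nullcline a = k/(1+k) substituted), giving
#' `P = D * k_star * (k_star/(1+k_star) - q)`.
#'
#' This is how the aging parameterization is constructed: the digestion rate
#' is lowered while `P` is recomputed so the homeostatic set point is
#' unchanged.
#'
#' @param k_star Target dimensionless stiffness fixed point, > 0.
#' @param q Dimensionless activity threshold.
#' @param D Dimensionless digestion rate.
#' @return The production rate `P` (dimensionless).
#' @examples
#' production_for_fixed_point(k_star = 2, q = 2/5, D = 0.08)  # 8/15 * 0.08
#' @export
production_for_fixed_point <- function(k_star, q, D) {
  stopifnot(k_star > 0, D > 0, q > 0, q < 1)
  a_star <- k_star / (1 + k_star)
  if (a_star <= q) {
    stop("requested fixed point has a* <= q, which needs P <= 0", call. = FALSE)
  }
  D * k_star * (a_star - q)
}

#' Aging parameterization
#'
#' Parameter set representing aged tissue: the stiffness set point is raised
#' to k* = 2 (hence a* = 2/3 and threshold q = 2/5), and the digestion rate is
#' reduced to D = 0.08; stationarity then fixes P/D = 8/15, i.e. P ~= 0.0427.
#' Healing toward the (unchanged-in-stability) fixed point is much slower than
#' under the baseline parameters.
#'
#' @return A [model_params()] object with q = 2/5, D = 0.08, P = 0.08 * 8/15.
#' @examples
#' fixed_point(aging_params())  # k* = 2, a* = 2/3
#' @export
aging_params <- function() {
  D <- 0.08
  model_params(q = 2 / 5, D = D, P = production_for_fixed_point(2, 2 / 5, D))
}
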
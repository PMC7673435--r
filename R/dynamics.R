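#' Right-hand side of the activity--stiffness system
#'
#' Evaluates the two coupled rates at a state (a, k):
#' \deqn{da/dt = k/(1+k) - a}
#' \deqn{dk/dt = -D k (a - q) + P}
#' Activity relaxes toward a saturating function of local stiffness; stiffness
#' is digested when activity exceeds the threshold `q` and deposited at the
#' baseline rate `P`.
#'
#' @param a Dimensionless activity in \[0, 1\] (vectorized).
#' @param k Dimensionless stiffness >= 0 (vectorized, recycled with `a`).
#' @param params A [model_params()] object.
#' @return A list with numeric components `da` and `dk`.
#' @examples
#' p <- model_params()
#' fp <- fixed_point(p)
#' model_rhs(fp$a_star, fp$k_star, p)  # both zero
#' @export
model_rhs <- function(a, k, params) {
  stopifnot(inherits(params, "selfheal_params"))
  if (any(a < 0 | a > 1)) stop("`a` must lie in [0, 1]", call. = FALSE)
  if (any(k < 0)) stop("`k` must be >= 0", call. = FALSE)
  list(da = k / (1 + k) - a,
       dk = -params$D * k * (a - params$q) + params$P)
}

#' Exponential activity relaxation (constant-stiffness limit)
#'
#' In the limit where the cell does not alter its substrate, activity decays
#' exponentially toward a baseline `beta` with rate `alpha`:
#' a'(t') = beta + W exp(-alpha t'). Kept as a regression reference for the
#' constant-stiffness special case; the full model is not exponential.
#'
#' @param t_prime Dimensional time (vectorized).
#' @param beta Baseline activity approached as t' -> Inf.
#' @param W Amplitude set by the initial condition.
#' @param alpha Relaxation rate, > 0.
#' @return Activity a'(t').
#' @export
activity_relaxation <- function(t_prime, beta, W, alpha = 1) {
  stopifnot(alpha > 0)
  beta + W * exp(-alpha * t_prime)
}

#' Fixed point of the activity--stiffness system
#'
#' Substituting the activity nullcline a = k/(1+k) into the stiffness equation
#' yields a quadratic in k; the only physically admissible (positive) root is
#' \deqn{k^* = \frac{qD + P + \sqrt{(qD+P)^2 + 4D(1-q)P}}{2D(1-q)}}
#' with a* = k*/(1+k*). When `P` is exactly zero the system degenerates to the
#' closed form a* = q, k* = q/(1-q) (independent of `D`).
#'
#' @param params A [model_params()] object (requires q < 1).
#' @return An object of class `selfheal_fixed_point`: list with `a_star`,
#'   `k_star`, and the generating `params`.
#' @examples
#' fixed_point(model_params(0.2, 0.32, 0.1))  # a* = 0.50559, k* = 1.022612
#' @export
fixed_point <- function(params) {
  stopifnot(inherits(params, "selfheal_params"))
  q <- params$q; D <- params$D; P <- params$P
  if (P == 0) {
    k_star <- q / (1 - q)
  } else {
    b <- q * D + P
    k_star <- (b + sqrt(b^2 + 4 * D * (1 - q) * P)) / (2 * D * (1 - q))
  }
  structure(list(a_star = k_star / (1 + k_star), k_star = k_star,
                 params = params),
            class = "selfheal_fixed_point")
}

#' @export
print.selfheal_fixed_point <- function(x, ...) {
  cat("<selfheal_fixed_point> a* =", format(x$a_star, digits = 7),
      " k* =", format(x$k_star, digits = 7), "\n")
  invisible(x)
}

#' Jacobian of the activity--stiffness system
#'
#' @param a Dimensionless activity.
#' @param k Dimensionless stiffness.
#' @param params A [model_params()] object.
#' @return A 2x2 numeric matrix with rows (da/dt, dk/dt) and columns (a, k):
#'   `[[-1, 1/(1+k)^2], [-D k, -D (a - q)]]`.
#' @export
model_jacobian <- function(a, k, params) {
  stopifnot(inherits(params, "selfheal_params"),
            length(a) == 1L, length(k) == 1L, k >= 0)
  matrix(c(-1,               1 / (1 + k)^2,
           -params$D * k,   -params$D * (a - params$q)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("da", "dk"), c("a", "k")))
}

#' Linear stability of the fixed point
#'
#' Evaluates the trace and determinant of the Jacobian at the fixed point:
#' tau = -1 - D(a* - q) and Delta = D(a* - q) + D k*/(1+k*)^2. The fixed point
#' is stable iff tau < 0 and Delta > 0. Setting D < 1 is a sufficient
#' condition for stability (it makes the right-hand sides of both inequality
#' bounds negative), which is also reported.
#'
#' @param params A [model_params()] object.
#' @return An object of class `selfheal_stability`: list with `trace`,
#'   `determinant`, `stable`, `sufficient_D_lt_1`, `fixed_point`, `params`.
#' @examples
#' stability_report(model_params())  # stable; tau ~= -1.0978
#' @export
stability_report <- function(params) {
  fp <- fixed_point(params)
  a <- fp$a_star; k <- fp$k_star; D <- params$D; q <- params$q
  tr <- -1 - D * (a - q)
  det <- D * (a - q) + D * k / (1 + k)^2
  structure(list(trace = tr, determinant = det,
                 stable = (tr < 0 && det > 0),
                 sufficient_D_lt_1 = D < 1,
                 fixed_point = fp, params = params),
            class = "selfheal_stability")
}

#' @export
print.selfheal_stability <- function(x, ...) {
  cat("<selfheal_stability> tau =", format(x$trace, digits = 6),
      " Delta =", format(x$determinant, digits = 6),
      " stable =", x$stable,
      if (x$sufficient_D_lt_1) " (D < 1 sufficiency holds)", "\n")
  invisible(x)
}

#' Integrate the activity--stiffness system
#'
#' Adaptive time-domain integration of the two-variable system with an
#' embedded Runge--Kutta 2(3) pair (Bogacki--Shampine), via
#' [deSolve::ode()]. Stiffness is clamped at zero from below if a step
#' undershoots (analytically impossible since dk/dt = P > 0 at k = 0, but
#' floating point can); a warning is emitted when the clamp fires.
#'
#' @param params A [model_params()] object.
#' @param a0,k0 Initial activity (in \[0,1\]) and stiffness (>= 0).
#' @param t_end Final dimensionless time, > 0.
#' @param times Optional explicit output times (default 501 equispaced points
#'   from 0 to `t_end`). Output times do not affect the adaptive internal step.
#' @param rtol,atol Relative / absolute solver tolerances.
#' @return A tibble of class `selfheal_trajectory` with columns `t`, `a`, `k`
#'   and the parameters stored in attribute `params`.
#' @examples
#' p <- model_params(); fp <- fixed_point(p)
#' tr <- integrate_model(p, a0 = fp$a_star, k0 = 2 * fp$k_star, t_end = 200)
#' tail(tr, 1)  # within tolerance of (a*, k*)
#' @export
integrate_model <- function(params, a0, k0, t_end,
                            times = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "selfheal_params"),
            a0 >= 0, a0 <= 1, k0 >= 0, t_end > 0)
  if (is.null(times)) times <- seq(0, t_end, length.out = 501L)
  stopifnot(all(diff(times) > 0))
  rhs_fun <- function(t, y, parms) {
    # trial stages of the embedded pair may probe k < 0; evaluate at 0 there
    k <- max(y[2L], 0)
    list(c(k / (1 + k) - y[1L],
           -parms$D * k * (y[1L] - parms$q) + parms$P))
  }
  sol <- deSolve::ode(y = c(a = a0, k = k0), times = times, func = rhs_fun,
                      parms = params, method = "ode23",
                      rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0) {
    stop("integration failed (step-size/tolerance failure); istate = ",
         diagn[1L], call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  names(out) <- c("t", "a", "k")
  if (any(out$k < 0)) {
    warning("stiffness undershot 0 and was clamped", call. = FALSE)
    out$k <- pmax(out$k, 0)
  }
  structure(out, params = params,
            class = c("selfheal_trajectory", class(out)))
}

#' Fixed point as a function of one parameter
#'
#' Sweeps a single parameter (`"q"`, `"D"` or `"P"`) across a grid while
#' holding the other two at their values in `params`, recording the fixed
#' point for each admissible grid value. Grid values violating the parameter
#' constraints (e.g. q >= 1) are kept in the table but flagged with `ok =
#' FALSE` and NA fixed points.
#'
#' @param params A [model_params()] baseline.
#' @param param One of `"q"`, `"D"`, `"P"`.
#' @param values Numeric grid of parameter values.
#' @return A tibble of class `selfheal_sweep` with columns `param`, `value`,
#'   `a_star`, `k_star`, `ok`.
#' @examples
#' fixed_point_sweep(model_params(), "D", seq(0.05, 1, by = 0.05))
#' @export
fixed_point_sweep <- function(params, param = c("q", "D", "P"), values) {
  stopifnot(inherits(params, "selfheal_params"), is.numeric(values))
  param <- match.arg(param)
  rows <- purrr::map(values, function(v) {
    p <- params
    p[[param]] <- v
    ok <- (p$q > 0 && p$q < 1 && p$D > 0 && p$P >= 0)
    if (ok) {
      fp <- fixed_point(do.call(model_params, p[c("q", "D", "P")]))
      tibble::tibble(param = param, value = v,
                     a_star = fp$a_star, k_star = fp$k_star, ok = TRUE)
    } else {
      warning("skipping inadmissible ", param, " = ", v, call. = FALSE)
      tibble::tibble(param = param, value = v,
                     a_star = NA_real_, k_star = NA_real_, ok = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, baseline = params,
            class = c("selfheal_sweep", class(out)))
}
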
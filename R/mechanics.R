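positions_of <- function(net, positions = NULL) {
  if (is.null(positions)) {
    positions <- cbind(net$nodes$x, net$nodes$y)
  }
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == nrow(net$nodes), ncol(positions) == 2L)
  positions
}

spring_lengths <- function(net, positions) {
  dx <- positions[net$springs$from, 1L] - positions[net$springs$to, 1L]
  dy <- positions[net$springs$from, 2L] - positions[net$springs$to, 2L]
  sqrt(dx^2 + dy^2)
}

#' Total strain energy of the network
#'
#' Sum over springs of the Hookean energy
#' `1/2 * stiffness * (length - rest_length)^2` at the supplied node
#' positions (defaults to the stored lattice positions).
#'
#' @param net A `hex_network`.
#' @param positions Optional n_nodes x 2 matrix of coordinates.
#' @return Scalar energy (dimensionless).
#' @export
total_strain_energy <- function(net, positions = NULL) {
  stopifnot(inherits(net, "hex_network"))
  positions <- positions_of(net, positions)
  len <- spring_lengths(net, positions)
  sum(0.5 * net$springs$stiffness * (len - net$springs$rest_length)^2)
}

# analytic gradient of the strain energy wrt free (interior) coordinates
strain_energy_grad <- function(net, positions) {
  from <- net$springs$from; to <- net$springs$to
  dx <- positions[from, 1L] - positions[to, 1L]
  dy <- positions[from, 2L] - positions[to, 2L]
  len <- sqrt(dx^2 + dy^2)
  len <- pmax(len, 1e-12)
  f <- net$springs$stiffness * (len - net$springs$rest_length) / len
  gx <- numeric(nrow(positions)); gy <- numeric(nrow(positions))
  agg_x <- rowsum(c(f * dx, -f * dx), c(from, to))
  agg_y <- rowsum(c(f * dy, -f * dy), c(from, to))
  gx[as.integer(rownames(agg_x))] <- agg_x[, 1L]
  gy[as.integer(rownames(agg_y))] <- agg_y[, 1L]
  cbind(gx, gy)
}

#' Equilibrate the network
#'
#' Finds interior node positions minimizing the total strain energy while
#' boundary nodes stay fixed. Two methods are provided: `"local"`, a
#' deterministic quasi-Newton descent (L-BFGS-B with the analytic gradient),
#' and `"anneal"`, seeded simulated annealing with geometric cooling and
#' Gaussian node displacements followed by a local polish so that both
#' methods land on the same minimum to tight tolerance. The two agree because
#' the pre-tensed Hookean energy is effectively convex over the configurations
#' reached from the lattice state; the minimization target, not the
#' algorithm, determines the result.
#'
#' @param net A `hex_network`.
#' @param positions Optional starting coordinates (default stored lattice
#'   positions).
#' @param method `"local"` (default) or `"anneal"`.
#' @param seed RNG seed for the annealing proposal sequence.
#' @param tol Convergence tolerance on the energy (factr-scaled for
#'   L-BFGS-B).
#' @param maxit Iteration cap; if the minimizer stops at the cap the
#'   best-so-far positions are returned with a warning.
#' @param sa_control List of annealing settings: `t0` initial temperature,
#'   `cooling` geometric factor per sweep, `sweeps`, `sigma` proposal s.d.
#' @return An n_nodes x 2 matrix of equilibrated positions with attributes
#'   `energy` (final total strain energy) and `converged`.
#' @export
equilibrate <- function(net, positions = NULL, method = c("local", "anneal"),
                        seed = 1L, tol = 1e-10, maxit = 2000L,
                        sa_control = list()) {
  stopifnot(inherits(net, "hex_network"))
  method <- match.arg(method)
  positions <- positions_of(net, positions)
  free <- which(!net$nodes$boundary)
  if (length(free) == 0L) {
    return(structure(positions, energy = total_strain_energy(net, positions),
                     converged = TRUE))
  }
  if (method == "anneal") {
    positions <- anneal_positions(net, positions, free, seed, sa_control)
  }
  pack <- function(p) as.vector(p[free, ])
  unpack <- function(theta) {
    positions[free, ] <- matrix(theta, ncol = 2L)
    positions
  }
  fn <- function(theta) total_strain_energy(net, unpack(theta))
  gr <- function(theta) {
    g <- strain_energy_grad(net, unpack(theta))
    as.vector(g[free, ])
  }
  opt <- stats::optim(pack(positions), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit,
                                     factr = tol / .Machine$double.eps,
                                     pgtol = 0))
  if (opt$convergence != 0L && opt$convergence != 52L) {
    warning("equilibration stopped before convergence (code ",
            opt$convergence, "); returning best-so-far positions",
            call. = FALSE)
  }
  structure(unpack(opt$par), energy = opt$value,
            converged = opt$convergence == 0L)
}

anneal_positions <- function(net, positions, free, seed, control) {
  ctl <- utils::modifyList(list(t0 = NULL, cooling = 0.9, sweeps = 60L,
                                sigma = 0.05 * net$spacing), control)
  set.seed(seed)
  e <- total_strain_energy(net, positions)
  t0 <- if (is.null(ctl$t0)) max(e, 1e-6) * 0.01 else ctl$t0
  temp <- t0
  for (sweep in seq_len(ctl$sweeps)) {
    for (v in free) {
      old <- positions[v, ]
      positions[v, ] <- old + stats::rnorm(2L, sd = ctl$sigma)
      e_new <- total_strain_energy(net, positions)
      if (e_new <= e || stats::runif(1L) < exp((e - e_new) / temp)) {
        e <- e_new
      } else {
        positions[v, ] <- old
      }
    }
    temp <- temp * ctl$cooling
  }
  positions
}

#' Average network stress
#'
#' Mean spring tension, `stiffness * (length - rest_length)`, over all
#' springs. Positive values mean net tension (springs stretched beyond rest),
#' as in the pre-stressed resting state.
#'
#' @param net A `hex_network`.
#' @param positions Optional coordinate matrix.
#' @return Scalar mean tension.
#' @export
average_stress <- function(net, positions = NULL) {
  stopifnot(inherits(net, "hex_network"))
  positions <- positions_of(net, positions)
  len <- spring_lengths(net, positions)
  mean(net$springs$stiffness * (len - net$springs$rest_length))
}

#' Macroscopic network stiffness from a biaxial strain probe
#'
#' Equilibrates the network, then scales the boundary node positions
#' biaxially by `1 +/- strain_amplitude` about the centroid (default +/-
#' 0.2%), re-equilibrates the interior at each strained boundary, and returns
#' the central-difference modulus
#' `(stress(+) - stress(-)) / (2 * strain_amplitude)`, where stress is the
#' mean spring tension.
#'
#' @param net A `hex_network`.
#' @param strain_amplitude Biaxial strain amplitude (default 0.002 = 0.2%).
#' @param positions Optional reference coordinates (default stored lattice
#'   positions; they are equilibrated before probing).
#' @param ... Passed to [equilibrate()] (e.g. `method`, `tol`).
#' @return Scalar network stiffness (mean tension per unit strain).
#' @export
network_stiffness <- function(net, strain_amplitude = 0.002,
                              positions = NULL, ...) {
  stopifnot(inherits(net, "hex_network"),
            strain_amplitude > 0, strain_amplitude < 1)
  pos0 <- equilibrate(net, positions, ...)
  cx <- mean(pos0[, 1L]); cy <- mean(pos0[, 2L])
  probe <- function(scale) {
    p <- pos0
    p[, 1L] <- cx + (p[, 1L] - cx) * scale
    p[, 2L] <- cy + (p[, 2L] - cy) * scale
    # boundary carries the imposed strain; interior relaxes from the scaled state
    p_eq <- equilibrate(net, p, ...)
    average_stress(net, p_eq)
  }
  (probe(1 + strain_amplitude) - probe(1 - strain_amplitude)) /
    (2 * strain_amplitude)
}
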
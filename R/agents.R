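#' Place agents on the network
#'
#' Drops `n` agents (fibroblast-like walkers) on nodes sampled uniformly at
#' random, by default with replacement (several agents may share a node).
#' Each agent starts at activity `a0`; in the healing experiments `a0` is the
#' activity fixed point a*, so an undisturbed network is exactly stationary.
#'
#' @param net A `hex_network`.
#' @param n Number of agents, >= 1.
#' @param seed Optional RNG seed (NULL leaves the RNG state alone).
#' @param a0 Initial activity in \[0, 1\].
#' @param replace Sample nodes with replacement (default TRUE). With
#'   `replace = FALSE` and `n` equal to the node count every node is occupied.
#' @return A tibble with columns `node` and `activity`.
#' @export
place_agents <- function(net, n, seed = NULL, a0 = 0.5, replace = TRUE) {
  stopifnot(inherits(net, "hex_network"), n >= 1,
            a0 >= 0, a0 <= 1)
  if (!replace && n > nrow(net$nodes)) {
    stop("cannot place ", n, " agents without replacement on ",
         nrow(net$nodes), " nodes", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(node = sample(nrow(net$nodes), n, replace = replace),
                 activity = a0)
}

#' Migration probabilities from a node
#'
#' For the stiffness-biased (durotactic) walk the probability of stepping to
#' an adjacent node equals the stiffness of the intervening spring as a
#' fraction of the summed stiffness of all springs incident on the current
#' node; for the pure random walk all incident springs are equally likely.
#' The rule is stated for degree-3 interior nodes and generalizes verbatim to
#' the lower-degree boundary nodes.
#'
#' @param net A `hex_network`.
#' @param node Node id.
#' @param walk `"biased"` or `"random"`.
#' @return A tibble with columns `spring`, `to`, `prob` (summing to 1).
#' @export
migration_probs <- function(net, node, walk = c("biased", "random")) {
  stopifnot(inherits(net, "hex_network"), length(node) == 1L,
            node %in% net$nodes$id)
  walk <- match.arg(walk)
  deg <- net$degree[node]
  if (deg == 0L) stop("node ", node, " is isolated", call. = FALSE)
  springs <- net$inc_springs[node, seq_len(deg)]
  w <- if (walk == "biased") net$springs$stiffness[springs] else rep(1, deg)
  tibble::tibble(spring = springs,
                 to = net$inc_nodes[node, seq_len(deg)],
                 prob = w / sum(w))
}

#' Simulation configuration
#'
#' Bundles and validates everything a healing run needs: the dimensionless
#' model parameters, agent count, walk mode, forward-Euler step `dt`
#' (one iteration advances dimensionless time by `dt`; `dt < 2` keeps the
#' discrete activity map stable), iteration count, injury factor, forcing
#' schedule, remodeling switch, optional imposed central-spring trajectory
#' (for the halo-prohibited variant), halo threshold, seed, and the cadence
#' of mechanical snapshots.
#'
#' @param params A [model_params()] object.
#' @param n_agents Number of agents, >= 1.
#' @param walk `"biased"` (stiffness-biased, durotactic) or `"random"`.
#' @param dt Dimensionless time per iteration, in (0, 2).
#' @param n_steps Number of iterations, >= 1.
#' @param injury_factor Central-spring injury multiplier applied at step 0
#'   (1 = no injury).
#' @param forcing_period Steps between activity resets to 0 (0 = no forcing).
#'   Note the convention that a = 0 represents a highly active, depositing
#'   agent: since 0 < q, the stiffness equation deposits matrix.
#' @param remodeling If FALSE agents never modify springs; the central spring
#'   instead follows `imposed_trajectory` while agent activity still updates.
#' @param imposed_trajectory Optional numeric vector of length `n_steps + 1`
#'   giving the central-spring stiffness at steps 0..n_steps (required when
#'   `remodeling = FALSE`).
#' @param halo_threshold Multiplicative halo threshold (default 1.001).
#' @param seed RNG seed for placement and migration.
#' @param snapshot_every Steps between biaxial network-stiffness readouts
#'   (0 = none; they require equilibration and dominate run time).
#' @param a0 Initial agent activity (default: the fixed point a* of
#'   `params`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(params = model_params(), n_agents = 64L,
                       walk = c("biased", "random"), dt = 1,
                       n_steps = 256L, injury_factor = 2,
                       forcing_period = 0L, remodeling = TRUE,
                       imposed_trajectory = NULL, halo_threshold = 1.001,
                       seed = 1L, snapshot_every = 0L, a0 = NULL) {
  stopifnot(inherits(params, "selfheal_params"))
  walk <- match.arg(walk)
  if (dt <= 0 || dt >= 2) {
    stop("`dt` must lie in (0, 2) for forward-Euler stability of the ",
         "activity update", call. = FALSE)
  }
  stopifnot(n_agents >= 1, n_steps >= 1, injury_factor > 0,
            forcing_period >= 0, halo_threshold > 0, snapshot_every >= 0)
  if (!remodeling && is.null(imposed_trajectory)) {
    stop("`remodeling = FALSE` requires `imposed_trajectory`", call. = FALSE)
  }
  if (!is.null(imposed_trajectory) &&
      length(imposed_trajectory) < n_steps + 1L) {
    stop("`imposed_trajectory` must have length >= n_steps + 1", call. = FALSE)
  }
  if (is.null(a0)) a0 <- fixed_point(params)$a_star
  structure(list(params = params, n_agents = as.integer(n_agents),
                 walk = walk, dt = dt, n_steps = as.integer(n_steps),
                 injury_factor = injury_factor,
                 forcing_period = as.integer(forcing_period),
                 remodeling = isTRUE(remodeling),
                 imposed_trajectory = imposed_trajectory,
                 halo_threshold = halo_threshold, seed = as.integer(seed),
                 snapshot_every = as.integer(snapshot_every), a0 = a0),
            class = "sim_config")
}

#' Run one healing simulation
#'
#' Realizes the activity--stiffness dynamics on the network with migrating
#' agents. Each iteration: (1) every agent samples one incident spring via
#' its walk rule and traverses it; (2) from PRE-step values each agent takes
#' `da = dt * (k/(1+k) - a)` with `k` the traversed spring's stiffness, and
#' contributes `dk = dt * (-D k (a - q) + P)` to that spring; (3) all
#' increments apply simultaneously, concurrent traversals of one spring
#' summing; springs are remodeled only when traversed, so unvisited springs
#' hold their value; (4) with remodeling disabled the central spring follows
#' the imposed trajectory instead; (5) with forcing on, every agent's
#' activity is reset to 0 after each `forcing_period`-th update. A uniform
#' network at k* with all agents at a* is exactly invariant.
#'
#' The injury (central spring set to `injury_factor * k*`) is applied at step
#' 0 before the loop.
#'
#' @param net A `hex_network` (built at baseline stiffness k*).
#' @param config A [sim_config()].
#' @return An object of class `healing_sim`: list with `series` (tibble:
#'   `step`, `time`, `injured_k`, `halo_size`, `mean_activity`, `mean_k`,
#'   `sd_k`), `snapshots` (tibble: `step`, `time`, `network_stiffness`),
#'   `net` (final network), `agents` (final tibble), `injured_spring`,
#'   `resolution_step` (first step with empty halo and injured spring within
#'   0.1% of k*; NA if never), and `config`.
#' @export
run_simulation <- function(net, config) {
  stopifnot(inherits(net, "hex_network"), inherits(config, "sim_config"))
  p <- config$params
  dt <- config$dt
  n_steps <- config$n_steps
  k_star <- net$k_star_reference
  inj <- central_spring(net)
  if (config$injury_factor != 1) {
    net <- apply_injury(net, inj, config$injury_factor)
  }
  if (!config$remodeling) {
    net$springs$stiffness[inj] <- config$imposed_trajectory[1L]
  }
  set.seed(config$seed)
  agents <- place_agents(net, config$n_agents, seed = NULL, a0 = config$a0)
  n_springs <- nrow(net$springs)
  K <- net$springs$stiffness
  v <- agents$node
  a <- agents$activity
  M_spr <- net$inc_springs
  M_nod <- net$inc_nodes
  k_floor <- 1e-9
  floored <- FALSE

  series <- matrix(NA_real_, n_steps + 1L, 5L)
  colnames(series) <- c("injured_k", "halo_size", "mean_activity",
                        "mean_k", "sd_k")
  record <- function(i) {
    series[i, ] <<- c(K[inj],
                      sum(K > config$halo_threshold * k_star),
                      mean(a), mean(K), sqrt(mean((K - mean(K))^2)))
  }
  snap_steps <- if (config$snapshot_every > 0L) {
    unique(c(0L, seq(config$snapshot_every, n_steps,
                     by = config$snapshot_every)))
  } else integer(0)
  snaps <- vector("list", length(snap_steps))
  take_snapshot <- function(idx, step) {
    net$springs$stiffness <- K
    snaps[[idx]] <<- tibble::tibble(
      step = step, time = step * dt,
      network_stiffness = network_stiffness(net))
  }
  record(1L)
  if (length(snap_steps) && snap_steps[1L] == 0L) take_snapshot(1L, 0L)

  K_ext <- c(K, 0)
  for (step in seq_len(n_steps)) {
    K_ext[seq_len(n_springs)] <- K
    idx <- M_spr[v, , drop = FALSE]
    w <- matrix(K_ext[idx], ncol = 3L)
    if (config$walk == "random") {
      w <- matrix(as.numeric(idx <= n_springs), ncol = 3L)
      w <- w * (K_ext[idx] > 0)  # degenerate zero-stiffness springs untraversable
    }
    tot <- w[, 1L] + w[, 2L] + w[, 3L]
    r <- stats::runif(length(v)) * tot
    choice <- 1L + (r > w[, 1L]) + (r > w[, 1L] + w[, 2L])
    sel <- cbind(v, choice)
    S <- M_spr[sel]
    v <- M_nod[sel]
    k_s <- K[S]
    da <- dt * (k_s / (1 + k_s) - a)
    if (config$remodeling) {
      contrib <- dt * (-p$D * k_s * (a - p$q) + p$P)
      agg <- rowsum(contrib, S)
      K[as.integer(rownames(agg))] <- K[as.integer(rownames(agg))] + agg[, 1L]
      if (any(K < k_floor)) {
        K[K < k_floor] <- k_floor
        floored <- TRUE
      }
    } else {
      K[inj] <- config$imposed_trajectory[step + 1L]
    }
    a <- a + da
    if (config$forcing_period > 0L &&
        step %% config$forcing_period == 0L) {
      a[] <- 0
    }
    record(step + 1L)
    si <- match(step, snap_steps)
    if (!is.na(si)) take_snapshot(si, step)
  }
  if (floored) {
    warning("spring stiffness hit the positive floor and was clamped",
            call. = FALSE)
  }
  net$springs$stiffness <- K
  series_tbl <- tibble::as_tibble(as.data.frame(series))
  series_tbl <- dplyr::mutate(series_tbl,
                              step = 0:n_steps, time = step * dt,
                              .before = 1L)
  resolved <- which(series_tbl$halo_size == 0 &
                      abs(series_tbl$injured_k - k_star) <= 0.001 * k_star)
  structure(list(series = series_tbl,
                 snapshots = dplyr::bind_rows(snaps),
                 net = net,
                 agents = tibble::tibble(node = v, activity = a),
                 injured_spring = inj,
                 resolution_step = if (length(resolved)) {
                   series_tbl$step[resolved[1L]]
                 } else NA_integer_,
                 config = config),
            class = "healing_sim")
}

#' @export
print.healing_sim <- function(x, ...) {
  cat("<healing_sim> ", x$config$n_agents, " agents (", x$config$walk,
      " walk), ", x$config$n_steps, " steps, dt = ", x$config$dt,
      "\n  injured spring ", x$injured_spring,
      ": k = ", format(x$series$injured_k[1L], digits = 5), " -> ",
      format(utils::tail(x$series$injured_k, 1L), digits = 5),
      "; resolution step = ", x$resolution_step, "\n", sep = "")
  invisible(x)
}

#' Run an ensemble of healing simulations
#'
#' Repeats a configuration `n_reps` times with independent seeds (replicate
#' i uses `base_seed + i`), tracking the per-step halo size and injured-spring
#' stiffness of every replicate plus each replicate's resolution time (first
#' step at which the halo is empty and the injured spring is within 0.1% of
#' k*).
#'
#' @param net A `hex_network`.
#' @param config A [sim_config()]; its `seed` is overridden per replicate.
#' @param n_reps Number of replicates, >= 2.
#' @param base_seed Base RNG seed.
#' @return An object of class `healing_ensemble`: list with `summary`
#'   (tibble: `step`, `time`, `halo_mean`, `halo_sd`, `injured_k_mean`,
#'   `injured_k_sd`), `halo` and `injured_k` (step x replicate matrices),
#'   `resolution_steps` (per replicate, NA if unresolved), `config`,
#'   `n_reps`, `base_seed`.
#' @export
run_ensemble <- function(net, config, n_reps = 100L, base_seed = 1L) {
  stopifnot(inherits(net, "hex_network"), inherits(config, "sim_config"),
            n_reps >= 2)
  halo_m <- matrix(NA_real_, config$n_steps + 1L, n_reps)
  kinj_m <- matrix(NA_real_, config$n_steps + 1L, n_reps)
  res <- rep(NA_integer_, n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    sim <- run_simulation(net, cfg)
    halo_m[, i] <- sim$series$halo_size
    kinj_m[, i] <- sim$series$injured_k
    res[i] <- sim$resolution_step
  }
  steps <- 0:config$n_steps
  summary <- tibble::tibble(
    step = steps, time = steps * config$dt,
    halo_mean = rowMeans(halo_m),
    halo_sd = apply(halo_m, 1L, stats::sd),
    injured_k_mean = rowMeans(kinj_m),
    injured_k_sd = apply(kinj_m, 1L, stats::sd))
  structure(list(summary = summary, halo = halo_m, injured_k = kinj_m,
                 resolution_steps = res, config = config,
                 n_reps = n_reps, base_seed = base_seed),
            class = "healing_ensemble")
}

#' @export
print.healing_ensemble <- function(x, ...) {
  cat("<healing_ensemble> ", x$n_reps, " replicates, ", x$config$walk,
      " walk, ", x$config$n_agents, " agents\n  median resolution step: ",
      stats::median(x$resolution_steps, na.rm = TRUE),
      " (", sum(is.na(x$resolution_steps)), " unresolved)\n", sep = "")
  invisible(x)
}

#' Per-step rank comparison of two ensembles
#'
#' Compares two equal-length ensembles (e.g. halo sizes under biased vs
#' random walks) step by step with a two-sided Mann--Whitney (Wilcoxon
#' rank-sum) test on the replicate values. Steps at which both ensembles are
#' entirely tied carry no rank information and are flagged `degenerate` with
#' an NA p-value rather than tested.
#'
#' @param series_a,series_b Step x replicate numeric matrices, or
#'   `healing_ensemble` objects (their halo matrices are compared).
#' @return A tibble with columns `step`, `statistic`, `p_value`,
#'   `degenerate`, and attribute `test` documenting the test used.
#' @export
compare_series <- function(series_a, series_b) {
  if (inherits(series_a, "healing_ensemble")) series_a <- series_a$halo
  if (inherits(series_b, "healing_ensemble")) series_b <- series_b$halo
  stopifnot(is.matrix(series_a), is.matrix(series_b),
            nrow(series_a) == nrow(series_b))
  n <- nrow(series_a)
  out <- purrr::map(seq_len(n), function(i) {
    xa <- series_a[i, ]; xb <- series_b[i, ]
    if (length(unique(c(xa, xb))) == 1L) {
      return(tibble::tibble(step = i - 1L, statistic = NA_real_,
                            p_value = NA_real_, degenerate = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
    tibble::tibble(step = i - 1L, statistic = unname(wt$statistic),
                   p_value = wt$p.value, degenerate = FALSE)
  })
  structure(dplyr::bind_rows(out),
            test = "two-sided Mann-Whitney (wilcox.test, normal approx.)",
            class = c("selfheal_comparison", class(dplyr::bind_rows(out))))
}

#' Resolution time of a healing run
#'
#' First step at which the halo is empty and the injured spring is within
#' 0.1% of the reference stiffness (the halo threshold reused symmetrically).
#'
#' @param x A `healing_sim` or `healing_ensemble`.
#' @return For a single run, one integer step (NA if never resolved); for an
#'   ensemble, the vector of per-replicate resolution steps.
#' @export
resolution_time <- function(x) {
  if (inherits(x, "healing_sim")) return(x$resolution_step)
  if (inherits(x, "healing_ensemble")) return(x$resolution_steps)
  stop("`x` must be a healing_sim or healing_ensemble", call. = FALSE)
}

#' Peak step of an ensemble mean-halo curve
#'
#' Locates the peak of the ensemble mean halo-size series after smoothing
#' with a centered running average. At reduced replicate counts the raw mean
#' curve is noisy near its flat maximum, so the argmax of the raw series
#' jitters; smoothing (as is standard for noisy simulation series) gives a
#' stable peak location.
#'
#' @param x A `healing_ensemble`, or a numeric series.
#' @param window Running-average window in steps (odd; default 21).
#' @return The step index (0-based) of the smoothed peak.
#' @export
ensemble_peak_step <- function(x, window = 21L) {
  series <- if (inherits(x, "healing_ensemble")) x$summary$halo_mean else x
  stopifnot(is.numeric(series), window >= 1L)
  sm <- stats::filter(series, rep(1 / window, window), sides = 2L)
  which.max(sm) - 1L
}
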
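scenario_names <- c("timecourses", "fixedpoint_sweeps", "injury_resolution",
                    "walk_variants", "halo_ensemble", "fibrosis", "aging")

baseline_params <- function() model_params(q = 0.2, D = 0.32, P = 0.1)

# default lattice for the network experiments: 10 x 10 honeycomb patch at
# the baseline stiffness fixed point
scenario_network <- function(overrides, params = baseline_params()) {
  rows <- overrides$rows %||% 10L
  cols <- overrides$cols %||% 10L
  build_hex_network(rows, cols, k_baseline = fixed_point(params)$k_star)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Run a packaged experiment scenario
#'
#' Drives the figure-level experiments at configurable scale: ODE time
#' courses, fixed-point parameter sweeps, single-injury resolution, walk
#' variants (including the halo-prohibited imposed-trajectory control),
#' halo-ensemble statistics, fibrosis under sustained forcing, and the aging
#' comparison. Defaults follow the published settings (q = 0.2, D = 0.32,
#' P = 0.1; 64 agents; injury factor 2; halo threshold 1.001; biaxial strain
#' 0.2%); ensembles default to 100 replicates, a desk-scale reduction of the
#' reference 2,000 (`reps` raises it).
#'
#' Every run writes its series as CSV plus a JSON manifest (config, seed,
#' package version, summary row) into `out_dir`, so [summarize_runs()] can
#' rebuild a results table and any run can be reproduced from its manifest.
#'
#' @param name Scenario name: one of `"timecourses"`, `"fixedpoint_sweeps"`,
#'   `"injury_resolution"`, `"walk_variants"`, `"halo_ensemble"`,
#'   `"fibrosis"`, `"aging"`.
#' @param overrides Named list of config deltas (`q`, `D`, `P`, `n_agents`,
#'   `walk`, `dt`, `n_steps`, `injury_factor`, `forcing_period`,
#'   `halo_threshold`, `snapshot_every`, `rows`, `cols`, `reps`).
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param config_file Optional YAML file of overrides; explicit `overrides`
#'   win over file values.
#' @param verbose Log progress messages.
#' @return A summary tibble (one row per run within the scenario),
#'   invisibly also written into the manifest.
#' @export
run_scenario <- function(name, overrides = list(),
                         out_dir = file.path(tempdir(), paste0("selfheal-", name)),
                         seed = 1L, config_file = NULL, verbose = TRUE) {
  name <- match.arg(name, scenario_names)
  if (!is.null(config_file)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading `config_file` requires the yaml package", call. = FALSE)
    }
    file_overrides <- yaml::read_yaml(config_file)
    overrides <- utils::modifyList(file_overrides, overrides)
  }
  known <- c("q", "D", "P", "n_agents", "walk", "dt", "n_steps",
             "injury_factor", "forcing_period", "halo_threshold",
             "snapshot_every", "rows", "cols", "reps")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    stop("unknown override(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_msg(verbose, "scenario ", name, " (seed ", seed, ") -> ", out_dir)
  params <- model_params(q = overrides$q %||% 0.2,
                         D = overrides$D %||% 0.32,
                         P = overrides$P %||% 0.1)
  summary <- switch(
    name,
    timecourses = scenario_timecourses(out_dir),
    fixedpoint_sweeps = scenario_sweeps(params, out_dir),
    injury_resolution = scenario_injury(params, overrides, seed, out_dir),
    walk_variants = scenario_walks(params, overrides, seed, out_dir),
    halo_ensemble = scenario_halo(params, overrides, seed, out_dir),
    fibrosis = scenario_fibrosis(params, overrides, seed, out_dir),
    aging = scenario_aging(overrides, seed, out_dir))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest <- list(scenario = name, seed = seed,
                   params = params[c("q", "D", "P")],
                   overrides = overrides,
                   package_version = as.character(utils::packageVersion("selfheal")),
                   elapsed_sec = elapsed,
                   timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
                   summary = summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  log_msg(verbose, "done in ", round(elapsed, 1), " s")
  summary
}

scenario_timecourses <- function(out_dir) {
  sets <- list(baseline = model_params(0.2, 0.32, 0.1),
               low_D = model_params(0.2, 0.08, 0.1),
               high_P = model_params(0.2, 0.32, 0.4),
               high_q = model_params(0.8, 0.32, 0.1))
  rows <- purrr::imap(sets, function(p, nm) {
    fp <- fixed_point(p)
    purrr::map(c(half = 0.5, double = 2), function(f) {
      tr <- integrate_model(p, a0 = fp$a_star, k0 = f * fp$k_star,
                            t_end = 200)
      readr::write_csv(tr, file.path(out_dir,
                                     sprintf("trajectory_%s_k0x%g.csv", nm, f)))
      final <- tr[nrow(tr), ]
      tibble::tibble(set = nm, k0_factor = f,
                     final_rel_dev_k = abs(final$k - fp$k_star) / fp$k_star,
                     final_rel_dev_a = abs(final$a - fp$a_star) / fp$a_star)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

scenario_sweeps <- function(params, out_dir) {
  grids <- list(D = seq(0.04, 1.28, length.out = 60),
                P = exp(seq(log(0.01), log(1.6), length.out = 60)),
                q = seq(0.02, 0.98, length.out = 60))
  purrr::imap(grids, function(g, nm) {
    sw <- fixed_point_sweep(params, nm, g)
    readr::write_csv(sw, file.path(out_dir, sprintf("sweep_%s.csv", nm)))
    ok <- sw[sw$ok, ]
    tibble::tibble(param = nm,
                   a_star_direction = sign(ok$a_star[nrow(ok)] - ok$a_star[1L]),
                   k_star_direction = sign(ok$k_star[nrow(ok)] - ok$k_star[1L]),
                   k_star_max = max(ok$k_star))
  }) |> dplyr::bind_rows()
}

scenario_injury <- function(params, ov, seed, out_dir) {
  net <- scenario_network(ov, params)
  cfg <- sim_config(params, n_agents = ov$n_agents %||% 64L,
                    walk = ov$walk %||% "biased", dt = ov$dt %||% 1,
                    n_steps = ov$n_steps %||% 400L,
                    injury_factor = ov$injury_factor %||% 2,
                    halo_threshold = ov$halo_threshold %||% 1.001,
                    snapshot_every = ov$snapshot_every %||% 0L,
                    seed = seed)
  sim <- run_simulation(net, cfg)
  readr::write_csv(sim$series, file.path(out_dir, "injury_series.csv"))
  glance(sim)
}

scenario_walks <- function(params, ov, seed, out_dir) {
  net <- scenario_network(ov, params)
  base_cfg <- function(walk) {
    sim_config(params, n_agents = ov$n_agents %||% 64L, walk = walk,
               dt = ov$dt %||% 1, n_steps = ov$n_steps %||% 400L,
               injury_factor = ov$injury_factor %||% 2, seed = seed)
  }
  biased <- run_simulation(net, base_cfg("biased"))
  random <- run_simulation(net, base_cfg("random"))
  # halo-prohibited control: agents update activity but never remodel; the
  # central spring is forced along the random-walk run's stiffness decline
  cfg_imp <- base_cfg("random")
  cfg_imp$remodeling <- FALSE
  cfg_imp$imposed_trajectory <- random$series$injured_k
  imposed <- run_simulation(net, cfg_imp)
  runs <- list(biased = biased, random = random, no_halo = imposed)
  purrr::iwalk(runs, function(s, nm) {
    readr::write_csv(s$series, file.path(out_dir, sprintf("walk_%s.csv", nm)))
  })
  dplyr::bind_rows(purrr::imap(runs, function(s, nm) {
    dplyr::mutate(glance(s), variant = nm, .before = 1L)
  }))
}

scenario_halo <- function(params, ov, seed, out_dir) {
  net <- scenario_network(ov, params)
  reps <- ov$reps %||% 100L
  cfg <- function(walk) {
    sim_config(params, n_agents = ov$n_agents %||% 64L, walk = walk,
               dt = ov$dt %||% 1, n_steps = ov$n_steps %||% 400L,
               injury_factor = ov$injury_factor %||% 2, seed = seed)
  }
  biased <- run_ensemble(net, cfg("biased"), n_reps = reps, base_seed = seed)
  random <- run_ensemble(net, cfg("random"), n_reps = reps,
                         base_seed = seed + reps)
  readr::write_csv(biased$summary, file.path(out_dir, "halo_biased.csv"))
  readr::write_csv(random$summary, file.path(out_dir, "halo_random.csv"))
  readr::write_csv(compare_series(biased, random),
                   file.path(out_dir, "halo_rank_tests.csv"))
  dplyr::bind_rows(glance(biased), glance(random))
}

scenario_fibrosis <- function(params, ov, seed, out_dir) {
  net <- scenario_network(ov, params)
  # dt = 0.25 keeps the periodic activity reset in its intended sustained
  # regime: after a reset, a single coarse Euler step would carry activity all
  # the way to the nullcline value k/(1+k), neutralizing the forcing within
  # one cycle; at dt = 0.25 agents remain near a = 0 (depositing) through the
  # cycle and stiffening is progressive rather than saturating.
  cfg <- function(walk) {
    sim_config(params, n_agents = ov$n_agents %||% 64L, walk = walk,
               dt = ov$dt %||% 0.25, n_steps = ov$n_steps %||% 400L,
               injury_factor = ov$injury_factor %||% 1,
               forcing_period = ov$forcing_period %||% 2L,
               snapshot_every = ov$snapshot_every %||% 100L, seed = seed)
  }
  runs <- list(biased = run_simulation(net, cfg("biased")),
               random = run_simulation(net, cfg("random")))
  purrr::iwalk(runs, function(s, nm) {
    readr::write_csv(s$series,
                     file.path(out_dir, sprintf("fibrosis_%s.csv", nm)))
    if (nrow(s$snapshots)) {
      readr::write_csv(s$snapshots,
                       file.path(out_dir, sprintf("fibrosis_%s_snapshots.csv", nm)))
    }
  })
  dplyr::bind_rows(purrr::imap(runs, function(s, nm) {
    snaps <- s$snapshots
    tibble::tibble(walk = nm,
                   final_mean_k = s$series$mean_k[nrow(s$series)],
                   final_sd_k = s$series$sd_k[nrow(s$series)],
                   network_stiffness_first = snaps$network_stiffness[1L],
                   network_stiffness_last =
                     snaps$network_stiffness[nrow(snaps)])
  }))
}

scenario_aging <- function(ov, seed, out_dir) {
  reps <- ov$reps %||% 30L
  models <- list(baseline = baseline_params(), aging = aging_params())
  dplyr::bind_rows(purrr::imap(models, function(p, nm) {
    net <- scenario_network(ov, p)
    steps <- ov$n_steps %||% if (nm == "aging") 4000L else 800L
    cfg <- sim_config(p, n_agents = ov$n_agents %||% 64L,
                      walk = ov$walk %||% "biased", dt = ov$dt %||% 1,
                      n_steps = steps,
                      injury_factor = ov$injury_factor %||% 2, seed = seed)
    ens <- run_ensemble(net, cfg, n_reps = reps, base_seed = seed)
    readr::write_csv(ens$summary,
                     file.path(out_dir, sprintf("aging_%s.csv", nm)))
    dplyr::mutate(glance(ens), model = nm, .before = 1L)
  }))
}

#' Summarize scenario runs in a directory
#'
#' Scans `dir` (recursively) for run manifests written by [run_scenario()]
#' and binds their summary rows, one block per run, tagged with scenario,
#' seed and elapsed time. Corrupt manifests are skipped with a warning.
#'
#' @param dir Directory containing scenario output folders.
#' @return A tibble (zero rows, with header columns, if no manifests).
#' @export
summarize_runs <- function(dir) {
  manifests <- list.files(dir, pattern = "^manifest\\.json$",
                          recursive = TRUE, full.names = TRUE)
  empty <- tibble::tibble(scenario = character(), seed = integer(),
                          elapsed_sec = numeric())
  if (!length(manifests)) return(empty)
  rows <- purrr::map(manifests, function(f) {
    m <- tryCatch(jsonlite::read_json(f, simplifyVector = TRUE),
                  error = function(e) NULL)
    if (is.null(m) || is.null(m$scenario)) {
      warning("skipping corrupt manifest: ", f, call. = FALSE)
      return(NULL)
    }
    s <- tibble::as_tibble(m$summary)
    dplyr::mutate(s, scenario = m$scenario, seed = m$seed,
                  elapsed_sec = m$elapsed_sec, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) empty else out
}
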
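test_that("agent placement is seeded and can cover every node", {
  net <- fixture_net()
  a1 <- place_agents(net, 10, seed = 4, a0 = 0.5)
  a2 <- place_agents(net, 10, seed = 4, a0 = 0.5)
  expect_identical(a1, a2)
  all_nodes <- place_agents(net, nrow(net$nodes), seed = 1, replace = FALSE)
  expect_setequal(all_nodes$node, net$nodes$id)
  expect_error(place_agents(net, nrow(net$nodes) + 1, replace = FALSE),
               "without replacement")
})

test_that("migration probabilities follow the stiffness-share rule", {
  net <- fixture_net()
  v <- which(!net$nodes$boundary)[1]
  springs <- net$inc_springs[v, 1:3]
  net$springs$stiffness[springs] <- c(1, 1, 2)
  pb <- migration_probs(net, v, "biased")
  expect_equal(pb$prob[order(net$springs$stiffness[pb$spring])],
               c(0.25, 0.25, 0.5))
  pr <- migration_probs(net, v, "random")
  expect_equal(pr$prob, rep(1 / 3, 3))
  # uniform stiffness: the bias disappears
  expect_equal(migration_probs(fixture_net(), v, "biased")$prob, rep(1 / 3, 3))
  expect_equal(sum(pb$prob), 1)
  # boundary (degree-2) nodes generalize the rule
  b <- which(net$degree == 2L)[1]
  expect_equal(sum(migration_probs(net, b, "biased")$prob), 1)
  expect_length(migration_probs(net, b, "random")$prob, 2L)
})

test_that("the homeostatic state is an exact fixed point of the discrete map", {
  p <- baseline_pars()
  net <- fixture_net(p)
  fp <- fixed_point(p)
  for (walk in c("biased", "random")) {
    for (dt in c(0.5, 1, 1.9)) {
      cfg <- sim_config(p, n_agents = 40, walk = walk, dt = dt,
                        n_steps = 30, injury_factor = 1, seed = 2)
      sim <- run_simulation(net, cfg)
      expect_lt(max(abs(sim$series$mean_k - fp$k_star)), 1e-12)
      expect_lt(max(abs(sim$series$sd_k)), 1e-12)
      expect_lt(max(abs(sim$series$mean_activity - fp$a_star)), 1e-12)
      expect_equal(sim$series$halo_size, rep(0, 31))
    }
  }
})

test_that("injury heals: stiffness decays toward the set point and agents activate", {
  p <- baseline_pars()
  net <- fixture_net(p)
  fp <- fixed_point(p)
  cfg <- sim_config(p, n_agents = nrow(net$nodes), walk = "biased",
                    n_steps = 60, injury_factor = 2, seed = 5)
  sim <- run_simulation(net, cfg)
  s <- sim$series
  expect_equal(s$injured_k[1], 2 * fp$k_star)
  expect_equal(s$halo_size[1], 1)
  # densely visited injured spring declines from the outset
  expect_true(all(diff(s$injured_k[1:10]) <= 0))
  expect_gt(sum(diff(s$injured_k[1:10]) < 0), 3)
  # agents crossing the stiff spring raise their activity above a*
  expect_gt(max(s$mean_activity), fp$a_star)
  expect_lt(s$injured_k[61], 1.2 * fp$k_star)
})

test_that("agents are conserved and stay on valid nodes with bounded activity", {
  p <- baseline_pars()
  net <- fixture_net(p)
  cfg <- sim_config(p, n_agents = 25, walk = "biased", n_steps = 200,
                    injury_factor = 2, seed = 8)
  sim <- run_simulation(net, cfg)
  expect_equal(nrow(sim$agents), 25L)
  expect_true(all(sim$agents$node %in% net$nodes$id))
  expect_true(all(sim$agents$activity >= 0 & sim$agents$activity <= 1))
})

test_that("periodic forcing zeroes every agent's activity on schedule", {
  p <- baseline_pars()
  net <- fixture_net(p)
  cfg <- sim_config(p, n_agents = 30, n_steps = 12, injury_factor = 1,
                    forcing_period = 2L, seed = 3)
  sim <- run_simulation(net, cfg)
  even <- sim$series$step > 0 & sim$series$step %% 2 == 0
  expect_true(all(sim$series$mean_activity[even] == 0))
  expect_true(all(sim$series$mean_activity[!even & sim$series$step > 0] > 0))
  # forcing drives deposition: stiffness climbs above the set point
  expect_gt(sim$series$mean_k[13], fixed_point(p)$k_star)
})

test_that("halo-prohibited runs follow the imposed central-spring trajectory", {
  p <- baseline_pars()
  net <- fixture_net(p)
  fp <- fixed_point(p)
  traj <- seq(2 * fp$k_star, fp$k_star, length.out = 41)
  cfg <- sim_config(p, n_agents = 30, n_steps = 40, injury_factor = 2,
                    remodeling = FALSE, imposed_trajectory = traj, seed = 6)
  sim <- run_simulation(net, cfg)
  expect_equal(sim$series$injured_k, traj)
  # all other springs are untouched
  other <- setdiff(net$springs$id, sim$injured_spring)
  expect_equal(sim$net$springs$stiffness[other],
               net$springs$stiffness[other])
  expect_error(sim_config(p, remodeling = FALSE), "imposed_trajectory")
})

test_that("ensembles are reproducible and use base_seed + replicate seeds", {
  p <- baseline_pars()
  net <- fixture_net(p)
  cfg <- sim_config(p, n_agents = 30, n_steps = 80, injury_factor = 2)
  e1 <- run_ensemble(net, cfg, n_reps = 3, base_seed = 50)
  e2 <- run_ensemble(net, cfg, n_reps = 3, base_seed = 50)
  expect_identical(e1$halo, e2$halo)
  expect_identical(e1$injured_k, e2$injured_k)
  cfg1 <- cfg; cfg1$seed <- 51L
  sim1 <- run_simulation(net, cfg1)
  expect_equal(e1$injured_k[, 1], sim1$series$injured_k)
  expect_equal(resolution_time(e1), e1$resolution_steps)
})

test_that("healing completes and more agents heal faster", {
  p <- baseline_pars()
  net <- fixture_net(p)
  cfg <- function(n) sim_config(p, n_agents = n, walk = "biased",
                                n_steps = 900, injury_factor = 2)
  few <- run_ensemble(net, cfg(32), n_reps = 10, base_seed = 21)
  many <- run_ensemble(net, cfg(128), n_reps = 10, base_seed = 21)
  # ensemble-median halo reaches zero and the injury stays repaired
  expect_true(all(!is.na(few$resolution_steps)))
  expect_true(all(!is.na(many$resolution_steps)))
  k_star <- net$k_star_reference
  expect_lt(median(abs(few$injured_k[901, ] - k_star)) / k_star, 0.001)
  expect_equal(median(few$halo[901, ]), 0)
  expect_lt(median(many$resolution_steps), median(few$resolution_steps))
})

test_that("network decay tracks the analytic relaxation from above", {
  p <- baseline_pars()
  net <- fixture_net(p, rows = 6, cols = 6)
  fp <- fixed_point(p)
  cfg <- sim_config(p, n_agents = nrow(net$nodes), walk = "biased",
                    dt = 0.5, n_steps = 200, injury_factor = 2)
  ens <- run_ensemble(net, cfg, n_reps = 10, base_seed = 2)
  tt <- pmax(ens$summary$time, 1e-9)
  ode <- integrate_model(p, fp$a_star, 2 * fp$k_star, t_end = max(tt),
                         times = tt)
  # migrating agents can only dilute, never exceed, the resident-agent rate
  expect_true(all(ens$summary$injured_k_mean >= ode$k - 0.02 * ode$k))
  # and the injury still resolves on the analytic horizon
  expect_lt(abs(ens$summary$injured_k_mean[201] - fp$k_star) / fp$k_star, 0.02)
})

test_that("aging parameters reproduce the slowed-healing operating point", {
  ap <- aging_params()
  expect_equal(ap$q, 0.4)
  expect_equal(ap$D, 0.08)
  expect_equal(ap$P / ap$D, 8 / 15)
  expect_equal(signif(ap$P, 3), 0.0427)
  fp <- fixed_point(ap)
  expect_equal(fp$k_star, 2)
  expect_equal(fp$a_star, 2 / 3)
  expect_equal(production_for_fixed_point(2, 0.4, 0.08), ap$P)
})

test_that("rank comparison flags ties and detects separated ensembles", {
  m <- matrix(rep(c(0, 1, 3, 2, 0), each = 30), nrow = 5, byrow = TRUE)
  same <- compare_series(m, m)
  expect_true(all(same$degenerate[c(1, 5)]))
  expect_true(all(same$p_value[!same$degenerate] > 0.9))
  shifted <- compare_series(m, m + 10)
  expect_true(all(shifted$p_value[!shifted$degenerate] < 1e-6))
  expect_match(attr(shifted, "test"), "Mann-Whitney")
  set.seed(1)
  noisy_a <- matrix(rpois(5 * 30, 3), nrow = 5)
  noisy_b <- noisy_a + 5L
  cs <- compare_series(noisy_a, noisy_b)
  expect_true(all(cs$p_value < 0.01))
})
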
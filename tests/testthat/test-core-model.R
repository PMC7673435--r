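test_that("nondimensionalization collapses the six dimensional parameters", {
  # unit alpha, A, Q leave the triple unchanged
  p <- nondimensionalize(dimensional_params(alpha = 1, A = 1, Q = 1,
                                            q_prime = 0.2, D_prime = 0.32,
                                            P_prime = 0.1))
  expect_equal(p$q, 0.2)
  expect_equal(p$D, 0.32)
  expect_equal(p$P, 0.1)
  # D = A D'/alpha and P = P'/(alpha Q)
  expect_equal(nondimensionalize(dimensional_params(alpha = 2, D_prime = 0.64,
                                                    P_prime = 0.1))$D, 0.32)
  expect_equal(nondimensionalize(dimensional_params(alpha = 2, Q = 2,
                                                    P_prime = 0.4))$P, 0.1)
  expect_error(dimensional_params(q_prime = 1.5, A = 1), "q_prime")
  expect_error(dimensional_params(alpha = -1), "> 0")
})

test_that("parameter constructors enforce their domains", {
  expect_error(model_params(q = 1.2), "q")
  expect_error(model_params(q = 0), "q")
  expect_error(model_params(D = -0.1), "D")
  expect_error(model_params(P = -0.1), "P")
  expect_s3_class(model_params(P = 0), "selfheal_params")
})

test_that("rhs matches direct evaluation of the rate equations", {
  p <- baseline_pars()
  fp <- fixed_point(p)
  r <- model_rhs(fp$a_star, fp$k_star, p)
  expect_equal(r$da, 0, tolerance = 1e-12)
  expect_equal(r$dk, 0, tolerance = 1e-12)
  # k = 0 annihilates both stiffness terms, leaving (0, P)
  r0 <- model_rhs(0, 0, p)
  expect_equal(r0$da, 0)
  expect_equal(r0$dk, p$P)
  # independent hand evaluation at a doubled-stiffness state
  a <- 0.50559; k <- 2 * 1.022612
  r2 <- model_rhs(a, k, p)
  expect_equal(r2$da, k / (1 + k) - a, tolerance = 1e-12)
  expect_equal(r2$da, 0.16603, tolerance = 1e-4)
  expect_equal(r2$dk, -0.32 * k * (a - 0.2) + 0.1, tolerance = 1e-12)
  expect_equal(r2$dk, -0.10001, tolerance = 1e-4)
  expect_error(model_rhs(1.5, 1, p), "a")
  expect_error(model_rhs(0.5, -1, p), "k")
})

test_that("constant-stiffness limit decays exponentially to baseline", {
  expect_equal(activity_relaxation(c(0, 1, 10), beta = 0.3, W = 0), rep(0.3, 3))
  expect_equal(activity_relaxation(0, beta = 0, W = 1, alpha = 1), 1)
  expect_equal(activity_relaxation(1e6, beta = 0.3, W = 5, alpha = 1), 0.3)
})

test_that("fixed point reproduces the baseline and aging operating points", {
  fp <- fixed_point(baseline_pars())
  expect_equal(fp$a_star, 0.50559, tolerance = 1e-5)
  expect_equal(fp$k_star, 1.022612, tolerance = 1e-6)
  expect_equal(fp$a_star, fp$k_star / (1 + fp$k_star))
  # degenerate P = 0 closed form: a* = q, k* = q/(1-q), independent of D
  for (D in c(0.01, 0.32, 5)) {
    fp0 <- fixed_point(model_params(q = 0.2, D = D, P = 0))
    expect_equal(fp0$a_star, 0.2)
    expect_equal(fp0$k_star, 0.25)
  }
  fpa <- fixed_point(aging_params())
  expect_equal(fpa$k_star, 2, tolerance = 1e-12)
  expect_equal(fpa$a_star, 2 / 3, tolerance = 1e-12)
  expect_equal(tidy(fp)$k_star, fp$k_star)
})

test_that("jacobian agrees with central finite differences", {
  p <- baseline_pars()
  fp <- fixed_point(p)
  states <- rbind(c(fp$a_star, fp$k_star), c(0.3, 0.05), c(0.2, 1.7),
                  c(0.9, 0.4), c(0.1, 3))
  h <- 1e-6
  for (i in seq_len(nrow(states))) {
    a <- states[i, 1]; k <- states[i, 2]
    J <- model_jacobian(a, k, p)
    fd <- function(da, dk) {
      rp <- model_rhs(a + da, k + dk, p)
      rm <- model_rhs(a - da, k - dk, p)
      c(rp$da - rm$da, rp$dk - rm$dk) / (2 * (da + dk))
    }
    num <- cbind(fd(h, 0), fd(0, h))
    expect_equal(unname(J), unname(num), tolerance = 1e-6)
  }
  # structural entries
  expect_equal(model_jacobian(0.5, 0, p)[1, 2], 1)
  expect_equal(model_jacobian(p$q, 1.3, p)[2, 2], 0)
})

test_that("stability holds whenever D < 1 and trace matches hand arithmetic", {
  rep <- stability_report(baseline_pars())
  expect_true(rep$stable)
  expect_true(rep$sufficient_D_lt_1)
  expect_equal(rep$trace, -1 - 0.32 * (fixed_point(baseline_pars())$a_star - 0.2))
  expect_equal(rep$trace, -1.0978, tolerance = 1e-4)
  set.seed(11)
  for (i in 1:200) {
    p <- model_params(q = runif(1, 0.02, 0.98), D = runif(1, 0.02, 0.99),
                      P = runif(1, 0.001, 2))
    expect_true(stability_report(p)$stable)
  }
  expect_equal(tidy(rep)$determinant, rep$determinant)
})

test_that("stationarity residual vanishes at the fixed point across parameter space", {
  set.seed(101)
  for (i in 1:1000) {
    p <- model_params(q = runif(1, 0.01, 0.99), D = runif(1, 0.01, 2),
                      P = runif(1, 0.001, 2))
    fp <- fixed_point(p)
    expect_gt(fp$k_star, 0)
    r <- model_rhs(fp$a_star, fp$k_star, p)
    expect_lt(abs(r$da), 1e-12)
    expect_lt(abs(r$dk), 1e-12)
  }
})

test_that("fixed point is continuous as production vanishes", {
  q <- 0.35; D <- 0.6
  limit <- fixed_point(model_params(q, D, P = 0))
  for (P in 10^(-c(4, 6, 8, 10))) {
    fp <- fixed_point(model_params(q, D, P))
    expect_equal(fp$k_star, limit$k_star, tolerance = 100 * P)
  }
})

test_that("integration holds the fixed point and relaxes perturbations to it", {
  p <- baseline_pars()
  fp <- fixed_point(p)
  tr0 <- integrate_model(p, fp$a_star, fp$k_star, t_end = 50)
  expect_lt(max(abs(tr0$k - fp$k_star)), 1e-7)
  expect_lt(max(abs(tr0$a - fp$a_star)), 1e-7)
  tr <- integrate_model(p, fp$a_star, 2 * fp$k_star, t_end = 200)
  expect_lt(abs(tr$k[nrow(tr)] - fp$k_star) / fp$k_star, 0.001)
  expect_true(all(diff(tr$k) <= 1e-9))  # monotone decay from above
})

test_that("the relaxation is not a single exponential", {
  p <- baseline_pars()
  fp <- fixed_point(p)
  # damage side (k0 = k*/2): the early log-residual slope is visibly
  # shallower than the asymptotic one, so the decay is not one exponential
  tr <- integrate_model(p, fp$a_star, 0.5 * fp$k_star, t_end = 80,
                        times = seq(0, 80, by = 0.5))
  lr <- log(abs(tr$k - fp$k_star))
  slope <- function(win) {
    sel <- tr$t >= win[1] & tr$t <= win[2] & is.finite(lr)
    unname(coef(lm(lr[sel] ~ tr$t[sel]))[2])
  }
  expect_lt(abs(slope(c(0, 5))) / abs(slope(c(40, 80))), 0.95)
  # scarring side: activity makes a brief excursion away from its fixed
  # point before relaxing back -- non-monotone, hence non-exponential
  tr2 <- integrate_model(p, fp$a_star, 2 * fp$k_star, t_end = 80,
                         times = seq(0, 80, by = 0.1))
  expect_gt(max(tr2$a), fp$a_star + 0.05)
  expect_equal(tr2$a[nrow(tr2)], fp$a_star, tolerance = 1e-5)
})

test_that("matched fixed points relax slower at low digestion rate", {
  low_D <- model_params(0.2, 0.08, 0.1)
  high_P <- model_params(0.2, 0.32, 0.4)
  fp1 <- fixed_point(low_D); fp2 <- fixed_point(high_P)
  expect_equal(fp1$k_star, fp2$k_star, tolerance = 1e-12)
  expect_equal(fp1$a_star, fp2$a_star, tolerance = 1e-12)
  t_reach <- function(p, fp) {
    tr <- integrate_model(p, fp$a_star, 2 * fp$k_star, t_end = 300,
                          times = seq(0, 300, by = 0.25))
    tr$t[which(abs(tr$k - fp$k_star) / fp$k_star < 0.01)[1]]
  }
  expect_gt(t_reach(low_D, fp1), t_reach(high_P, fp2))
})

test_that("fixed-point sweeps reproduce the qualitative parameter dependences", {
  p <- baseline_pars()
  swD <- fixed_point_sweep(p, "D", seq(0.05, 1.2, length.out = 30))
  expect_true(all(diff(swD$a_star) < 0))
  expect_true(all(diff(swD$k_star) < 0))
  swP <- fixed_point_sweep(p, "P", seq(0.02, 1.5, length.out = 30))
  expect_true(all(diff(swP$k_star) > 0))
  swq <- fixed_point_sweep(p, "q", c(seq(0.1, 0.9, by = 0.1), 0.99, 0.999))
  expect_true(all(diff(swq$k_star) > 0))
  expect_gt(max(swq$k_star), 1e2)  # k* grows without bound as q -> 1
  # inadmissible grid values are flagged, not dropped
  expect_warning(sw_bad <- fixed_point_sweep(p, "q", c(0.5, 1.2)), "inadmissible")
  expect_equal(sw_bad$ok, c(TRUE, FALSE))
  expect_true(is.na(sw_bad$k_star[2]))
})
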
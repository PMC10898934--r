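# Frozen 3-variant fixture used across estimator oracles.
fix3 <- function() make_pair(gamma = c(0.1, 0.2, 0.15),
                             Gamma = c(0.02, 0.05, 0.03),
                             se_x = c(0.01, 0.01, 0.01),
                             se_y = c(0.01, 0.01, 0.02))

test_that("all estimators return the exact common ratio on noiseless input", {
  ss <- simulate_summary_stats(12, true_effect = 0.25, noise = FALSE,
                               n_palindromic = 0, seed = 1)
  expect_equal(mr_ivw(ss)$theta, 0.25, tolerance = 1e-12)
  expect_equal(mr_egger(ss)$theta, 0.25, tolerance = 1e-8)
  expect_equal(mr_weighted_median(ss, bootstrap = 0)$theta, 0.25,
               tolerance = 1e-12)
  expect_equal(mr_weighted_mode(ss, bootstrap = 0)$theta, 0.25,
               tolerance = 1e-12)
  expect_equal(mr_ivw(ss)$Q, 0, tolerance = 1e-20)
})

test_that("IVW equals the hand-computed weighted mean of ratios and the
           weighted-regression formulation to 1e-12", {
  p <- fix3()
  g <- p$exposure$beta; G <- p$outcome$beta; sy <- p$outcome$se
  # oracle 1: weighted mean of ratios
  w <- g^2 / sy^2
  theta_wm <- sum(w * (G / g)) / sum(w)
  # oracle 2: zero-intercept weighted regression of Gamma on gamma
  theta_wls <- sum(g * G / sy^2) / sum(g^2 / sy^2)
  expect_equal(theta_wm, theta_wls, tolerance = 1e-14)

  est <- mr_ivw(p$exposure, p$outcome)
  expect_equal(est$theta, theta_wm, tolerance = 1e-12)
  # fixed-effect SE and Q from the definitions
  est_f <- mr_ivw(p$exposure, p$outcome, model = "fixed")
  expect_equal(est_f$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_equal(est$Q, sum(w * (G / g - theta_wm)^2), tolerance = 1e-12)
})

test_that("IVW inflates but never deflates the fixed-effect SE", {
  p <- fix3()
  fe <- mr_ivw(p$exposure, p$outcome, model = "fixed")
  re <- mr_ivw(p$exposure, p$outcome, model = "random")
  expect_gte(re$se, fe$se)
  # homogeneous input: random-effects SE equals fixed-effect SE
  ss <- simulate_summary_stats(6, true_effect = 0.1, noise = FALSE,
                               n_palindromic = 0, seed = 2)
  expect_equal(mr_ivw(ss, model = "random")$se,
               mr_ivw(ss, model = "fixed")$se)
})

test_that("MR-Egger recovers an exact linear construction", {
  g <- c(0.08, 0.12, 0.2, 0.3)
  G <- 0.01 + 0.3 * g
  p <- make_pair(g, G, se_x = 0.01, se_y = 0.01)
  est <- mr_egger(p$exposure, p$outcome)
  expect_equal(est$theta, 0.3, tolerance = 1e-10)
  expect_equal(est$intercept, 0.01, tolerance = 1e-10)
  expect_equal(est$Q, 0, tolerance = 1e-16)
})

test_that("MR-Egger matches a hand-solved 2x2 weighted normal system", {
  p <- fix3()
  g <- p$exposure$beta; G <- p$outcome$beta; w <- 1 / p$outcome$se^2
  # normal equations for (intercept, slope), solved by Cramer's rule
  s0 <- sum(w); s1 <- sum(w * g); s2 <- sum(w * g^2)
  t0 <- sum(w * G); t1 <- sum(w * g * G)
  det <- s0 * s2 - s1^2
  b0 <- (s2 * t0 - s1 * t1) / det
  b1 <- (s0 * t1 - s1 * t0) / det
  est <- mr_egger(p$exposure, p$outcome)
  expect_equal(est$theta, b1, tolerance = 1e-10)
  expect_equal(est$intercept, b0, tolerance = 1e-10)

  # I2_GX from its definition
  wx <- 1 / p$exposure$se^2
  gbar <- sum(wx * g) / sum(wx)
  Qx <- sum(wx * (g - gbar)^2)
  expect_equal(est$i2gx, (Qx - 2) / Qx, tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative-weight definition", {
  # symmetric equal-weight triple: the middle ratio
  p <- make_pair(c(1, 1, 1), c(0.1, 0.2, 0.3), se_x = 0.01, se_y = 0.1)
  expect_equal(mr_weighted_median(p$exposure, p$outcome,
                                  bootstrap = 0)$theta, 0.2)

  # 4 unequal-weight ratios: evaluate the interpolation formula by hand
  g <- c(1, 1, 1, 1)
  G <- c(0.1, 0.2, 0.4, 0.8)
  sy <- c(0.1, 0.2, 0.1, 0.2)
  w <- (g^2 / sy^2); w <- w / sum(w)      # 0.4, 0.1, 0.4, 0.1 ordered
  s <- cumsum(w) - w / 2                  # 0.2, 0.45, 0.7, 0.95
  # crossing of 0.5 between ratios 2 and 3
  oracle <- 0.2 + (0.4 - 0.2) * (0.5 - s[2]) / (s[3] - s[2])
  est <- mr_weighted_median(make_stats(g, 0.01), make_stats(G, sy),
                            bootstrap = 0)
  expect_equal(est$theta, oracle, tolerance = 1e-12)
})

test_that("weighted mode finds the density argmax of the ratio set", {
  # all ratios equal: mode is that value at any bandwidth
  p <- make_pair(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2), 0.01, 0.01)
  expect_equal(mr_weighted_mode(p$exposure, p$outcome,
                                bootstrap = 0)$theta, 0.5)

  # 3-vs-1 cluster with small bandwidth: mode at the cluster, and the
  # estimate matches a direct evaluation of the kernel density argmax
  g <- rep(1, 4); G <- c(0.1, 0.1, 0.1, 0.5); sy <- rep(0.1, 4)
  est <- mr_weighted_mode(make_stats(g, 0.01), make_stats(G, sy),
                          bandwidth_factor = 0.5, bootstrap = 0)
  th <- G / g; w <- rep(0.25, 4)
  spread <- if (mad(th) > sd(th) * 1e-8) min(sd(th), mad(th)) else sd(th)
  h <- 0.5 * 0.9 * spread * 4^(-1 / 5)
  grid <- seq(min(th) - 3 * h, max(th) + 3 * h, length.out = 2048)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - th) / h)),
                 numeric(1))
  expect_equal(est$theta, grid[which.max(dens)])
  expect_lt(abs(est$theta - 0.1), 0.02)
})

test_that("bootstrap standard errors are reproducible and leave the RNG
           state untouched", {
  ss <- simulate_summary_stats(10, true_effect = 0.1, seed = 4)
  h <- harmonize(ss$exposure, ss$outcome)
  set.seed(123); before <- rnorm(1)
  e1 <- mr_weighted_median(h, bootstrap = 200, seed = 42)
  e2 <- mr_weighted_median(h, bootstrap = 200, seed = 42)
  expect_equal(e1$se, e2$se)
  set.seed(123)
  expect_equal(rnorm(1), before)
})

test_that("estimates are equivariant under exposure-unit rescaling", {
  p <- fix3()
  scaled <- p
  scaled$exposure$beta <- p$exposure$beta * 3
  scaled$exposure$se <- p$exposure$se * 3
  for (f in list(mr_ivw, mr_egger,
                 function(a, b) mr_weighted_median(a, b, bootstrap = 0),
                 function(a, b) mr_weighted_mode(a, b, bootstrap = 0))) {
    expect_equal(f(scaled$exposure, scaled$outcome)$theta,
                 f(p$exposure, p$outcome)$theta / 3, tolerance = 1e-10)
  }
})

test_that("estimators refuse unharmonized or degenerate input", {
  ss <- simulate_summary_stats(5, true_effect = 0, seed = 2)
  bad <- ss$outcome[5:1, ]
  expect_error(mr_ivw(ss$exposure, bad), "not harmonized")
  one <- make_pair(0.1, 0.02, 0.01, 0.01)
  expect_error(mr_ivw(one$exposure, one$outcome), "at least 2")
  two <- make_pair(c(0.1, 0.2), c(0.02, 0.05), 0.01, 0.01)
  expect_error(mr_egger(two$exposure, two$outcome), "at least 3")
  zero <- make_pair(c(0, 0.2, 0.1), c(0.01, 0.05, 0.02), 0.01, 0.01)
  expect_error(mr_ivw(zero$exposure, zero$outcome), "exactly zero")
})

test_that("the Wald ratio and its delta-method SE match plug-in arithmetic", {
  # beta_Y = 0.02, beta_X = 0.5, se_Y = 0.01, se_X = 0.05
  se <- adipomr:::delta_ratio_se(0.02, 0.5, 0.01, 0.05)
  expect_equal(0.02 / 0.5, 0.04)
  expect_equal(se, sqrt(0.01^2 / 0.5^2 + 0.02^2 * 0.05^2 / 0.5^4),
               tolerance = 1e-15)
})

test_that("a null instrument-outcome association gives causal RR 1", {
  coh <- simulate_cohort(sim_config(n_individuals = 4000,
                                    outcome_base_rate = 0.01, seed = 17))
  sc <- build_score(coh, "internal")
  est <- mr_wald(coh, sc)
  expect_s3_class(est, "mr_estimate")
  expect_equal(est$rr, exp(est$theta))
  # CI transforms monotonically
  expect_equal(est$rr_ci, exp(est$ci))
  expect_true(est$ci[1] < est$theta && est$theta < est$ci[2])
})

test_that("MR power obeys its closed form and monotonicity", {
  expect_equal(mr_power(1e5, 0.03, 0.1, effect = 0), pnorm(qnorm(0.025)))
  # inversion identity: ncp = z_{0.975} + z_{0.80} gives power 0.80
  ncp <- qnorm(0.975) + qnorm(0.80)
  eff <- ncp / sqrt(1e5 * 0.03 * 0.1 * 0.9)
  expect_equal(mr_power(1e5, 0.03, 0.1, effect = eff), 0.80,
               tolerance = 1e-12)
  grid_n <- c(1e4, 5e4, 1e5)
  pw <- vapply(grid_n, function(n) mr_power(n, 0.03, 0.1, effect = 0.2),
               numeric(1))
  expect_true(all(diff(pw) > 0))
  pw2 <- vapply(c(0.01, 0.03, 0.1), function(r2)
    mr_power(5e4, r2, 0.1, effect = 0.2), numeric(1))
  expect_true(all(diff(pw2) > 0))
})
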
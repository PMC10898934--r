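# wrap a bare survival data.frame as the cohort the fitters expect
as_cohort <- function(d) {
  structure(
    data.frame(id = seq_len(nrow(d)),
               g1 = 0L,
               exposure = if (is.null(d$exposure)) exp(d$z) else d$exposure,
               log_exposure = if (is.null(d$exposure)) d$z else
                 log(d$exposure),
               measured = TRUE, sex = 0L, confounder = 0,
               age_entry = d$entry, age_exit = d$exit, event = d$event),
    class = c("cohort_table", "data.frame"))
}

test_that("one-event toy data reproduces the closed-form partial
           likelihood maximum", {
  # two individuals at risk at the single event time; covariate z = 0/1,
  # the z = 1 individual dies: l(b) = b - log(1 + e^b), maximized as
  # b -> Inf, so instead use three individuals with two events where the
  # maximum is finite: events at t=1 (z=1) and t=2 (z=0), risk sets
  # {1,2,3} then {2,3} with z = (1,0,0):
  # l(b) = b - log(e^b + 2) - log(2)... solved analytically: dl/db =
  # 1 - e^b/(e^b + 2) = 0 has no root; use z = (1,0,1) instead:
  # risk set 1: {1,2,3}, death z=1; risk set 2: {2,3}, death z=0
  # l(b) = b - log(2 e^b + 1) + 0 - log(e^b + 1)
  d <- data.frame(entry = c(0, 0, 0), exit = c(1, 2, 2),
                  event = c(1, 1, 0), z = c(1, 0, 1))
  nll <- function(b) -(b - log(2 * exp(b) + 1) - log(exp(b) + 1))
  oracle <- optimize(nll, c(-5, 5))$minimum
  fit <- fit_cox(as_cohort(d), encoding = "log")
  expect_equal(unname(coef(fit)[".x"]), oracle, tolerance = 1e-5)
})

test_that("the Cox engine matches a brute-force Efron grid maximization
           on a 30-row tied fixture to 1e-4", {
  d <- tied_cox_fixture()
  fit <- fit_cox(as_cohort(d), encoding = "log", covariates = character(0))
  grid <- seq(-2, 2, by = 1e-5)
  # coarse-to-fine grid search of the hand-written partial likelihood
  coarse <- seq(-2, 2, by = 0.01)
  llc <- vapply(coarse, efron_loglik, numeric(1), d = d)
  b0 <- coarse[which.max(llc)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, efron_loglik, numeric(1), d = d)
  oracle <- fine[which.max(llf)]
  expect_equal(unname(coef(fit)[".x"]), oracle, tolerance = 1e-4)
})

test_that("Efron and Breslow tie handling agree when there are no ties", {
  set.seed(77)
  d <- data.frame(entry = runif(40, 50, 55),
                  exit = NA, event = rbinom(40, 1, 0.6),
                  z = rnorm(40))
  d$exit <- d$entry + runif(40, 0.1, 10)   # continuous: no ties
  ce <- coef(fit_cox(as_cohort(d), encoding = "log", ties = "efron"))
  cb <- coef(fit_cox(as_cohort(d), encoding = "log", ties = "breslow"))
  expect_equal(ce, cb, tolerance = 1e-10)
})

test_that("coefficients rescale exactly under exposure-unit changes", {
  coh <- simulate_cohort(sim_config(n_individuals = 3000,
                                    outcome_base_rate = 0.02, seed = 31))
  f1 <- fit_cox(coh, encoding = "linear")
  coh2 <- coh
  coh2$exposure <- coh$exposure * 10     # e.g. per 10 ug/mL
  f2 <- fit_cox(coh2, encoding = "linear")
  expect_equal(unname(coef(f2)[".x"]) * 10, unname(coef(f1)[".x"]),
               tolerance = 1e-6)
})

test_that("delayed entry keeps individuals out of earlier risk sets", {
  # an individual entering after every event time must not influence
  # the fit: compare with and without a late entrant
  d <- data.frame(entry = c(0, 0, 0, 9), exit = c(2, 4, 6, 10),
                  event = c(1, 1, 0, 0), z = c(1, 0, 1, 1))
  f_all <- fit_cox(as_cohort(d), encoding = "log")
  f_sub <- fit_cox(as_cohort(d[1:3, ]), encoding = "log")
  expect_equal(coef(f_all), coef(f_sub), tolerance = 1e-8)
})

test_that("null-effect coverage: log HR within 2 SE of zero in most
           replicates", {
  set.seed(41)
  hits <- replicate(100, {
    coh <- simulate_cohort(sim_config(
      n_individuals = 1500, outcome_base_rate = 0.02,
      seed = sample.int(1e6, 1)))
    fit <- fit_cox(coh, encoding = "log", covariates = "sex")
    b <- coef(fit)[".x"]
    se <- sqrt(vcov(fit)[".x", ".x"])
    abs(b) < 2 * se
  })
  expect_gte(sum(hits), 93)
})

test_that("restricted cubic spline basis is linear beyond the boundary
           knots and smooth at the knots", {
  knots <- c(1, 2, 3, 5, 8)
  f_at <- function(x) rcs_basis(x, knots) %*% c(0.5, 1, -2, 0.7)
  # second differences vanish outside the boundary knots
  for (x0 in c(0.2, 0.5, 8.5, 9.5)) {
    d2 <- (f_at(x0 + 0.01) - 2 * f_at(x0) + f_at(x0 - 0.01)) / 0.01^2
    expect_lt(abs(d2), 1e-6)
  }
  # continuity and C1 at each interior knot by finite differences
  for (k in knots) {
    eps <- 1e-6
    expect_lt(abs(f_at(k + eps) - f_at(k - eps)), 1e-4)
    d_left <- (f_at(k) - f_at(k - eps)) / eps
    d_right <- (f_at(k + eps) - f_at(k)) / eps
    expect_lt(abs(d_left - d_right), 1e-3)
  }
})

test_that("the spline hazard-ratio curve is 1 with zero-width CI at the
           reference", {
  coh <- simulate_cohort(sim_config(n_individuals = 4000,
                                    outcome_base_rate = 0.02, seed = 33))
  fit <- fit_cox(coh, encoding = "spline")
  ref <- 16
  cv <- spline_curve(fit, reference = ref, grid = c(5, ref, 40))
  at_ref <- cv[cv$x == ref, ]
  expect_equal(at_ref$hr, 1)
  expect_equal(at_ref$ci_low, 1)
  expect_equal(at_ref$ci_high, 1)
  expect_error(spline_curve(fit, reference = 1e6), "outside")
  lin <- fit_cox(coh, encoding = "log")
  expect_error(spline_curve(lin), "spline")
})

test_that("under a log-linear truth the spline curve tracks the true
           line over the interior of the grid", {
  coh <- simulate_cohort(sim_config(n_individuals = 30000,
                                    true_causal_effect = 0.6,
                                    outcome_base_rate = 0.02, seed = 34))
  fit <- fit_cox(coh, encoding = "spline", covariates = "sex")
  xr <- quantile(coh$exposure, c(0.05, 0.95))
  grid <- seq(xr[1], xr[2], length.out = 50)
  ref <- median(coh$exposure)
  cv <- spline_curve(fit, reference = ref, grid = grid)
  truth <- exp(0.6 * (log(grid) - log(ref)))
  inside <- truth >= cv$ci_low & truth <= cv$ci_high
  expect_gte(mean(inside), 0.9)
})

test_that("a U-shaped truth yields a curve minimum near the true minimum", {
  # build event times by hand with a quadratic log-hazard in log X
  set.seed(35)
  n <- 30000
  lx <- rnorm(n, log(16), 0.5)
  entry <- runif(n, 40, 80)
  rate <- 0.02 * exp(0.8 * (lx - log(16))^2)
  t_ev <- rexp(n, rate)
  d <- data.frame(entry = entry, exit = entry + pmin(t_ev, 15),
                  event = as.integer(t_ev <= 15), exposure = exp(lx),
                  z = lx)
  fit <- fit_cox(as_cohort(d), encoding = "spline",
                 covariates = character(0))
  cv <- spline_curve(fit, grid = exp(seq(log(6), log(45),
                                         length.out = 200)))
  x_min <- cv$x[which.min(cv$hr)]
  knots_nat <- exp(fit$knots)
  k_int <- max(diff(knots_nat))
  expect_lt(abs(x_min - 16), k_int)
})

test_that("quartile geometric means match the closed form and degenerate
           exposure fails", {
  vals <- c(1, 2, 4, 8)
  coh <- simulate_cohort(sim_config(n_individuals = 4000,
                                    outcome_base_rate = 0.02, seed = 36))
  coh$exposure <- rep(vals, each = 1000)
  coh$log_exposure <- log(coh$exposure)
  qa <- quartile_analysis(coh)
  expect_equal(qa$geo_mean, vals)          # constant within quartile
  expect_equal(qa$hr[1], 1)
  expect_equal(qa$n, rep(1000, 4))

  coh$exposure <- rep(2, 4000)
  expect_error(quartile_analysis(coh), "4 distinct")
})

test_that("follow-up exclusion removes exactly the short-follow-up rows", {
  d <- data.frame(entry = c(50, 51, 52, 53, 54),
                  exit = c(50.5, 52.5, 54, 56, 64),
                  event = c(1, 1, 0, 1, 0), z = rnorm(5))
  coh <- as_cohort(d)
  expect_equal(nrow(exclude_early_followup(coh, 0)), 5)  # identity
  ex2 <- exclude_early_followup(coh, 2)
  expect_equal(nrow(ex2), 3)               # follow-ups 0.5 and 1.5 drop
  expect_equal(attr(ex2, "n_removed"), 2)
  cen <- exclude_early_followup(coh, 2, mode = "censor")
  expect_equal(nrow(cen), 5)
  expect_equal(sum(cen$event), 1)          # early events censored
  expect_error(exclude_early_followup(coh, -1), ">= 0")
})

test_that("early-risk truth: top-vs-bottom quartile HR attenuates as the
           exclusion window grows", {
  # all excess hazard of high exposure concentrated in the first 2 years
  set.seed(37)
  n <- 20000
  lx <- rnorm(n, log(16), 0.5)
  hi <- lx > quantile(lx, 0.75)
  entry <- runif(n, 50, 70)
  rate_early <- 0.03 * exp(1.5 * hi)
  rate_late <- 0.03
  t1 <- rexp(n, rate_early)
  t2 <- 2 + rexp(n, rate_late)
  t_ev <- ifelse(t1 <= 2, t1, t2)
  d <- data.frame(entry = entry, exit = entry + pmin(t_ev, 12),
                  event = as.integer(t_ev <= 12), exposure = exp(lx),
                  z = lx)
  coh <- as_cohort(d)
  hr_at <- function(years) {
    qa <- quartile_analysis(exclude_early_followup(coh, years),
                            covariates = character(0))
    qa$hr[4]
  }
  hrs <- vapply(c(0, 1, 2, 4), hr_at, numeric(1))
  expect_gt(hrs[1], 1.3)                   # strong early association
  expect_true(all(hrs[-1] < hrs[1]))       # attenuates toward null
  expect_lt(abs(log(hrs[4])), 0.2)         # near 1 once early risk gone
})

test_that("interaction LRT is near zero on duplicated strata and holds
           level / power in simulation", {
  # duplicated strata with identical structure: no interaction signal
  set.seed(38)
  base <- data.frame(entry = runif(200, 50, 60), z = rnorm(200))
  base$exit <- base$entry + rexp(200, 0.05 * exp(0.3 * base$z))
  base$exit <- pmin(base$exit, base$entry + 10)
  base$event <- as.integer(base$exit < base$entry + 10)
  d <- rbind(base, base)
  coh <- as_cohort(d)
  coh$sex <- rep(0:1, each = 200)
  out <- interaction_lrt(coh, modifier = "sex",
                         covariates = character(0))
  expect_lt(out$statistic, 1e-8)
  expect_gt(out$p, 0.999)

  # power against a built-in sex-by-exposure interaction
  power_hits <- replicate(25, {
    n <- 4000
    lx <- rnorm(n, log(16), 0.5)
    sex <- rbinom(n, 1, 0.5)
    entry <- runif(n, 50, 70)
    rate <- 0.02 * exp((0.2 + 0.8 * sex) * (lx - log(16)))
    t_ev <- rexp(n, rate)
    d <- data.frame(entry = entry, exit = entry + pmin(t_ev, 10),
                    event = as.integer(t_ev <= 10), exposure = exp(lx),
                    z = lx)
    coh <- as_cohort(d)
    coh$sex <- sex
    interaction_lrt(coh, modifier = "sex",
                    covariates = "sex")$p < 0.05
  })
  expect_gt(mean(power_hits), 0.8)
})

test_that("interaction LRT type-I error is near nominal under the null", {
  set.seed(39)
  rej <- replicate(200, {
    coh <- simulate_cohort(sim_config(
      n_individuals = 1200, outcome_base_rate = 0.03,
      seed = sample.int(1e6, 1)))
    interaction_lrt(coh, modifier = "sex", covariates = "sex")$p < 0.05
  })
  # binomial(200, 0.05): allow ~3 MC standard errors
  expect_lt(abs(mean(rej) - 0.05), 0.05)
})

test_that("continuous modifiers are dichotomized at the stated cuts", {
  coh <- simulate_cohort(sim_config(n_individuals = 3000,
                                    outcome_base_rate = 0.03, seed = 40))
  out <- interaction_lrt(coh, modifier = "age_entry")
  expect_s3_class(out, "interaction_lrt")
  expect_equal(out$df, 1)
  expect_true(out$p >= 0 && out$p <= 1)
})
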
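#' Construct an MR estimate object
#'
#' Internal constructor shared by all estimators. The causal effect
#' `theta` lives on the log risk-ratio scale per 1 unit of the exposure
#' (natural or log units, depending on what fed the estimator); the
#' reported causal risk ratio is `exp(theta)`.
#'
#' @keywords internal
mr_estimate <- function(method, theta, se, n_variants,
                        Q = NA_real_, Q_df = NA_integer_,
                        Q_p = NA_real_, intercept = NA_real_,
                        intercept_se = NA_real_, i2gx = NA_real_,
                        weak = FALSE) {
  z <- theta / se
  out <- list(method = method, theta = theta, se = se,
              ci = theta + c(-1, 1) * stats::qnorm(0.975) * se,
              rr = exp(theta),
              rr_ci = exp(theta + c(-1, 1) * stats::qnorm(0.975) * se),
              p = 2 * stats::pnorm(-abs(z)),
              n_variants = n_variants,
              Q = Q, Q_df = Q_df, Q_p = Q_p,
              intercept = intercept, intercept_se = intercept_se,
              i2gx = i2gx, weak_instrument = weak)
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s: causal risk ratio %.*f (95%% CI %.*f-%.*f), p = %.3g\n",
              x$method, digits, x$rr, digits, x$rr_ci[1], digits,
              x$rr_ci[2], x$p))
  if (is.finite(x$Q))
    cat(sprintf("  heterogeneity Q = %.2f on %d df (p = %.3g)\n",
                x$Q, x$Q_df, x$Q_p))
  if (is.finite(x$intercept))
    cat(sprintf("  Egger intercept = %.4f (se %.4f); I2_GX = %.1f%%\n",
                x$intercept, x$intercept_se, 100 * x$i2gx))
  if (isTRUE(x$weak_instrument))
    cat("  warning: weak instrument\n")
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  stats::setNames(object$theta, "theta")
}

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  matrix(object$theta + c(-1, 1) * z * object$se, nrow = 1,
         dimnames = list("theta", c("lower", "upper")))
}

#' @export
summary.mr_estimate <- function(object, ...) object

# internal: aligned (gamma, se_x, Gamma, se_y) from two summary tables,
# accepting a harmonized_pair or two already-aligned tables
align_pair <- function(exposure, outcome = NULL) {
  if (inherits(exposure, "harmonized_pair")) {
    outcome <- exposure$outcome
    exposure <- exposure$exposure
  } else if (inherits(exposure, "summary_pair")) {
    outcome <- exposure$outcome
    exposure <- exposure$exposure
  }
  exposure <- summary_stats(exposure)
  outcome <- summary_stats(outcome)
  if (!identical(exposure$id, outcome$id) ||
      !identical(exposure$effect_allele, outcome$effect_allele))
    stop("inputs are not harmonized (ids or effect alleles differ); ",
         "run harmonize() first")
  if (any(exposure$beta == 0))
    stop("a variant has an exposure association of exactly zero; ",
         "its Wald ratio is undefined")
  list(id = exposure$id, gamma = exposure$beta, se_x = exposure$se,
       Gamma = outcome$beta, se_y = outcome$se)
}

# internal: first-order delta-method SE of a ratio by/bx
delta_ratio_se <- function(by, bx, se_y, se_x) {
  sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
}

# internal: per-variant Wald ratios and their delta-method variances
wald_ratios <- function(d, second_order = FALSE) {
  theta_j <- d$Gamma / d$gamma
  v <- d$se_y^2 / d$gamma^2
  if (second_order) v <- v + d$Gamma^2 * d$se_x^2 / d$gamma^4
  list(theta = theta_j, var = v)
}

#' Inverse-variance-weighted MR estimator
#'
#' Combines per-variant Wald ratios `Gamma_j / gamma_j` with weights
#' `gamma_j^2 / se_yj^2`, equivalently a zero-intercept regression of the
#' outcome associations on the exposure associations weighted by
#' `1/se_yj^2`. With `model = "random"` (the default) the fixed-effect
#' standard error is inflated by `sqrt(Q / (L - 1))` whenever Cochran's Q
#' exceeds its degrees of freedom — multiplicative random effects, never
#' deflating.
#'
#' @param exposure,outcome Harmonized `summary_stats` tables (identical
#'   variants and effect alleles); alternatively pass a
#'   `harmonized_pair` or `summary_pair` as the first argument.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An object of class `mr_estimate`.
#' @examples
#' ss <- simulate_summary_stats(12, true_effect = 0.2, seed = 2)
#' mr_ivw(ss)
#' @export
mr_ivw <- function(exposure, outcome = NULL,
                   model = c("random", "fixed")) {
  model <- match.arg(model)
  d <- align_pair(exposure, outcome)
  L <- length(d$gamma)
  if (L < 2) stop("IVW requires at least 2 variants")
  w <- d$gamma^2 / d$se_y^2
  theta_j <- d$Gamma / d$gamma
  theta <- sum(w * theta_j) / sum(w)
  Q <- sum(w * (theta_j - theta)^2)
  se <- 1 / sqrt(sum(w))
  if (model == "random" && Q / (L - 1) > 1) se <- se * sqrt(Q / (L - 1))
  mr_estimate("IVW", theta, se, L, Q = Q, Q_df = L - 1L,
              Q_p = stats::pchisq(Q, L - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome associations on exposure associations
#' with a free intercept, after orienting every exposure association to
#' be non-negative (flipping the outcome association jointly). The slope
#' estimates the causal effect under the InSIDE assumption; the intercept
#' tests directional pleiotropy. Standard errors use multiplicative
#' overdispersion bounded below at 1. Also reports `I2_GX`, the
#' heterogeneity statistic of the exposure associations that measures
#' susceptibility to regression-dilution bias (values near 1 mean little
#' attenuation).
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with `intercept`, `intercept_se` and `i2gx`
#'   filled in.
#' @export
mr_egger <- function(exposure, outcome = NULL) {
  d <- align_pair(exposure, outcome)
  L <- length(d$gamma)
  if (L < 3) stop("MR-Egger requires at least 3 variants")
  flip <- sign(d$gamma)
  flip[flip == 0] <- 1
  g <- d$gamma * flip
  G <- d$Gamma * flip
  w <- 1 / d$se_y^2

  X <- cbind(1, g)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * G)
  est <- solve(XtWX, XtWy)
  resid <- G - X %*% est
  phi <- max(1, sum(w * resid^2) / (L - 2))
  V <- phi * solve(XtWX)

  # precision-weighted heterogeneity of the exposure associations
  wx <- 1 / d$se_x^2
  gbar <- sum(wx * g) / sum(wx)
  Qx <- sum((g - gbar)^2 * wx)
  i2gx <- max(0, min(1, (Qx - (L - 1)) / Qx))

  Q <- sum(w * resid^2)
  mr_estimate("MR-Egger", est[2], sqrt(V[2, 2]), L,
              Q = Q, Q_df = L - 2L,
              Q_p = stats::pchisq(Q, L - 2, lower.tail = FALSE),
              intercept = est[1], intercept_se = sqrt(V[1, 1]),
              i2gx = i2gx)
}

#' Weighted-median MR estimator
#'
#' The weighted median of the per-variant Wald ratios: ratios are sorted,
#' inverse-variance weights normalized, and the estimate interpolated
#' where the cumulative midpoint weight crosses one half. Consistent when
#' valid instruments carry at least 50\% of the weight. The standard
#' error comes from a parametric bootstrap resampling the summary
#' associations from their reported normal distributions.
#'
#' @inheritParams mr_ivw
#' @param bootstrap Number of bootstrap draws (default 1000).
#' @param seed Seed for the bootstrap.
#' @param second_order Use second-order delta-method ratio variances.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(exposure, outcome = NULL,
                               bootstrap = 1000, seed = 1L,
                               second_order = FALSE) {
  d <- align_pair(exposure, outcome)
  L <- length(d$gamma)
  if (L < 3) stop("the weighted median requires at least 3 variants")
  est <- weighted_median_point(d, second_order)
  se <- bootstrap_se(d, bootstrap, seed,
                     function(dd) weighted_median_point(dd, second_order))
  mr_estimate("Weighted median", est, se, L)
}

weighted_median_point <- function(d, second_order = FALSE) {
  r <- wald_ratios(d, second_order)
  w <- 1 / r$var
  ord <- order(r$theta)
  th <- r$theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(th[1])
  if (s[length(s)] <= 0.5) return(th[length(th)])
  k <- max(which(s < 0.5))
  th[k] + (th[k + 1] - th[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted-mode MR estimator
#'
#' The mode of the smoothed weighted empirical density of the per-variant
#' Wald ratios, consistent when the largest group of variants sharing a
#' ratio value are valid instruments (plurality validity). A normal
#' kernel is used with bandwidth `bandwidth_factor` times the modified
#' Silverman rule `0.9 * min(sd, mad) * L^(-1/5)` on the ratio set; the
#' standard error comes from a parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the modified Silverman bandwidth
#'   (default 1; smaller values make the mode more local).
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(exposure, outcome = NULL,
                             bandwidth_factor = 1, bootstrap = 1000,
                             seed = 1L, second_order = FALSE) {
  d <- align_pair(exposure, outcome)
  L <- length(d$gamma)
  if (L < 3) stop("the weighted mode requires at least 3 variants")
  est <- weighted_mode_point(d, bandwidth_factor, second_order)
  se <- bootstrap_se(d, bootstrap, seed, function(dd)
    weighted_mode_point(dd, bandwidth_factor, second_order))
  mr_estimate("Weighted mode", est, se, L)
}

weighted_mode_point <- function(d, bandwidth_factor = 1,
                                second_order = FALSE) {
  r <- wald_ratios(d, second_order)
  th <- r$theta
  w <- 1 / r$var
  w <- w / sum(w)
  sdv <- stats::sd(th)
  madv <- stats::mad(th)
  # a mad of floating-point dust (majority of ratios tied) degenerates
  # the bandwidth; fall back to the sd
  spread <- if (madv > sdv * 1e-8) min(sdv, madv) else sdv
  if (!is.finite(spread) || spread == 0) return(th[1]) # all ratios equal
  h <- bandwidth_factor * 0.9 * spread * length(th)^(-1 / 5)
  grid <- seq(min(th) - 3 * h, max(th) + 3 * h, length.out = 2048)
  dens <- vapply(grid, function(x)
    sum(w * stats::dnorm((x - th) / h)), numeric(1))
  grid[which.max(dens)]
}

# internal: parametric bootstrap SE for ratio-based point estimators
bootstrap_se <- function(d, bootstrap, seed, point_fun) {
  if (bootstrap < 2) return(NA_real_)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  L <- length(d$gamma)
  draws <- vapply(seq_len(bootstrap), function(b) {
    dd <- d
    dd$gamma <- stats::rnorm(L, d$gamma, d$se_x)
    dd$Gamma <- stats::rnorm(L, d$Gamma, d$se_y)
    dd$gamma[dd$gamma == 0] <- .Machine$double.eps
    point_fun(dd)
  }, numeric(1))
  stats::sd(draws)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' One-sample Wald-type (ratio) estimator from an allele score
#'
#' The causal effect is the ratio of the instrument-outcome association
#' (log-odds per score unit from an age- and sex-adjusted logistic
#' regression) to the instrument-exposure association (exposure units per
#' score unit from an age- and sex-adjusted linear regression in the
#' measured subsample). The standard error uses the first-order delta
#' method `sqrt(se_y^2/bx^2 + by^2 se_x^2 / bx^4)`.
#'
#' @param cohort A `cohort_table`.
#' @param score An `allele_score` from [build_score()], or any numeric
#'   vector of per-individual instrument values.
#' @param outcome Name of the event-indicator column (default `"event"`).
#' @param exposure_scale `"log"` (default; effect per 1 log-unit
#'   exposure) or `"natural"` (per 1 ug/mL).
#' @param weak_f_threshold Instrument-strength F below which the estimate
#'   is flagged weak (default 10); the estimate is still returned.
#' @return An `mr_estimate` (method `"Wald ratio"`).
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 5000, seed = 11))
#' sc <- build_score(coh, scheme = "internal")
#' mr_wald(coh, sc)
#' @export
mr_wald <- function(cohort, score, outcome = "event",
                    exposure_scale = c("log", "natural"),
                    weak_f_threshold = 10) {
  exposure_scale <- match.arg(exposure_scale)
  s <- score_values(score, cohort)
  if (stats::var(s) == 0) stop("the allele score is degenerate")
  y <- cohort[[outcome]]
  if (sum(y) == 0) stop("outcome has zero events")

  m <- cohort$measured
  xvar <- if (exposure_scale == "log") cohort$log_exposure else
    cohort$exposure
  fx <- stats::lm(xvar ~ s + age_entry + sex, data = cohort,
                  subset = m)
  bx <- stats::coef(fx)[["s"]]
  se_x <- sqrt(stats::vcov(fx)["s", "s"])

  fy <- stats::glm(y ~ s + age_entry + sex, family = stats::binomial(),
                   data = cohort)
  by <- stats::coef(fy)[["s"]]
  se_y <- sqrt(stats::vcov(fy)["s", "s"])

  theta <- by / bx
  se <- delta_ratio_se(by, bx, se_y, se_x)
  f_inst <- (bx / se_x)^2
  mr_estimate("Wald ratio", theta, se, n_variants = score_n_variants(score),
              weak = f_inst < weak_f_threshold)
}

score_values <- function(score, cohort) {
  if (inherits(score, "allele_score")) score$values else as.numeric(score)
}

score_n_variants <- function(score) {
  if (inherits(score, "allele_score")) length(score$weights) else NA_integer_
}

#' Run every summary-data MR estimator
#'
#' Convenience wrapper running IVW, MR-Egger, weighted median and
#' weighted mode on one harmonized pair and returning a result table in
#' the usual forest-plot layout.
#'
#' @inheritParams mr_weighted_median
#' @return A data.frame of class `mr_result_set` with one row per method:
#'   `method, n_variants, rr, ci_low, ci_high, p, Q, egger_intercept,
#'   i2gx`.
#' @export
mr_all <- function(exposure, outcome = NULL, bootstrap = 1000, seed = 1L) {
  fits <- list(
    mr_ivw(exposure, outcome),
    mr_egger(exposure, outcome),
    mr_weighted_median(exposure, outcome, bootstrap = bootstrap,
                       seed = seed),
    mr_weighted_mode(exposure, outcome, bootstrap = bootstrap,
                     seed = seed))
  out <- do.call(rbind, lapply(fits, function(f)
    data.frame(method = f$method, n_variants = f$n_variants, rr = f$rr,
               ci_low = f$rr_ci[1], ci_high = f$rr_ci[2], p = f$p,
               Q = f$Q, egger_intercept = f$intercept, i2gx = f$i2gx)))
  class(out) <- c("mr_result_set", "data.frame")
  out
}

#' MR power for a binary outcome
#'
#' Normal-approximation power of a two-sided level-`alpha` test of a log
#' odds-ratio `effect` per exposure SD, with an instrument explaining
#' `r2` of the exposure variance in a sample of `n` with the given case
#' fraction:
#' `power = Phi(|effect| * sqrt(n * r2 * cf * (1 - cf)) - z_{1-alpha/2})`.
#'
#' @param n Sample size.
#' @param r2 Variance in the exposure explained by the instrument.
#' @param case_fraction Proportion of cases.
#' @param alpha Two-sided significance level (default 0.05).
#' @param effect True log odds ratio per exposure SD.
#' @return The power, a number in (0, 1).
#' @export
mr_power <- function(n, r2, case_fraction, alpha = 0.05, effect) {
  stopifnot(n > 0, r2 >= 0, r2 < 1,
            case_fraction > 0, case_fraction < 1,
            alpha > 0, alpha < 1)
  ncp <- abs(effect) * sqrt(n * r2 * case_fraction * (1 - case_fraction))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}
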
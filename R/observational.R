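#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline (natural spline) basis in the
#' Harrell parameterization: for `k` knots `t_1 < ... < t_k` it returns
#' `k - 1` regressors (the linear term plus `k - 2` normalized cubic
#' terms) such that the fitted function is linear beyond the boundary
#' knots.
#'
#' @param x Numeric vector to expand.
#' @param knots Strictly increasing knot locations (length >= 3). The
#'   default, used by [fit_cox()], places 5 knots at the
#'   5/27.5/50/72.5/95th percentiles.
#' @return An `n x (k - 1)` matrix; knots attached as attribute.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(unique(knots))
  k <- length(knots)
  if (k < 3) stop("a restricted cubic spline needs at least 3 knots")
  tau <- (knots[k] - knots[1])^2
  cube <- function(u) pmax(u, 0)^3
  B <- matrix(x, ncol = 1)
  for (j in seq_len(k - 2)) {
    B <- cbind(B, (cube(x - knots[j]) -
                     cube(x - knots[k - 1]) * (knots[k] - knots[j]) /
                       (knots[k] - knots[k - 1]) +
                     cube(x - knots[k]) * (knots[k - 1] - knots[j]) /
                       (knots[k] - knots[k - 1])) / tau)
  }
  colnames(B) <- paste0("rcs", seq_len(k - 1))
  attr(B, "knots") <- knots
  B
}

default_knots <- function(x, n_knots = 5) {
  probs <- switch(as.character(n_knots),
                  "3" = c(0.1, 0.5, 0.9),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.5, 0.725, 0.95),
                  seq(0.02, 0.98, length.out = n_knots))
  unname(stats::quantile(x, probs))
}

#' Cox proportional hazards fit with age as the timescale
#'
#' Fits the observational exposure-outcome association by Cox partial
#' likelihood with age as the time axis and delayed entry at the study
#' entry age, so each individual contributes to risk sets only between
#' entry and exit age; ties are handled by the Efron method. The
#' exposure enters the linear predictor per `encoding`:
#' \describe{
#'   \item{`"log"`}{natural-log-transformed exposure (one coefficient,
#'     log HR per 1 log-unit);}
#'   \item{`"linear"`}{untransformed exposure (per 1 ug/mL);}
#'   \item{`"spline"`}{restricted cubic spline of the (optionally
#'     log-transformed) exposure;}
#'   \item{`"quartile"`}{exposure quartile as a factor, first quartile
#'     as referent.}
#' }
#'
#' @param cohort A `cohort_table` (rows without a measured exposure are
#'   dropped: complete-case analysis).
#' @param outcome Event-indicator column (default `"event"`).
#' @param encoding One of `"log"`, `"linear"`, `"spline"`, `"quartile"`.
#' @param covariates Additional adjustment columns (default
#'   `c("sex", "confounder")`; age is always adjusted through the
#'   timescale).
#' @param knots Spline knot locations, or `NULL` for 5 knots at the
#'   Harrell percentiles.
#' @param spline_log Fit the spline on the log-exposure scale
#'   (default `TRUE`).
#' @param ties Tie-handling method (default `"efron"`).
#' @return An object of class `cox_fit`: the `survival::coxph` fit plus
#'   the encoding descriptor, exposure vector and spline basis knots.
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 3000,
#'   outcome_base_rate = 0.01, seed = 5))
#' fit <- fit_cox(coh, encoding = "log")
#' summary(fit)
#' @export
fit_cox <- function(cohort, outcome = "event",
                    encoding = c("log", "linear", "spline", "quartile"),
                    covariates = c("sex", "confounder"),
                    knots = NULL, spline_log = TRUE, ties = "efron") {
  encoding <- match.arg(encoding)
  dat <- as.data.frame(cohort)[cohort$measured, , drop = FALSE]
  dat$.event <- dat[[outcome]]
  if (sum(dat$.event) < 1) stop("no events for outcome '", outcome, "'")

  xname <- switch(encoding, log = "log_exposure", linear = "exposure",
                  spline = if (spline_log) "log_exposure" else "exposure",
                  quartile = "exposure")
  x <- dat[[xname]]

  exposure_terms <- switch(encoding,
    log = , linear = {
      dat$.x <- x
      ".x"
    },
    spline = {
      if (is.null(knots)) knots <- default_knots(x)
      B <- rcs_basis(x, knots)
      knots <- attr(B, "knots")
      for (j in seq_len(ncol(B))) dat[[colnames(B)[j]]] <- B[, j]
      colnames(B)
    },
    quartile = {
      if (length(unique(x)) < 4)
        stop("quartile encoding needs at least 4 distinct exposure values")
      q <- stats::quantile(x, c(0.25, 0.5, 0.75))
      dat$.quart <- factor(1 + findInterval(x, q, left.open = TRUE),
                           levels = 1:4, labels = paste0("Q", 1:4))
      ".quart"
    })

  covariates <- intersect(covariates, names(dat))
  # constant adjustment columns carry no information and break the fit
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(dat[[cv]])) > 1, logical(1))]
  rhs <- paste(c(exposure_terms, covariates), collapse = " + ")
  fml <- stats::as.formula(
    paste("survival::Surv(age_entry, age_exit, .event) ~", rhs))
  fit <- survival::coxph(fml, data = dat, ties = ties, x = FALSE,
                         model = FALSE)
  if (!is.null(fit$fail))
    stop("Cox fit did not converge: ", fit$fail)
  if (any(!is.finite(stats::coef(fit))) ||
      any(!is.finite(diag(stats::vcov(fit)))))
    stop("Cox fit failed: non-finite coefficients (separation?)")
  structure(list(fit = fit, encoding = encoding,
                 exposure_terms = exposure_terms,
                 covariates = covariates, knots = knots,
                 spline_log = isTRUE(spline_log) && encoding == "spline",
                 exposure = x, n_events = sum(dat$.event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (age timescale, delayed entry), encoding '%s', %d events\n",
              x$encoding, x$n_events))
  cf <- stats::coef(x$fit)
  se <- sqrt(diag(stats::vcov(x$fit)))
  tab <- data.frame(coef = cf, HR = exp(cf),
                    ci_low = exp(cf - 1.96 * se),
                    ci_high = exp(cf + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(cf / se)))
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.cox_fit <- function(object, ...) stats::vcov(object$fit)

#' @export
logLik.cox_fit <- function(object, ...) stats::logLik(object$fit)

#' @export
summary.cox_fit <- function(object, ...) summary(object$fit)

#' Hazard-ratio curve from a spline Cox fit
#'
#' Evaluates `HR(x) = exp(f(x) - f(ref))` over a grid, with pointwise
#' 95\% confidence intervals by the delta method on the basis contrast.
#' The reference exposure gets HR exactly 1 with a zero-width interval.
#'
#' @param fit A `cox_fit` with spline encoding.
#' @param reference Reference exposure value (same units the spline was
#'   fitted on is not required: pass natural units; default the median
#'   of the fitted exposures).
#' @param grid Exposure values to evaluate (natural units); default 100
#'   points spanning the fitted range.
#' @param trim_upper Drop grid points above this exposure quantile
#'   (display convention; default `NULL`, no trimming).
#' @return A data.frame `x, hr, ci_low, ci_high` of class
#'   `spline_curve`.
#' @export
spline_curve <- function(fit, reference = NULL, grid = NULL,
                         trim_upper = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$encoding != "spline")
    stop("spline_curve requires a spline-encoded fit")
  xnat <- if (fit$spline_log) exp(fit$exposure) else fit$exposure
  if (is.null(reference)) reference <- stats::median(xnat)
  if (reference < min(xnat) || reference > max(xnat))
    stop("reference exposure lies outside the data range")
  if (is.null(grid))
    grid <- seq(min(xnat), max(xnat), length.out = 100)
  if (!is.null(trim_upper))
    grid <- grid[grid <= stats::quantile(xnat, trim_upper)]

  tx <- function(v) if (fit$spline_log) log(v) else v
  Bg <- rcs_basis(tx(grid), fit$knots)
  Br <- rcs_basis(tx(reference), fit$knots)
  contrast <- sweep(Bg, 2, as.numeric(Br))

  idx <- match(fit$exposure_terms, names(stats::coef(fit$fit)))
  beta <- stats::coef(fit$fit)[idx]
  V <- stats::vcov(fit$fit)[idx, idx, drop = FALSE]
  eta <- as.numeric(contrast %*% beta)
  se <- sqrt(rowSums((contrast %*% V) * contrast))
  out <- data.frame(x = grid, hr = exp(eta),
                    ci_low = exp(eta - 1.96 * se),
                    ci_high = exp(eta + 1.96 * se))
  attr(out, "reference") <- reference
  class(out) <- c("spline_curve", "data.frame")
  out
}

#' @export
plot.spline_curve <- function(x, log = "y", xlab = "Exposure",
                              ylab = "Hazard ratio", ...) {
  graphics::plot(x$x, x$hr, type = "l", log = log, xlab = xlab,
                 ylab = ylab, ylim = range(x$ci_low, x$ci_high), ...)
  graphics::lines(x$x, x$ci_low, lty = 2)
  graphics::lines(x$x, x$ci_high, lty = 2)
  graphics::abline(h = 1, col = "grey")
  invisible(x)
}

#' Quartile analysis of the exposure-outcome association
#'
#' Splits the measured exposure into quartiles, fits the Cox model with
#' the first quartile as referent, and reports per-quartile hazard
#' ratios alongside the within-quartile geometric mean exposure with a
#' t-based 95\% confidence interval on the log scale.
#'
#' @inheritParams fit_cox
#' @return A data.frame `quartile, n, events, geo_mean, geo_ci_low,
#'   geo_ci_high, hr, hr_ci_low, hr_ci_high`, with the underlying
#'   `cox_fit` as attribute `fit`.
#' @export
quartile_analysis <- function(cohort, outcome = "event",
                              covariates = c("sex", "confounder")) {
  fit <- fit_cox(cohort, outcome, encoding = "quartile",
                 covariates = covariates)
  dat <- as.data.frame(cohort)[cohort$measured, , drop = FALSE]
  x <- dat$exposure
  q <- stats::quantile(x, c(0.25, 0.5, 0.75))
  quart <- 1 + findInterval(x, q, left.open = TRUE)
  if (any(tabulate(quart, 4) == 0)) stop("empty exposure quartile")

  geo <- t(vapply(1:4, function(k) {
    lx <- log(x[quart == k])
    m <- mean(lx)
    hw <- stats::qt(0.975, length(lx) - 1) * stats::sd(lx) /
      sqrt(length(lx))
    exp(c(m, m - hw, m + hw))
  }, numeric(3)))

  cf <- stats::coef(fit$fit)
  se <- sqrt(diag(stats::vcov(fit$fit)))
  qn <- paste0(".quartQ", 2:4)
  hr <- c(1, exp(cf[qn]))
  lo <- c(1, exp(cf[qn] - 1.96 * se[qn]))
  hi <- c(1, exp(cf[qn] + 1.96 * se[qn]))

  out <- data.frame(quartile = paste0("Q", 1:4),
                    n = tabulate(quart, 4),
                    events = vapply(1:4, function(k)
                      sum(dat[[outcome]][quart == k]), numeric(1)),
                    geo_mean = geo[, 1], geo_ci_low = geo[, 2],
                    geo_ci_high = geo[, 3],
                    hr = hr, hr_ci_low = lo, hr_ci_high = hi,
                    row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Likelihood-ratio test for effect modification
#'
#' Compares Cox models with and without an exposure-by-modifier
#' interaction term by likelihood ratio. Continuous modifiers are
#' dichotomized first at the conventional clinical cut (age 60, BMI 30,
#' waist 88 cm for women / 102 cm for men) or at a supplied `cut`.
#'
#' @inheritParams fit_cox
#' @param modifier Column name of the putative effect modifier.
#' @param cut Dichotomization threshold for a continuous modifier;
#'   `NULL` uses the built-in clinical cut when the name is recognized
#'   (`age_entry` 60, `bmi` 30, `waist` 88/102 by sex), else the median.
#' @param encoding Exposure encoding for both models (default `"log"`).
#' @return A list of class `interaction_lrt`: `statistic`, `df`, `p`,
#'   and the two log-likelihoods.
#' @export
interaction_lrt <- function(cohort, outcome = "event", modifier,
                            cut = NULL, encoding = "log",
                            covariates = c("sex", "confounder")) {
  dat <- as.data.frame(cohort)[cohort$measured, , drop = FALSE]
  dat$.event <- dat[[outcome]]
  mv <- dat[[modifier]]
  if (is.null(mv)) stop("no such modifier column: ", modifier)
  if (length(unique(mv)) > 2) {
    if (is.null(cut)) {
      cut <- switch(modifier, age_entry = 60, bmi = 30,
                    waist = NULL, stats::median(mv))
      if (modifier == "waist")
        mv <- as.integer(mv >= ifelse(dat$sex == 1, 102, 88))
    }
    if (length(unique(mv)) > 2) mv <- as.integer(mv >= cut)
  }
  dat$.mod <- mv
  dat$.x <- if (encoding == "log") dat$log_exposure else dat$exposure
  covariates <- setdiff(intersect(covariates, names(dat)), modifier)
  rhs0 <- paste(c(".x", ".mod", covariates), collapse = " + ")
  f0 <- stats::as.formula(
    paste("survival::Surv(age_entry, age_exit, .event) ~", rhs0))
  f1 <- stats::update(f0, . ~ . + .x:.mod)
  fit0 <- survival::coxph(f0, data = dat, ties = "efron")
  fit1 <- survival::coxph(f1, data = dat, ties = "efron")
  ll0 <- fit0$loglik[2]
  ll1 <- fit1$loglik[2]
  stat <- 2 * (ll1 - ll0)
  if (stat < -1e-6)
    stop("nested log-likelihood ordering violated; optimizer failure")
  stat <- max(0, stat)
  df <- length(stats::coef(fit1)) - length(stats::coef(fit0))
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 loglik_full = ll1, loglik_reduced = ll0,
                 modifier = modifier),
            class = "interaction_lrt")
}

#' @export
print.interaction_lrt <- function(x, ...) {
  cat(sprintf("Interaction LRT (%s): chi2 = %.3f on %d df, p = %.3g\n",
              x$modifier, x$statistic, x$df, x$p))
  invisible(x)
}

#' Exclude individuals with short follow-up
#'
#' Reverse-causation sensitivity filter: removes every individual whose
#' total follow-up (exit minus entry age) is shorter than `years`
#' (default mode `"drop"`). The alternative mode `"censor"` keeps
#' everyone but administratively censors events occurring within
#' `years` of entry.
#'
#' @param cohort A `cohort_table`.
#' @param years Non-negative window in years; 0 is the identity.
#' @param mode `"drop"` (default) or `"censor"`.
#' @return The filtered `cohort_table`; number of rows removed (or
#'   events censored) in attribute `n_removed`.
#' @export
exclude_early_followup <- function(cohort, years,
                                   mode = c("drop", "censor")) {
  mode <- match.arg(mode)
  if (years < 0) stop("years must be >= 0")
  fup <- cohort$age_exit - cohort$age_entry
  if (mode == "drop") {
    keep <- fup >= years
    out <- cohort[keep, , drop = FALSE]
    attr(out, "n_removed") <- sum(!keep)
  } else {
    early_event <- cohort$event == 1L & fup < years
    out <- cohort
    out$event[early_event] <- 0L
    attr(out, "n_removed") <- sum(early_event)
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}
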
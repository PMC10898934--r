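#' Doubly-ranked stratification
#'
#' Partitions the cohort into `n_strata` strata that are (a) balanced on
#' the instrument and (b) ordered in exposure, without conditioning on
#' the exposure itself in a way that would reintroduce collider bias:
#' individuals are sorted by allele score (ties broken by stable input
#' order), cut into consecutive pre-strata of size `n_strata`, ranked by
#' exposure within each pre-stratum, and the individual with exposure
#' rank `q` joins stratum `q`. Because only ranks are used, the
#' assignment is invariant to any strictly monotone transformation of
#' the exposure. A residual group of `n mod n_strata` individuals forms
#' a final partial pre-stratum assigned by the same within-ranking.
#'
#' @param cohort A `cohort_table` (only measured individuals are
#'   stratified).
#' @param score An `allele_score` or numeric vector aligned to `cohort`.
#' @param n_strata Number of strata (default 10).
#' @return Integer vector of length `nrow(cohort)`: stratum in
#'   `1..n_strata` for measured individuals, `NA` otherwise.
#' @export
doubly_ranked_strata <- function(cohort, score, n_strata = 10) {
  s_all <- score_values(score, cohort)
  idx <- which(cohort$measured)
  n <- length(idx)
  if (n < n_strata^2)
    stop("need at least n_strata^2 = ", n_strata^2,
         " measured individuals for stable double ranking")
  s <- s_all[idx]
  x <- cohort$log_exposure[idx]

  ord <- order(s)                      # stable in R: ties keep input order
  pre <- ceiling(seq_len(n) / n_strata)  # consecutive pre-strata
  stratum <- integer(n)
  for (b in unique(pre)) {
    members <- ord[pre == b]
    r <- rank(x[members], ties.method = "first")
    stratum[members] <- r
  }
  out <- rep(NA_integer_, nrow(cohort))
  out[idx] <- stratum
  out
}

#' Stratum-specific causal estimates (LACE)
#'
#' Within each stratum of a doubly-ranked partition, estimates the
#' localized average causal effect as the Wald ratio of the age- and
#' sex-adjusted instrument-outcome association (log-odds per score unit)
#' to the instrument-log-exposure association, with a first-order
#' delta-method standard error. Strata with no events or a degenerate
#' score are flagged and excluded.
#'
#' @param cohort A `cohort_table`.
#' @param assignment Stratum assignment from [doubly_ranked_strata()].
#' @param score An `allele_score` or numeric vector.
#' @param outcome Event-indicator column (default `"event"`).
#' @return A data.frame of class `stratum_estimates`: `stratum, n,
#'   events, x_mean, x_min, x_max` (log-exposure scale), `theta, se,
#'   usable`.
#' @export
lace_per_stratum <- function(cohort, assignment, score,
                             outcome = "event") {
  s <- score_values(score, cohort)
  y <- cohort[[outcome]]
  strata <- sort(unique(assignment[!is.na(assignment)]))
  rows <- lapply(strata, function(q) {
    in_q <- !is.na(assignment) & assignment == q
    xs <- cohort$log_exposure[in_q]
    base <- data.frame(stratum = q, n = sum(in_q),
                       events = sum(y[in_q]), x_mean = mean(xs),
                       x_min = min(xs), x_max = max(xs))
    if (base$events == 0 || stats::var(s[in_q]) == 0)
      return(cbind(base, theta = NA_real_, se = NA_real_,
                   usable = FALSE))
    fx <- stats::lm(xs ~ s[in_q] + cohort$age_entry[in_q] +
                      cohort$sex[in_q])
    bx <- stats::coef(fx)[[2]]
    se_x <- sqrt(stats::vcov(fx)[2, 2])
    fy <- stats::glm(y[in_q] ~ s[in_q] + cohort$age_entry[in_q] +
                       cohort$sex[in_q], family = stats::binomial())
    by <- stats::coef(fy)[[2]]
    se_y <- sqrt(stats::vcov(fy)[2, 2])
    cbind(base, theta = by / bx,
          se = delta_ratio_se(by, bx, se_y, se_x), usable = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stratum_estimates", "data.frame")
  out
}

#' @export
print.stratum_estimates <- function(x, digits = 3, ...) {
  cat("Stratum-specific causal estimates (log-exposure scale):\n")
  print(round(as.data.frame(x)[c("stratum", "n", "events", "x_mean",
                                 "theta", "se")], digits))
  invisible(x)
}

fp_powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# FP basis term evaluated at x (> 0); power 0 means log(x)
fp_term <- function(x, p) if (p == 0) log(x) else x^p

# weighted Gaussian log-likelihood of stratum estimates about a fitted
# effect function d(x)
fp_loglik <- function(theta, se, fitted) {
  sum(stats::dnorm(theta, fitted, se, log = TRUE))
}

#' Reconstruct the causal exposure-outcome curve from stratum estimates
#'
#' Treats each stratum's LACE as an estimate of the derivative of the
#' causal curve at the stratum's mean exposure and reconstructs the
#' curve `h(x)` (log risk ratio relative to a reference exposure) by:
#' \describe{
#'   \item{fractional polynomials (`"fp"`)}{weighted meta-regression of
#'     the stratum estimates on transformations of the stratum mean with
#'     powers from \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (0 meaning log),
#'     degree 1 or 2, best powers by maximized weighted likelihood; the
#'     curve is the analytic integral of the fitted effect function from
#'     the reference;}
#'   \item{piecewise linear (`"piecewise"`)}{each stratum's estimate is
#'     the constant slope over that stratum's exposure range; `h` is the
#'     running integral, anchored at 0 at the reference, hence
#'     continuous.}
#' }
#' Non-linearity is assessed two ways: Cochran heterogeneity Q of the
#' stratum estimates, and a 1-df likelihood-ratio test of the best
#' fractional polynomial of degree 1 against the constant-effect model.
#'
#' Because strata live on the log-exposure scale, `x` here denotes the
#' exposure after the same log transform; the FP transformations are
#' applied to `exp(x_mean)` (the natural-scale mean) to keep all
#' candidate powers well defined.
#'
#' @param strata A `stratum_estimates` table (>= 3 usable strata).
#' @param method `"fp"` (default), `"piecewise"`.
#' @param degree Fractional-polynomial degree, 1 or 2 (default 1).
#' @param reference Reference log-exposure; default the weighted
#'   mid-stratum median (the mean of the middle stratum).
#' @param grid Log-exposure grid for curve evaluation; default 100
#'   points over the span of the strata.
#' @return An object of class `causal_curve`: `method`, `powers`,
#'   `coefficients`, `curve` (data.frame `x, h, ci_low, ci_high`),
#'   `reference`, `heterogeneity` (Q, df, p) and `nonlinearity_p` (FP
#'   LRT; `NA` for piecewise).
#' @export
fit_causal_curve <- function(strata, method = c("fp", "piecewise"),
                             degree = 1, reference = NULL, grid = NULL) {
  method <- match.arg(method)
  st <- strata[strata$usable, , drop = FALSE]
  if (nrow(st) < 3) stop("need at least 3 usable strata")
  if (is.null(reference))
    reference <- st$x_mean[ceiling(nrow(st) / 2)]
  if (is.null(grid))
    grid <- seq(min(st$x_min), max(st$x_max), length.out = 100)

  w <- 1 / st$se^2
  # heterogeneity of the stratum estimates about their IVW mean
  th_bar <- sum(w * st$theta) / sum(w)
  Q <- sum(w * (st$theta - th_bar)^2)
  Q_df <- nrow(st) - 1L
  het <- list(Q = Q, df = Q_df,
              p = stats::pchisq(Q, Q_df, lower.tail = FALSE))

  if (method == "piecewise") {
    res <- piecewise_curve(st, reference, grid)
    out <- c(list(method = "piecewise", powers = NULL,
                  coefficients = st$theta, curve = res,
                  reference = reference, heterogeneity = het,
                  nonlinearity_p = NA_real_, strata = st))
    class(out) <- "causal_curve"
    return(out)
  }

  xm <- exp(st$x_mean)  # natural scale keeps every candidate power defined
  fit_for <- function(pows) {
    Z <- vapply(pows, function(p) fp_term(xm, p), numeric(nrow(st)))
    Z <- matrix(Z, nrow = nrow(st))
    ZtWZ <- crossprod(Z, w * Z)
    if (rcond(ZtWZ) < 1e-12) return(NULL)
    beta <- solve(ZtWZ, crossprod(Z, w * st$theta))
    list(powers = pows, beta = as.numeric(beta),
         V = solve(ZtWZ),
         ll = fp_loglik(st$theta, st$se, as.numeric(Z %*% beta)))
  }

  cand <- if (degree == 1) lapply(fp_powers, function(p) list(p))
  else {
    cs <- list()
    for (i in seq_along(fp_powers))
      for (j in i:length(fp_powers))
        cs[[length(cs) + 1]] <- list(fp_powers[i], fp_powers[j])
    cs
  }
  fits <- Filter(Negate(is.null),
                 lapply(cand, function(ps) fit_for(unlist(ps))))
  if (degree == 2)  # repeated powers need the (x^p, x^p log x) basis; drop
    fits <- Filter(function(f) length(unique(f$powers)) ==
                     length(f$powers), fits)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]

  # constant-effect model: non-linearity LRT reference, and itself a
  # candidate (its curve is the straight line theta_bar * (x - ref))
  ll_const <- fp_loglik(st$theta, st$se, th_bar)
  best_fp1 <- if (degree == 1) best else {
    f1 <- Filter(Negate(is.null),
                 lapply(fp_powers, function(p) fit_for(p)))
    f1[[which.max(vapply(f1, `[[`, numeric(1), "ll"))]]
  }
  lrt <- max(0, 2 * (best_fp1$ll - ll_const))
  nonlin_p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (ll_const >= best$ll)
    best <- list(powers = numeric(0), beta = th_bar,
                 V = matrix(1 / sum(w)), ll = ll_const)

  # integrate the fitted effect function (per log-unit exposure,
  # evaluated at natural-scale x) with respect to log exposure
  basis_int <- if (length(best$powers) == 0) {
    matrix(grid - reference, ncol = 1)  # constant-effect model
  } else {
    matrix(vapply(best$powers, function(p)
      fp_integral_log(grid, p) - fp_integral_log(reference, p),
      numeric(length(grid))), nrow = length(grid))
  }
  h <- as.numeric(basis_int %*% best$beta)
  se_h <- sqrt(rowSums((basis_int %*% best$V) * basis_int))
  curve <- data.frame(x = grid, h = h, ci_low = h - 1.96 * se_h,
                      ci_high = h + 1.96 * se_h)

  out <- list(method = sprintf("fractional polynomial (degree %d)",
                               degree),
              powers = best$powers, coefficients = best$beta,
              vcov = best$V, curve = curve, reference = reference,
              heterogeneity = het, nonlinearity_p = nonlin_p,
              strata = st)
  class(out) <- "causal_curve"
  out
}

# antiderivative with respect to log-exposure u of d(exp(u)) where
# d(x) = x^p: integral of exp(p u) du
fp_integral_log <- function(u, p) {
  if (p == 0) u^2 / 2      # d = log x = u; integral u du
  else exp(p * u) / p
}

piecewise_curve <- function(st, reference, grid) {
  st <- st[order(st$x_mean), , drop = FALSE]
  # breakpoints: stratum boundaries, midway where ranges abut/overlap
  brk <- c(st$x_min[1],
           (st$x_max[-nrow(st)] + st$x_min[-1]) / 2,
           st$x_max[nrow(st)])
  slope_at <- function(u) {
    k <- findInterval(u, brk, rightmost.closed = TRUE,
                      all.inside = TRUE)
    list(theta = st$theta[k], var = st$se[k]^2, k = k)
  }
  # h(x): signed accumulation of slope * width from the reference
  h_of <- function(u) {
    lo <- min(u, reference); hi <- max(u, reference)
    cuts <- sort(unique(c(lo, hi, brk[brk > lo & brk < hi])))
    seg_mid <- (cuts[-1] + cuts[-length(cuts)]) / 2
    widths <- diff(cuts)
    sl <- slope_at(seg_mid)
    val <- sum(sl$theta * widths)
    wid_k <- tapply(widths, sl$k, sum)
    vr <- sum(wid_k^2 * st$se[as.integer(names(wid_k))]^2)
    c(if (u >= reference) val else -val, vr)
  }
  res <- t(vapply(grid, h_of, numeric(2)))
  data.frame(x = grid, h = res[, 1],
             ci_low = res[, 1] - 1.96 * sqrt(res[, 2]),
             ci_high = res[, 1] + 1.96 * sqrt(res[, 2]))
}

#' @export
print.causal_curve <- function(x, ...) {
  cat("Causal exposure-outcome curve:", x$method, "\n")
  if (length(x$powers)) {
    cat("  selected powers:", paste(x$powers, collapse = ", "),
        "; coefficients:",
        paste(signif(x$coefficients, 3), collapse = ", "), "\n")
  } else if (startsWith(x$method, "fractional")) {
    cat("  constant-effect model selected (linear curve), slope",
        signif(x$coefficients, 3), "\n")
  }
  cat(sprintf("  heterogeneity across strata: Q = %.2f on %d df (p = %.3g)\n",
              x$heterogeneity$Q, x$heterogeneity$df, x$heterogeneity$p))
  if (is.finite(x$nonlinearity_p))
    cat(sprintf("  non-linearity LRT p = %.3g\n", x$nonlinearity_p))
  invisible(x)
}

#' @export
plot.causal_curve <- function(x, xlab = "log exposure",
                              ylab = "log risk ratio", ...) {
  cv <- x$curve
  graphics::plot(cv$x, cv$h, type = "l",
                 ylim = range(cv$ci_low, cv$ci_high),
                 xlab = xlab, ylab = ylab, ...)
  graphics::lines(cv$x, cv$ci_low, lty = 2)
  graphics::lines(cv$x, cv$ci_high, lty = 2)
  graphics::abline(h = 0, col = "grey")
  graphics::points(x$strata$x_mean, rep(0, nrow(x$strata)), pch = 3)
  invisible(x)
}
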
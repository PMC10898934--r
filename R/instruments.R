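#' Hardy-Weinberg equilibrium test for one variant
#'
#' Pearson's chi-squared test (1 df) of the observed genotype counts
#' against the proportions expected from the estimated allele frequency.
#'
#' @param dosages Integer vector of dosages in \{0, 1, 2\}.
#' @return The p-value, with attributes `chisq` and `monomorphic`. A
#'   monomorphic variant returns p = 1 with a warning.
#' @examples
#' hwe_test(rep(c(0, 1, 2), c(25, 50, 25)))  # exact HWE: p = 1
#' @export
hwe_test <- function(dosages) {
  if (!all(dosages %in% 0:2)) stop("dosages must be 0, 1 or 2")
  n <- length(dosages)
  if (n < 1) stop("need at least one genotype")
  obs <- tabulate(dosages + 1L, nbins = 3L)
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (p == 0 || p == 1) {
    warning("monomorphic variant; HWE p-value set to 1")
    out <- 1
    attr(out, "chisq") <- 0
    attr(out, "monomorphic") <- TRUE
    return(out)
  }
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((obs - expd)^2 / expd)
  out <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  attr(out, "chisq") <- chisq
  attr(out, "monomorphic") <- FALSE
  out
}

#' Build an allele score from cohort genotypes
#'
#' Combines the per-variant dosages into a single instrument. Variants
#' are first oriented so the counted allele raises the exposure
#' (orientation from internal per-variant regressions, or from the
#' external weights when given); a dosage `g` for an exposure-lowering
#' allele contributes `2 - g`. Schemes:
#' \describe{
#'   \item{`"unweighted"`}{count of exposure-increasing alleles, an
#'     integer in \[0, 2L\];}
#'   \item{`"internal"`}{weights are per-variant marginal age- and
#'     sex-adjusted regressions of log exposure on dosage in the
#'     measured subsample (a joint fit via `joint = TRUE`);}
#'   \item{`"external"`}{weights supplied in `external_weights`
#'     (log-exposure units per effect allele), e.g. from an independent
#'     exposure GWAS.}
#' }
#'
#' @param cohort A `cohort_table`.
#' @param scheme `"internal"` (default), `"external"` or `"unweighted"`.
#' @param external_weights Numeric vector of per-variant betas, required
#'   for the external scheme and used for orientation of the unweighted
#'   scheme when given.
#' @param joint Use one joint regression on all dosages for internal
#'   weights instead of marginal fits (default `FALSE`; with independent
#'   variants the two coincide up to noise).
#' @return An object of class `allele_score`: list with `values`
#'   (per-individual score), `scheme`, `weights` (per variant, on the
#'   oriented exposure-increasing allele, always >= 0) and `flipped`
#'   (which variants were re-oriented).
#' @export
build_score <- function(cohort,
                        scheme = c("internal", "external", "unweighted"),
                        external_weights = NULL, joint = FALSE) {
  scheme <- match.arg(scheme)
  gcols <- genotype_columns(cohort)
  L <- length(gcols)
  if (L == 0) stop("cohort has no genotype columns")
  G <- as.matrix(cohort[gcols])

  betas <- switch(scheme,
    external = {
      if (is.null(external_weights))
        stop("external scheme requires external_weights")
      if (length(external_weights) != L)
        stop("need one external weight per variant")
      as.numeric(external_weights)
    },
    internal = ,
    unweighted = {
      if (!is.null(external_weights) && scheme == "unweighted") {
        as.numeric(external_weights)
      } else {
        if (!any(cohort$measured))
          stop("internal weighting requires measured exposures")
        internal_weights(cohort, G, joint)
      }
    })

  # orient every variant to its exposure-increasing allele; a tie
  # (beta exactly 0) keeps the input orientation
  flip <- betas < 0
  Gor <- G
  Gor[, flip] <- 2 - Gor[, flip]
  w_or <- abs(betas)

  values <- switch(scheme,
    unweighted = as.numeric(Gor %*% rep(1, L)),
    as.numeric(Gor %*% w_or))
  weights <- if (scheme == "unweighted") rep(1, L) else w_or

  structure(list(values = values, scheme = scheme, weights = weights,
                 betas = betas, flipped = flip, variants = gcols),
            class = "allele_score")
}

# internal weights: regression of log-exposure on dosage, age, sex in
# the measured subsample; marginal per-variant by default
internal_weights <- function(cohort, G, joint) {
  m <- cohort$measured
  if (joint) {
    df <- data.frame(y = cohort$log_exposure[m], G[m, , drop = FALSE],
                     age_entry = cohort$age_entry[m], sex = cohort$sex[m])
    fit <- stats::lm(y ~ ., data = df)
    unname(stats::coef(fit)[colnames(G)])
  } else {
    apply(G[m, , drop = FALSE], 2, function(g)
      stats::coef(stats::lm(cohort$log_exposure[m] ~ g +
                              cohort$age_entry[m] + cohort$sex[m]))[["g"]])
  }
}

#' @export
print.allele_score <- function(x, ...) {
  cat(sprintf("Allele score (%s) over %d variants; mean %.3f, sd %.3f\n",
              x$scheme, length(x$weights), mean(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' Instrument-strength F statistic (analytic formula)
#'
#' `F = ((N - K - 1) / K) * (R2 / (1 - R2))` for an instrument of `K`
#' variants explaining `R2` of the exposure variance in a sample of `N`.
#'
#' @param n Sample size.
#' @param k Number of variants.
#' @param r2 Proportion of exposure variance explained.
#' @return The F statistic.
#' @examples
#' f_statistic(29347, 12, 0.14)  # ~398
#' @export
f_statistic <- function(n, k, r2) {
  stopifnot(n > k + 1, k >= 1, r2 >= 0, r2 < 1)
  (n - k - 1) / k * (r2 / (1 - r2))
}

#' Instrument diagnostics: R-squared, F and Hardy-Weinberg tests
#'
#' `R2` comes from the regression of log exposure on the allele score in
#' the measured subsample. Two F conventions are reported: the analytic
#' formula [f_statistic()] with `K` = number of variants, and the
#' regression F of the one-predictor score fit
#' (`(N - 2) * R2 / (1 - R2)`); the two answer slightly different
#' questions and can differ noticeably, so both are returned rather than
#' collapsed.
#'
#' @param cohort A `cohort_table`.
#' @param score An `allele_score`.
#' @return A list of class `instrument_diagnostics`: `r2`, `f_formula`,
#'   `f_regression`, `n`, `k`, `hwe_p` (per-variant HWE p-values).
#' @export
instrument_diagnostics <- function(cohort, score) {
  stopifnot(inherits(score, "allele_score"))
  s <- score$values
  if (stats::var(s) == 0) stop("allele score has zero variance")
  m <- cohort$measured
  fit <- stats::lm(cohort$log_exposure[m] ~ s[m])
  r2 <- summary(fit)$r.squared
  n <- sum(m)
  k <- length(score$weights)
  gcols <- genotype_columns(cohort)
  hwe <- vapply(gcols, function(gc)
    suppressWarnings(as.numeric(hwe_test(cohort[[gc]]))), numeric(1))
  structure(list(r2 = r2,
                 f_formula = f_statistic(n, k, r2),
                 f_regression = (n - 2) * r2 / (1 - r2),
                 n = n, k = k, hwe_p = hwe),
            class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Instrument: R2 = %.4f over N = %d, K = %d\n  F (analytic formula) = %.1f; F (score regression) = %.1f\n",
    x$r2, x$n, x$k, x$f_formula, x$f_regression))
  cat(sprintf("  HWE p-values: min %.3g\n", min(x$hwe_p)))
  invisible(x)
}

#' Screen covariates for association with exposure and allele score
#'
#' Regresses each covariate on the allele score (linear for continuous
#' covariates, logistic for binary ones) and, for contrast, on log
#' exposure. A valid instrument should show the classic asymmetry: the
#' measured exposure associates with confounders while the score does
#' not. Flags use a Bonferroni level `alpha / m` over the `m` covariates
#' screened.
#'
#' @param cohort A `cohort_table`.
#' @param score An `allele_score` or numeric vector.
#' @param covariates Character vector of covariate column names.
#' @param alpha Family-wise level before correction (default 0.05).
#' @return A data.frame: `covariate, p_score, p_exposure,
#'   significant_score, significant_exposure`, with the Bonferroni
#'   threshold as attribute `threshold`.
#' @export
confounder_screen <- function(cohort, score, covariates, alpha = 0.05) {
  s <- score_values(score, cohort)
  m <- cohort$measured
  pvals <- t(vapply(covariates, function(cv) {
    y <- cohort[[cv]]
    if (is.null(y)) stop("no such covariate: ", cv)
    binary <- length(unique(y[!is.na(y)])) == 2
    p_of <- function(x, sub) {
      if (binary) {
        fit <- stats::glm(y[sub] ~ x[sub], family = stats::binomial())
        stats::coef(summary(fit))[2, 4]
      } else {
        fit <- stats::lm(y[sub] ~ x[sub])
        stats::coef(summary(fit))[2, 4]
      }
    }
    p_exp <- if (cv %in% c("exposure", "log_exposure"))
      NA_real_ else p_of(cohort$log_exposure, m)  # never screen X on X
    c(p_of(s, rep(TRUE, nrow(cohort))), p_exp)
  }, numeric(2)))
  thr <- alpha / length(covariates)
  out <- data.frame(covariate = covariates,
                    p_score = pvals[, 1], p_exposure = pvals[, 2],
                    significant_score = pvals[, 1] < thr,
                    significant_exposure = pvals[, 2] < thr,
                    row.names = NULL)
  attr(out, "threshold") <- thr
  out
}

#' Per-variant association estimates from a one-sample cohort
#'
#' Estimates, for every variant, the association with log exposure
#' (linear regression in the measured subsample) and with the outcome
#' (logistic regression in the full cohort), both age- and sex-adjusted,
#' and emits the two tables in the standard summary-statistics layout.
#' This turns the one-sample cohort into inputs the summary-data
#' estimators consume identically to a two-sample analysis.
#'
#' @param cohort A `cohort_table`.
#' @param outcome Event-indicator column name (default `"event"`).
#' @return A `summary_pair` (elements `exposure` and `outcome`). Allele
#'   labels are synthetic (effect allele `"A"`, other `"G"`) because
#'   dosage data carry no strand information; frequencies are estimated
#'   from the dosages.
#' @export
per_variant_associations <- function(cohort, outcome = "event") {
  y <- cohort[[outcome]]
  if (sum(y) == 0) stop("outcome has zero events")
  gcols <- genotype_columns(cohort)
  m <- cohort$measured
  res <- lapply(gcols, function(gc) {
    g <- cohort[[gc]]
    fx <- stats::lm(cohort$log_exposure[m] ~ g[m] + cohort$age_entry[m] +
                      cohort$sex[m])
    cx <- stats::coef(summary(fx))[2, 1:2]
    fy <- stats::glm(y ~ g + age_entry + sex, family = stats::binomial(),
                     data = cohort)
    cy <- stats::coef(summary(fy))[2, 1:2]
    c(gx = cx[[1]], sx = cx[[2]], gy = cy[[1]], sy = cy[[2]],
      eaf = mean(g) / 2)
  })
  res <- do.call(rbind, res)
  ids <- gcols
  exposure <- summary_stats(data.frame(
    id = ids, effect_allele = "A", other_allele = "G",
    eaf = res[, "eaf"], beta = res[, "gx"], se = res[, "sx"],
    n = sum(m)))
  outcome_tab <- summary_stats(data.frame(
    id = ids, effect_allele = "A", other_allele = "G",
    eaf = res[, "eaf"], beta = res[, "gy"], se = res[, "sy"],
    n = nrow(cohort)))
  out <- list(exposure = exposure, outcome = outcome_tab)
  class(out) <- "summary_pair"
  out
}
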
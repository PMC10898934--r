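#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' The defaults describe an adiponectin-like setting: a log-normal exposure
#' centred at 16 ug/mL, five uncorrelated biallelic variants jointly
#' explaining 3\% of the variance of log exposure, an age-scale exponential
#' hazard for each outcome, and a single shared confounder standing in for
#' the usual covariate battery (adiposity, blood pressure, lipids, ...).
#'
#' @param n_individuals Number of individuals to simulate.
#' @param n_variants Number of independent biallelic variants (default 5,
#'   the size of a typical directly genotyped instrument).
#' @param effect_allele_freqs Vector of effect-allele frequencies in (0,1);
#'   recycled to `n_variants`. Default 0.3.
#' @param score_r2 Proportion of log-exposure variance explained by the
#'   genotypes jointly (default 0.03).
#' @param exposure_mean_log Mean of log exposure (log ug/mL; default
#'   `log(16)`, so the median exposure is 16 ug/mL).
#' @param exposure_sd_log Standard deviation of log exposure (default 0.5).
#' @param true_causal_effect Log risk ratio per 1 log-unit higher exposure
#'   (default 0: exposure has no causal effect on the outcome).
#' @param confounder_effect_exposure Effect of the standard-normal shared
#'   confounder on log exposure (log ug/mL per SD; default 0).
#' @param confounder_effect_outcome Effect of the confounder on the log
#'   hazard (default 0).
#' @param reverse_causation_effect Upward shift of log exposure in
#'   individuals whose event falls within `reverse_window` years of study
#'   entry (default 0), emulating preclinical disease raising the measured
#'   biomarker.
#' @param reverse_window Years after entry within which an event triggers
#'   the reverse-causation exposure shift (default 2).
#' @param outcome_base_rate Baseline hazard per year (default 0.005).
#' @param sex_effect_outcome Log-hazard difference for men vs women
#'   (default 0.3).
#' @param entry_age_range Uniform range of study-entry ages (default
#'   `c(40, 80)`).
#' @param followup_max Administrative censoring time in years after entry
#'   (default 15).
#' @param measured_fraction Fraction of individuals with the exposure
#'   measured (default 1; set to ~0.3 to emulate a biomarker subsample).
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_summary_stats()]
#' @export
sim_config <- function(n_individuals = 10000,
                       n_variants = 5,
                       effect_allele_freqs = 0.3,
                       score_r2 = 0.03,
                       exposure_mean_log = log(16),
                       exposure_sd_log = 0.5,
                       true_causal_effect = 0,
                       confounder_effect_exposure = 0,
                       confounder_effect_outcome = 0,
                       reverse_causation_effect = 0,
                       reverse_window = 2,
                       outcome_base_rate = 0.005,
                       sex_effect_outcome = 0.3,
                       entry_age_range = c(40, 80),
                       followup_max = 15,
                       measured_fraction = 1,
                       seed = 1L) {
  if (length(n_individuals) != 1 || n_individuals < 1)
    stop("n_individuals must be a positive count")
  if (length(n_variants) != 1 || n_variants < 1)
    stop("n_variants must be >= 1")
  freqs <- rep_len(as.numeric(effect_allele_freqs), n_variants)
  if (any(freqs <= 0 | freqs >= 1))
    stop("effect_allele_freqs must lie strictly in (0, 1)")
  if (score_r2 < 0 || score_r2 >= 1)
    stop("score_r2 must lie in [0, 1)")
  if (exposure_sd_log <= 0) stop("exposure_sd_log must be positive")
  resid_var <- exposure_sd_log^2 * (1 - score_r2) -
    confounder_effect_exposure^2
  if (resid_var < 0)
    stop("confounder_effect_exposure too large for the requested ",
         "exposure_sd_log and score_r2 (residual variance negative)")
  if (reverse_window < 0) stop("reverse_window must be >= 0")
  if (outcome_base_rate <= 0) stop("outcome_base_rate must be positive")
  if (measured_fraction <= 0 || measured_fraction > 1)
    stop("measured_fraction must lie in (0, 1]")
  if (length(entry_age_range) != 2 || diff(entry_age_range) <= 0)
    stop("entry_age_range must be an increasing pair of ages")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    effect_allele_freqs = freqs,
    score_r2 = score_r2,
    exposure_mean_log = exposure_mean_log,
    exposure_sd_log = exposure_sd_log,
    true_causal_effect = true_causal_effect,
    confounder_effect_exposure = confounder_effect_exposure,
    confounder_effect_outcome = confounder_effect_outcome,
    reverse_causation_effect = reverse_causation_effect,
    reverse_window = reverse_window,
    outcome_base_rate = outcome_base_rate,
    sex_effect_outcome = sex_effect_outcome,
    entry_age_range = as.numeric(entry_age_range),
    followup_max = followup_max,
    measured_fraction = measured_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read a simulation configuration from a flat key-value file
#'
#' The file holds one `key: value` pair per line (YAML mapping); keys are
#' the arguments of [sim_config()]. Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

#' Simulate an individual-level cohort
#'
#' Generates genotypes, a strictly positive exposure, covariates and an
#' interval-censored outcome with the structure a one-sample Mendelian
#' randomization study assumes: genotypes are drawn per variant as
#' binomial(2, eaf); log exposure is a linear genetic effect (equal
#' standardized per-variant effects, rescaled so the allele score explains
#' `score_r2` of its variance in expectation) plus a confounder effect and
#' Gaussian noise; event ages come from an exponential hazard on the age
#' scale depending on log exposure, the confounder and sex, with uniform
#' entry ages (so delayed entry is exercised by construction) and
#' administrative censoring. If `reverse_causation_effect` is non-zero,
#' individuals whose event occurs within `reverse_window` years of entry
#' have their measured log exposure shifted upward, reproducing the
#' discordance pattern in which the observational hazard ratio exceeds 1
#' while the genetic estimate stays null.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` of class `cohort_table` with one row per
#'   individual: columns `id`, `g1..gL` (dosages in 0/1/2), `exposure`
#'   (ug/mL), `log_exposure`, `measured` (logical), `sex` (0 = female,
#'   1 = male), `confounder`, `age_entry`, `age_exit`, `event`. The
#'   generating config is attached as attribute `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 500, seed = 7))
#' head(coh)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  L <- config$n_variants
  f <- config$effect_allele_freqs

  G <- vapply(f, function(p) stats::rbinom(n, 2L, p), integer(n))
  if (n == 1) G <- matrix(G, nrow = 1)
  colnames(G) <- paste0("g", seq_len(L))

  # equal standardized per-variant effects; total genetic variance on the
  # log scale is score_r2 * exposure_sd_log^2 in expectation
  geno_var <- sum(2 * f * (1 - f))
  beta_g <- if (config$score_r2 > 0 && geno_var > 0)
    sqrt(config$score_r2 * config$exposure_sd_log^2 / geno_var) else 0
  confounder <- stats::rnorm(n)
  resid_sd <- sqrt(config$exposure_sd_log^2 * (1 - config$score_r2) -
                     config$confounder_effect_exposure^2)
  centered_score <- as.numeric(G %*% rep(1, L)) - sum(2 * f)
  log_x <- config$exposure_mean_log + beta_g * centered_score +
    config$confounder_effect_exposure * confounder +
    stats::rnorm(n, sd = resid_sd)

  sex <- stats::rbinom(n, 1L, 0.45)
  age_entry <- stats::runif(n, config$entry_age_range[1],
                            config$entry_age_range[2])

  # exponential hazard on the age axis, constant given covariates
  rate <- config$outcome_base_rate *
    exp(config$true_causal_effect * (log_x - config$exposure_mean_log) +
          config$confounder_effect_outcome * confounder +
          config$sex_effect_outcome * sex)
  t_event <- stats::rexp(n, rate)
  censor <- config$followup_max
  event <- as.integer(t_event <= censor)
  age_exit <- age_entry + pmin(t_event, censor)

  if (config$reverse_causation_effect != 0) {
    soon <- event == 1L & t_event <= config$reverse_window
    log_x[soon] <- log_x[soon] + config$reverse_causation_effect
  }

  measured <- rep(TRUE, n)
  if (config$measured_fraction < 1)
    measured <- seq_len(n) %in%
      sample.int(n, size = max(1L, round(config$measured_fraction * n)))

  out <- data.frame(id = seq_len(n), G, exposure = exp(log_x),
                    log_exposure = log_x, measured = measured,
                    sex = sex, confounder = confounder,
                    age_entry = age_entry, age_exit = age_exit,
                    event = event)
  attr(out, "config") <- config
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Emulates a two-sample design: per-variant exposure associations
#' `gamma_j` (log ug/mL per effect allele) with standard errors implied by
#' the exposure-GWAS size, and outcome associations
#' `Gamma_j = true_effect * gamma_j + alpha_j + noise`, where `alpha_j` is
#' a pleiotropic direct effect. Alleles are assigned so that
#' `n_palindromic` variants are palindromic (A/T or C/G), to exercise
#' harmonization.
#'
#' @param n_variants Number of variants (>= 3; default 12, the size of a
#'   genome-wide significant adiponectin instrument).
#' @param true_effect Causal log risk ratio per 1 log-unit exposure.
#' @param pleiotropy_mean Mean of the pleiotropic effects `alpha_j`
#'   (directional pleiotropy when non-zero).
#' @param pleiotropy_sd SD of the pleiotropic effects (default 0).
#' @param n_invalid Number of variants carrying pleiotropy; default all
#'   when `pleiotropy_mean` or `pleiotropy_sd` is non-zero.
#' @param eaf Effect-allele frequencies; default drawn uniform on
#'   (0.1, 0.9).
#' @param n_exposure,n_outcome GWAS sample sizes (defaults 29347 and
#'   1e5); they set the standard errors.
#' @param case_fraction Case fraction of the binary outcome GWAS
#'   (default 0.1); enters the outcome standard errors.
#' @param gamma_mean,gamma_sd Distribution of the true per-variant
#'   exposure effects (defaults 0.1 and 0.02 log-units per allele);
#'   `gamma_mean` may be a vector to give variants unequal strength.
#' @param sd_log SD of log exposure in the exposure GWAS (default 0.5).
#' @param n_palindromic How many variants get palindromic allele pairs
#'   (default 2 of 12).
#' @param noise If `FALSE`, observed betas equal their true values
#'   (useful for exact-identity checks); standard errors are still
#'   reported.
#' @param seed Integer seed.
#'
#' @return A list of class `summary_pair` with elements `exposure` and
#'   `outcome`, each a `summary_stats` data.frame with columns
#'   `id, effect_allele, other_allele, eaf, beta, se, n`, plus the vector
#'   of true pleiotropic effects as attribute `alpha`.
#' @examples
#' ss <- simulate_summary_stats(n_variants = 12, true_effect = 0, seed = 1)
#' ss$exposure
#' @export
simulate_summary_stats <- function(n_variants = 12,
                                   true_effect = 0,
                                   pleiotropy_mean = 0,
                                   pleiotropy_sd = 0,
                                   n_invalid = NULL,
                                   eaf = NULL,
                                   n_exposure = 29347,
                                   n_outcome = 100000,
                                   case_fraction = 0.1,
                                   gamma_mean = 0.1,
                                   gamma_sd = 0.02,
                                   sd_log = 0.5,
                                   n_palindromic = 2,
                                   noise = TRUE,
                                   seed = 1L) {
  if (n_variants < 3)
    stop("n_variants must be >= 3 for regression-based estimators")
  if (n_palindromic > n_variants)
    stop("n_palindromic cannot exceed n_variants")
  set.seed(as.integer(seed))
  if (is.null(eaf)) eaf <- stats::runif(n_variants, 0.1, 0.9)
  eaf <- rep_len(eaf, n_variants)

  # per-allele regression SEs: se ~ sd(resid) / sqrt(2 f (1-f) n)
  se_x <- sd_log / sqrt(2 * eaf * (1 - eaf) * n_exposure)
  se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * n_outcome *
                     case_fraction * (1 - case_fraction))

  gamma_true <- abs(stats::rnorm(n_variants, rep_len(gamma_mean, n_variants),
                                 gamma_sd))
  if (is.null(n_invalid))
    n_invalid <- if (pleiotropy_mean != 0 || pleiotropy_sd != 0)
      n_variants else 0
  alpha <- numeric(n_variants)
  if (n_invalid > 0)
    alpha[seq_len(n_invalid)] <-
      stats::rnorm(n_invalid, pleiotropy_mean, pleiotropy_sd)

  if (noise) {
    gamma_hat <- gamma_true + stats::rnorm(n_variants, sd = se_x)
    Gamma_hat <- true_effect * gamma_true + alpha +
      stats::rnorm(n_variants, sd = se_y)
  } else {
    gamma_hat <- gamma_true
    Gamma_hat <- true_effect * gamma_true + alpha
  }

  pal_pairs <- list(c("A", "T"), c("C", "G"))
  nonpal_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  is_pal <- seq_len(n_variants) %in%
    sample.int(n_variants, n_palindromic)
  alleles <- t(vapply(seq_len(n_variants), function(j) {
    if (is_pal[j]) pal_pairs[[1 + (j %% 2)]] else
      nonpal_pairs[[1 + (j %% 4)]]
  }, character(2)))

  ids <- sprintf("rs%06d", seq_len(n_variants))
  exposure <- summary_stats(data.frame(
    id = ids, effect_allele = alleles[, 1], other_allele = alleles[, 2],
    eaf = eaf, beta = gamma_hat, se = se_x, n = n_exposure))
  outcome <- summary_stats(data.frame(
    id = ids, effect_allele = alleles[, 1], other_allele = alleles[, 2],
    eaf = eaf, beta = Gamma_hat, se = se_y, n = n_outcome))
  out <- list(exposure = exposure, outcome = outcome)
  attr(out, "alpha") <- alpha
  attr(out, "gamma_true") <- gamma_true
  class(out) <- "summary_pair"
  out
}

#' Validate a GWAS summary-statistics table
#'
#' Checks and stamps a data.frame with the standard per-variant columns
#' `id, effect_allele, other_allele, eaf, beta, se, n`. The same layout is
#' produced by MR-Base-style exports, [simulate_summary_stats()] and
#' [per_variant_associations()], so every estimator consumes one-sample
#' and two-sample inputs identically.
#'
#' @param x A data.frame with the seven standard columns.
#' @return `x` with class `summary_stats` prepended.
#' @export
summary_stats <- function(x) {
  need <- c("id", "effect_allele", "other_allele", "eaf", "beta", "se", "n")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("summary statistics lack columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$id))
    stop("duplicate variant ids in summary statistics")
  bases <- c("A", "C", "G", "T")
  if (!all(x$effect_allele %in% bases) || !all(x$other_allele %in% bases))
    stop("alleles must be single bases A/C/G/T")
  if (any(x$effect_allele == x$other_allele))
    stop("effect and other allele must differ")
  if (any(x$se <= 0)) stop("all standard errors must be positive")
  if (any(x$eaf <= 0 | x$eaf >= 1))
    stop("effect-allele frequencies must lie in (0, 1)")
  x <- as.data.frame(x)
  class(x) <- c("summary_stats", "data.frame")
  x
}

#' Read / write summary statistics and cohort tables
#'
#' Delimited text with a one-line header. `read_summary_stats()` accepts
#' any file with (at least) the seven standard columns, including
#' MR-Base-style exports.
#'
#' @param path File path.
#' @param sep Field delimiter (default tab).
#' @return `read_summary_stats()` a `summary_stats` data.frame;
#'   `read_cohort()` a `cohort_table` data.frame.
#' @export
read_summary_stats <- function(path, sep = "\t") {
  summary_stats(utils::read.table(path, header = TRUE, sep = sep,
                                  stringsAsFactors = FALSE))
}

#' @rdname read_summary_stats
#' @param x Table to write.
#' @export
write_summary_stats <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "summary_stats"))
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_summary_stats
#' @export
read_cohort <- function(path, sep = "\t") {
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  validate_cohort(out)
  out
}

#' @rdname read_summary_stats
#' @export
write_cohort <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "cohort_table"))
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: structural invariants of a cohort table
validate_cohort <- function(cohort) {
  g <- genotype_columns(cohort)
  dos <- as.matrix(cohort[g])
  if (!all(dos %in% 0:2)) stop("genotype dosages must be 0, 1 or 2")
  if (any(cohort$exposure[cohort$measured] <= 0))
    stop("measured exposures must be strictly positive")
  if (any(cohort$age_exit <= cohort$age_entry))
    stop("every exit age must exceed the entry age")
  invisible(cohort)
}

# internal: names of the dosage columns g1..gL
genotype_columns <- function(cohort) {
  grep("^g[0-9]+$", names(cohort), value = TRUE)
}

#' @export
print.summary_pair <- function(x, ...) {
  cat("Paired GWAS summary statistics:", nrow(x$exposure), "variants\n")
  cat("  exposure n =", x$exposure$n[1],
      "; outcome n =", x$outcome$n[1], "\n")
  invisible(x)
}
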
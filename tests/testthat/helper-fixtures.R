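# Shared fixtures, built in code.

# Minimal harmonizable summary table from raw vectors.
make_stats <- function(beta, se, eaf = NULL, ea = "A", oa = "G",
                       id = NULL, n = 10000) {
  L <- length(beta)
  if (is.null(eaf)) eaf <- rep(0.3, L)
  if (is.null(id)) id <- sprintf("rs%03d", seq_len(L))
  summary_stats(data.frame(
    id = id, effect_allele = rep_len(ea, L), other_allele = rep_len(oa, L),
    eaf = eaf, beta = beta, se = se, n = n))
}

# Aligned exposure/outcome pair from gamma, Gamma and their SEs.
make_pair <- function(gamma, Gamma, se_x, se_y, ...) {
  list(exposure = make_stats(gamma, se_x, ...),
       outcome = make_stats(Gamma, se_y, ...))
}

# 30-row survival fixture with delayed entry and tied event times,
# deterministic by construction.
tied_cox_fixture <- function() {
  set.seed(421)
  n <- 30
  z <- rep(0:1, each = n / 2)
  # integer ages force heavy ties in the event times
  entry <- sample(50:54, n, replace = TRUE)
  exit <- entry + sample(1:5, n, replace = TRUE) + ifelse(z == 1, 0, 1)
  event <- rbinom(n, 1, 0.7)
  data.frame(entry = entry, exit = exit, event = event, z = z)
}

# Brute-force Efron partial log-likelihood for a single binary covariate
# with delayed entry; independent of the survival package.
efron_loglik <- function(beta, d) {
  times <- sort(unique(d$exit[d$event == 1]))
  ll <- 0
  for (t in times) {
    dead <- which(d$event == 1 & d$exit == t)
    risk <- which(d$entry < t & d$exit >= t)
    m <- length(dead)
    eta <- exp(beta * d$z)
    sum_risk <- sum(eta[risk])
    sum_dead <- sum(eta[dead])
    ll <- ll + beta * sum(d$z[dead])
    for (l in seq_len(m) - 1) {
      ll <- ll - log(sum_risk - (l / m) * sum_dead)
    }
  }
  ll
}
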
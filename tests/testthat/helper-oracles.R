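# Independent brute-force oracles used to validate the package's estimators.
# These deliberately share no code with the implementation paths they check.

# ICC(2,1) via R's two-way ANOVA fit (subject + rater), Shrout-Fleiss
# absolute-agreement single-rater form.
oracle_icc21 <- function(x1, x2) {
  n <- length(x1)
  d <- data.frame(value = c(x1, x2),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Kaplan-Meier product-limit by explicit risk-set walking.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), survival = numeric(0),
                    n_risk = numeric(0), n_event = numeric(0))
  for (t in ut) {
    n_risk <- sum(time >= t)          # events precede censorings at ties
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, survival = s,
                                 n_risk = n_risk, n_event = d))
  }
  out
}

# Multi-group log-rank chi-square by observed-vs-expected tabulation with the
# hypergeometric covariance, dropping the last group and inverting.
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.integer(factor(group))
  g <- max(group)
  ut <- sort(unique(time[event == 1]))
  OmE <- numeric(g)
  V <- matrix(0, g, g)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    for (i in seq_len(g)) {
      ni <- sum(at_risk & group == i)
      di <- sum(time == t & event == 1 & group == i)
      OmE[i] <- OmE[i] + di - d * ni / n
      for (j in seq_len(g)) {
        nj <- sum(at_risk & group == j)
        delta <- as.numeric(i == j)
        if (n > 1)
          V[i, j] <- V[i, j] +
            d * (ni / n) * (delta - nj / n) * (n - d) / (n - 1)
      }
    }
  }
  idx <- seq_len(g - 1)
  drop(t(OmE[idx]) %*% solve(V[idx, idx]) %*% OmE[idx])
}

# Harrell's C by exhaustive pair enumeration. Comparability: the shorter
# observed time is an event; at tied times an event-censoring pair counts
# (the censored subject survived at least as long), an event-event tie does
# not. Tied risks score 1/2.
oracle_cindex <- function(risk, time, event) {
  n <- length(risk)
  conc <- 0; comp <- 0
  score <- function(r_short, r_long) {
    if (r_short > r_long) 1 else if (r_short == r_long) 0.5 else 0
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]
    if (ti < tj && event[i] == 1) {
      comp <- comp + 1; conc <- conc + score(risk[i], risk[j])
    } else if (tj < ti && event[j] == 1) {
      comp <- comp + 1; conc <- conc + score(risk[j], risk[i])
    } else if (ti == tj && event[i] != event[j]) {
      s <- if (event[i] == 1) i else j
      l <- if (event[i] == 1) j else i
      comp <- comp + 1; conc <- conc + score(risk[s], risk[l])
    }
  }
  conc / comp
}

# Plain binary AUC by pair enumeration (ties 0.5).
oracle_binary_auc <- function(risk, label) {
  pos <- risk[label == 1]; neg <- risk[label == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Monotone-trajectory check used across factorization tests: non-increasing
# within 1e-9 relative, with an absolute guard at machine-zero scale.
expect_monotone_trajectory <- function(tr) {
  slack <- 1e-9 * tr[-length(tr)] + 1e-12 * max(tr, .Machine$double.xmin)
  expect_true(all(diff(tr) <= slack))
}

# Small high-signal cohort used by several modules.
smallCohort <- function(seed = 1, n = 80, k_f = 4) {
  simulateCohort(cohortConfig(n_patients = n, n_features_pet = 40,
                              n_features_ct = 20, k_f = k_f, seed = seed))
}
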
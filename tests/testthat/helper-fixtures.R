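# Shared fixture builders. Everything is generated in code; no stored data.

# A minimal beep-record table on the full (day, beep) grid for one person,
# with all catalogue item columns present but only `motives` filled.
toy_records <- function(person_id = "P01", n_days = 2, beeps_per_day = 3,
                        motives = c("intimacy", "autonomy"),
                        values = NULL, status = NULL, latency_s = 120,
                        mood = NULL) {
  n <- n_days * beeps_per_day
  prompt <- as.POSIXct("2024-03-04 10:00:00", tz = "UTC") +
    rep((seq_len(n_days) - 1) * 86400, each = beeps_per_day) +
    rep(seq_len(beeps_per_day) - 1, n_days) * 7200
  status <- status %||% rep("completed", n)
  latency_s <- rep_len(latency_s, n)
  response <- prompt + latency_s
  response[status != "completed"] <- NA
  df <- data.frame(person_id = person_id,
                   day = rep(seq_len(n_days), each = beeps_per_day),
                   beep = rep(seq_len(beeps_per_day), n_days),
                   prompt_time = prompt, response_time = response,
                   initiation = "prompted", status = status,
                   stringsAsFactors = FALSE)
  items <- matrix(NA_real_, n, 14,
                  dimnames = list(NULL, paste0("m_", motive_catalogue())))
  if (is.null(values)) values <- matrix(5, n, length(motives))
  items[, paste0("m_", motives)] <- values
  items[status != "completed", ] <- NA
  mood <- mood %||% rep(4, n)
  mood[status != "completed"] <- NA
  cbind(df, as.data.frame(items, check.names = FALSE), mood = mood)
}

# Latent-scale person series (continuous, single or multi-day grid).
latent_series <- function(model, n, seed, days = rep(1L, n)) {
  X <- simulate_latent_var(model, n, seed = seed)
  person_series(model$person_id, model$node_labels, X, days)
}

# Person-level index/outcome table with planted regression structure.
toy_person_table <- function(n, beta_sat = 0, beta_idx = 0, noise_sd = 0.5,
                             intercept = 3, floor = -Inf, seed = 1) {
  withr::local_seed(seed)
  tab <- data.frame(
    person_id = sprintf("P%03d", seq_len(n)),
    mean_satisfaction = rnorm(n, 6, 0.5),
    conflict_proportion = runif(n, 0, 0.3),
    max_conflict = -runif(n, 0, 0.35),
    max_concordance = runif(n, 0.1, 0.7))
  tab$dass_d <- pmax(floor, intercept + beta_sat * tab$mean_satisfaction +
                       beta_idx * tab$max_concordance +
                       rnorm(n, 0, noise_sd))
  tab
}

# Independent two-sided regression-residual partial correlation: regress
# node i and node j each on all remaining nodes, correlate the residuals.
# This is the oracle the precision-inversion implementation must match.
pcor_regression_oracle <- function(E) {
  m <- ncol(E)
  P <- diag(0, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    others <- E[, -c(i, j), drop = FALSE]
    ri <- if (ncol(others) > 0) stats::resid(stats::lm(E[, i] ~ others))
          else E[, i] - mean(E[, i])
    rj <- if (ncol(others) > 0) stats::resid(stats::lm(E[, j] ~ others))
          else E[, j] - mean(E[, j])
    P[i, j] <- P[j, i] <- stats::cor(ri, rj)
  }
  P
}

# Gaussian marginal log-likelihood of a random-intercept model evaluated at
# given fixed effects and variance components (used to check the ML
# optimum dominates the pooled-OLS corner).
ri_loglik <- function(dataset, beta, var_ri, var_res) {
  X <- cbind(1, dataset$person_mean_satisfaction,
             dataset$satisfaction_centered)
  r <- dataset$mood - X %*% beta
  ll <- 0
  for (pid in unique(dataset$person_id)) {
    ri <- r[dataset$person_id == pid]
    n <- length(ri)
    V <- diag(var_res, n) + matrix(var_ri, n, n)
    ll <- ll + mvtnorm_dens(ri, V)
  }
  ll
}

mvtnorm_dens <- function(x, V) {
  ch <- chol(V)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, x, transpose = TRUE)^2))
}
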
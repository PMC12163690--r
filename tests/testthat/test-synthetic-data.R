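test_that("config validation rejects impossible designs", {
  expect_error(sim_config(missing_rate = 1.2), "probability")
  expect_error(sim_config(n_days = 0), "positive count")
  expect_error(sim_config(negative_edge_strength = c(0.3, 0.1)), "range")
  expect_equal(sim_config()$n_days * sim_config()$beeps_per_day, 36)
})

test_that("planted partial-correlation truth respects signs and definiteness", {
  cfg0 <- sim_config(negative_edge_rate = 0)
  for (i in 1:5) {
    mod <- make_person_model(cfg0, i, seed = 3)
    off <- mod$contemporaneous_pcor[upper.tri(mod$contemporaneous_pcor)]
    expect_true(all(off >= 0))
    expect_true(all(diag(mod$contemporaneous_pcor) == 1))
    # implied precision positive definite
    K <- -mod$contemporaneous_pcor; diag(K) <- 1
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
    # stationarity
    expect_lt(max(Mod(eigen(mod$temporal_matrix, only.values = TRUE)$values)), 1)
  }
})

test_that("zero temporal dynamics yield serially uncorrelated series", {
  cfg <- sim_config(ar_range = c(0, 0), cross_lag_sd = 0)
  mod <- make_person_model(cfg, 1, seed = 2)
  expect_equal(max(abs(mod$temporal_matrix)), 0)
  X <- simulate_latent_var(mod, 5000, seed = 9)
  ac <- vapply(seq_len(ncol(X)), function(j)
    stats::cor(X[-1, j], X[-nrow(X), j]), numeric(1))
  expect_lt(max(abs(ac)), 0.05)
})

test_that("stationary covariance solves the discrete Lyapunov equation", {
  # oracle: fixed-point iteration Sigma <- B Sigma B' + Psi
  cfg <- sim_config(n_selected = 3)
  mod <- make_person_model(cfg, 1, seed = 4)
  omega_off <- c(0.4, -0.3, 0.0)
  K <- diag(3); K[upper.tri(K)] <- -omega_off; K[lower.tri(K)] <- t(K)[lower.tri(K)]
  Psi <- solve(K)
  B <- mod$temporal_matrix
  S_iter <- diag(3)
  for (it in 1:2000) S_iter <- B %*% S_iter %*% t(B) + Psi
  expect_equal(stationary_cov(B, Psi), S_iter, tolerance = 1e-10)
})

test_that("each person gets the full scheduled beep grid", {
  cfg <- sim_config(n_participants = 2)
  mod <- make_person_model(cfg, 1, seed = 1)
  rec <- simulate_person_series(mod, cfg, 1, seed = 1)
  expect_equal(nrow(rec), 36)
  expect_equal(unname(table(rec$day)), rep(6L, 6), ignore_attr = TRUE)

  # prompt window and >= 60-minute spacing
  for (d in unique(rec$day)) {
    tt <- rec$prompt_time[rec$day == d]
    h <- as.numeric(format(tt, "%H")) + as.numeric(format(tt, "%M")) / 60
    expect_true(all(h >= 9.5 & h <= 21.5))
    expect_true(all(diff(as.numeric(tt)) >= 3600))
  }
})

test_that("missingness boundary cases behave", {
  cfg <- sim_config(missing_rate = 0, n_participants = 1)
  mod <- make_person_model(cfg, 1, seed = 6)
  rec <- simulate_person_series(mod, cfg, 1, seed = 6)
  expect_true(all(rec$status == "completed"))
  expect_false(anyNA(rec[, paste0("m_", mod$node_labels)]))
})

test_that("completed share stays inside binomial bounds at the study design", {
  share <- vapply(1:20, function(s) {
    cfg <- sim_config()
    done <- 0L
    for (i in 1:51) {
      mod <- make_person_model(cfg, i, seed = 500 + s)
      rec <- simulate_person_series(mod, cfg, i, seed = 500 + s)
      done <- done + sum(rec$status == "completed")
    }
    done / (51 * 36)
  }, numeric(1))
  expect_true(all(share >= 0.76 & share <= 0.86))
})

test_that("the same seed reproduces the study bit-for-bit and persons are stable", {
  cfg <- sim_config(n_participants = 5)
  s1 <- simulate_study(cfg, seed = 11)
  s2 <- simulate_study(cfg, seed = 11)
  expect_identical(s1$beeps, s2$beeps)
  expect_identical(s1$outcome, s2$outcome)

  # enlarging the sample never perturbs earlier persons
  s3 <- simulate_study(sim_config(n_participants = 8), seed = 11)
  expect_identical(s1$beeps, s3$beeps[s3$beeps$person_id %in%
                                        unique(s1$beeps$person_id), ])
})

test_that("baseline generation honours the planted truth and the floor", {
  cfg <- sim_config(n_participants = 6)
  models <- lapply(1:6, function(i) make_person_model(cfg, i, seed = 8))
  idx <- true_network_indices(models)

  tr0 <- between_truth(intercept = 2, beta_satisfaction = 0, beta_index = 0,
                       noise_sd = 1e-12)
  base <- simulate_baseline(models, tr0, idx, seed = 8)
  expect_equal(base$outcome$dass_d, rep(2, 6), tolerance = 1e-6)

  tr <- between_truth()
  base <- simulate_baseline(models, tr, idx, seed = 8)
  expect_true(all(base$outcome$dass_d >= tr$floor))

  # importance scores guarantee deterministic top-k selection of the nodes
  prof <- importance_profiles(base$importance)
  for (i in 1:6)
    expect_equal(top_k_motives(prof[[models[[i]]$person_id]], 7),
                 models[[i]]$node_labels)
})

test_that("OLS recovers the planted satisfaction slope at n = 200", {
  cfg <- sim_config(n_participants = 200)
  models <- lapply(1:200, function(i) make_person_model(cfg, i, seed = 13))
  idx <- true_network_indices(models)
  withr::local_seed(13)
  idx$mean_satisfaction <- idx$mean_satisfaction + rnorm(200, 0, 0.3)
  tr <- between_truth(floor = -Inf)   # uncensored, pure linear truth
  base <- simulate_baseline(models, tr, idx, seed = 13)
  tab <- merge(idx, base$outcome, by = "person_id")
  fit <- ols_fit(tab, "dass_d", c("mean_satisfaction", "max_concordance"))
  co <- fit$coefficients[fit$coefficients$term == "mean_satisfaction", ]
  expect_lt(abs(co$b - tr$beta_satisfaction), 2 * co$SE)
})

test_that("long-run innovation partial correlations match the planted truth", {
  cfg <- sim_config()
  for (i in 1:3) {
    mod <- make_person_model(cfg, i, seed = 21)
    X <- simulate_latent_var(mod, 5000, seed = 600 + i)
    f <- fit_person_var(person_series("p", mod$node_labels, X, rep(1, 5000)))
    est <- residual_pcor(f$residuals)$pcor
    tru <- mod$contemporaneous_pcor
    err <- abs(est[upper.tri(est)] - tru[upper.tri(tru)])
    # per-edge sampling SE at T = 5000 is ~0.014: the average error must be
    # well inside it and no single edge may stray beyond ~5 SE
    expect_lt(mean(err), 0.02)
    expect_lt(max(err), 0.075)

    # discretisation to 0-9 attenuates but never flips strong edges
    Xd <- pmax(pmin(floor(X + 0.5), 9), 0)
    fd <- fit_person_var(person_series("p", mod$node_labels, Xd, rep(1, 5000)))
    estd <- residual_pcor(fd$residuals)$pcor
    strong <- abs(tru) >= 0.2 & upper.tri(tru)
    if (any(strong))
      expect_true(all(sign(estd[strong]) == sign(tru[strong])))
  }
})

test_that("study CSVs round-trip through the strict reader", {
  study <- simulate_study(sim_config(n_participants = 3), seed = 5)
  dir <- withr::local_tempdir()
  write_study_csv(study, dir)
  back <- read_beeps_csv(file.path(dir, "beeps.csv"))
  expect_equal(nrow(back), nrow(study$beeps))
  expect_equal(back$status, study$beeps$status)
  expect_equal(back$prompt_time, study$beeps$prompt_time)
  expect_equal(back[["m_intimacy"]], study$beeps[["m_intimacy"]])
})
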
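test_that("lag pairs form only within days and drop around missing slots", {
  cfg <- sim_config(n_participants = 1, missing_rate = 0)
  mod <- make_person_model(cfg, 1, seed = 2)
  X <- matrix(rep(1:36, 7), 36, 7)
  s <- person_series("p", mod$node_labels, X, rep(1:6, each = 6))
  expect_equal(build_lag_pairs(s)$n_pairs, 30)

  # one missing slot mid-day kills its incoming and outgoing pair
  X2 <- X; X2[3, ] <- NA
  s2 <- person_series("p", mod$node_labels, X2, rep(1:6, each = 6))
  expect_equal(build_lag_pairs(s2)$n_pairs, 28)

  # fully missing person
  s3 <- person_series("p", mod$node_labels, X * NA, rep(1:6, each = 6))
  expect_equal(build_lag_pairs(s3)$n_pairs, 0)
})

test_that("too few pairs raises a classed, catchable condition", {
  cfg <- sim_config(n_selected = 3)
  mod <- make_person_model(cfg, 1, seed = 2)
  s <- latent_series(mod, 8, seed = 1)
  expect_error(fit_person_var(s, min_pairs = 12),
               class = "motivenets_too_few_pairs")
})

test_that("temporal coefficients recover the generator truth", {
  cfg <- sim_config(n_selected = 3)
  for (i in 1:3) {
    mod <- make_person_model(cfg, i, seed = 31)
    s <- latent_series(mod, 5000, seed = 700 + i)
    f <- fit_person_var(s)
    expect_lt(max(abs(f$temporal - mod$temporal_matrix)), 0.05)
  }

  # zero dynamics
  cfg0 <- sim_config(n_selected = 3, ar_range = c(0, 0), cross_lag_sd = 0)
  mod0 <- make_person_model(cfg0, 1, seed = 32)
  f0 <- fit_person_var(latent_series(mod0, 5000, seed = 71))
  expect_lt(max(abs(f0$temporal)), 0.05)
})

test_that("a constant node is dropped with a warning", {
  cfg <- sim_config(n_selected = 3)
  mod <- make_person_model(cfg, 1, seed = 2)
  X <- simulate_latent_var(mod, 40, seed = 2)
  X[, 2] <- 5
  s <- person_series("p", mod$node_labels, X, rep(1, 40))
  expect_warning(f <- fit_person_var(s), "zero-variance")
  expect_equal(f$nodes, mod$node_labels[-2])
  expect_equal(dim(f$temporal), c(2, 2))
})

test_that("independent residuals give a near-empty network", {
  withr::local_seed(5)
  E <- matrix(rnorm(5000 * 4), 5000, 4)
  pp <- residual_pcor(E, ridge = 0)
  expect_lt(max(abs(network_edges(pp$pcor))), 0.05)
  expect_equal(diag(pp$pcor), rep(0, 4))
})

test_that("precision inversion equals the two-sided regression oracle", {
  withr::local_seed(8)
  E <- matrix(rnorm(60 * 3), 60, 3) %*%
    matrix(c(1, 0.4, 0.2, 0, 1, -0.3, 0, 0, 1), 3, 3)
  pp <- residual_pcor(E, ridge = 0)
  expect_equal(pp$pcor, pcor_regression_oracle(E), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("partial correlations are invariant to positive rescaling of a node", {
  withr::local_seed(9)
  for (i in 1:5) {
    m <- sample(3:6, 1)
    E <- matrix(rnorm(50 * m), 50, m) %*% (diag(m) + matrix(runif(m * m, -0.3, 0.3), m, m))
    p1 <- residual_pcor(E, ridge = 0)$pcor
    E2 <- E
    E2[, 1] <- E2[, 1] * runif(1, 0.1, 10)
    p2 <- residual_pcor(E2, ridge = 0)$pcor
    expect_equal(p1, p2, tolerance = 1e-10)
  }
})

test_that("planted signs are recovered from long latent series", {
  cfg <- sim_config()
  for (i in 1:3) {
    mod <- make_person_model(cfg, i, seed = 33)
    f <- fit_person_var(latent_series(mod, 500, seed = 720 + i))
    est <- residual_pcor(f$residuals)$pcor
    tru <- mod$contemporaneous_pcor
    strong <- abs(tru) >= 0.25 & upper.tri(tru)
    if (any(strong))
      expect_true(all(sign(est[strong]) == sign(tru[strong])))
  }
})

test_that("a single participant is unaffected by the estimation mode", {
  cfg <- sim_config()
  mod <- make_person_model(cfg, 1, seed = 34)
  s <- latent_series(mod, 60, seed = 73)
  pw <- estimate_all(list(s), mode = "person_wise")
  # with one person the pooled target is that person's own matrix, so
  # shrinkage toward it is a no-op
  ps <- estimate_all(list(s), mode = "pooled_shrunk")
  expect_equal(pw$networks[[1]]$pcor, ps$networks[[1]]$pcor,
               tolerance = 1e-10)
})

test_that("total shrinkage collapses everyone onto the pooled network", {
  cfg <- sim_config()
  mod <- make_person_model(cfg, 1, seed = 35)
  series <- lapply(1:3, function(i) {
    s <- latent_series(mod, 60, seed = 80 + i)
    s$person_id <- paste0("P", i)
    s
  })
  names(series) <- paste0("P", 1:3)
  est <- estimate_all(series, mode = "pooled_shrunk", lambda = 1)
  expect_equal(est$networks[[1]]$pcor, est$networks[[2]]$pcor,
               tolerance = 1e-10)
  expect_equal(est$networks[[2]]$pcor, est$networks[[3]]$pcor,
               tolerance = 1e-10)
})

test_that("failing persons are flagged, not dropped silently", {
  cfg <- sim_config()
  mod <- make_person_model(cfg, 1, seed = 36)
  good <- latent_series(mod, 60, seed = 90)
  short <- latent_series(mod, 6, seed = 91)
  short$person_id <- "Pshort"
  est <- estimate_all(stats::setNames(list(good, short), c("P01", "Pshort")))
  expect_length(est$networks, 1)
  expect_equal(est$flagged$person_id, "Pshort")
  expect_match(est$flagged$reason, "lag pairs")
})

test_that("pooled shrinkage beats person-wise fits at the study length", {
  # study-scale comparison: mean absolute edge error against the planted
  # truth, 3 replicate cohorts
  cfg <- sim_config(n_participants = 20)
  better <- logical(3)
  for (r in 1:3) {
    st <- simulate_study(cfg, seed = 800 + r, indices_from = "none")
    sel <- lapply(st$models, function(m) m$node_labels)
    names(sel) <- vapply(st$models, `[[`, character(1), "person_id")
    ser <- assemble_series(apply_validity_filter(st$beeps), sel)
    mae <- vapply(c("person_wise", "pooled_shrunk"), function(md) {
      est <- estimate_all(ser, mode = md)
      errs <- unlist(lapply(est$networks, function(net) {
        tru <- st$models[[net$person_id]]$contemporaneous_pcor
        abs(network_edges(net) - tru[upper.tri(tru)])
      }))
      mean(errs)
    }, numeric(1))
    better[r] <- mae["pooled_shrunk"] < mae["person_wise"]
  }
  expect_true(all(better))
})

test_that("network export formats carry the full edge set", {
  cfg <- sim_config()
  mod <- make_person_model(cfg, 1, seed = 37)
  est <- estimate_all(list(P01 = latent_series(mod, 60, seed = 95)))
  net <- est$networks[[1]]
  dir <- withr::local_tempdir()
  jp <- write_network_json(net, file.path(dir, "net.json"))
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$nodes, net$nodes)
  expect_equal(as.matrix(back$pcor), unname(net$pcor), tolerance = 1e-12)
  ep <- write_edge_list(net, file.path(dir, "edges.tsv"))
  el <- utils::read.delim(ep)
  expect_equal(nrow(el), choose(length(net$nodes), 2))
  expect_equal(el$weight, network_edges(net), tolerance = 1e-12)
})
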
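test_that("OLS reports the classical columns with the right df", {
  tab <- toy_person_table(51, beta_sat = -0.2, beta_idx = -1, seed = 2)
  fit <- ols_fit(tab, "dass_d", c("mean_satisfaction", "max_concordance"))
  expect_equal(unique(fit$coefficients$df), 48)
  expect_equal(nrow(fit$coefficients), 3)
  # agrees with lm directly
  ref <- summary(lm(dass_d ~ mean_satisfaction + max_concordance, tab))
  expect_equal(fit$coefficients$b, unname(ref$coefficients[, 1]))
  expect_equal(fit$coefficients$SE, unname(ref$coefficients[, 2]))
})

test_that("perfect fits and collinear designs are caught", {
  tab <- toy_person_table(20, seed = 3)
  tab$dass_d <- 1 + 2 * tab$mean_satisfaction
  w <- capture_warnings(ols_fit(tab, "dass_d", "mean_satisfaction"))
  expect_match(w, "degenerate", all = FALSE)

  tab$dup <- 2 * tab$mean_satisfaction
  expect_error(ols_fit(tab, "dass_d", c("mean_satisfaction", "dup")),
               "collinear.*dup")
  tab$const <- 1
  expect_error(ols_fit(tab, "dass_d", c("mean_satisfaction", "const")),
               "collinear")
})

test_that("coefficients recover a known truth at n = 500", {
  tab <- toy_person_table(500, beta_sat = -0.15, beta_idx = -1.1,
                          noise_sd = 0.5, seed = 4)
  fit <- ols_fit(tab, "dass_d", c("mean_satisfaction", "max_concordance"))
  co <- fit$coefficients
  expect_lt(abs(co$b[co$term == "mean_satisfaction"] + 0.15),
            2 * co$SE[co$term == "mean_satisfaction"])
  expect_lt(abs(co$b[co$term == "max_concordance"] + 1.1),
            2 * co$SE[co$term == "max_concordance"])
})

test_that("BCa reduces to the percentile interval in the symmetric case", {
  withr::local_seed(5)
  x <- rnorm(200)
  ci_b <- bca_interval(mean, x, n_boot = 2000, seed = 42)
  ci_p <- bca_interval(mean, x, n_boot = 2000, seed = 42,
                       method = "percentile")
  expect_lt(max(abs(ci_b - ci_p)), 0.02)
  expect_lt(abs(attr(ci_b, "z0")), 0.1)
  expect_lt(abs(attr(ci_b, "a")), 0.05)
})

test_that("intervals are bit-identical under a fixed seed", {
  withr::local_seed(6)
  x <- rexp(50)
  a <- bca_interval(mean, x, n_boot = 500, seed = 7)
  b <- bca_interval(mean, x, n_boot = 500, seed = 7)
  expect_identical(a, b)
  c2 <- bca_interval(mean, x, n_boot = 500, seed = 8)
  expect_false(identical(as.numeric(a), as.numeric(c2)))
})

test_that("degenerate bootstrap distributions are handled", {
  x <- rep(3, 20)
  expect_warning(ci <- bca_interval(mean, x, n_boot = 100, seed = 1),
                 "degenerate")
  expect_equal(as.numeric(ci), c(3, 3))
  # statistic identically zero: never excludes zero
  expect_equal(suppressWarnings(bootstrap_p(function(d) 0, rnorm(20),
                                            n_boot = 100, seed = 1)), 1)
})

test_that("bootstrap p-values track effect strength and stay CI-coherent", {
  withr::local_seed(8)
  n <- 200
  x <- rnorm(n)
  slope_stat <- function(d) stats::lm.fit(cbind(1, d$x), d$y)$coefficients[2]
  p_prev <- Inf
  ps <- c()
  for (eff in c(0.5, 0.25, 0.05)) {
    d <- data.frame(x = x, y = eff * x + rnorm(n, 0, 1))
    ps <- c(ps, bootstrap_p(slope_stat, d, n_boot = 800, seed = 9))
  }
  expect_lt(ps[1], 0.01)           # |b|/SE ~ 7: decisively nonzero
  expect_true(all(diff(ps) >= 0))  # weaker planted effect, larger p

  # coherence: p < alpha exactly when the (1 - alpha) interval excludes 0
  for (i in 1:5) {
    d <- data.frame(x = x, y = 0.12 * x + rnorm(n))
    ci <- bca_interval(slope_stat, d, n_boot = 500, seed = 20 + i)
    p <- bootstrap_p(slope_stat, d, n_boot = 500, seed = 20 + i)
    expect_equal(p < 0.05, ci[1] > 0 || ci[2] < 0)
  }
})

test_that("the three-model report carries analytic and bootstrap columns", {
  tab <- toy_person_table(51, beta_sat = -0.15, beta_idx = -1.1,
                          noise_sd = 0.4, floor = 1, seed = 10)
  rep3 <- run_table3(tab[, -which(names(tab) == "dass_d")],
                     tab[, c("person_id", "dass_d")],
                     n_boot = 400, seed = 3)
  expect_equal(nrow(rep3), 6)
  expect_equal(unique(rep3$df), 48)
  expect_setequal(unique(rep3$model),
                  c("conflict_proportion", "max_conflict", "max_concordance"))
  expect_true(all(rep3$boot_lo < rep3$boot_hi))
  expect_true(all(rep3$boot_p >= 0 & rep3$boot_p <= 1))
  d <- attr(rep3, "diagnostics")
  expect_named(d, c("conflict_proportion", "max_conflict", "max_concordance"))

  # reruns reproduce bit-for-bit
  rep3b <- run_table3(tab[, -which(names(tab) == "dass_d")],
                      tab[, c("person_id", "dass_d")],
                      n_boot = 400, seed = 3)
  expect_identical(as.data.frame(rep3), as.data.frame(rep3b))

  # a constant index column is a collinearity error
  tab2 <- tab
  tab2$max_conflict <- 0
  expect_error(run_table3(tab2[, -which(names(tab2) == "dass_d")],
                          tab2[, c("person_id", "dass_d")],
                          n_boot = 100, seed = 3), "collinear")
})

test_that("a planted concordance effect has a recoverable sign", {
  hits <- 0
  for (r in 1:20) {
    tab <- toy_person_table(200, beta_sat = -0.15, beta_idx = -1.1,
                            noise_sd = 0.5, floor = 1, seed = 100 + r)
    fit <- ols_fit(tab, "dass_d", c("mean_satisfaction", "max_concordance"))
    b <- fit$coefficients$b[fit$coefficients$term == "max_concordance"]
    hits <- hits + (b < 0)
  }
  expect_gte(hits, 18)
})

test_that("the exploratory exclusion drops the targeted persons", {
  tab <- toy_person_table(51, seed = 12)
  tab$dass_d <- 2
  tab$conflict_proportion <- 0.1
  # plant 15 persons with neither a symptom nor any conflict
  tab$dass_d[1:15] <- 1
  tab$conflict_proportion[1:15] <- 0
  for (rule in c("either_absent", "both_absent")) {
    ex <- exploratory_subsample(tab, rule = rule, score_floor = 1,
                                refit = FALSE)
    expect_equal(ex$n_dropped, 15)
    expect_equal(nrow(ex$table), 36)
  }

  # the two readings differ when only one absence holds
  tab$dass_d[16] <- 1
  ex_or <- exploratory_subsample(tab, rule = "either_absent",
                                 score_floor = 1, refit = FALSE)
  ex_and <- exploratory_subsample(tab, rule = "both_absent",
                                  score_floor = 1, refit = FALSE)
  expect_equal(ex_or$n_dropped, 16)
  expect_equal(ex_and$n_dropped, 15)

  # no-op and degenerate cases
  none <- tab[17:51, ]
  ex0 <- exploratory_subsample(none, rule = "either_absent", score_floor = 1,
                               refit = FALSE)
  expect_equal(ex0$n_dropped, 0)
  expect_equal(nrow(ex0$table), nrow(none))
  allm <- tab[1:15, ]
  expect_error(exploratory_subsample(allm, score_floor = 1, refit = FALSE),
               "every participant")
})

test_that("the exploratory refit reports the max-conflict model", {
  tab <- toy_person_table(60, beta_sat = -0.1, noise_sd = 0.4, floor = 1,
                          seed = 13)
  tab$dass_d[1:8] <- 1
  ex <- exploratory_subsample(tab, n_boot = 300, seed = 2)
  expect_equal(nrow(ex$refit), 2)
  expect_setequal(ex$refit$term, c("mean_satisfaction", "max_conflict"))
  expect_equal(unique(ex$refit$df), nrow(ex$table) - 3)
})

test_that("Cronbach's alpha matches direct formula evaluation", {
  # perfectly parallel items
  x <- matrix(rep(rnorm(30), 4), 30, 4)
  expect_equal(cronbach_alpha(x), 1)

  # independent items: alpha near zero
  withr::local_seed(14)
  z <- matrix(rnorm(2000 * 7), 2000, 7)
  expect_lt(abs(cronbach_alpha(z)), 0.05)

  # 3-item toy, hand-evaluated formula
  toy <- matrix(c(1, 2, 3, 4,
                  2, 2, 4, 5,
                  1, 3, 3, 5), 4, 3)
  k <- 3
  direct <- k / (k - 1) *
    (1 - sum(apply(toy, 2, var)) / var(rowSums(toy)))
  expect_equal(cronbach_alpha(toy), direct)

  expect_error(cronbach_alpha(toy[, 1, drop = FALSE]), "2 items")
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero variance")
  expect_warning(cronbach_alpha(rbind(toy, c(NA, 2, 3))), "complete cases")
})
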
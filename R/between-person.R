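# Between-person inference: OLS models predicting depression from one
# network index plus mean motive satisfaction, with analytic t-tests and
# nonparametric case-resampling BCa bootstrap intervals and p-values.
# Case (person-level) resampling is used throughout: the outcome is skewed
# and heteroscedastic, which is the reason for bootstrapping at all.

#' Fit a person-level OLS model with analytic tests
#'
#' @param data data.frame of person-level rows, no missing values in the
#'   used columns.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor column names.
#' @return object of class `ols_result`: `$coefficients` is a data.frame
#'   with term, b, SE, t, df, p; `$diagnostics` holds residual skewness and
#'   a Breusch-Pagan heteroscedasticity flag; `$fit` is the underlying
#'   `lm` object.
#' @export
ols_fit <- function(data, outcome, predictors) {
  stopifnot(is.data.frame(data))
  used <- c(outcome, predictors)
  miss <- setdiff(used, names(data))
  if (length(miss) > 0)
    stopf("column(s) not in data: %s", paste(miss, collapse = ", "))
  if (anyNA(data[, used]))
    stopf("missing values in model columns")
  if (nrow(data) < length(predictors) + 2)
    stopf("need at least %d rows", length(predictors) + 2)

  # collinearity check before fitting, so the error can name the offender
  X <- as.matrix(cbind(1, data[, predictors, drop = FALSE]))
  colnames(X)[1] <- "(Intercept)"
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("collinear design: %s is linearly dependent on the other terms",
          paste(aliased, collapse = ", "))
  }

  f <- stats::as.formula(paste(outcome, "~",
                               paste(sprintf("`%s`", predictors), collapse = "+")))
  fit <- stats::lm(f, data = data)
  sm <- summary(fit)
  co <- sm$coefficients
  res_df <- fit$df.residual
  degenerate <- sm$sigma < 1e-10
  if (degenerate)
    warnf("perfect fit: residual SD ~ 0, standard errors are degenerate")

  bp <- tryCatch(lmtest::bptest(fit)$p.value, error = function(e) NA_real_)
  coef_df <- data.frame(term = rownames(co), b = co[, 1], SE = co[, 2],
                        t = co[, 3], df = res_df, p = co[, 4],
                        row.names = NULL)
  structure(list(coefficients = coef_df, n = nrow(data),
                 sigma = sm$sigma, r_squared = sm$r.squared,
                 degenerate = degenerate,
                 diagnostics = list(residual_skewness = skewness(stats::resid(fit)),
                                    bp_p = unname(bp),
                                    heteroscedastic = isTRUE(unname(bp) < 0.05)),
                 fit = fit),
            class = "ols_result")
}

#' @export
print.ols_result <- function(x, digits = 3, ...) {
  cat(sprintf("OLS fit (n = %d, residual df = %d)\n", x$n,
              x$coefficients$df[1]))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

# ---- BCa bootstrap machinery (hand-rolled) --------------------------------

# Resample rows (data.frame/matrix) or elements (vector).
boot_take <- function(data) {
  if (is.data.frame(data) || is.matrix(data))
    list(n = nrow(data), get = function(i) data[i, , drop = FALSE])
  else
    list(n = length(data), get = function(i) data[i])
}

# Compute everything both the interval and the p-value need once:
# point estimate, n_boot bootstrap replicates, jackknife-based acceleration
# and the bias-correction constant, per statistic component.
boot_machinery <- function(statistic_fn, data, n_boot, seed) {
  tk <- boot_take(data)
  n <- tk$n
  if (n < 3) stopf("need at least 3 cases to bootstrap")
  theta <- statistic_fn(data)
  k <- length(theta)

  tb <- matrix(NA_real_, n_boot, k)
  with_seed(seed, {
    for (b in seq_len(n_boot))
      tb[b, ] <- statistic_fn(tk$get(sample.int(n, n, replace = TRUE)))
  })
  ok <- stats::complete.cases(tb)
  if (!all(ok)) tb <- tb[ok, , drop = FALSE]

  jk <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) jk[i, ] <- statistic_fn(tk$get(-i))

  z0 <- a <- numeric(k)
  zcap <- stats::qnorm(1 - 1 / (nrow(tb) + 1))
  for (j in seq_len(k)) {
    p_below <- mean(tb[, j] < theta[j])
    z0[j] <- min(max(stats::qnorm(p_below), -zcap), zcap)
    d <- mean(jk[, j]) - jk[, j]
    denom <- sum(d^2)^1.5
    a[j] <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  }
  list(theta = theta, tb = tb, z0 = z0, a = a, n_boot = nrow(tb),
       n_dropped = sum(!ok))
}

# BCa-adjusted (or raw percentile) endpoints for component j.
boot_endpoints <- function(mach, j, ci_level, method = "bca") {
  alpha <- (1 - ci_level) / 2
  tbj <- mach$tb[, j]
  if (max(tbj) - min(tbj) == 0) {
    warnf("degenerate bootstrap distribution: all replicates equal")
    return(c(tbj[1], tbj[1]))
  }
  if (method == "percentile") {
    probs <- c(alpha, 1 - alpha)
  } else {
    z <- stats::qnorm(c(alpha, 1 - alpha))
    zz <- mach$z0[j] + z
    probs <- stats::pnorm(mach$z0[j] + zz / (1 - mach$a[j] * zz))
  }
  B <- mach$n_boot
  probs <- pmin(pmax(probs, 1 / (B + 1)), B / (B + 1))
  stats::quantile(tbj, probs, type = 6, names = FALSE)
}

#' Bias-corrected and accelerated bootstrap confidence interval
#'
#' Nonparametric case-resampling bootstrap with the standard BCa
#' construction: the bias-correction constant `z0` is the normal quantile
#' of the share of bootstrap replicates below the point estimate, the
#' acceleration `a` comes from the skewness of leave-one-out jackknife
#' estimates, and the percentile endpoints are adjusted accordingly.
#' `method = "percentile"` forces `z0 = a = 0` (raw percentile interval on
#' the same resamples).
#'
#' @param statistic_fn function mapping a dataset (rows resampled) to a
#'   scalar statistic.
#' @param data data.frame, matrix (rows = cases) or vector.
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param ci_level coverage (default 0.95).
#' @param seed integer seed; the same seed gives a bit-identical interval.
#' @param method `"bca"` (default) or `"percentile"`.
#' @return length-2 numeric `c(lo, hi)` with attributes `z0`, `a`,
#'   `estimate`.
#' @export
bca_interval <- function(statistic_fn, data, n_boot = 5000, ci_level = 0.95,
                         seed = 1, method = c("bca", "percentile")) {
  method <- match.arg(method)
  mach <- boot_machinery(statistic_fn, data, n_boot, seed)
  ep <- boot_endpoints(mach, 1, ci_level, method)
  structure(ep, z0 = mach$z0[1], a = mach$a[1], estimate = mach$theta[1])
}

# Smallest alpha at which the (1 - alpha) BCa interval excludes 0, by
# bisection on the shared resample set.
p_from_machinery <- function(mach, j, tol = 1e-6) {
  excludes <- function(alpha) {
    ep <- suppressWarnings(boot_endpoints(mach, j, 1 - alpha))
    ep[1] > 0 || ep[2] < 0
  }
  B <- mach$n_boot
  lo <- 2 / B                       # finest resolution the resamples carry
  hi <- 1 - 1e-9
  if (!excludes(hi)) return(1)
  if (excludes(lo)) return(lo)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (excludes(mid)) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  hi
}

#' Bootstrap p-value by confidence-interval inversion
#'
#' The p-value is the smallest `alpha` at which the `1 - alpha` BCa
#' interval (computed on the same resample set) excludes zero, found by
#' bisection over `alpha`. This keeps the reported interval and p-value
#' logically coherent: `p < 1 - ci_level` exactly when the `ci_level`
#' interval excludes 0.
#'
#' @inheritParams bca_interval
#' @return p-value in (0, 1].
#' @export
bootstrap_p <- function(statistic_fn, data, n_boot = 5000, seed = 1) {
  mach <- boot_machinery(statistic_fn, data, n_boot, seed)
  p_from_machinery(mach, 1)
}

# ---- Table-3 style report -------------------------------------------------

TABLE3_INDICES <- c("conflict_proportion", "max_conflict", "max_concordance")

# Fast two-predictor coefficient extractor used inside the bootstrap loop.
coef_pair <- function(d, outcome, index) {
  X <- cbind(1, d$mean_satisfaction, d[[index]])
  cf <- stats::lm.fit(X, d[[outcome]])$coefficients
  cf[2:3]
}

#' Run the three index-vs-depression regression models
#'
#' One OLS model per network index: depression on mean motive satisfaction
#' plus that index. Each coefficient gets its analytic t-test and a BCa
#' bootstrap interval and p-value from `n_boot` person resamples. The three
#' models use independent resampling substreams derived from one seed, keyed
#' by model position, so reruns are reproducible and adding a model never
#' perturbs the others.
#'
#' @param indices data.frame with `person_id`, `mean_satisfaction` and the
#'   three index columns (see [indices_table()]).
#' @param outcome data.frame with `person_id` and the depression score
#'   column, or a numeric vector aligned with `indices`.
#' @param outcome_col name of the depression column (default `"dass_d"`).
#' @param n_boot bootstrap resamples per model (default 5000).
#' @param seed integer seed.
#' @param ci_level bootstrap interval coverage (default 0.95).
#' @return object of class `table3_report`: data.frame with one row per
#'   model x predictor (model, term, b, SE, t, df, p, boot_lo, boot_hi,
#'   boot_p) plus per-model diagnostics in `attr(, "diagnostics")`.
#' @export
run_table3 <- function(indices, outcome, outcome_col = "dass_d",
                       n_boot = 5000, seed = 1, ci_level = 0.95) {
  stopifnot(is.data.frame(indices))
  if (is.data.frame(outcome)) {
    tab <- merge(indices, outcome[, c("person_id", outcome_col)],
                 by = "person_id")
  } else {
    tab <- indices
    tab[[outcome_col]] <- outcome
  }
  need <- c(outcome_col, "mean_satisfaction", TABLE3_INDICES)
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(tab[, need])) stopf("missing values in the person-level table")

  rows <- list()
  diags <- list()
  for (i in seq_along(TABLE3_INDICES)) {
    index <- TABLE3_INDICES[i]
    fit <- ols_fit(tab, outcome_col, c("mean_satisfaction", index))
    mach <- boot_machinery(function(d) coef_pair(d, outcome_col, index),
                           tab, n_boot, seed = substream_seed(seed, i, 7L))
    co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    for (j in 1:2) {
      ep <- boot_endpoints(mach, j, ci_level)
      rows[[length(rows) + 1]] <- data.frame(
        model = index, term = co$term[j], b = co$b[j], SE = co$SE[j],
        t = co$t[j], df = co$df[j], p = co$p[j],
        boot_lo = ep[1], boot_hi = ep[2],
        boot_p = p_from_machinery(mach, j))
    }
    diags[[index]] <- fit$diagnostics
  }
  out <- do.call(rbind, rows)
  attr(out, "diagnostics") <- diags
  attr(out, "n") <- nrow(tab)
  attr(out, "n_boot") <- n_boot
  class(out) <- c("table3_report", "data.frame")
  out
}

#' @export
print.table3_report <- function(x, digits = 3, ...) {
  cat(sprintf("Index regressions on depression (n = %d, %d bootstrap resamples)\n",
              attr(x, "n"), attr(x, "n_boot")))
  df <- as.data.frame(x)
  df$ci <- sprintf("[%.3f, %.3f]", df$boot_lo, df$boot_hi)
  print(format(df[, c("model", "term", "b", "SE", "t", "df", "p", "ci",
                      "boot_p")], digits = digits), row.names = FALSE)
  invisible(x)
}

#' Exploratory subsample re-analysis
#'
#' Drops persons showing no depressive symptoms and/or no motive conflict,
#' then refits the maximum-conflict model on the remainder. The exclusion
#' rule is ambiguous in prose, so both readings are available:
#' `"either_absent"` (default) excludes a person whose depression score sits
#' at the scale floor OR whose network has no negative edge;
#' `"both_absent"` requires both absences.
#'
#' @param tab person-level table with the depression and index columns (as
#'   assembled by [run_table3()] internals: `person_id`, `mean_satisfaction`,
#'   the three indices, and the outcome column).
#' @param outcome_col depression column name (default `"dass_d"`).
#' @param rule `"either_absent"` or `"both_absent"`.
#' @param score_floor scale floor of the depression score (default 1.0).
#' @param refit refit the max-conflict model on the remainder (default TRUE).
#' @param n_boot,seed,ci_level bootstrap settings for the refit.
#' @return list with `table` (retained rows), `n_dropped`, `dropped_ids`,
#'   and `refit` (a [run_table3()]-style row pair for the max-conflict
#'   model, or NULL).
#' @export
exploratory_subsample <- function(tab, outcome_col = "dass_d",
                                  rule = c("either_absent", "both_absent"),
                                  score_floor = 1.0, refit = TRUE,
                                  n_boot = 5000, seed = 1, ci_level = 0.95) {
  rule <- match.arg(rule)
  need <- c(outcome_col, "conflict_proportion")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stopf("missing column(s): %s", paste(miss, collapse = ", "))
  no_symptom <- tab[[outcome_col]] <= score_floor + 1e-9
  no_conflict <- tab$conflict_proportion == 0
  drop <- if (rule == "either_absent") no_symptom | no_conflict
          else no_symptom & no_conflict
  kept <- tab[!drop, , drop = FALSE]
  if (nrow(kept) == 0) stopf("exclusion rule removed every participant")
  out <- list(table = kept, n_dropped = sum(drop),
              dropped_ids = tab$person_id[drop], rule = rule, refit = NULL)
  if (refit) {
    fit <- ols_fit(kept, outcome_col, c("mean_satisfaction", "max_conflict"))
    mach <- boot_machinery(function(d) coef_pair(d, outcome_col, "max_conflict"),
                           kept, n_boot, seed = substream_seed(seed, 4L, 7L))
    co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    rr <- lapply(1:2, function(j) {
      ep <- boot_endpoints(mach, j, ci_level)
      data.frame(term = co$term[j], b = co$b[j], SE = co$SE[j], t = co$t[j],
                 df = co$df[j], p = co$p[j], boot_lo = ep[1], boot_hi = ep[2],
                 boot_p = p_from_machinery(mach, j))
    })
    out$refit <- do.call(rbind, rr)
  }
  out
}

#' Cronbach's alpha
#'
#' Internal consistency `k/(k-1) * (1 - sum(item variances) / variance of
#' the total score)`.
#'
#' @param items numeric matrix or data.frame, respondents x items.
#' @return alpha coefficient.
#' @export
#' @examples
#' set.seed(1)
#' f <- rnorm(200)
#' cronbach_alpha(sapply(1:5, function(i) f + rnorm(200, sd = 0.5)))
cronbach_alpha <- function(items) {
  X <- as.matrix(items)
  if (ncol(X) < 2) stopf("need at least 2 items")
  if (anyNA(X)) {
    warnf("missing responses: using complete cases only")
    X <- X[stats::complete.cases(X), , drop = FALSE]
  }
  if (nrow(X) < 2) stopf("need at least 2 respondents")
  tot_var <- stats::var(rowSums(X))
  if (tot_var <= 0) stopf("total score has zero variance")
  k <- ncol(X)
  k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / tot_var)
}
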
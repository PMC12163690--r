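# Hybrid random-intercept mixed model of momentary mood on motive
# satisfaction: the time-varying predictor is decomposed into a person mean
# (between-person component) and a person-mean-centred deviation
# (within-person component), so one fixed effect per component cleanly
# separates the two sources of variance.

#' Build the hybrid (between/within) momentary dataset
#'
#' For every answered slot with both a satisfaction value (mean of the
#' person's selected-motive items at that beep) and a mood rating, emits one
#' row; then derives each person's mean satisfaction over their included
#' rows and the person-mean-centred deviation. Persons with fewer than two
#' usable rows are dropped with a warning.
#'
#' @param series_list list of [person_series()] objects carrying slot-level
#'   mood (as produced by [assemble_series()]).
#' @return data.frame of class `momentary_dataset`: person_id, slot,
#'   satisfaction, mood, person_mean_satisfaction, satisfaction_centered.
#' @export
build_hybrid_dataset <- function(series_list) {
  rows <- lapply(series_list, function(s) {
    if (is.null(s$mood)) return(NULL)
    sat <- rowMeans(s$mat, na.rm = TRUE)
    sat[is.nan(sat)] <- NA
    ok <- !is.na(sat) & !is.na(s$mood)
    if (sum(ok) < 2) {
      warnf("person %s has %d usable mood slots; dropped", s$person_id, sum(ok))
      return(NULL)
    }
    data.frame(person_id = s$person_id, slot = which(ok),
               satisfaction = sat[ok], mood = s$mood[ok])
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0)
    stopf("no usable (satisfaction, mood) rows")
  pm <- tapply(df$satisfaction, df$person_id, mean)
  df$person_mean_satisfaction <- as.numeric(pm[df$person_id])
  df$satisfaction_centered <- df$satisfaction - df$person_mean_satisfaction
  class(df) <- c("momentary_dataset", "data.frame")
  df
}

#' Fit the hybrid random-intercept mixed model
#'
#' Maximum-likelihood fit (not REML) of
#' `mood ~ person_mean_satisfaction + satisfaction_centered + (1 | person)`.
#' Fixed-effect tests are Wald z-tests against a normal reference.
#' If the within-person predictor has essentially no variance the
#' within-person slope is reported as inestimable (flag), not as a number.
#'
#' @param dataset a [build_hybrid_dataset()] result.
#' @return object of class `lmm_result`: `$fixed` (term, b, SE, z, p),
#'   `$variance` (random-intercept and residual variances), `$logLik`,
#'   `$n_persons`, `$n_obs`, `$converged`, `$b_within_inestimable`.
#' @export
fit_random_intercept <- function(dataset) {
  stopifnot(is.data.frame(dataset))
  need <- c("person_id", "mood", "person_mean_satisfaction",
            "satisfaction_centered")
  miss <- setdiff(need, names(dataset))
  if (length(miss) > 0)
    stopf("dataset lacks column(s): %s", paste(miss, collapse = ", "))
  if (length(unique(dataset$person_id)) < 2)
    stopf("need at least 2 persons")

  inest <- stats::var(dataset$satisfaction_centered) < 1e-12
  form <- if (inest)
    mood ~ person_mean_satisfaction + (1 | person_id)
  else
    mood ~ person_mean_satisfaction + satisfaction_centered + (1 | person_id)

  fit <- lme4::lmer(form, data = dataset, REML = FALSE)
  cm <- conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(cm) || !any(grepl("failed to converge", cm))
  if (!converged)
    stopf("mixed-model fit did not converge: %s", paste(cm, collapse = "; "))

  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  fixed <- data.frame(term = names(b), b = unname(b), SE = unname(se),
                      z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))),
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == "person_id"]
  res_var <- vc$vcov[vc$grp == "Residual"]

  structure(list(fixed = fixed,
                 variance = c(random_intercept = ri_var, residual = res_var),
                 logLik = as.numeric(stats::logLik(fit)),
                 n_persons = length(unique(dataset$person_id)),
                 n_obs = nrow(dataset), converged = converged,
                 b_within_inestimable = inest, fit = fit),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, digits = 3, ...) {
  cat(sprintf("Hybrid random-intercept LMM (ML): %d obs, %d persons, logLik %.1f\n",
              x$n_obs, x$n_persons, x$logLik))
  print(format(x$fixed, digits = digits), row.names = FALSE)
  cat(sprintf("  var(intercept) = %.3f, var(residual) = %.3f\n",
              x$variance["random_intercept"], x$variance["residual"]))
  if (x$b_within_inestimable)
    cat("  within-person slope inestimable: predictor has no within-person variance\n")
  invisible(x)
}

#' Write an LMM report as JSON
#'
#' @param res a [fit_random_intercept()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_lmm_json <- function(res, path) {
  jsonlite::write_json(list(
    fixed = res$fixed, variance = as.list(res$variance),
    logLik = res$logLik, n_persons = res$n_persons, n_obs = res$n_obs,
    converged = res$converged,
    b_within_inestimable = res$b_within_inestimable),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
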
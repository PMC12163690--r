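#' Simulation configuration for a synthetic ESM study
#'
#' Bundles the design constants of the emulated experience-sampling study:
#' 51 participants assessed 6 times per day for 6 days (36 scheduled beeps),
#' with roughly 19% of beeps missed, 7 personally selected motive nodes out
#' of a 14-motive catalogue, and a mostly-positive contemporaneous network
#' with a planted minority of negative edges.
#'
#' Defaults that the emulated design does not pin down are stand-ins chosen
#' once at realistic values: the missingness mechanism is
#' completely-at-random (no dropout mechanism is assumed), within-day lag-1
#' autocorrelation is moderate (diagonal of the temporal matrix drawn in
#' `ar_range`), and 5% of completed entries are relabelled as manually
#' initiated, carrying identical data.
#'
#' @param n_participants number of simulated persons (default 51).
#' @param n_days study days per person (default 6).
#' @param beeps_per_day scheduled prompts per day (default 6).
#' @param missing_rate probability a scheduled beep is missed (default 0.19).
#' @param n_motives_pool size of the motive catalogue (fixed at 14).
#' @param n_selected motives per person / network nodes (default 7).
#' @param negative_edge_rate probability an off-diagonal partial correlation
#'   is planted negative (default 0.10; with 21 node pairs this gives a
#'   planted negative edge-mass share around 6% and roughly one person in
#'   ten with no negative edge at all).
#' @param negative_edge_strength range of |weight| for negative edges
#'   (default `c(0.03, 0.30)`; magnitudes are drawn right-skewed within the
#'   range, see Details).
#' @param positive_edge_strength range of weight for positive edges
#'   (default `c(0.02, 0.38)`). Magnitudes are drawn as
#'   `lo + (hi - lo) * Beta(1, 3)`: mostly weak edges with a skewed tail of
#'   strong ones, the shape idiographic networks show empirically. A dense
#'   network of uniformly strong positive partial correlations is not
#'   representable: it pushes the implied precision matrix to the
#'   positive-definite boundary and forces implausibly collinear marginal
#'   series.
#' @param ar_range range for the diagonal of the lag-1 temporal matrix.
#' @param cross_lag_sd SD of off-diagonal lag-1 coefficients.
#' @param manual_rate share of completed entries relabelled as
#'   participant-initiated (default 0.05).
#' @param mood_slope within-person slope of momentary mood (1-7 scale) on
#'   mean momentary motive satisfaction (default 0.4).
#' @param mood_sd residual SD of the latent mood variable (default 0.8).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 51, n_days = 6, beeps_per_day = 6,
                       missing_rate = 0.19, n_motives_pool = 14,
                       n_selected = 7, negative_edge_rate = 0.10,
                       negative_edge_strength = c(0.03, 0.30),
                       positive_edge_strength = c(0.02, 0.38),
                       ar_range = c(0.10, 0.30), cross_lag_sd = 0.02,
                       manual_rate = 0.05, mood_slope = 0.4, mood_sd = 0.8) {
  cfg <- list(n_participants = n_participants, n_days = n_days,
              beeps_per_day = beeps_per_day, missing_rate = missing_rate,
              n_motives_pool = n_motives_pool, n_selected = n_selected,
              negative_edge_rate = negative_edge_rate,
              negative_edge_strength = negative_edge_strength,
              positive_edge_strength = positive_edge_strength,
              ar_range = ar_range, cross_lag_sd = cross_lag_sd,
              manual_rate = manual_rate, mood_slope = mood_slope,
              mood_sd = mood_sd)
  for (f in c("n_participants", "n_days", "beeps_per_day", "n_selected"))
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1) stopf("%s must be a positive count", f)
  for (f in c("missing_rate", "negative_edge_rate", "manual_rate"))
    if (!is_prob(cfg[[f]])) stopf("%s must be a probability in [0, 1]", f)
  if (cfg$n_motives_pool != length(motive_catalogue()))
    stopf("n_motives_pool must equal the catalogue size (%d)",
          length(motive_catalogue()))
  if (cfg$n_selected > cfg$n_motives_pool)
    stopf("n_selected cannot exceed the motive pool")
  for (f in c("negative_edge_strength", "positive_edge_strength"))
    if (length(cfg[[f]]) != 2 || any(cfg[[f]] < 0) || diff(cfg[[f]]) < 0)
      stopf("%s must be an increasing nonnegative range", f)
  if (cfg$mood_sd <= 0) stopf("mood_sd must be positive")
  structure(cfg, class = "sim_config")
}

#' Planted between-person truth for the depression outcome
#'
#' Defines the linear data-generating model for the person-level depression
#' score: `max(floor, intercept + beta_satisfaction * mean_satisfaction +
#' beta_index * index + noise)`. The floor produces the right-skewed,
#' floor-heavy outcome distribution typical of subclinical samples.
#'
#' @param intercept intercept of the linear predictor (default 2.65, placing
#'   the observed outcome mean near 1.6 with roughly a fifth of persons
#'   censored at the floor under the default generator).
#' @param beta_satisfaction slope on mean motive satisfaction (default -0.15).
#' @param beta_index slope on the chosen network index (default -1.1).
#' @param index which index carries the planted effect: one of
#'   `"max_concordance"` (default), `"conflict_proportion"`, `"max_conflict"`.
#' @param noise_sd residual SD (default 0.6).
#' @param floor lower bound of the score scale (default 1.0).
#' @return object of class `between_truth`.
#' @export
between_truth <- function(intercept = 2.65, beta_satisfaction = -0.15,
                          beta_index = -1.1, index = "max_concordance",
                          noise_sd = 0.6, floor = 1.0) {
  index <- match.arg(index,
                     c("max_concordance", "conflict_proportion", "max_conflict"))
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  structure(list(intercept = intercept,
                 beta_satisfaction = beta_satisfaction,
                 beta_index = beta_index, index = index,
                 noise_sd = noise_sd, floor = floor),
            class = "between_truth")
}

# Sampling weights over the catalogue used when drawing which motives a
# person holds important; skewed so that confidence/variety/intimacy are
# near-ubiquitous while status is rare, mimicking typical selection
# prevalence in young non-clinical samples.
catalogue_weights <- function() {
  w <- c(intimacy = 0.90, affiliation = 0.60, altruism = 0.45, support = 0.40,
         recognition = 0.30, control = 0.70, education = 0.50, meaning = 0.35,
         confidence = 0.95, "self-reward" = 0.80, autonomy = 0.85,
         achievement = 0.60, variety = 0.95, status = 0.05)
  w[motive_catalogue()]
}

#' Draw one person's true data-generating model
#'
#' Constructs a stationary VAR(1) truth for one person: which motives they
#' hold important (their network nodes), a lag-1 temporal coefficient matrix
#' `B`, a contemporaneous innovation partial-correlation matrix `omega` with
#' a planted minority of negative edges, per-node innovation SDs and node
#' means on the 0-9 satisfaction scale.
#'
#' The partial-correlation matrix is built sign-first: each off-diagonal pair
#' is negative with probability `negative_edge_rate` (magnitude uniform in
#' `negative_edge_strength`), otherwise positive (uniform in
#' `positive_edge_strength`). The implied precision matrix is repaired to
#' positive definiteness by diagonal loading on a geometric ladder and
#' re-normalisation; loading only shrinks magnitudes, never flips signs, and
#' the stored `omega` is the post-repair truth.
#'
#' @param config a [sim_config()].
#' @param person_index 1-based person index; drives the RNG substream so
#'   adding persons never perturbs earlier ones.
#' @param seed global integer seed.
#' @return object of class `true_person_model` with fields `person_id`,
#'   `node_labels`, `temporal_matrix`, `contemporaneous_pcor`,
#'   `innovation_sd`, `node_means`, `innovation_cov`.
#' @export
make_person_model <- function(config, person_index = 1, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_selected
  with_seed(substream_seed(seed, person_index, offset = 1L), {
    w <- catalogue_weights()
    nodes <- sample(motive_catalogue(), m, prob = w)
    nodes <- nodes[order(match(nodes, motive_catalogue()))]

    # temporal matrix: moderate diagonal AR, weak cross-lags; enforce
    # stationarity by scaling if the spectral radius creeps up
    B <- matrix(stats::rnorm(m * m, 0, config$cross_lag_sd), m, m)
    diag(B) <- stats::runif(m, config$ar_range[1], config$ar_range[2])
    sr <- max(Mod(eigen(B, only.values = TRUE)$values))
    if (sr >= 0.95) B <- B * (0.9 / sr)

    # signed partial-correlation skeleton
    omega <- diag(m)
    neg <- config$negative_edge_strength
    pos <- config$positive_edge_strength
    skewed_mag <- function(range) range[1] + diff(range) * stats::rbeta(1, 1, 3)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      v <- if (stats::runif(1) < config$negative_edge_rate)
        -skewed_mag(neg) else skewed_mag(pos)
      omega[i, j] <- omega[j, i] <- v
    }
    rep <- repair_pcor(omega)

    innovation_sd <- stats::runif(m, 1.2, 1.8)
    node_means <- stats::runif(m, 4.5, 7.5)
    sigma_corr <- stats::cov2cor(solve(rep$precision))
    innovation_cov <- outer(innovation_sd, innovation_sd) * sigma_corr

    structure(list(person_id = sprintf("P%02d", person_index),
                   node_labels = nodes, temporal_matrix = B,
                   contemporaneous_pcor = rep$pcor,
                   innovation_sd = innovation_sd, node_means = node_means,
                   innovation_cov = innovation_cov,
                   diagonal_loading = rep$loading),
              class = "true_person_model")
  })
}

# Repair a unit-diagonal partial-correlation matrix to one whose implied
# precision matrix is positive definite: diagonal loading delta on a
# geometric ladder, then renormalisation to unit partial variance. Loading
# scales all off-diagonal partial correlations by 1/(1+delta) -- signs are
# preserved by construction; the error branch guards the magnitude collapse
# that would make planted signs meaningless.
repair_pcor <- function(omega, max_loading = 2) {
  m <- nrow(omega)
  K <- -omega
  diag(K) <- 1
  ladder <- c(0, 0.01 * 2^(0:8))
  for (delta in ladder) {
    Kd <- K + delta * diag(m)
    ev <- eigen(Kd, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-6) {
      pcor <- -Kd / sqrt(outer(diag(Kd), diag(Kd)))
      diag(pcor) <- 1
      if (delta > max_loading)
        stopf("positive-definite repair needed loading %g, planted signs no longer meaningful", delta)
      return(list(pcor = pcor, precision = Kd, loading = delta))
    }
  }
  stopf("could not repair planted partial-correlation matrix to positive definiteness")
}

#' Stationary covariance of a VAR(1) process
#'
#' Solves the discrete Lyapunov equation `Sigma = B Sigma B' + Psi` exactly
#' via the Kronecker-vectorised linear system.
#'
#' @param B lag-1 coefficient matrix (spectral radius < 1).
#' @param Psi innovation covariance matrix.
#' @return stationary covariance matrix.
#' @export
stationary_cov <- function(B, Psi) {
  m <- nrow(B)
  sr <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (sr >= 1) stopf("temporal matrix is non-stationary (spectral radius %.3f)", sr)
  s <- solve(diag(m * m) - B %x% B, as.vector(Psi))
  S <- matrix(s, m, m)
  (S + t(S)) / 2
}

#' Simulate a latent (continuous, gap-free) VAR(1) series
#'
#' Used for long-run recovery diagnostics where the discretised beep grid
#' would only add noise: draws `n` consecutive observations from the
#' person's stationary VAR(1) without day breaks, missingness or rounding.
#'
#' @param model a [make_person_model()] truth.
#' @param n series length.
#' @param seed integer seed.
#' @return `n` x m numeric matrix with node labels as column names.
#' @export
simulate_latent_var <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "true_person_model"))
  m <- length(model$node_labels)
  B <- model$temporal_matrix
  mu <- model$node_means
  S0 <- stationary_cov(B, model$innovation_cov)
  with_seed(seed, {
    X <- matrix(NA_real_, n, m, dimnames = list(NULL, model$node_labels))
    X[1, ] <- MASS::mvrnorm(1, mu, S0)
    E <- MASS::mvrnorm(n, rep(0, m), model$innovation_cov)
    for (t in 2:n) X[t, ] <- mu + B %*% (X[t - 1, ] - mu) + E[t, ]
    X
  })
}

#' Simulate one person's beep-level ESM records
#'
#' Generates the full scheduled grid of `n_days * beeps_per_day` prompt
#' records. Prompt times are pseudo-random within the 9:30-21:30 window with
#' at least 60 minutes between consecutive prompts. Latent motive
#' satisfaction follows the person's VAR(1) within each day; the first beep
#' of a day restarts from the stationary distribution (overnight gaps dwarf
#' the within-day spacing, so no dependence is carried across nights).
#' Latent values are rounded half-up to the 0-9 integer scale and clipped at
#' the bounds. Each record is independently missed with probability
#' `missing_rate` (completely at random); missed records carry a
#' dismissed/ignored/discontinued status and no responses. A share
#' `manual_rate` of completed records is relabelled as manually initiated.
#' Momentary mood (1-7) is a person-intercept plus `mood_slope` times the
#' reported (discretised) mean satisfaction plus Gaussian noise, discretised.
#'
#' @param model a [make_person_model()] truth.
#' @param config a [sim_config()].
#' @param person_index 1-based person index (RNG substream key).
#' @param seed global integer seed.
#' @return data.frame of beep records: `person_id, day, beep, prompt_time,
#'   response_time, initiation, status`, one `m_<motive>` item column per
#'   catalogue motive (NA for motives the person does not track), and
#'   `mood`.
#' @export
simulate_person_series <- function(model, config, person_index = 1, seed = 1) {
  stopifnot(inherits(model, "true_person_model"), inherits(config, "sim_config"))
  m <- length(model$node_labels)
  nd <- config$n_days
  nb <- config$beeps_per_day
  S0 <- stationary_cov(model$temporal_matrix, model$innovation_cov)

  with_seed(substream_seed(seed, person_index, offset = 2L), {
    mood_intercept <- stats::rnorm(1, 1.2, 0.4)
    rows <- vector("list", nd)
    day0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
    for (d in seq_len(nd)) {
      # prompt times: order statistics in the feasible window plus the
      # mandatory 60-minute offsets guarantee the spacing constraint
      window_min <- 720 - 60 * (nb - 1)
      mins <- sort(stats::runif(nb, 0, window_min)) + 60 * (seq_len(nb) - 1)
      prompt <- day0 + (d - 1) * 86400 + (9.5 * 60 + mins) * 60

      X <- matrix(NA_real_, nb, m)
      X[1, ] <- MASS::mvrnorm(1, model$node_means, S0)
      if (nb > 1) for (t in 2:nb) {
        X[t, ] <- model$node_means +
          model$temporal_matrix %*% (X[t - 1, ] - model$node_means) +
          MASS::mvrnorm(1, rep(0, m), model$innovation_cov)
      }
      items <- clip_round(X, 0, 9)

      missed <- stats::runif(nb) < config$missing_rate
      status <- ifelse(missed,
                       sample(c("ignored", "dismissed", "discontinued"), nb,
                              replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                       "completed")
      manual <- !missed & stats::runif(nb) < config$manual_rate
      latency <- ifelse(manual,
                        stats::runif(nb, 60, 1700),
                        pmin(stats::rlnorm(nb, log(30), 1.3), 1790))
      response <- prompt + latency
      response[missed] <- NA

      sat_mean <- rowMeans(items)
      mood <- clip_round(mood_intercept + config$mood_slope * sat_mean +
                           stats::rnorm(nb, 0, config$mood_sd), 1, 7)
      mood[missed] <- NA
      items[missed, ] <- NA

      df <- data.frame(person_id = model$person_id, day = d,
                       beep = seq_len(nb), prompt_time = prompt,
                       response_time = response,
                       initiation = ifelse(manual, "manual", "prompted"),
                       status = status, stringsAsFactors = FALSE)
      full <- matrix(NA_real_, nb, length(motive_catalogue()),
                     dimnames = list(NULL, item_col(motive_catalogue())))
      full[, item_col(model$node_labels)] <- items
      rows[[d]] <- cbind(df, as.data.frame(full, check.names = FALSE),
                         mood = mood)
    }
    do.call(rbind, rows)
  })
}

#' Simulate baseline questionnaires (importance profile and depression score)
#'
#' Importance scores are generated so that each person's true network nodes
#' are unambiguously their top-`m` motives (selected motives score in
#' [3.6, 5], the rest in [1, 3.4]), making downstream selection
#' deterministic. The depression score follows the planted between-person
#' truth, floored at the scale minimum; a 7-item depression item matrix
#' consistent with the score (single common factor) is generated alongside
#' for psychometric checks.
#'
#' @param models list of [make_person_model()] truths.
#' @param truth a [between_truth()].
#' @param realized_indices data.frame with columns `person_id`,
#'   `mean_satisfaction` and the index named in `truth$index` (typically
#'   from [true_network_indices()] or the estimation pipeline).
#' @param seed global integer seed.
#' @return list with `importance` (person x motive data.frame), `outcome`
#'   (person_id, dass_d) and `dass_items` (persons x 7 item matrix).
#' @export
simulate_baseline <- function(models, truth, realized_indices, seed = 1) {
  stopifnot(inherits(truth, "between_truth"), is.data.frame(realized_indices))
  need <- c("person_id", "mean_satisfaction", truth$index)
  miss <- setdiff(need, names(realized_indices))
  if (length(miss) > 0)
    stopf("realized_indices lacks column(s): %s", paste(miss, collapse = ", "))

  ids <- vapply(models, `[[`, character(1), "person_id")
  idx <- realized_indices[match(ids, realized_indices$person_id), ]
  if (anyNA(idx$person_id)) stopf("realized_indices missing some persons")

  cat14 <- motive_catalogue()
  imp <- matrix(NA_real_, length(models), length(cat14),
                dimnames = list(NULL, cat14))
  dass <- numeric(length(models))
  items <- matrix(NA_real_, length(models), 7)
  for (i in seq_along(models)) {
    mod <- models[[i]]
    with_seed(substream_seed(seed, i, offset = 3L), {
      sel <- cat14 %in% mod$node_labels
      imp[i, sel] <- stats::runif(sum(sel), 3.6, 5.0)
      imp[i, !sel] <- stats::runif(sum(!sel), 1.0, 3.4)
      lin <- truth$intercept +
        truth$beta_satisfaction * idx$mean_satisfaction[i] +
        truth$beta_index * idx[[truth$index]][i]
      dass[i] <- max(truth$floor, lin + stats::rnorm(1, 0, truth$noise_sd))
      items[i, ] <- dass[i] + stats::rnorm(7, 0, 0.35)
    })
  }
  list(importance = data.frame(person_id = ids,
                               as.data.frame(imp, check.names = FALSE)),
       outcome = data.frame(person_id = ids, dass_d = dass),
       dass_items = items)
}

#' Indices of the planted (true) networks
#'
#' Computes the three concordance/discordance indices directly from each
#' person's planted partial-correlation truth, plus mean satisfaction from
#' the generated records (mean of all answered selected-motive items).
#'
#' @param models list of person truths.
#' @param beeps beep-level records from [simulate_person_series()] (may be
#'   `NULL`, in which case mean satisfaction defaults to the mean node mean).
#' @return data.frame: person_id, conflict_proportion, max_conflict,
#'   max_concordance, mean_satisfaction.
#' @export
true_network_indices <- function(models, beeps = NULL) {
  rows <- lapply(models, function(mod) {
    w <- mod$contemporaneous_pcor[upper.tri(mod$contemporaneous_pcor)]
    ms <- if (is.null(beeps)) mean(mod$node_means) else {
      b <- beeps[beeps$person_id == mod$person_id & beeps$status == "completed",
                 item_col(mod$node_labels), drop = FALSE]
      mean(as.matrix(b), na.rm = TRUE)
    }
    data.frame(person_id = mod$person_id,
               conflict_proportion = conflict_proportion(w),
               max_conflict = max_conflict(w),
               max_concordance = max_concordance(w),
               mean_satisfaction = ms)
  })
  do.call(rbind, rows)
}

#' Simulate a complete synthetic ESM study
#'
#' Fans one global seed out to per-person substreams (keyed by person index,
#' so enlarging the sample never perturbs earlier persons) and produces the
#' beep-level table, the baseline tables, and the list of true person
#' models. Baseline depression is generated from the planted-network indices
#' by default (`indices_from = "truth"`); `"none"` skips the outcome.
#'
#' @param config a [sim_config()].
#' @param truth a [between_truth()].
#' @param seed global integer seed; the same seed reproduces the study
#'   bit-for-bit.
#' @param indices_from `"truth"` (default) to drive the outcome from the
#'   planted networks.
#' @return object of class `esm_study`: list with `beeps`, `importance`,
#'   `outcome`, `dass_items`, `models`, `config`, `truth`, `seed`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_participants = 4), seed = 7)
#' table(study$beeps$status)
simulate_study <- function(config = sim_config(), truth = between_truth(),
                           seed = 1, indices_from = c("truth", "none")) {
  indices_from <- match.arg(indices_from)
  models <- lapply(seq_len(config$n_participants), function(i)
    make_person_model(config, i, seed))
  names(models) <- vapply(models, `[[`, character(1), "person_id")
  beeps <- do.call(rbind, lapply(seq_len(config$n_participants), function(i)
    simulate_person_series(models[[i]], config, i, seed)))
  out <- list(beeps = beeps, models = models, config = config, truth = truth,
              seed = seed)
  if (indices_from == "truth") {
    idx <- true_network_indices(models, beeps)
    base <- simulate_baseline(models, truth, idx, seed)
    out$importance <- base$importance
    out$outcome <- base$outcome
    out$dass_items <- base$dass_items
    out$true_indices <- idx
  }
  structure(out, class = "esm_study")
}

#' @export
print.esm_study <- function(x, ...) {
  cat(sprintf("Synthetic ESM study: %d persons x %d days x %d beeps (seed %d)\n",
              x$config$n_participants, x$config$n_days,
              x$config$beeps_per_day, x$seed))
  cat(sprintf("  completed beeps: %d of %d\n",
              sum(x$beeps$status == "completed"), nrow(x$beeps)))
  invisible(x)
}

#' Write a simulated study to CSV/JSON files
#'
#' Writes `beeps.csv` and `importance.csv` (and `baseline.csv` when an
#' outcome was generated) in the exact dialect the ingest module reads
#' (ISO-8601 timestamps, empty cell as missing marker), plus the true person
#' models as `models.json` for recovery tests.
#'
#' @param study an [simulate_study()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "esm_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beeps <- study$beeps
  beeps$prompt_time <- format(beeps$prompt_time, "%Y-%m-%dT%H:%M:%S")
  beeps$response_time <- ifelse(is.na(beeps$response_time), NA,
                                format(beeps$response_time, "%Y-%m-%dT%H:%M:%S"))
  paths <- file.path(dir, "beeps.csv")
  utils::write.csv(beeps, paths[1], row.names = FALSE, na = "")
  if (!is.null(study$importance)) {
    p <- file.path(dir, "importance.csv")
    utils::write.csv(study$importance, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  if (!is.null(study$outcome)) {
    p <- file.path(dir, "baseline.csv")
    utils::write.csv(study$outcome, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  mj <- lapply(study$models, function(m) list(
    person_id = m$person_id, node_labels = m$node_labels,
    temporal_matrix = m$temporal_matrix,
    contemporaneous_pcor = m$contemporaneous_pcor,
    innovation_sd = m$innovation_sd, node_means = m$node_means))
  p <- file.path(dir, "models.json")
  jsonlite::write_json(mj, p, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, p))
}
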
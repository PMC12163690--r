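# Per-person contemporaneous partial-correlation networks from the
# residuals of lag-1 temporal regressions.
#
# Estimation proceeds in three steps per person: (1) build usable
# (t-1, t) slot pairs, lagging only within days; (2) regress every node at
# t on all nodes at t-1 (one least-squares fit per node) and collect the
# residuals; (3) invert the (possibly shrunken/ridged) residual covariance
# and read off partial correlations from the precision matrix. An optional
# pooled mode shrinks each person's residual correlation matrix toward the
# sample-size-weighted average before inversion, an empirical-Bayes
# stand-in for multilevel partial pooling.

#' Build within-day lag-1 slot pairs
#'
#' Pairs consecutive scheduled slots within the same day; slots are never
#' lagged across the overnight gap. A pair is usable only if both rows are
#' fully observed (listwise deletion per pair), so a missing slot removes
#' both its incoming and outgoing pair.
#'
#' @param series a [person_series()].
#' @return list with `X` (rows at t-1), `Y` (rows at t) and `n_pairs`.
#' @export
build_lag_pairs <- function(series) {
  stopifnot(inherits(series, "person_series"))
  M <- series$mat
  T_ <- nrow(M)
  if (T_ < 2) return(list(X = M[0, , drop = FALSE], Y = M[0, , drop = FALSE],
                          n_pairs = 0L))
  prev <- seq_len(T_ - 1)
  nxt <- prev + 1
  same_day <- series$day[prev] == series$day[nxt]
  ok <- same_day &
    stats::complete.cases(M[prev, , drop = FALSE]) &
    stats::complete.cases(M[nxt, , drop = FALSE])
  list(X = M[prev[ok], , drop = FALSE], Y = M[nxt[ok], , drop = FALSE],
       n_pairs = sum(ok))
}

#' Fit a person's lag-1 temporal model and collect residuals
#'
#' For each node, least-squares regression of the node at t on an intercept
#' plus all nodes at t-1, over the usable pairs. Residuals are collected per
#' pair and column-centred. A rank-deficient lagged design is stabilised by
#' a small ridge penalty on the normal equations; a node with zero variance
#' over the pairs is dropped with a warning.
#'
#' @param series a [person_series()].
#' @param min_pairs minimum usable pairs to attempt the fit (default 12,
#'   mirroring the participant-level inclusion threshold).
#' @param design_ridge ridge added to the normal equations when the lagged
#'   design is rank deficient (default 1e-6 relative to the mean predictor
#'   variance).
#' @return list with `temporal` (m x m, rows = outcome node, columns =
#'   predictor at t-1), `intercepts`, `residuals` (n_pairs x m, centred),
#'   `n_pairs`, `nodes`, `dropped` (zero-variance nodes removed).
#'   Errors with condition class `motivenets_too_few_pairs` when the pair
#'   count is below `min_pairs`.
#' @export
fit_person_var <- function(series, min_pairs = 12, design_ridge = 1e-6) {
  lp <- build_lag_pairs(series)
  if (lp$n_pairs < min_pairs) {
    cond <- structure(
      class = c("motivenets_too_few_pairs", "error", "condition"),
      list(message = sprintf(
        "person %s has %d usable lag pairs (< %d); excluded from network estimation",
        series$person_id, lp$n_pairs, min_pairs), call = NULL))
    stop(cond)
  }
  X <- lp$X
  Y <- lp$Y
  # drop nodes that are constant over the usable pairs
  sds <- apply(Y, 2, stats::sd)
  dropped <- colnames(Y)[sds == 0 | apply(X, 2, stats::sd) == 0]
  if (length(dropped) > 0) {
    warnf("person %s: zero-variance node(s) dropped: %s", series$person_id,
          paste(dropped, collapse = ", "))
    keep <- setdiff(colnames(Y), dropped)
    X <- X[, keep, drop = FALSE]
    Y <- Y[, keep, drop = FALSE]
  }
  m <- ncol(Y)
  D <- cbind(1, X)
  XtX <- crossprod(D)
  r <- 0
  if (qr(D)$rank < ncol(D)) {
    r <- design_ridge * mean(diag(XtX)[-1])
    XtX <- XtX + r * diag(ncol(D))
  }
  coef <- solve(XtX, crossprod(D, Y))      # (m+1) x m
  E <- Y - D %*% coef
  E <- scale(E, center = TRUE, scale = FALSE)
  list(temporal = t(coef[-1, , drop = FALSE]),
       intercepts = coef[1, ],
       residuals = E, n_pairs = lp$n_pairs,
       nodes = colnames(Y), dropped = dropped, design_ridge = r)
}

#' Partial correlations from residual rows
#'
#' Computes the residual covariance `S`, inverts `K = (S + ridge I)^{-1}`
#' and reads off partial correlations `pcor_ij = -K_ij / sqrt(K_ii K_jj)`.
#' The ridge is the smallest value on a geometric ladder (0, then
#' `1e-5 ... 1` times the mean residual variance) under which the inverse is
#' computable with condition number below `cond_cap`. The reporting
#' convention sets the diagonal to 0.
#'
#' @param residuals n x m matrix of (centred) residual rows, or an m x m
#'   covariance matrix with `n_obs` supplied.
#' @param ridge `NULL` (default) to pick from the ladder, or a fixed
#'   nonnegative value.
#' @param cond_cap maximum acceptable condition number of `S + ridge I`
#'   (default 1e8).
#' @param n_obs number of rows behind a covariance input.
#' @return list with `pcor` (diagonal 0), `ridge` (value used), `S`.
#' @export
residual_pcor <- function(residuals, ridge = NULL, cond_cap = 1e8,
                          n_obs = NULL) {
  if (is.matrix(residuals) && is.null(n_obs) &&
      nrow(residuals) == ncol(residuals) && isSymmetric(unname(residuals))) {
    # ambiguous square input: treat as data unless told otherwise
  }
  if (!is.null(n_obs)) {
    S <- residuals
    n <- n_obs
  } else {
    E <- as.matrix(residuals)
    n <- nrow(E)
    m <- ncol(E)
    if (n < m + 2) stopf("need at least m + 2 residual rows (%d < %d)", n, m + 2)
    S <- stats::cov(E)
  }
  pcor_from_cov(S, ridge = ridge, cond_cap = cond_cap)
}

# Shared core: partial correlations from a covariance matrix via precision
# inversion with a ridge ladder.
pcor_from_cov <- function(S, ridge = NULL, cond_cap = 1e8) {
  m <- ncol(S)
  scale0 <- mean(diag(S))
  ladder <- if (is.null(ridge)) c(0, 10^seq(-5, 0)) * scale0 else ridge
  for (r in ladder) {
    Sr <- S + r * diag(m)
    ev <- eigen(Sr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / min(ev) > cond_cap) next
    K <- solve(Sr)
    pc <- -K / sqrt(outer(diag(K), diag(K)))
    diag(pc) <- 0
    dimnames(pc) <- dimnames(S)
    return(list(pcor = pc, ridge = r, S = S))
  }
  stopf("residual covariance not invertible at maximum ridge")
}

#' Construct a motive network object
#'
#' @param person_id identifier.
#' @param nodes ordered node labels.
#' @param pcor symmetric partial-correlation matrix, diagonal 0.
#' @param temporal lag-1 coefficient matrix (rows = outcome).
#' @param residual_cov residual covariance.
#' @param n_lag_pairs usable pair count.
#' @param mode estimation mode label.
#' @param ridge ridge penalty applied at inversion.
#' @param shrinkage pooling weight lambda applied (0 for person-wise).
#' @return object of class `motive_network`.
#' @export
motive_network <- function(person_id, nodes, pcor, temporal = NULL,
                           residual_cov = NULL, n_lag_pairs = NA_integer_,
                           mode = "person_wise", ridge = 0, shrinkage = 0) {
  pcor <- as.matrix(pcor)
  if (max(abs(pcor - t(pcor))) > 1e-10)
    stopf("partial-correlation matrix is not symmetric")
  if (any(abs(pcor[upper.tri(pcor)]) > 1 + 1e-12))
    stopf("partial correlations outside [-1, 1]")
  diag(pcor) <- 0
  dimnames(pcor) <- list(nodes, nodes)
  structure(list(person_id = person_id, nodes = nodes, pcor = pcor,
                 temporal = temporal, residual_cov = residual_cov,
                 n_lag_pairs = n_lag_pairs, mode = mode, ridge = ridge,
                 shrinkage = shrinkage),
            class = "motive_network")
}

#' @export
print.motive_network <- function(x, ...) {
  w <- network_edges(x)
  cat(sprintf("Motive network %s: %d nodes, %d edges (%d negative), mode %s\n",
              x$person_id, length(x$nodes), length(w), sum(w < 0), x$mode))
  invisible(x)
}

#' Upper-triangle edge weights of a network
#'
#' @param net a [motive_network()] or a symmetric matrix.
#' @return numeric vector of the m(m-1)/2 edge weights.
#' @export
network_edges <- function(net) {
  M <- if (inherits(net, "motive_network")) net$pcor else as.matrix(net)
  M[upper.tri(M)]
}

#' Estimate contemporaneous networks for a set of persons
#'
#' `person_wise` fits each person independently. `pooled_shrunk` first
#' computes every person's residual correlation matrix, forms their
#' pair-count-weighted average `Rbar`, and shrinks each person's matrix
#' toward it with weight `lambda = m / (m + n_lag_pairs)` before inversion
#' (partial correlations are scale-free, so shrinking on the correlation
#' scale is exact). Persons failing preconditions are collected in
#' `$flagged` with the reason, not silently dropped.
#'
#' @param series_list list of [person_series()] objects.
#' @param mode `"person_wise"` (default) or `"pooled_shrunk"`.
#' @param min_pairs minimum usable lag pairs per person (default 12).
#' @param cond_cap condition-number cap passed to [residual_pcor()].
#' @param lambda optional fixed pooling weight in `[0, 1]` overriding the
#'   per-person `m / (m + n_lag_pairs)` (1 = total shrinkage: every person
#'   gets the pooled matrix).
#' @return list with `networks` (list of [motive_network()]) and `flagged`
#'   (data.frame person_id, reason).
#' @export
estimate_all <- function(series_list, mode = c("person_wise", "pooled_shrunk"),
                         min_pairs = 12, cond_cap = 1e8, lambda = NULL) {
  mode <- match.arg(mode)
  if (length(series_list) == 0) stopf("at least one person series required")
  fits <- list()
  flagged <- list()
  for (s in series_list) {
    f <- tryCatch(fit_person_var(s, min_pairs = min_pairs),
                  motivenets_too_few_pairs = function(e) conditionMessage(e))
    if (is.character(f)) {
      flagged[[s$person_id]] <- f
    } else {
      f$person_id <- s$person_id
      fits[[s$person_id]] <- f
    }
  }
  flag_df <- data.frame(person_id = names(flagged),
                        reason = unlist(flagged, use.names = FALSE) %||% character(0),
                        row.names = NULL)
  if (length(fits) == 0) return(list(networks = list(), flagged = flag_df))

  networks <- list()
  if (mode == "person_wise") {
    for (f in fits) {
      pp <- residual_pcor(f$residuals, cond_cap = cond_cap)
      networks[[f$person_id]] <- motive_network(
        f$person_id, f$nodes, pp$pcor, temporal = f$temporal,
        residual_cov = pp$S, n_lag_pairs = f$n_pairs, mode = mode,
        ridge = pp$ridge, shrinkage = 0)
    }
  } else {
    # pooled target: pair-count-weighted mean residual correlation,
    # aligned on the union of node labels (entries a person lacks simply
    # do not contribute)
    all_nodes <- motive_catalogue()
    acc <- matrix(0, length(all_nodes), length(all_nodes),
                  dimnames = list(all_nodes, all_nodes))
    wt <- acc
    Rp <- list()
    for (f in fits) {
      R <- stats::cov2cor(stats::cov(f$residuals))
      Rp[[f$person_id]] <- R
      acc[f$nodes, f$nodes] <- acc[f$nodes, f$nodes] + f$n_pairs * R
      wt[f$nodes, f$nodes] <- wt[f$nodes, f$nodes] + f$n_pairs
    }
    Rbar <- acc / ifelse(wt > 0, wt, 1)
    diag(Rbar) <- 1
    for (f in fits) {
      m <- length(f$nodes)
      lam <- lambda %||% (m / (m + f$n_pairs))
      Rs <- (1 - lam) * Rp[[f$person_id]] + lam * Rbar[f$nodes, f$nodes]
      pp <- pcor_from_cov(Rs, cond_cap = cond_cap)
      networks[[f$person_id]] <- motive_network(
        f$person_id, f$nodes, pp$pcor, temporal = f$temporal,
        residual_cov = stats::cov(f$residuals), n_lag_pairs = f$n_pairs,
        mode = mode, ridge = pp$ridge, shrinkage = lam)
    }
  }
  list(networks = networks, flagged = flag_df)
}

#' Write a network as JSON
#'
#' @param net a [motive_network()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(list(
    person_id = net$person_id, nodes = net$nodes, pcor = net$pcor,
    temporal = net$temporal, n_lag_pairs = net$n_lag_pairs,
    mode = net$mode, ridge = net$ridge, shrinkage = net$shrinkage),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a signed weighted edge list
#'
#' @param net a [motive_network()].
#' @param path output TSV file.
#' @return invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  m <- length(net$nodes)
  idx <- which(upper.tri(net$pcor), arr.ind = TRUE)
  df <- data.frame(node_a = net$nodes[idx[, 1]], node_b = net$nodes[idx[, 2]],
                   weight = net$pcor[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
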
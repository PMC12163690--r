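# Signed summary indices of a person's motive network.
#
# All three indices are functions of the m(m-1)/2 upper-triangle edge
# weights of the contemporaneous partial-correlation matrix, taken raw
# (no thresholding).

edge_weights <- function(net, floor_abs = 0) {
  w <- if (inherits(net, "motive_network")) network_edges(net) else
    if (is.matrix(net)) network_edges(net) else as.numeric(net)
  if (length(w) == 0) stopf("network has no edges")
  if (floor_abs > 0) w[abs(w) < floor_abs] <- 0
  w
}

#' Conflict proportion of a network
#'
#' Sum of absolute negative edge weights divided by the sum of absolute
#' values of all edge weights. A network with uniformly positive edges has
#' conflict proportion 0; a network with zero total edge strength returns 0
#' by convention.
#'
#' @param net a [motive_network()], a symmetric weight matrix, or a vector
#'   of edge weights.
#' @param floor_abs optional absolute-value floor below which edges are
#'   treated as 0 (default 0 = off; exposed to probe sensitivity to tiny
#'   estimated edges).
#' @return fraction in [0, 1].
#' @export
#' @examples
#' conflict_proportion(c(0.3, -0.1, 0.2))  # 0.1 / 0.6
conflict_proportion <- function(net, floor_abs = 0) {
  w <- edge_weights(net, floor_abs)
  tot <- sum(abs(w))
  if (tot == 0) return(0)
  sum(abs(w[w < 0])) / tot
}

#' Maximum conflict (strongest negative edge)
#'
#' The most negative edge weight; 0 if the network has no negative edge.
#'
#' @inheritParams conflict_proportion
#' @return weight <= 0.
#' @export
max_conflict <- function(net, floor_abs = 0) {
  w <- edge_weights(net, floor_abs)
  if (any(w < 0)) min(w) else 0
}

#' Maximum concordance (strongest positive edge)
#'
#' The most positive edge weight; 0 if the network has no positive edge.
#'
#' @inheritParams conflict_proportion
#' @return weight >= 0.
#' @export
max_concordance <- function(net, floor_abs = 0) {
  w <- edge_weights(net, floor_abs)
  if (any(w > 0)) max(w) else 0
}

#' Mean motive satisfaction over the ESM period
#'
#' Mean of all answered selected-motive item responses across the series,
#' ignoring missing entries.
#'
#' @param series a [person_series()].
#' @return mean on the 0-9 scale.
#' @export
mean_satisfaction <- function(series) {
  stopifnot(inherits(series, "person_series"))
  v <- series$mat[!is.na(series$mat)]
  if (length(v) == 0) stopf("person %s has no answered items", series$person_id)
  mean(v)
}

#' Person-level index table
#'
#' Computes the three network indices and mean satisfaction for every
#' person with both an estimated network and a series.
#'
#' @param networks list of [motive_network()] objects (named by person).
#' @param series_list list of [person_series()] objects (named by person).
#' @param floor_abs optional absolute edge floor, see
#'   [conflict_proportion()].
#' @return data.frame: person_id, conflict_proportion, max_conflict,
#'   max_concordance, mean_satisfaction, n_lag_pairs.
#' @export
indices_table <- function(networks, series_list, floor_abs = 0) {
  ids <- intersect(names(networks), names(series_list))
  if (length(ids) == 0) stopf("no persons shared between networks and series")
  rows <- lapply(ids, function(pid) {
    net <- networks[[pid]]
    data.frame(person_id = pid,
               conflict_proportion = conflict_proportion(net, floor_abs),
               max_conflict = max_conflict(net, floor_abs),
               max_concordance = max_concordance(net, floor_abs),
               mean_satisfaction = mean_satisfaction(series_list[[pid]]),
               n_lag_pairs = net$n_lag_pairs)
  })
  do.call(rbind, rows)
}

#' Sample-level summary of the network indices
#'
#' @param indices data.frame from [indices_table()] (>= 2 persons).
#' @return data.frame with mean, SD, min and max per index, plus an
#'   attribute `n_zero_conflict` counting persons without any negative edge.
#' @export
sample_summary <- function(indices) {
  stopifnot(is.data.frame(indices), nrow(indices) >= 2)
  vars <- c("conflict_proportion", "max_conflict", "max_concordance",
            "mean_satisfaction")
  vars <- intersect(vars, names(indices))
  out <- data.frame(
    index = vars,
    mean = vapply(vars, function(v) mean(indices[[v]]), numeric(1)),
    sd = vapply(vars, function(v) stats::sd(indices[[v]]), numeric(1)),
    min = vapply(vars, function(v) min(indices[[v]]), numeric(1)),
    max = vapply(vars, function(v) max(indices[[v]]), numeric(1)),
    row.names = NULL)
  attr(out, "n_zero_conflict") <- sum(indices$conflict_proportion == 0)
  out
}
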
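#' Canonical catalogue of approach motives
#'
#' The fixed, ordered catalogue of the 14 approach motives scored by the
#' importance inventory (IAAM-style instruments cover 14 approach motives;
#' avoidance motives are out of scope here). The order is canonical: it is
#' the tie-breaking order for motive selection and the column order of every
#' per-person network, so node ordering is stable across persons and runs.
#'
#' @return character vector of 14 motive names, in canonical order.
#' @export
#' @examples
#' motive_catalogue()
motive_catalogue <- function() {
  c("intimacy", "affiliation", "altruism", "support", "recognition",
    "control", "education", "meaning", "confidence", "self-reward",
    "autonomy", "achievement", "variety", "status")
}

#' Select a person's k most important motives
#'
#' Picks the `k` motives with the highest importance scores. Ties at the
#' selection boundary are broken by canonical catalogue order
#' ([motive_catalogue()]), which makes selection deterministic. The result is
#' returned in canonical order (not score order) so node ordering is
#' identical across persons sharing a motive.
#'
#' @param scores named numeric vector of mean importance scores on the 1-5
#'   scale, one element per motive; names must be catalogue motives.
#' @param k number of motives to select (default 7).
#' @return character vector of `k` motive names in canonical catalogue order.
#' @export
#' @examples
#' sc <- stats::setNames(seq(5, 1.5, length.out = 14), motive_catalogue())
#' top_k_motives(sc, 7)
top_k_motives <- function(scores, k = 7) {
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (is.null(names(scores)) || anyNA(names(scores)))
    stopf("scores must be a named vector of motive importances")
  cat_order <- motive_catalogue()
  unknown <- setdiff(names(scores), cat_order)
  if (length(unknown) > 0)
    stopf("unknown motive(s) in importance profile: %s",
          paste(unknown, collapse = ", "))
  if (anyDuplicated(names(scores)))
    stopf("duplicated motive names in importance profile")
  if (length(scores) < k)
    stopf("profile scores %d motives but k = %d requested", length(scores), k)
  if (any(!is.finite(scores)) || any(scores < 1) || any(scores > 5))
    stopf("importance scores must lie on the 1-5 scale")
  # order by score (desc), ties by canonical position (asc)
  pos <- match(names(scores), cat_order)
  ord <- order(-scores, pos)
  chosen <- names(scores)[ord[seq_len(k)]]
  chosen[order(match(chosen, cat_order))]
}

#' Share of persons whose network includes each motive
#'
#' @param profiles list of named score vectors (one per person), or a
#'   data.frame with a `person_id` column plus one column per motive.
#' @param k motives selected per person (default 7).
#' @return named numeric vector: per-motive fraction of persons selecting it,
#'   over the full catalogue (zeros included). Fractions need not sum to 1.
#' @export
selection_prevalence <- function(profiles, k = 7) {
  if (is.data.frame(profiles)) profiles <- importance_profiles(profiles)
  if (length(profiles) == 0) stopf("at least one importance profile required")
  sel <- lapply(profiles, top_k_motives, k = k)
  tab <- table(factor(unlist(sel), levels = motive_catalogue()))
  as.vector(tab) / length(profiles) -> out
  names(out) <- motive_catalogue()
  out
}

#' Turn an importance table into per-person score vectors
#'
#' @param importance data.frame with `person_id` plus one numeric column per
#'   catalogue motive (the baseline CSV layout). Columns may use `.` in place
#'   of `-` (as produced by [utils::read.csv()] with default name mangling).
#' @return named list person_id -> named score vector.
#' @export
importance_profiles <- function(importance) {
  stopifnot(is.data.frame(importance), "person_id" %in% names(importance))
  cols <- setdiff(names(importance), "person_id")
  fixed <- gsub(".", "-", cols, fixed = TRUE)
  keep <- fixed %in% motive_catalogue()
  if (!any(keep)) stopf("no catalogue motive columns found in importance table")
  out <- lapply(seq_len(nrow(importance)), function(i) {
    v <- as.numeric(importance[i, cols[keep]])
    names(v) <- fixed[keep]
    v
  })
  names(out) <- as.character(importance$person_id)
  out
}
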
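# End-to-end orchestration: ingest (or simulate) -> motive selection ->
# network estimation -> indices -> between-person inference -> hybrid LMM,
# with every artifact written to disk under a checksummed manifest.

#' Pipeline configuration
#'
#' Exactly one data source must be given: either the two input CSV paths
#' (`beeps_csv`, `baseline_csv` with importance scores and the depression
#' score) or a `simulate` block.
#'
#' @param beeps_csv path to the beep-level CSV (see [read_beeps_csv()]).
#' @param importance_csv path to the baseline importance CSV.
#' @param baseline_csv path to the baseline outcome CSV (person_id, dass_d).
#' @param simulate a [sim_config()] to generate data instead of reading it.
#' @param truth a [between_truth()] used when simulating.
#' @param mode network estimation mode, see [estimate_all()].
#' @param n_selected motives per person (default 7).
#' @param min_pairs minimum usable lag pairs per person (default 12).
#' @param adherence_threshold minimum valid assessments (default 12).
#' @param floor_abs absolute edge floor for the indices (default 0 = off).
#' @param n_boot bootstrap resamples (default 5000).
#' @param ci_level bootstrap interval coverage (default 0.95).
#' @param seed integer seed; mandatory (drives simulation and resampling).
#' @param outdir output directory for the report bundle.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(beeps_csv = NULL, importance_csv = NULL,
                            baseline_csv = NULL, simulate = NULL,
                            truth = between_truth(),
                            mode = "pooled_shrunk", n_selected = 7,
                            min_pairs = 12, adherence_threshold = 12,
                            floor_abs = 0, n_boot = 5000, ci_level = 0.95,
                            seed = NULL, outdir = tempfile("motivenets_")) {
  have_paths <- !is.null(beeps_csv)
  have_sim <- !is.null(simulate)
  if (have_paths == have_sim)
    stopf("exactly one of input paths / simulate must be given")
  if (have_sim && !inherits(simulate, "sim_config"))
    stopf("simulate must be a sim_config")
  if (have_paths && (is.null(importance_csv) || is.null(baseline_csv)))
    stopf("importance_csv and baseline_csv are required with beeps_csv")
  if (is.null(seed) || !is_count(abs(seed)))
    stopf("an integer seed is mandatory")
  structure(list(beeps_csv = beeps_csv, importance_csv = importance_csv,
                 baseline_csv = baseline_csv, simulate = simulate,
                 truth = truth, mode = mode, n_selected = n_selected,
                 min_pairs = min_pairs,
                 adherence_threshold = adherence_threshold,
                 floor_abs = floor_abs, n_boot = n_boot,
                 ci_level = ci_level, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes ingest (or simulation), the validity filter, adherence
#' accounting, low-adherence exclusion, motive selection, per-person network
#' estimation, index computation, the three between-person regression models
#' with bootstrap inference, and the hybrid mixed model; writes every
#' artifact into `config$outdir` and finishes with a checksum manifest.
#' Progress and filter-stage counts are logged via [message()]. A stage
#' error aborts with the stage name; artifacts already written persist.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the report bundle: list with `adherence`, `exclusion`,
#'   `selection`, `networks`, `flagged`, `indices`, `table3`, `exploratory`,
#'   `lmm`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(x) files <<- c(files, x)

  if (!is.null(config$simulate)) {
    study <- stage("simulate", simulate_study(config$simulate, config$truth,
                                              seed = config$seed))
    put(stage("simulate", write_study_csv(study,
                                          file.path(config$outdir, "data"))))
    beeps <- study$beeps
    importance <- study$importance
    outcome <- study$outcome
    message(sprintf("simulated %d persons, %d beep records",
                    config$simulate$n_participants, nrow(beeps)))
  } else {
    beeps <- stage("ingest", read_beeps_csv(config$beeps_csv))
    importance <- stage("ingest", utils::read.csv(config$importance_csv,
                                                  check.names = FALSE))
    outcome <- stage("ingest", utils::read.csv(config$baseline_csv,
                                               check.names = FALSE))
    message(sprintf("read %d beep records", nrow(beeps)))
  }

  filtered <- stage("validity_filter", apply_validity_filter(beeps))
  message(sprintf("validity filter: %d of %d records valid",
                  sum(filtered$status == "completed"), nrow(filtered)))

  slots <- max(table(filtered$person_id))
  adh <- stage("adherence", compute_adherence(
    filtered, n_participants = length(unique(filtered$person_id)),
    slots_per_person = slots))
  p <- file.path(config$outdir, "adherence.json")
  jsonlite::write_json(unclass(adh), p, digits = NA, auto_unbox = TRUE)
  put(p)
  message(sprintf("adherence: %d%%", adh$adherence_pct))

  excl <- stage("exclusion", exclude_low_adherence(valid_counts(filtered),
                                                   config$adherence_threshold))
  p <- file.path(config$outdir, "exclusions.tsv")
  utils::write.table(excl$excluded, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  put(p)
  message(sprintf("exclusion: %d retained, %d dropped",
                  length(excl$retained), nrow(excl$excluded)))

  profiles <- stage("selection", importance_profiles(importance))
  profiles <- profiles[intersect(names(profiles), excl$retained)]
  selection <- stage("selection",
                     lapply(profiles, top_k_motives, k = config$n_selected))
  sel_df <- data.frame(person_id = names(selection),
                       do.call(rbind, selection))
  names(sel_df)[-1] <- paste0("motive_", seq_len(config$n_selected))
  p <- file.path(config$outdir, "selection.tsv")
  utils::write.table(sel_df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  put(p)

  keep <- filtered[filtered$person_id %in% excl$retained, , drop = FALSE]
  series <- stage("assemble", assemble_series(keep, selection))

  est <- stage("network_estimation",
               estimate_all(series, mode = config$mode,
                            min_pairs = config$min_pairs))
  net_dir <- file.path(config$outdir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (net in est$networks) {
    put(write_network_json(net, file.path(net_dir,
                                          paste0(net$person_id, ".json"))))
    put(write_edge_list(net, file.path(net_dir,
                                       paste0(net$person_id, "_edges.tsv"))))
  }
  message(sprintf("estimated %d networks (%d flagged)",
                  length(est$networks), nrow(est$flagged)))

  idx <- stage("indices", indices_table(est$networks, series,
                                        floor_abs = config$floor_abs))
  p <- file.path(config$outdir, "indices.csv")
  utils::write.csv(idx, p, row.names = FALSE)
  put(p)

  tab3 <- stage("between_person", run_table3(
    idx, outcome, n_boot = config$n_boot, seed = config$seed,
    ci_level = config$ci_level))
  p <- file.path(config$outdir, "table3.tsv")
  utils::write.table(as.data.frame(tab3), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  put(p)

  merged <- merge(idx, outcome, by = "person_id")
  expl <- stage("exploratory", exploratory_subsample(
    merged, n_boot = config$n_boot, seed = config$seed,
    ci_level = config$ci_level))
  p <- file.path(config$outdir, "exploratory.json")
  jsonlite::write_json(list(rule = expl$rule, n_dropped = expl$n_dropped,
                            dropped_ids = expl$dropped_ids,
                            refit = expl$refit),
                       p, digits = NA, auto_unbox = TRUE)
  put(p)

  hyb <- stage("lmm", build_hybrid_dataset(series))
  lmm <- stage("lmm", fit_random_intercept(hyb))
  lmm_path <- file.path(config$outdir, "lmm.json")
  put(write_lmm_json(lmm, lmm_path))

  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)))
  manifest$file <- substring(manifest$file, nchar(config$outdir) + 2)
  p <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(list(seed = config$seed, mode = config$mode,
                            n_boot = config$n_boot, files = manifest),
                       p, digits = NA, auto_unbox = TRUE)

  invisible(list(adherence = adh, exclusion = excl, selection = selection,
                 networks = est$networks, flagged = est$flagged,
                 indices = idx, table3 = tab3, exploratory = expl, lmm = lmm,
                 files = c(files, p), outdir = config$outdir))
}

#' Export a network as a Graphviz DOT drawing
#'
#' Green edges for concordant (positive) and red for discordant (negative)
#' relationships; pen width proportional to |weight|; exact-zero edges are
#' omitted.
#'
#' @param net a [motive_network()].
#' @param path output `.dot` file.
#' @return invisibly, `path`.
#' @export
export_network_graph <- function(net, path) {
  stopifnot(inherits(net, "motive_network"))
  idx <- which(upper.tri(net$pcor), arr.ind = TRUE)
  w <- net$pcor[idx]
  keep <- w != 0
  wmax <- if (any(keep)) max(abs(w[keep])) else 1
  lines <- c(sprintf('graph "%s" {', net$person_id),
             "  layout=circo;",
             sprintf('  "%s";', net$nodes))
  for (k in which(keep)) {
    lines <- c(lines, sprintf(
      '  "%s" -- "%s" [color=%s, penwidth=%.3f, weight_value=%.6f];',
      net$nodes[idx[k, 1]], net$nodes[idx[k, 2]],
      if (w[k] > 0) "green" else "red",
      0.5 + 4 * abs(w[k]) / wmax, w[k]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
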
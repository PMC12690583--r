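# End-to-end orchestration: curate -> cluster -> down-sample -> augment ->
# split, as one configurable, seeded, logged run. All stage randomness is
# derived from the single global seed via derive_seed(seed, stage), so adding
# or re-running a stage never perturbs another stage's stream.

#' Pipeline configuration
#'
#' Validates every stage's parameters up front so a run fails before any work
#' starts rather than mid-way.
#'
#' @param threshold pChEMBL labeling threshold.
#' @param K Number of chemical-space clusters.
#' @param variance_target PCA variance fraction to retain.
#' @param cap_multitarget,cap_rest Down-sampling caps.
#' @param balance A [balance_params()] object.
#' @param cutoffs Named per-family cutoff-year vector (with a `default`).
#' @param prevalence_threshold Reporting threshold for "high-prevalence"
#'   targets.
#' @param seed Global seed.
#' @return Config list of class `cdpn_config`.
#' @export
cdpn_config <- function(threshold = 6.0, K = 50, variance_target = 0.95,
                        cap_multitarget = 3, cap_rest = 3,
                        balance = balance_params(),
                        cutoffs = c(default = 2015),
                        prevalence_threshold = 0.8, seed = 1) {
  stopifnot(is.finite(threshold), K >= 1,
            variance_target > 0, variance_target <= 1,
            cap_multitarget >= 1, cap_rest >= 1,
            inherits(balance, "cdpn_balance_params"),
            length(cutoffs) >= 1, !is.null(names(cutoffs)),
            prevalence_threshold > 0, prevalence_threshold < 1,
            is.finite(seed))
  structure(as.list(environment()), class = "cdpn_config")
}

#' Run the full dataset-construction pipeline
#'
#' Stages, in order: curation (unit filter, drug-likeness, labeling at the
#' pChEMBL threshold, frequent hitters, conflict resolution), chemical-space
#' clustering (PCA + k-means on the compound pool, cluster assignment),
#' cluster-capped down-sampling, putative-negative augmentation, and the
#' time/scenario split. Returns the intermediate tables plus a bias report
#' (per-target prevalence before/after augmentation, the accounting identity
#' rows_final = rows_downsampled + rows_putative, and the final positive /
#' negative percentages). When `out_dir` is given the bundle is written
#' atomically: everything goes to a temporary sibling directory which is
#' renamed into place only on success.
#'
#' @param records Raw activity records (see [curate_records()]).
#' @param compounds Compound pool: a `cdpn_synth_compounds` object or a list
#'   with `props` (data.frame) and `fingerprints` (matrix, row names =
#'   compound ids).
#' @param config A [cdpn_config()].
#' @param blocklist Optional frequent-hitter compound ids.
#' @param out_dir Optional output directory for the dataset bundle.
#' @return List of class `cdpn_run`: `curated`, `model`, `downsampled`,
#'   `balanced`, `split`, `report`.
#' @export
run_cdpn <- function(records, compounds, config = cdpn_config(),
                     blocklist = character(), out_dir = NULL) {
  stopifnot(inherits(config, "cdpn_config"))
  if (!all(c("props", "fingerprints") %in% names(compounds)))
    stop("compounds must provide $props and $fingerprints")
  props <- as_interaction_dt(compounds$props, "compound_id")
  fp <- compounds$fingerprints
  if (is.null(rownames(fp)))
    stop("fingerprint matrix must carry compound ids as row names")

  # stage 1: curation
  curated <- curate_records(records, props = props, blocklist = blocklist,
                            threshold = config$threshold)
  if (!nrow(curated)) stop("curation produced an empty table")

  # stage 2: chemical-space clustering on the drug-like pool
  ok <- filter_druglike(props)
  pool_ids <- props$compound_id[ok]
  model <- fit_cluster_model(fp[pool_ids, , drop = FALSE], K = config$K,
                             variance_target = config$variance_target,
                             seed = derive_seed(config$seed, "cluster"))
  pool <- data.table::data.table(
    compound_id = pool_ids,
    cluster_id = as.integer(model$assignment))
  curated[, cluster_id := NULL]
  curated <- pool[curated, on = "compound_id"]
  if (any(is.na(curated$cluster_id)))
    stop("curated compounds missing from the clustered pool")
  data.table::setcolorder(curated, c("compound_id", "target_id", "label",
                                     "provenance", "year", "family",
                                     "cluster_id"))

  # stage 3: cluster-capped down-sampling
  downsampled <- run_downsampling(curated,
                                  cap_multitarget = config$cap_multitarget,
                                  cap_rest = config$cap_rest,
                                  seed = derive_seed(config$seed, "downsample"))

  # stage 4: putative-negative augmentation
  bal_params <- config$balance
  bal_params$seed <- derive_seed(config$seed, "balance")
  balanced <- balance_dataset(downsampled, pool, bal_params)

  # stage 5: time/scenario split
  split <- scenario_split(balanced, config$cutoffs)

  rep_bal <- balance_report(downsampled, balanced,
                            threshold = config$prevalence_threshold)
  n_put <- sum(balanced$provenance == "putative")
  report <- list(
    n_records_raw = nrow(records),
    n_curated = nrow(curated),
    n_downsampled = nrow(downsampled),
    n_putative = n_put,
    n_balanced = nrow(balanced),
    rows_reconciled = nrow(balanced) == nrow(downsampled) + n_put,
    pct_positive = 100 * mean(balanced$label == "positive"),
    pct_negative = 100 * mean(balanced$label == "negative"),
    prevalence_threshold = config$prevalence_threshold,
    n_high_prevalence_before = rep_bal$n_high_before,
    n_high_prevalence_after = rep_bal$n_high_after,
    scenario_counts = lapply(split, nrow))

  run <- structure(list(curated = curated, model = model,
                        downsampled = downsampled, balanced = balanced,
                        split = split, report = report,
                        per_target = rep_bal$per_target),
                   class = "cdpn_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.cdpn_run <- function(x, ...) {
  r <- x$report
  cat("cdpn pipeline run\n")
  cat(sprintf("  curated pairs:        %d\n", r$n_curated))
  cat(sprintf("  after down-sampling:  %d\n", r$n_downsampled))
  cat(sprintf("  putative negatives:   %d\n", r$n_putative))
  cat(sprintf("  final dataset:        %d (%.2f%% positive)\n",
              r$n_balanced, r$pct_positive))
  cat(sprintf("  targets with prevalence > %.2f: %d -> %d\n",
              r$prevalence_threshold, r$n_high_prevalence_before,
              r$n_high_prevalence_after))
  invisible(x)
}

# Atomic bundle write: stage into a temp sibling, rename on success.
write_run <- function(run, out_dir) {
  parent <- dirname(normalizePath(out_dir, mustWork = FALSE))
  dir.create(parent, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile("cdpn_bundle_", tmpdir = parent)
  dir.create(tmp)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  data.table::fwrite(run$curated, file.path(tmp, "curated.csv"))
  data.table::fwrite(run$downsampled, file.path(tmp, "downsampled.csv"))
  data.table::fwrite(run$balanced, file.path(tmp, "balanced.csv"))
  data.table::fwrite(run$per_target, file.path(tmp, "prevalence_report.csv"))
  write_cluster_model(run$model, file.path(tmp, "cluster_model.json"))
  write_split(run$split, file.path(tmp, "split"))
  jsonlite::write_json(run$report, file.path(tmp, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  if (!file.rename(tmp, out_dir))
    stop("failed to move bundle into place at ", out_dir)
  ok <- TRUE
  invisible(out_dir)
}
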
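# Time-based train/validation splitting and the four seen/unseen screening
# scenarios. "Seen" is defined against the training partition: a target is
# seen if it occurs in training; a compound is seen if its chemical cluster
# occurs in training. Putative rows have no measurement date and are always
# routed to training.

#' Split interactions at per-family cutoff years
#'
#' Measured rows dated strictly before their family's cutoff go to training;
#' rows at or after the cutoff go to validation. Putative (augmented) rows
#' always go to training. Cutoffs are a named vector by family; a `default`
#' entry covers families without their own cutoff.
#'
#' @param interactions Interaction table with `year`, `family`, and
#'   optionally `provenance`.
#' @param cutoff_year_by_family Named numeric vector, e.g.
#'   `c(Kinase = 2016, default = 2015)`.
#' @return List with `train` and `val` data.tables.
#' @export
time_split <- function(interactions,
                       cutoff_year_by_family = c(default = 2015)) {
  dt <- as_interaction_dt(interactions,
                          c("compound_id", "target_id", "year", "family"))
  if (!"provenance" %in% names(dt)) dt[, provenance := "measured"]
  fams <- unique(dt$family)
  cut <- cutoff_year_by_family[fams]
  if (any(is.na(cut))) {
    if (!"default" %in% names(cutoff_year_by_family))
      stop("no cutoff year for family(ies): ",
           paste(fams[is.na(cut)], collapse = ", "),
           " and no 'default' entry")
    cut[is.na(cut)] <- cutoff_year_by_family[["default"]]
  }
  names(cut) <- fams
  if (any(dt$provenance == "measured" & is.na(dt$year)))
    stop("measured rows must carry a year")
  to_train <- dt$provenance == "putative" | dt$year < cut[dt$family]
  list(train = dt[to_train], val = dt[!to_train])
}

#' Partition validation rows into the four seen/unseen scenarios
#'
#' Cross-classifies each validation row by whether its target occurs in
#' training (seen target) and whether its compound cluster occurs in
#' training (seen cluster): seen/seen probes drug repurposing, seen target /
#' unseen cluster probes novel lead discovery, and the two unseen-target
#' sets probe generalization to novel targets.
#'
#' @param train,val Output of [time_split()].
#' @return Object of class `cdpn_split`: `train` plus the four validation
#'   sets `val_seen_seen`, `val_seen_unseen_cluster`,
#'   `val_unseen_target_seen_cluster`, `val_unseen_unseen`.
#' @export
assign_scenarios <- function(train, val) {
  train <- as_interaction_dt(train, c("target_id", "cluster_id"))
  val <- as_interaction_dt(val, c("target_id", "cluster_id"))
  if (nrow(val) && any(is.na(val$cluster_id)))
    stop("cluster_id must be assigned on every validation row")
  seen_t <- val$target_id %in% unique(train$target_id)
  seen_c <- val$cluster_id %in% unique(train$cluster_id)
  structure(list(
    train = train,
    val_seen_seen = val[seen_t & seen_c],
    val_seen_unseen_cluster = val[seen_t & !seen_c],
    val_unseen_target_seen_cluster = val[!seen_t & seen_c],
    val_unseen_unseen = val[!seen_t & !seen_c]),
    class = "cdpn_split")
}

#' Time split plus scenario assignment in one call
#'
#' @inheritParams time_split
#' @return A `cdpn_split` (see [assign_scenarios()]) with the cutoffs
#'   attached as attribute `cutoffs`.
#' @export
scenario_split <- function(interactions,
                           cutoff_year_by_family = c(default = 2015)) {
  ts <- time_split(interactions, cutoff_year_by_family)
  out <- assign_scenarios(ts$train, ts$val)
  attr(out, "cutoffs") <- cutoff_year_by_family
  out
}

#' @export
print.cdpn_split <- function(x, ...) {
  cat("cdpn scenario split\n")
  for (nm in names(x))
    cat(sprintf("  %-32s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Write a scenario split as five CSV files plus a JSON manifest
#'
#' @param split A `cdpn_split`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "cdpn_split"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- lapply(split, nrow)
  for (nm in names(split))
    data.table::fwrite(split[[nm]], file.path(dir, paste0(nm, ".csv")))
  manifest <- file.path(dir, "split_manifest.json")
  jsonlite::write_json(counts, manifest, auto_unbox = TRUE)
  invisible(manifest)
}
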
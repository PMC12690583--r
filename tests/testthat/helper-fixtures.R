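# Shared fixtures and independent oracles for the test suite.

# One-liner interaction rows for hand-built tables.
make_inter <- function(compound_id, target_id, label = "positive",
                       year = 2010L, family = "Kinase", cluster_id = 1L,
                       provenance = "measured") {
  data.table::data.table(compound_id = compound_id, target_id = target_id,
                         label = label, provenance = provenance,
                         year = as.integer(year), family = family,
                         cluster_id = as.integer(cluster_id))
}

# Random labeled-record table for property tests.
random_records <- function(n, n_compounds = 20, n_targets = 8, seed = 1) {
  set.seed(seed)
  data.table::data.table(
    compound_id = sprintf("C%03d", sample.int(n_compounds, n, replace = TRUE)),
    target_id = sprintf("T%02d", sample.int(n_targets, n, replace = TRUE)),
    label = sample(c("positive", "negative"), n, replace = TRUE),
    year = sample(2000:2020, n, replace = TRUE),
    family = sample(cpi_families(), n, replace = TRUE))
}

# Brute-force conflict-resolution oracle: group by pair, drop pairs seen
# with both labels, keep the earliest year among duplicates.
resolve_oracle <- function(dt) {
  dt <- as.data.frame(dt)
  key <- paste(dt$compound_id, dt$target_id, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(dt)), key), function(ix) {
    if (length(unique(dt$label[ix])) > 1) return(integer(0))
    ix[which.min(dt$year[ix])]
  }))
  out <- dt[sort(keep), c("compound_id", "target_id", "label", "year")]
  out[order(out$compound_id, out$target_id), , drop = FALSE]
}

# Independent loop-based BEDROC oracle (distinct scores assumed: the
# ranking is then unambiguous and tie-shuffling is a no-op).
bedroc_oracle <- function(scores, labels, alpha) {
  ord <- order(scores, decreasing = TRUE)
  N <- length(scores)
  s <- 0; n <- 0
  for (i in seq_len(N)) {
    if (labels[ord[i]] == 1) { s <- s + exp(-alpha * i / N); n <- n + 1 }
  }
  smax <- 0
  for (i in seq_len(n)) smax <- smax + exp(-alpha * i / N)
  smin <- 0
  for (i in seq.int(N - n + 1, N)) smin <- smin + exp(-alpha * i / N)
  (s - smin) / (smax - smin)
}

# Sorted canonical copy for set-style table comparisons.
sorted_tbl <- function(dt) {
  dt <- data.table::as.data.table(dt)
  data.table::setorderv(data.table::copy(dt), names(dt), na.last = TRUE)[]
}

# Tiny synthetic bundle used by several suites.
small_bundle <- function(seed = 11, n_targets = 20, n_compounds = 400,
                         n_clusters = 10) {
  generate_synth_bundle(synth_config(
    n_targets = n_targets, n_compounds = n_compounds,
    n_clusters = n_clusters, records_per_target_range = c(10, 30),
    seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
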
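# Seeded synthetic CPI tables with the structure the pipeline assumes:
# compounds planted in chemical clusters (cluster-biased fingerprint bits),
# targets in six protein families, per-target positive prevalence drawn from
# a skewed Beta distribution, each target screened against a small set of
# clusters (analogue concentration), record years spanning a cutoff, and
# injected duplicates / label conflicts.

#' Synthetic dataset configuration
#'
#' Defaults describe the standard desk-scale bundle: 200 targets, 5,000
#' compounds in 50 planted clusters, 50-150 records per target (~20,000
#' rows), per-target positive prevalence Beta(5, 1) (heavily
#' positive-skewed), each target drawing its compounds from 8 clusters.
#'
#' @param n_targets,n_compounds,n_clusters Sizes; `n_clusters <= n_compounds`.
#' @param fp_len Fingerprint length in bits.
#' @param signature_bits Cluster-specific high-probability bits per cluster.
#' @param prevalence_shape `c(a, b)` of the Beta distribution of per-target
#'   positive prevalence.
#' @param records_per_target_range Integer interval of records per target.
#' @param clusters_per_target Number of clusters a target's compounds are
#'   drawn from (analogue concentration of real screens).
#' @param year_range Integer interval of record years.
#' @param conflict_rate Fraction of pairs receiving a conflicting-label
#'   duplicate record.
#' @param duplicate_rate Fraction of rows duplicated (consistent label).
#' @param druglike_violation_rate Fraction of compounds violating a
#'   drug-likeness rule (metal atom, MW >= 1000, or heavy atoms <= 12).
#' @param seed Integer seed; all outputs are byte-deterministic under it.
#' @return Validated config of class `cdpn_synth_config`.
#' @export
synth_config <- function(n_targets = 200, n_compounds = 5000,
                         n_clusters = 50, fp_len = 128, signature_bits = 8,
                         prevalence_shape = c(5, 1),
                         records_per_target_range = c(50, 150),
                         clusters_per_target = min(8, n_clusters),
                         year_range = c(2000, 2020),
                         conflict_rate = 0.02, duplicate_rate = 0.05,
                         druglike_violation_rate = 0.05, seed = 1) {
  stopifnot(n_targets >= 1, n_compounds >= 1,
            n_clusters >= 1, n_clusters <= n_compounds,
            fp_len >= 8, signature_bits >= 1, signature_bits < fp_len,
            length(prevalence_shape) == 2, all(prevalence_shape > 0),
            length(records_per_target_range) == 2,
            records_per_target_range[1] >= 1,
            diff(records_per_target_range) >= 0,
            clusters_per_target >= 1, clusters_per_target <= n_clusters,
            length(year_range) == 2, diff(year_range) >= 0,
            conflict_rate >= 0, conflict_rate < 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            druglike_violation_rate >= 0, druglike_violation_rate < 1)
  structure(as.list(environment()), class = "cdpn_synth_config")
}

#' Generate synthetic compounds with planted clusters
#'
#' Fingerprints have a low background on-bit rate plus cluster-specific
#' signature bits at high rate, so a fitted k-means model can recover the
#' planted partition. A configured fraction of compounds violates one
#' drug-likeness rule each.
#'
#' @param config A [synth_config()].
#' @return List of class `cdpn_synth_compounds`: `props` (data.table of
#'   `compound_id`, `cluster_true`, `mol_weight`, `heavy_atoms`,
#'   `contains_metal`, `complexity_bits`) and `fingerprints` (0/1 matrix,
#'   row names = compound ids).
#' @export
generate_compounds <- function(config) {
  stopifnot(inherits(config, "cdpn_synth_config"))
  with_seed(derive_seed(config$seed, "compounds"), {
    n <- config$n_compounds
    ids <- sprintf("C%05d", seq_len(n))
    cluster_true <- sort(rep_len(seq_len(config$n_clusters), n))
    # each cluster owns a block of signature bits (wrapping if needed)
    sig <- lapply(seq_len(config$n_clusters), function(k) {
      ((k - 1) * config$signature_bits +
         seq_len(config$signature_bits) - 1) %% config$fp_len + 1
    })
    fp <- matrix(rbinom(n * config$fp_len, 1, 0.05), nrow = n,
                 dimnames = list(ids, NULL))
    for (k in seq_len(config$n_clusters)) {
      rows <- which(cluster_true == k)
      fp[rows, sig[[k]]] <- matrix(
        rbinom(length(rows) * config$signature_bits, 1, 0.9),
        nrow = length(rows))
    }
    props <- data.table::data.table(
      compound_id = ids,
      cluster_true = cluster_true,
      mol_weight = round(exp(rnorm(n, log(380), 0.25)), 1),
      heavy_atoms = pmax(13L, as.integer(rpois(n, 26))),
      contains_metal = rep(FALSE, n))
    # inject drug-likeness violations, one rule per violator
    n_bad <- round(config$druglike_violation_rate * n)
    if (n_bad > 0) {
      bad <- sample.int(n, n_bad)
      kind <- sample(c("metal", "mw", "heavy"), n_bad, replace = TRUE)
      props[bad[kind == "metal"], contains_metal := TRUE]
      props[bad[kind == "mw"], mol_weight := round(runif(.N, 1000, 1800), 1)]
      props[bad[kind == "heavy"], heavy_atoms := sample(3:12, .N, replace = TRUE)]
    }
    props[, complexity_bits := as.integer(rowSums(fp))]
  })
  structure(list(props = props, fingerprints = fp),
            class = "cdpn_synth_compounds")
}

#' Generate a synthetic raw activity table
#'
#' One row per assay record. Per target: a protein family (round-robin over
#' the six-family vocabulary), a positive prevalence drawn from the
#' configured Beta distribution, a record count from the configured range,
#' and compounds drawn from the target's own small set of clusters. Activity
#' values are sampled on the correct side of 1000 nM for the drawn label, so
#' labels and values are consistent except for injected conflicts.
#' Duplicates re-issue a row with a new year/source; conflicts add a record
#' on the opposite side of the threshold for a chosen pair (the affected
#' pairs are recorded in attribute `conflict_pairs`).
#'
#' @param config A [synth_config()].
#' @param compounds Result of [generate_compounds()].
#' @return data.table of activity records: `compound_id`, `target_id`,
#'   `family`, `source`, `activity_unit`, `value_nM`, `year`.
#' @export
generate_activity_table <- function(config, compounds) {
  stopifnot(inherits(config, "cdpn_synth_config"),
            inherits(compounds, "cdpn_synth_compounds"))
  props <- compounds$props
  units <- allowed_activity_units()
  sources <- c("chembl", "bindingdb", "pdbbind")
  with_seed(derive_seed(config$seed, "activity"), {
    per_target <- lapply(seq_len(config$n_targets), function(t) {
      tid <- sprintf("T%04d", t)
      fam <- CPI_FAMILIES[(t - 1) %% length(CPI_FAMILIES) + 1]
      prev <- rbeta(1, config$prevalence_shape[1], config$prevalence_shape[2])
      n_rec <- sample(seq(config$records_per_target_range[1],
                          config$records_per_target_range[2]), 1)
      cls <- sample.int(config$n_clusters,
                        min(config$clusters_per_target, config$n_clusters))
      cand <- props[cluster_true %in% cls, compound_id]
      n_rec <- min(n_rec, length(cand))
      cmp <- sample(cand, n_rec)
      pos <- runif(n_rec) < prev
      pch <- ifelse(pos, runif(n_rec, 6.05, 10), runif(n_rec, 3, 5.95))
      data.table::data.table(
        compound_id = cmp, target_id = tid, family = fam,
        source = sample(sources, n_rec, replace = TRUE),
        activity_unit = sample(units, n_rec, replace = TRUE),
        value_nM = 10^(9 - pch),
        year = sample(seq(config$year_range[1], config$year_range[2]),
                      n_rec, replace = TRUE))
    })
    dt <- data.table::rbindlist(per_target)
    # consistent duplicates: same pair and label side, new year/source
    n_dup <- round(config$duplicate_rate * nrow(dt))
    if (n_dup > 0) {
      dup <- dt[sample.int(nrow(dt), n_dup)]
      dup[, `:=`(year = sample(seq(config$year_range[1],
                                   config$year_range[2]),
                               .N, replace = TRUE),
                 source = sample(sources, .N, replace = TRUE))]
      dt <- rbind(dt, dup)
    }
    # conflicts: an extra record on the other side of the threshold
    n_con <- round(config$conflict_rate * nrow(dt))
    conflict_pairs <- data.table::data.table(compound_id = character(0),
                                             target_id = character(0))
    if (n_con > 0) {
      con <- dt[sample.int(nrow(dt), n_con)]
      con <- unique(con, by = c("compound_id", "target_id"))
      was_pos <- compute_pchembl(con$value_nM) >= 6
      con[, value_nM := 10^(9 - ifelse(was_pos, runif(.N, 3, 5.95),
                                       runif(.N, 6.05, 10)))]
      con[, source := "conflict-src"]
      conflict_pairs <- con[, .(compound_id, target_id)]
      dt <- rbind(dt, con)
    }
  })
  canonical_order(dt)
  data.table::setattr(dt, "conflict_pairs", conflict_pairs)
  dt[]
}

#' Generate the full synthetic bundle
#'
#' @param config A [synth_config()].
#' @return List with `config`, `compounds` and `records`.
#' @export
generate_synth_bundle <- function(config = synth_config()) {
  compounds <- generate_compounds(config)
  records <- generate_activity_table(config, compounds)
  list(config = config, compounds = compounds, records = records)
}
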
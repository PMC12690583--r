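# Cluster-aware down-sampling of analogue series. Two passes: records of
# multi-target compounds are capped per (target, cluster) first, then the
# remaining records per (target, cluster, label). Within each capped group,
# retained rows are a seeded uniform draw; the per-group random permutation
# is keyed on the group itself, so the result is independent of row order and
# raising the cap never drops a previously retained row.

#' Split interactions by compound target degree
#'
#' @param interactions Interaction table with `compound_id`, `target_id`.
#' @return List with `multi` (rows of compounds hitting >= 2 distinct
#'   targets) and `single` (the rest); their union is the input.
#' @export
split_multitarget <- function(interactions) {
  dt <- as_interaction_dt(interactions)
  deg <- dt[, .(n_targets = data.table::uniqueN(target_id)), by = compound_id]
  multi_ids <- deg[n_targets >= 2L, compound_id]
  list(multi = dt[compound_id %in% multi_ids],
       single = dt[!compound_id %in% multi_ids])
}

#' Cap group sizes by seeded uniform down-sampling
#'
#' Every group defined by `key_fields` retains at most `cap` rows; groups at
#' or under the cap are untouched. Selection within an over-full group is a
#' uniform draw without replacement, seeded per group (mixing `seed` with the
#' group key), hence deterministic, order-invariant, and monotone in `cap`.
#'
#' @param interactions Interaction table.
#' @param key_fields Character vector of grouping columns.
#' @param cap Maximum rows per group (>= 1).
#' @param seed Integer seed.
#' @return The retained rows, canonical order.
#' @export
downsample <- function(interactions, key_fields, cap, seed = 1) {
  stopifnot(cap >= 1)
  dt <- as_interaction_dt(interactions, required = key_fields)
  if (!nrow(dt)) return(dt)
  canonical_order(dt)
  picked <- dt[, {
    keep <- if (.N <= cap) rep(TRUE, .N) else {
      key <- paste(unlist(lapply(.BY, as.character)), collapse = "\r")
      perm <- with_seed(derive_seed(seed, "downsample", key), sample.int(.N))
      perm <= cap
    }
    .(I = .I[keep])
  }, by = key_fields]
  out <- dt[sort(picked$I)]
  canonical_order(out)
  out[]
}

#' Two-pass cluster-capped down-sampling
#'
#' Records of multi-target compounds are capped per (target, cluster); the
#' remaining records are capped per (target, cluster, label); the two subsets
#' are then re-joined. The first pass deliberately ignores the label (its key
#' is the target x cluster pair); set `multitarget_label_aware = TRUE` to
#' make both passes label-aware.
#'
#' @param interactions Interaction table with assigned `cluster_id`.
#' @param cap_multitarget Cap for the multi-target pass.
#' @param cap_rest Cap for the single-target pass.
#' @param seed Integer seed.
#' @param multitarget_label_aware Include `label` in the first pass key.
#' @return Down-sampled table (a subset of the input rows).
#' @export
run_downsampling <- function(interactions, cap_multitarget = 3, cap_rest = 3,
                             seed = 1, multitarget_label_aware = FALSE) {
  dt <- as_interaction_dt(interactions,
                          c("compound_id", "target_id", "cluster_id", "label"))
  if (any(is.na(dt$cluster_id)))
    stop("cluster_id must be assigned before down-sampling")
  key_multi <- c("target_id", "cluster_id",
                 if (multitarget_label_aware) "label")
  # Iterate the two-pass procedure to its fixed point. A single application
  # can demote a capped compound to single-target status, whose surviving
  # rows may then overflow a label-aware group; iterating (rows only ever
  # shrink, so this terminates) makes the operation a true projection:
  # re-applying it to its own output is the identity.
  out <- dt
  repeat {
    parts <- split_multitarget(out)
    nxt <- rbind(
      downsample(parts$multi, key_multi, cap_multitarget, seed),
      downsample(parts$single, c("target_id", "cluster_id", "label"),
                 cap_rest, seed))
    if (nrow(nxt) == nrow(out)) break
    out <- nxt
  }
  canonical_order(out)
  out[]
}
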
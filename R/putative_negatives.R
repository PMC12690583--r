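# Putative-negative (PN) augmentation. Measured bioactivity tables are
# heavily positive-skewed; this module adds unmeasured pairs assumed
# inactive, at two levels:
#   stage 1 - PN compounds for positively skewed targets, drawn from chemical
#     clusters with no recorded interaction with the target;
#   stage 2 - PN targets for compounds, drawn from protein families the
#     compound has no recorded interaction with.
# Quotas come from a rectified half sigmoid mapping of the observed
# imbalance: alpha(x) = max(x, (2 - 2m) / (1 + exp(-g (x - 1))) + m) and
# N_PN = round(alpha * N_P - N_N), clamped at zero. Entities already at
# negative prevalence >= 0.5 therefore stay unchanged.

#' Balancing parameters
#'
#' @param g Sigmoid steepness (> 0).
#' @param m Sigmoid floor, in (0, 1); `alpha(0) = (2 - 2m)/(1 + e^g) + m`.
#' @param skew_trigger Positive:negative ratio at or above which a target
#'   receives PN compounds (targets with no negatives always qualify).
#' @param max_per_cluster PN compounds drawn per eligible cluster.
#' @param eligibility `"two_tier"` prefers clusters that are positive-only
#'   dataset-wide before any other interaction-free cluster;
#'   `"interaction_free"` treats all interaction-free clusters alike.
#' @param compound_trigger Optional negative:positive ratio below which a
#'   compound receives PN targets; `NULL` applies the quota to every
#'   compound with at least one positive record and an untouched family.
#' @param seed Integer seed.
#' @return Validated parameter list of class `cdpn_balance_params`.
#' @export
balance_params <- function(g = 3, m = 0.4, skew_trigger = 2.0,
                           max_per_cluster = 3,
                           eligibility = c("two_tier", "interaction_free"),
                           compound_trigger = NULL, seed = 1) {
  stopifnot(g > 0, m > 0, m < 1, skew_trigger >= 1, max_per_cluster >= 1)
  structure(list(g = g, m = m, skew_trigger = skew_trigger,
                 max_per_cluster = max_per_cluster,
                 eligibility = match.arg(eligibility),
                 compound_trigger = compound_trigger, seed = seed),
            class = "cdpn_balance_params")
}

#' Rectified half sigmoid
#'
#' Maps an observed imbalance ratio `x` (target-level negative prevalence, or
#' compound-level negative:positive ratio) to a post-sampling negative ratio:
#' `alpha(x) = max(x, (2 - 2m)/(1 + exp(-g (x - 1))) + m)`. The function is
#' continuous, non-decreasing, fixes `alpha(1) = 1`, and equals `x` wherever
#' the data are already balanced enough (`x` at or above the sigmoid branch),
#' so balanced entities are left unchanged.
#'
#' @param x Non-negative finite numeric vector.
#' @param g Steepness (default 3).
#' @param m Floor (default 0.4).
#' @return `alpha`, the larger of `x` and the sigmoid branch.
#' @export
rectified_half_sigmoid <- function(x, g = 3, m = 0.4) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("x must be finite and non-negative")
  pmax(x, (2 - 2 * m) / (1 + exp(-g * (x - 1))) + m)
}

#' Putative-negative quota
#'
#' `max(0, round(alpha * N_P - N_N))` with round-half-up; the clamp at zero
#' means entities whose negatives already meet the post-sampling ratio get
#' no PNs.
#'
#' @param alpha Output of [rectified_half_sigmoid()].
#' @param n_pos,n_neg Non-negative counts of positive / negative records.
#' @return Integer quota vector.
#' @export
pn_quota <- function(alpha, n_pos, n_neg) {
  stopifnot(all(n_pos >= 0), all(n_neg >= 0))
  as.integer(pmax(0, floor(alpha * n_pos - n_neg + 0.5)))
}

#' Per-target label profiles
#'
#' For each target: positive/negative counts, negative prevalence
#' `x = N_N / (N_P + N_N)`, the sigmoid output `alpha`, the PN quota, and
#' whether the skew trigger fires (`N_P / N_N >= skew_trigger`, or no
#' negatives at all while positives exist).
#'
#' @param interactions Labeled interaction table.
#' @param params A [balance_params()] object.
#' @return data.table keyed by `target_id`.
#' @export
target_label_profiles <- function(interactions, params = balance_params()) {
  dt <- as_interaction_dt(interactions,
                          c("compound_id", "target_id", "label"))
  prof <- dt[, .(n_pos = sum(label == "positive"),
                 n_neg = sum(label == "negative")), by = target_id]
  prof[, x := ifelse(n_pos + n_neg > 0, n_neg / (n_pos + n_neg), NA_real_)]
  prof[, alpha := rectified_half_sigmoid(x, params$g, params$m)]
  prof[, quota := pn_quota(alpha, n_pos, n_neg)]
  prof[, triggered := n_pos > 0 &
         (n_neg == 0 | n_pos / pmax(n_neg, 1) >= params$skew_trigger)]
  data.table::setorder(prof, target_id)
  prof[]
}

#' Per-compound label profiles
#'
#' Compound-level imbalance is the negative:positive ratio `x = N_N / N_P`;
#' compounds with no positive record are excluded (putative positives are
#' never generated, so there is nothing to balance against).
#'
#' @inheritParams target_label_profiles
#' @return data.table keyed by `compound_id`, including the number of
#'   distinct protein families the compound has measured records in.
#' @export
compound_label_profiles <- function(interactions, params = balance_params()) {
  dt <- as_interaction_dt(interactions,
                          c("compound_id", "target_id", "label", "family"))
  prof <- dt[, .(n_pos = sum(label == "positive"),
                 n_neg = sum(label == "negative"),
                 n_families = data.table::uniqueN(family)),
             by = compound_id][n_pos > 0]
  prof[, x := n_neg / n_pos]
  prof[, alpha := rectified_half_sigmoid(x, params$g, params$m)]
  prof[, quota := pn_quota(alpha, n_pos, n_neg)]
  data.table::setorder(prof, compound_id)
  prof[]
}

#' Clusters eligible to supply PN compounds for a target
#'
#' A cluster is eligible when it has zero recorded interactions with the
#' target. Under `"two_tier"` eligibility, clusters that are positive-only
#' dataset-wide (every recorded interaction of the cluster, against any
#' target, is positive) form the preferred first tier; all other
#' interaction-free clusters (including clusters with no records at all)
#' form the second.
#'
#' @param target_id Target to balance.
#' @param interactions Measured interaction table with `cluster_id`.
#' @param all_clusters Integer vector of every cluster id in the pool.
#' @param mode `"two_tier"` or `"interaction_free"`.
#' @return List with integer vectors `tier1` and `tier2`;
#'   `c(tier1, tier2)` is the full eligible set.
#' @export
eligible_clusters <- function(target_id, interactions, all_clusters,
                              mode = c("two_tier", "interaction_free")) {
  mode <- match.arg(mode)
  tid <- target_id
  dt <- as_interaction_dt(interactions,
                          c("target_id", "label", "cluster_id"))
  touched <- unique(dt[target_id == tid, cluster_id])
  free <- sort(setdiff(all_clusters, touched))
  if (mode == "interaction_free" || !nrow(dt))
    return(list(tier1 = integer(0), tier2 = free))
  by_cluster <- dt[, .(all_pos = all(label == "positive"), n = .N),
                   by = cluster_id]
  pos_only <- by_cluster[all_pos == TRUE & n > 0, cluster_id]
  list(tier1 = intersect(free, sort(pos_only)),
       tier2 = setdiff(free, pos_only))
}

#' Sample PN compounds for one target
#'
#' Visits eligible clusters in seeded random order (first tier before second)
#' taking at most `max_per_cluster` compounds per cluster until the quota is
#' met or the pool is exhausted. Compounds already paired with the target are
#' never drawn; a shortfall raises a warning, not an error.
#'
#' @param target_id Target receiving PNs.
#' @param quota Number of PN rows wanted (>= 0).
#' @param eligibility Result of [eligible_clusters()].
#' @param pool Data frame of candidate compounds: `compound_id`,
#'   `cluster_id`.
#' @param interactions Measured table (used to exclude existing pairs).
#' @param max_per_cluster Per-cluster cap.
#' @param seed Integer seed.
#' @param family Family of the target, copied onto the PN rows.
#' @return data.table of PN interaction rows (`label = "negative"`,
#'   `provenance = "putative"`, `year = NA`).
#' @export
sample_pn_compounds <- function(target_id, quota, eligibility, pool,
                                interactions = NULL, max_per_cluster = 3,
                                seed = 1, family = NA_character_) {
  stopifnot(quota >= 0)
  tid <- target_id
  pool <- as_interaction_dt(pool, c("compound_id", "cluster_id"))
  exclude <- if (!is.null(interactions))
    as_interaction_dt(interactions)[target_id == tid,
                                    compound_id] else character(0)
  picked_id <- character(0); picked_cl <- integer(0)
  if (quota > 0) {
    s <- derive_seed(seed, "pn_compounds", target_id)
    with_seed(s, {
      tiers <- list(eligibility$tier1, eligibility$tier2)
      for (tier in tiers) {
        if (length(picked_id) >= quota) break
        for (cl in (if (length(tier) > 1) sample(tier) else tier)) {
          if (length(picked_id) >= quota) break
          cand <- setdiff(pool[cluster_id == cl, compound_id],
                          c(exclude, picked_id))
          if (!length(cand)) next
          take <- min(max_per_cluster, length(cand),
                      quota - length(picked_id))
          sel <- if (length(cand) > 1) sample(cand, take) else cand[seq_len(take)]
          picked_id <- c(picked_id, sel)
          picked_cl <- c(picked_cl, rep(cl, length(sel)))
        }
      }
    })
    if (length(picked_id) < quota)
      warning(sprintf("target %s: PN quota %d unmet, shortfall %d",
                      target_id, quota, quota - length(picked_id)))
  }
  data.table::data.table(
    compound_id = picked_id, target_id = rep(target_id, length(picked_id)),
    label = rep("negative", length(picked_id)),
    provenance = rep("putative", length(picked_id)),
    year = rep(NA_integer_, length(picked_id)),
    family = rep(family, length(picked_id)), cluster_id = picked_cl)
}

#' Sample PN targets for one compound
#'
#' Draws targets uniformly from protein families the compound has no
#' measured record in; requires at least one positive record and fewer than
#' six touched families (a compound spanning all families gets nothing).
#' The quota applies [rectified_half_sigmoid()] to the compound-level
#' negative:positive ratio and [pn_quota()] to the compound counts.
#'
#' @param compound_id Compound receiving PN targets.
#' @param interactions Interaction table supplying the compound's counts
#'   (may include stage-1 putative rows).
#' @param target_families Data frame mapping `target_id` to `family`.
#' @param params A [balance_params()] object.
#' @param measured Optional measured-only table used for family
#'   eligibility; defaults to the measured rows of `interactions`.
#' @param cluster_id Cluster of the compound, copied onto PN rows.
#' @return data.table of PN interaction rows.
#' @export
sample_pn_targets <- function(compound_id, interactions, target_families,
                              params = balance_params(),
                              measured = NULL, cluster_id = NA_integer_) {
  cid <- compound_id
  dt <- as_interaction_dt(interactions,
                          c("compound_id", "target_id", "label"))
  rows <- dt[compound_id == cid]
  n_pos <- sum(rows$label == "positive")
  n_neg <- sum(rows$label == "negative")
  if (n_pos < 1) stop("compound has no positive record; nothing to balance")
  meas <- if (is.null(measured)) {
    if ("provenance" %in% names(dt)) dt[provenance == "measured"] else dt
  } else as_interaction_dt(measured)
  fam_map <- as_interaction_dt(target_families, c("target_id", "family"))
  touched <- unique(
    fam_map[meas[compound_id == cid],
            on = "target_id", nomatch = NULL]$family)
  open_fams <- setdiff(CPI_FAMILIES, touched)
  quota <- pn_quota(rectified_half_sigmoid(n_neg / n_pos, params$g, params$m),
                    n_pos, n_neg)
  empty <- data.table::data.table(
    compound_id = character(0), target_id = character(0),
    label = character(0), provenance = character(0), year = integer(0),
    family = character(0), cluster_id = integer(0))
  if (!length(open_fams) || quota == 0) return(empty)
  cand <- fam_map[family %in% open_fams]
  cand <- cand[!target_id %in% rows$target_id]
  # never route PNs to negative-dominant targets: entities at negative
  # prevalence >= 0.5 must remain unchanged at both levels
  negdom <- dt[, .(np = sum(label == "positive"),
                   nn = sum(label == "negative")), by = target_id][
                     nn >= np, target_id]
  cand <- cand[!target_id %in% negdom]
  data.table::setorder(cand, target_id)
  if (!nrow(cand)) return(empty)
  take <- min(quota, nrow(cand))
  sel <- with_seed(derive_seed(params$seed, "pn_targets", compound_id),
                   cand[sample.int(nrow(cand), take)])
  data.table::data.table(
    compound_id = rep(compound_id, nrow(sel)), target_id = sel$target_id,
    label = rep("negative", nrow(sel)),
    provenance = rep("putative", nrow(sel)),
    year = rep(NA_integer_, nrow(sel)), family = sel$family,
    cluster_id = rep(as.integer(cluster_id), nrow(sel)))
}

#' Balance a dataset with putative negatives
#'
#' Stage 1 adds PN compounds to every target whose positive:negative ratio
#' reaches `skew_trigger` (or that has positives but no negatives), up to its
#' sigmoid quota. Stage 2 recomputes compound-level counts on the augmented
#' table and adds PN targets from untouched families. Measured rows pass
#' through untouched; every added row carries `provenance = "putative"`,
#' `label = "negative"` and a sentinel `NA` year so augmented rows can never
#' masquerade as dated measurements.
#'
#' @param interactions Curated, clustered (optionally down-sampled)
#'   interaction table.
#' @param pool Candidate PN compounds: `compound_id`, `cluster_id` (pass the
#'   drug-like subset of the compound library).
#' @param params A [balance_params()] object.
#' @return The augmented table: input rows plus putative rows.
#' @export
balance_dataset <- function(interactions, pool, params = balance_params()) {
  dt <- as_interaction_dt(interactions,
                          c("compound_id", "target_id", "label",
                            "family", "cluster_id"))
  if (!"provenance" %in% names(dt)) dt[, provenance := "measured"]
  if (!"year" %in% names(dt)) dt[, year := NA_integer_]
  pool <- as_interaction_dt(pool, c("compound_id", "cluster_id"))
  all_clusters <- sort(unique(pool$cluster_id))
  measured <- dt[provenance == "measured"]

  prof <- target_label_profiles(dt, params)
  todo <- prof[triggered & quota > 0]
  fam_of_target <- dt[, .(family = family[1]), by = target_id]
  stage1 <- lapply(todo$target_id, function(tid) {
    elig <- eligible_clusters(tid, measured, all_clusters,
                              mode = params$eligibility)
    sample_pn_compounds(
      tid, todo[target_id == tid, quota], elig, pool,
      interactions = dt, max_per_cluster = params$max_per_cluster,
      seed = params$seed,
      family = fam_of_target[target_id == tid, family])
  })
  aug1 <- data.table::rbindlist(c(list(dt[, names(dt), with = FALSE]),
                                  stage1), fill = TRUE)

  cprof <- compound_label_profiles(aug1, params)
  cprof <- cprof[n_families < length(CPI_FAMILIES)]
  if (!is.null(params$compound_trigger))
    cprof <- cprof[x <= params$compound_trigger]
  cprof <- cprof[quota > 0]
  cluster_of <- dt[, .(cluster_id = cluster_id[1]), by = compound_id]
  fam_map <- fam_of_target
  stage2 <- lapply(cprof$compound_id, function(cid) {
    cl <- cluster_of[compound_id == cid, cluster_id]
    sample_pn_targets(cid, aug1, fam_map, params, measured = measured,
                      cluster_id = if (length(cl)) cl else NA_integer_)
  })
  out <- data.table::rbindlist(c(list(aug1), stage2), fill = TRUE)
  canonical_order(out)
  out[]
}

#' Before/after balance report
#'
#' Per-target positive prevalence before and after augmentation, plus the
#' count of targets above a prevalence threshold in each table.
#'
#' @param before,after Interaction tables.
#' @param threshold Prevalence threshold of interest.
#' @return List with `per_target` (data.table) and summary counts.
#' @export
balance_report <- function(before, after, threshold = 0.8) {
  pb <- positive_prevalence(before, by = "target")
  pa <- positive_prevalence(after, by = "target")
  merged <- merge(pb[, .(target_id = id, prevalence_before = prevalence)],
                  pa[, .(target_id = id, prevalence_after = prevalence)],
                  by = "target_id", all = TRUE)
  list(per_target = merged,
       n_high_before = sum(pb$prevalence > threshold),
       n_high_after = sum(pa$prevalence > threshold),
       threshold = threshold)
}
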
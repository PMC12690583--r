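# Bias diagnostics and virtual-screening metrics: positive prevalence,
# BEDROC, enrichment factors, top-decile score summaries, and
# attention-vs-pocket coverage / IoU.

#' Positive prevalence by target or cluster
#'
#' The fraction of positive rows among all rows for each target (or each
#' compound cluster). Values near 1 flag label-distribution bias.
#'
#' @param interactions Labeled interaction table.
#' @param by `"target"` or `"cluster"`.
#' @return data.table with `id`, `n_pos`, `n`, `prevalence`.
#' @export
positive_prevalence <- function(interactions, by = c("target", "cluster")) {
  by <- match.arg(by)
  col <- if (by == "target") "target_id" else "cluster_id"
  dt <- as_interaction_dt(interactions, c(col, "label"))
  out <- dt[, .(n_pos = sum(label == "positive"), n = .N),
            by = c(col)]
  data.table::setnames(out, col, "id")
  out[, prevalence := n_pos / n]
  data.table::setorder(out, id)
  out[]
}

# Descending ranks with seeded random tie-breaking: deterministic under the
# seed, unbiased across tied scores.
ranked_order <- function(scores, seed) {
  tie <- with_seed(derive_seed(seed, "rank_ties"),
                   sample.int(length(scores)))
  order(-scores, tie)
}

check_screen <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  if (sum(labels) == 0 || sum(labels) == length(labels))
    stop("degenerate label vector: need at least one active and one inactive")
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of ROC. Ranks items by decreasing score
#' (ties broken by a seeded shuffle), computes the exponentially weighted sum
#' `S = sum_i exp(-alpha r_i / N)` over active ranks, and min-max normalizes
#' it between the worst possible ranking (0) and the perfect ranking (1).
#' Large `alpha` concentrates the weight on the very top of the list; the
#' screening default is `alpha = 80.5` (80% of the weight in the top ~2%).
#'
#' @param scores Numeric score vector (higher = more likely active).
#' @param labels Binary vector, 1 = active.
#' @param alpha Exponential weight parameter.
#' @param seed Seed for tie-breaking.
#' @return BEDROC in `[0, 1]`.
#' @export
bedroc <- function(scores, labels, alpha = 80.5, seed = 1) {
  check_screen(scores, labels)
  N <- length(scores)
  ranks <- which(labels[ranked_order(scores, seed)] == 1)
  n <- length(ranks)
  s <- sum(exp(-alpha * ranks / N))
  s_max <- sum(exp(-alpha * seq_len(n) / N))
  s_min <- sum(exp(-alpha * seq.int(N - n + 1, N) / N))
  (s - s_min) / (s_max - s_min)
}

#' Enrichment factor at a fraction of the ranked list
#'
#' Actives found in the top `ceiling(fraction * N)` picks, relative to the
#' number expected under the global active rate. 1 means no enrichment; the
#' maximum is `1 / active_rate`.
#'
#' @inheritParams bedroc
#' @param fraction Fraction of the list screened (default 0.01, i.e. EF1%).
#' @return Non-negative enrichment factor.
#' @export
enrichment_factor <- function(scores, labels, fraction = 0.01, seed = 1) {
  check_screen(scores, labels)
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  N <- length(scores)
  top_n <- ceiling(fraction * N)
  hits <- sum(labels[ranked_order(scores, seed)][seq_len(top_n)])
  (hits / top_n) / (sum(labels) / N)
}

#' Top-decile score summary per entity
#'
#' For each entity (target or compound), summarizes the highest `decile`
#' fraction of its scores with median and quartiles. Inflated top-decile
#' scores across entities with near-1 positive prevalence are the signature
#' of label-distribution bias in a trained screen. Entities with fewer than
#' `min_items` scores are skipped with a warning.
#'
#' @param scores Data frame with columns `entity_id` and `score`.
#' @param decile Fraction of top scores to summarize.
#' @param min_items Minimum scores an entity needs.
#' @return data.table with `entity_id`, `n_top`, `q1`, `median`, `q3`.
#' @export
top_decile_scores <- function(scores, decile = 0.10, min_items = 10) {
  dt <- as_interaction_dt(scores, c("entity_id", "score"))
  sizes <- dt[, .N, by = entity_id]
  small <- sizes[N < min_items, entity_id]
  if (length(small))
    warning("skipping entity(ies) with fewer than ", min_items, " scores: ",
            paste(small, collapse = ", "))
  dt <- dt[!entity_id %in% small]
  out <- dt[, {
    top <- sort(score, decreasing = TRUE)[seq_len(ceiling(decile * .N))]
    .(n_top = length(top),
      q1 = as.numeric(quantile(top, 0.25)),
      median = as.numeric(median(top)),
      q3 = as.numeric(quantile(top, 0.75)))
  }, by = entity_id]
  data.table::setorder(out, entity_id)
  out[]
}

#' Attention-vs-pocket coverage and IoU
#'
#' Binarizes per-residue attention weights into a selected set (default:
#' top-k with k equal to the pocket size; alternatively every residue above
#' a weight quantile) and compares it to an annotated binding-pocket mask:
#' coverage is the fraction of pocket residues selected (recall), IoU the
#' intersection over union. Coverage always bounds IoU from above.
#'
#' @param weights Non-negative attention weight vector over residues.
#' @param pocket_mask Binary vector (1 = pocket residue), same length.
#' @param rule `"topk"` or `"quantile"`.
#' @param k Number of residues to select under `"topk"`; defaults to the
#'   pocket size.
#' @param quantile_level Weight quantile under `"quantile"` (default 0.9).
#' @return List with `coverage` and `iou`, both in `[0, 1]`.
#' @export
attention_pocket_eval <- function(weights, pocket_mask,
                                  rule = c("topk", "quantile"), k = NULL,
                                  quantile_level = 0.9) {
  rule <- match.arg(rule)
  if (length(weights) != length(pocket_mask))
    stop("weights and pocket_mask must have equal length")
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be finite and non-negative")
  if (all(weights == 0)) stop("all-zero attention weights")
  if (!any(pocket_mask == 1)) stop("pocket mask has no residues")
  pocket <- which(pocket_mask == 1)
  selected <- if (rule == "topk") {
    kk <- k %||% length(pocket)
    order(-weights, seq_along(weights))[seq_len(kk)]  # ties by residue index
  } else {
    which(weights >= quantile(weights, quantile_level))
  }
  inter <- length(intersect(selected, pocket))
  list(coverage = inter / length(pocket),
       iou = inter / length(union(selected, pocket)))
}
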
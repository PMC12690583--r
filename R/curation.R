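# Curation: clean raw activity tables into deduplicated, conflict-free,
# binary-labeled compound-protein interactions.
#
# A raw table has one row per assay record: compound_id, target_id, family,
# activity_unit, value_nM (nanomolar), year, source, and optionally
# confidence / assay_type. Curation applies, in order: unit whitelist,
# drug-likeness filter (if compound properties are supplied), pChEMBL
# labeling at 1000 nM, frequent-hitter removal, and conflict resolution.

#' Activity units comparable on the pChEMBL scale
#'
#' Half-maximal response / potency / affinity units whose nanomolar values can
#' be placed on a common negative-log scale.
#'
#' @return Character vector of unit names.
#' @export
allowed_activity_units <- function() {
  c("Potency", "Ki", "Kd", "IC50", "AC50", "EC50", "ED50", "XC50")
}

#' Convert a nanomolar activity value to pChEMBL
#'
#' pChEMBL is the negative base-10 logarithm of the molar activity value, so
#' 1000 nM corresponds to pChEMBL 6.
#'
#' @param value_nM Positive numeric vector of activities in nanomolar.
#' @return Numeric vector of pChEMBL values.
#' @export
#' @examples
#' compute_pchembl(1000) # 6
compute_pchembl <- function(value_nM) {
  if (!is.numeric(value_nM) || any(!is.finite(value_nM)) || any(value_nM <= 0))
    stop("value_nM must be finite and strictly positive")
  9 - log10(value_nM)
}

#' Binarize pChEMBL values into activity labels
#'
#' @param pchembl Numeric vector of pChEMBL values.
#' @param threshold Label boundary; values at or above it are positive.
#'   The boundary itself is inclusive (pChEMBL 6, i.e. exactly 1000 nM, is
#'   labeled positive); pass a slightly larger threshold to flip that.
#' @return Character vector, `"positive"` or `"negative"`.
#' @export
label_activity <- function(pchembl, threshold = 6.0) {
  if (!is.numeric(pchembl) || any(!is.finite(pchembl)))
    stop("pchembl must be finite numeric")
  ifelse(pchembl >= threshold, "positive", "negative")
}

#' Filter activity records on unit, confidence and assay type
#'
#' Records with units outside the whitelist are dropped. Confidence and
#' assay-type constraints apply only when the corresponding column exists;
#' records with missing (`NA`) metadata pass those checks.
#'
#' @param records Data frame of activity records with at least
#'   `activity_unit`.
#' @param allowed_units Character vector of admissible units.
#' @param min_confidence Minimum confidence score, or `NULL` to skip.
#' @param allowed_assay_types Admissible assay types, or `NULL` to skip.
#' @return Filtered records (same columns).
#' @export
filter_records <- function(records,
                           allowed_units = allowed_activity_units(),
                           min_confidence = NULL,
                           allowed_assay_types = NULL) {
  dt <- as_interaction_dt(records, required = character())
  keep <- rep(TRUE, nrow(dt))
  if ("activity_unit" %in% names(dt))
    keep <- keep & (dt$activity_unit %in% allowed_units)
  if (!is.null(min_confidence) && "confidence" %in% names(dt))
    keep <- keep & (is.na(dt$confidence) | dt$confidence >= min_confidence)
  if (!is.null(allowed_assay_types) && "assay_type" %in% names(dt))
    keep <- keep & (is.na(dt$assay_type) |
                      dt$assay_type %in% allowed_assay_types)
  dt[keep]
}

#' Drug-likeness filter
#'
#' Keeps compounds without metal atoms, with molecular weight strictly below
#' `max_mw` daltons and strictly more than `min_heavy` heavy atoms. The
#' inequalities are strict on both property bounds.
#'
#' @param props Data frame of compound properties with columns `mol_weight`,
#'   `heavy_atoms`, `contains_metal`.
#' @param max_mw Molecular weight ceiling in Da.
#' @param min_heavy Heavy-atom floor (exclusive).
#' @return Logical vector, `TRUE` for compounds passing the filter.
#' @export
filter_druglike <- function(props, max_mw = 1000, min_heavy = 12) {
  need <- c("mol_weight", "heavy_atoms", "contains_metal")
  miss <- setdiff(need, names(props))
  if (length(miss))
    stop("missing property column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(props$mol_weight)) || any(is.na(props$heavy_atoms)) ||
      any(is.na(props$contains_metal)))
    stop("missing property values; drug-likeness requires complete fields")
  !props$contains_metal & props$mol_weight < max_mw &
    props$heavy_atoms > min_heavy
}

#' Remove frequent-hitter compounds
#'
#' Blocklisted compounds (known aggregators, luciferase inhibitors, ...) with
#' at least one positive record are removed: either all their records
#' (`scope = "compound"`, the default, which also discards their suspect
#' negatives) or only their positive records (`scope = "positives_only"`).
#' Blocklisted compounds with no positive record are untouched.
#'
#' @param records Data frame with `compound_id` and either a `label` column or
#'   `value_nM` (labels are then derived at pChEMBL 6).
#' @param blocklist Character vector of compound ids.
#' @param scope `"compound"` or `"positives_only"`.
#' @return Filtered records.
#' @export
remove_frequent_hitters <- function(records, blocklist,
                                    scope = c("compound", "positives_only")) {
  scope <- match.arg(scope)
  dt <- as_interaction_dt(records, required = "compound_id")
  if (!length(blocklist) || !nrow(dt)) return(dt)
  lab <- if ("label" %in% names(dt)) dt$label
         else label_activity(compute_pchembl(dt$value_nM))
  hit <- dt$compound_id %in% blocklist
  pos_hitters <- unique(dt$compound_id[hit & lab == "positive"])
  drop <- if (scope == "compound") dt$compound_id %in% pos_hitters
          else dt$compound_id %in% pos_hitters & lab == "positive"
  dt[!drop]
}

#' Resolve duplicate and conflicting labels per pair
#'
#' Collapses records to one row per (compound, target) pair. Pairs observed
#' with both labels across records are removed entirely; duplicates with a
#' consistent label collapse to a single row retaining the earliest year
#' (a stable choice for downstream time splitting).
#'
#' @param records Labeled records with `compound_id`, `target_id`, `label`,
#'   and optionally `year`, `family`.
#' @return One row per surviving pair, canonical order.
#' @export
resolve_conflicts <- function(records) {
  dt <- as_interaction_dt(records, c("compound_id", "target_id", "label"))
  if (!nrow(dt)) return(dt)
  if (!"year" %in% names(dt)) dt[, year := NA_integer_]
  canonical_order(dt)
  nlab <- dt[, .(n_labels = data.table::uniqueN(label)),
             by = .(compound_id, target_id)]
  dt <- dt[nlab[n_labels == 1L, .(compound_id, target_id)],
           on = c("compound_id", "target_id")]
  out <- dt[, .SD[which.min(ifelse(is.na(year), .Machine$integer.max, year))],
            by = .(compound_id, target_id)]
  canonical_order(out)
  out[]
}

#' Run the full curation chain
#'
#' Applies, in order: unit/metadata filters, drug-likeness filter (when
#' `props` is given), pChEMBL labeling, frequent-hitter removal, and conflict
#' resolution. Already-labeled input (a `label` column present, no `value_nM`
#' needed) skips the labeling step, which makes the chain idempotent.
#'
#' @param records Raw activity records (see [filter_records()]).
#' @param props Optional compound property table (see [filter_druglike()]).
#' @param blocklist Optional character vector of frequent-hitter ids.
#' @param threshold pChEMBL labeling threshold.
#' @param allowed_units,min_confidence,allowed_assay_types Passed to
#'   [filter_records()].
#' @param hitter_scope Passed to [remove_frequent_hitters()].
#' @return Curated interactions: one row per pair with columns
#'   `compound_id`, `target_id`, `label`, `provenance` (= `"measured"`),
#'   `year`, `family`, `cluster_id` (`NA` until assigned).
#' @export
curate_records <- function(records, props = NULL, blocklist = character(),
                           threshold = 6.0,
                           allowed_units = allowed_activity_units(),
                           min_confidence = NULL, allowed_assay_types = NULL,
                           hitter_scope = "compound") {
  dt <- filter_records(records, allowed_units, min_confidence,
                       allowed_assay_types)
  if (!is.null(props)) {
    ok_ids <- props$compound_id[filter_druglike(props)]
    dt <- dt[compound_id %in% ok_ids]
  }
  if (!"label" %in% names(dt)) {
    if (!nrow(dt)) dt[, label := character()]
    else dt[, label := label_activity(compute_pchembl(value_nM), threshold)]
  }
  dt <- remove_frequent_hitters(dt, blocklist, hitter_scope)
  dt <- resolve_conflicts(dt)
  keep <- intersect(c("compound_id", "target_id", "label", "year", "family"),
                    names(dt))
  out <- dt[, ..keep]
  if (!"family" %in% names(out)) out[, family := NA_character_]
  out[, provenance := "measured"]
  if (!"cluster_id" %in% names(out)) out[, cluster_id := NA_integer_]
  data.table::setcolorder(out, c("compound_id", "target_id", "label",
                                 "provenance", "year", "family", "cluster_id"))
  canonical_order(out)
  out[]
}
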
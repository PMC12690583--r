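# Internal helpers shared across modules: seeded RNG scoping, seed derivation,
# canonical row ordering, and input validation.

#' @import data.table
#' @importFrom stats prcomp rbeta rbinom rnorm rpois runif median quantile setNames
#' @importFrom utils head
NULL

# The six-family vocabulary is closed: every target belongs to exactly one.
CPI_FAMILIES <- c("Kinase", "Nonkinase Enzyme", "Nuclear Receptor",
                  "Membrane Receptor", "Ion Channel", "Others")

#' Protein family vocabulary
#'
#' The closed six-family vocabulary used to group protein targets.
#'
#' @return Character vector of the six family names.
#' @export
cpi_families <- function() CPI_FAMILIES

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage- or group-specific seed from a global seed
#'
#' Mixes an integer seed with one or more strings (stage names, group keys)
#' into a new seed in `[0, 2^31 - 2]`. Adding a stage never perturbs the
#' stream of any other stage because each stream is keyed by its own label.
#'
#' @param seed Integer global seed.
#' @param ... Character scalars mixed into the seed (e.g. a stage name).
#' @return A single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  h <- abs(as.numeric(seed)) %% m
  for (s in c(...)) {
    for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% m
    h <- (h * 37 + 17) %% m
  }
  as.integer(h)
}

# Canonical ordering makes every seeded operation independent of input row
# order: tables are sorted on their identifying columns before any sampling.
canonical_order <- function(dt) {
  cols <- intersect(c("compound_id", "target_id", "label", "year",
                      "source", "value_nM"), names(dt))
  if (length(cols)) data.table::setorderv(dt, cols, na.last = TRUE)
  dt
}

as_interaction_dt <- function(x, required = c("compound_id", "target_id")) {
  if (!is.data.frame(x)) stop("expected a data.frame of interactions")
  dt <- data.table::as.data.table(x)
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table NSE column names
utils::globalVariables(c(
  ".", "..keep", "compound_id", "target_id", "label", "provenance", "year",
  "family", "cluster_id", "cluster_true", "complexity_bits", "value_nM",
  "activity_unit", "contains_metal", "mol_weight", "heavy_atoms", "source",
  "n_labels", "n_pos", "n_neg", "n", "x", "alpha", "quota", "triggered",
  "n_families", "all_pos", "pos_only", "prevalence", "id", "entity_id",
  "score", "N", "n_targets", "V1", "I"))
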
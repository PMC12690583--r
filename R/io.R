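# Delimited-text I/O. Column dictionary for activity tables:
#   compound_id, target_id, family, activity_unit, value_nM, year, source
# with optional smiles, confidence, assay_type. Values must arrive in
# nanomolar; conversion from other molar units is explicit via
# `unit_scale`, never silent.

#' Read a raw activity table
#'
#' @param path CSV/TSV file with the documented columns.
#' @param unit_scale Optional named vector of multiplicative factors applied
#'   to `value_nM` per `activity_unit` entry (e.g. `c(uM = 1000)` if a source
#'   recorded micromolar values); units not named are assumed nanomolar.
#' @return data.table of activity records.
#' @export
read_activity_table <- function(path, unit_scale = NULL) {
  dt <- data.table::fread(path)
  need <- c("compound_id", "target_id", "activity_unit", "value_nM", "year")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("activity table missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(unit_scale)) {
    f <- unit_scale[dt$activity_unit]
    f[is.na(f)] <- 1
    dt[, value_nM := value_nM * f]
  }
  dt[]
}

#' Write curated interactions
#'
#' @param interactions Interaction table.
#' @param path Output CSV/TSV path (delimiter by extension).
#' @export
write_interactions <- function(interactions, path) {
  data.table::fwrite(as_interaction_dt(interactions), path)
  invisible(path)
}

#' Read a frequent-hitter blocklist
#'
#' One compound id per line; blank lines and `#` comments ignored.
#'
#' @param path Text file path.
#' @return Character vector of compound ids.
#' @export
read_blocklist <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
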
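# Canonical cohort CSV: one row per woman, missing values encoded as empty
# fields (not "NA") so the file parses unambiguously as numeric.

canonical_columns <- function(item_count = 10L) {
  c("id", "age", "ethnicity", "income", "education", "employment",
    "interpreter", "mode", "dx_depression", "dx_anxiety", "dx_any",
    "screen_q1", "screen_q2", "help_q", paste0("item_", seq_len(item_count)),
    "consented", "stratum", "module_observed_depression", "module_observed_any")
}

sampling_columns <- c("invited", "interviewed", "design_weight")

#' Write a cohort to the canonical CSV
#'
#' Writes the canonical per-woman columns (plus the sampling columns
#' `invited`, `interviewed`, `design_weight` when present). Missing values are
#' written as empty fields.
#'
#' @param records cohort data frame.
#' @param path output file.
#' @param item_count number of item columns.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path, item_count = 10L) {
  cols <- canonical_columns(item_count)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0)
    stop("records lack canonical columns: ", paste(missing_cols, collapse = ", "))
  cols <- c(cols, intersect(sampling_columns, names(records)))
  out <- records[cols]
  for (nm in names(out)) if (is.logical(out[[nm]])) out[[nm]] <- as.integer(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a canonical cohort CSV
#'
#' Checks the schema and the structural invariants of a screening record:
#' stratum must equal "positive" exactly when either screen question was
#' endorsed, the help question must be absent for screen-negatives, and item
#' scores must lie in 0--3. Unknown columns are kept but ignored downstream.
#'
#' @param path CSV file written by [write_cohort_csv()].
#' @param item_count number of item columns expected.
#' @return a `screening_cohort` data frame with `total_score` recomputed.
#' @export
load_cohort_csv <- function(path, item_count = 10L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  cols <- canonical_columns(item_count)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0)
    stop("cohort CSV schema violation: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("cohort CSV schema violation: no data rows")
  for (nm in c("consented", "module_observed_depression", "module_observed_any",
               intersect(c("invited", "interviewed"), names(df))))
    df[[nm]] <- as.logical(df[[nm]])

  pos <- df$screen_q1 == 1 | df$screen_q2 == 1
  bad <- which((df$stratum == "positive") != pos)
  if (length(bad) > 0)
    stop("cohort CSV schema violation: stratum inconsistent with screen answers at row ",
         bad[1])
  bad <- which(!pos & !is.na(df$help_q))
  if (length(bad) > 0)
    stop("cohort CSV schema violation: help_q populated for screen-negative row ",
         bad[1])
  items <- as.matrix(df[paste0("item_", seq_len(item_count))])
  bad_item <- which(!is.na(items) & (items < 0 | items > 3), arr.ind = TRUE)
  if (nrow(bad_item) > 0)
    stop("cohort CSV schema violation: item score out of range 0-3 in column item_",
         bad_item[1, 2], " row ", bad_item[1, 1])
  df <- with_total_score(df, item_count)
  class(df) <- c("screening_cohort", "data.frame")
  df
}
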
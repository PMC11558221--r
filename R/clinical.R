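# Clinical table input: diagnoses, medication and rating-scale items.

#' Read a clinical table
#'
#' Expects a CSV with columns `subject_id`, `group` (HC/MD), `diagnosis`
#' (HC/unipolar/bipolar), `medication` (yes/no) and the item scores
#' `hamd_1..hamd_17` and `ymrs_1..ymrs_11`. Scale totals are computed as the
#' item sums, never read from the file. Item scores must be nonnegative
#' integers within their scale range (HAM-D items 0-4, YMRS items 0-8).
#'
#' @param path file path.
#' @return a validated data.frame with added `hamd_total` and `ymrs_total`.
#' @export
read_clinical <- function(path) {
  d <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  need <- c("subject_id", "group", "diagnosis", "medication",
            paste0("hamd_", 1:17), paste0("ymrs_", 1:11))
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop_keymix("clinical table is missing column(s): %s", toString(miss))
  check_levels <- function(col, valid) {
    bad <- which(!(d[[col]] %in% valid))
    if (length(bad) > 0)
      stop_keymix("invalid %s %s at %s row %s (valid: %s)", col,
                  dQuote(d[[col]][bad[1]]), path, bad[1], toString(valid))
  }
  check_levels("group", c("HC", "MD"))
  check_levels("diagnosis", c("HC", "unipolar", "bipolar"))
  check_levels("medication", c("yes", "no"))
  check_items <- function(prefix, n_items, max_score) {
    cols <- paste0(prefix, "_", seq_len(n_items))
    m <- as.matrix(d[cols])
    bad <- which(!is.finite(m) | m < 0 | m > max_score | m != round(m),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop_keymix("invalid %s score at %s row %d (%s)", prefix, path,
                  bad[1, 1], cols[bad[1, 2]])
    rowSums(m)
  }
  d$hamd_total <- check_items("hamd", 17, 4)
  d$ymrs_total <- check_items("ymrs", 11, 8)
  d
}
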
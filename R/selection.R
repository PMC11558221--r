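# Choosing the number of phenotype classes: internal fit (DIC, minimum class
# size) combined with external validity (chi-square association between the
# modal classes and clinical diagnoses).

#' Pearson chi-square test of independence on a contingency table
#'
#' Plain Pearson statistic `sum (O - E)^2 / E` with expected counts from the
#' row/column margins, `df = (r - 1)(c - 1)` and an upper-tail chi-square
#' p-value; no continuity correction. Rows or columns whose margin is zero
#' are dropped with a warning before testing.
#'
#' @param table a matrix of nonnegative counts with at least 2 rows and 2
#'   columns after dropping all-zero margins.
#' @return list with `statistic`, `df`, `p_value` and the `expected` counts.
#' @examples
#' # class-by-diagnosis table: rows HC / bipolar / unipolar,
#' # columns Low / Medium / High
#' tab <- rbind(c(13, 14, 0), c(7, 4, 3), c(27, 54, 6))
#' pearson_chisq(tab)
#' @export
pearson_chisq <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_keymix("the contingency table must contain nonnegative integer counts")
  zr <- rowSums(table) == 0
  zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warn_keymix("dropping %d all-zero row(s) and %d all-zero column(s)",
                sum(zr), sum(zc))
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2)
    stop_keymix("degenerate table: need at least 2 rows and 2 columns after dropping zero margins")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

# Per-K summary used by select_model; accepts a full bgmm fit or any list
# with elements K, dic$DIC and modal (integer classes aligned to diagnoses).
fit_record <- function(fit, diagnoses) {
  stopifnot(!is.null(fit$K), !is.null(fit$modal))
  modal <- factor(fit$modal, levels = seq_len(fit$K))
  sizes <- as.integer(table(modal))
  tab <- table(factor(as.character(diagnoses)), modal)
  chi <- tryCatch(pearson_chisq(unclass(tab)), error = function(e) NULL)
  list(K = fit$K, dic = fit$dic$DIC, class_sizes = sizes,
       smallest_class = min(sizes),
       chisq = if (is.null(chi)) NA_real_ else chi$statistic,
       df = if (is.null(chi)) NA_real_ else chi$df,
       p_value = if (is.null(chi)) NA_real_ else chi$p_value)
}

#' Select the number of phenotype classes
#'
#' Applies the study's dual criterion to a set of mixture fits with different
#' K. First, any K whose smallest modal class holds fewer than
#' `min_class_size` subjects is excluded (such classes are too small to be
#' clinically meaningful). Among the remaining candidates, models whose modal
#' classes show a significant chi-square association with the clinical
#' diagnoses (`p < alpha`) are preferred: if any candidate is externally
#' valid, the choice is restricted to those. The lowest-DIC candidate then
#' wins, except that when two candidates are within `dic_tie` DIC units the
#' smaller K is chosen on parsimony grounds. If no candidate attains external
#' significance the selection falls back to internal fit alone and records an
#' audit note -- external validity adjudicates between otherwise acceptable
#' models rather than vetoing all of them. If no K passes the class-size
#' filter, `chosen` is `NA` and every K carries its exclusion reason.
#'
#' @param fits list of fitted [bgmm()] objects (one per K), in any order.
#' @param diagnoses per-subject diagnosis labels (e.g. HC / unipolar /
#'   bipolar), aligned with the subjects of each fit.
#' @param min_class_size smallest acceptable modal class (default 5 subjects).
#' @param alpha significance level for the external chi-square (default .05).
#' @param dic_tie DIC margin treated as a tie, resolved toward smaller K
#'   (default 2).
#' @return an object of class `selection_report`: data.frame `table` (one row
#'   per K with DIC, smallest class, chi-square, df, p, status), `chosen` K
#'   (or `NA`), `reasons` per rejected K, and `notes`.
#' @export
select_model <- function(fits, diagnoses, min_class_size = 5, alpha = 0.05,
                         dic_tie = 2) {
  stopifnot(length(fits) >= 1, min_class_size >= 1, alpha > 0, alpha < 1)
  recs <- lapply(fits, fit_record, diagnoses = diagnoses)
  recs <- recs[order(vapply(recs, `[[`, 0, "K"))]
  ks <- vapply(recs, `[[`, 0, "K")
  if (anyDuplicated(ks)) stop_keymix("supply exactly one fit per K")

  tab <- data.frame(
    K = ks,
    DIC = vapply(recs, `[[`, 0, "dic"),
    smallest_class = vapply(recs, `[[`, 0, "smallest_class"),
    chisq = vapply(recs, `[[`, 0, "chisq"),
    df = vapply(recs, `[[`, 0, "df"),
    p_value = vapply(recs, `[[`, 0, "p_value")
  )

  reasons <- stats::setNames(vector("list", length(ks)), paste0("K", ks))
  notes <- character()

  size_ok <- tab$smallest_class >= min_class_size
  for (i in which(!size_ok))
    reasons[[i]] <- c(reasons[[i]], sprintf(
      "smallest modal class has %d subject(s) < %d",
      tab$smallest_class[i], min_class_size))

  ext_ok <- size_ok & !is.na(tab$p_value) & tab$p_value < alpha
  if (any(size_ok) && !any(ext_ok)) {
    notes <- c(notes, sprintf(
      "no candidate reached external significance (alpha = %g); falling back to internal fit",
      alpha))
    candidates <- which(size_ok)
  } else {
    for (i in which(size_ok & !ext_ok))
      reasons[[i]] <- c(reasons[[i]], sprintf(
        "no external validity: chi-square p = %.3f >= %g",
        tab$p_value[i], alpha))
    candidates <- which(ext_ok)
  }

  chosen <- NA_integer_
  if (length(candidates) > 0) {
    best <- candidates[which.min(tab$DIC[candidates])]
    near <- candidates[tab$DIC[candidates] <= tab$DIC[best] + dic_tie]
    pick <- near[which.min(tab$K[near])]
    if (pick != best)
      notes <- c(notes, sprintf(
        "DIC within %g between K = %d and K = %d; smaller K chosen for parsimony",
        dic_tie, tab$K[pick], tab$K[best]))
    chosen <- tab$K[pick]
    for (i in setdiff(candidates, pick))
      reasons[[i]] <- c(reasons[[i]], sprintf(
        "DIC %.3f not preferred over K = %d (DIC %.3f)",
        tab$DIC[i], chosen, tab$DIC[pick]))
  }

  tab$status <- ifelse(tab$K %in% chosen, "chosen",
                       vapply(reasons, function(r)
                         if (is.null(r)) "rejected" else r[1], ""))
  structure(list(table = tab, chosen = chosen, reasons = reasons,
                 notes = notes, min_class_size = min_class_size,
                 alpha = alpha, dic_tie = dic_tie),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, digits = 3, ...) {
  cat("Phenotype model selection (min class size ", x$min_class_size,
      ", alpha ", x$alpha, ")\n\n", sep = "")
  tab <- x$table
  tab$DIC <- round(tab$DIC, digits)
  tab$chisq <- round(tab$chisq, 2)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  if (is.na(x$chosen)) cat("\nNo model selected.\n")
  else cat("\nChosen: K =", x$chosen, "\n")
  for (nt in x$notes) cat("Note:", nt, "\n")
  invisible(x)
}
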
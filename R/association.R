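# Downstream models linking phenotype membership to clinical outcomes:
# group-level LMM on the continuous rates, linear severity regression for
# depression, hurdle gamma for mania totals, and per-item proportional-odds
# models with structural-zero handling.

# Coerce phenotype labels to a factor with Low as the reference level
# (alphabetical ordering would put High first).
phenotype_factor <- function(x) {
  if (is.factor(x)) return(x)
  known <- c("Low", "Medium", "High")
  lev <- if (all(x %in% known)) intersect(known, unique(x)) else unique(x)
  factor(x, levels = lev)
}

new_assoc_result <- function(model, coefficients, converged = TRUE,
                             notes = character(), extra = list()) {
  structure(c(list(model = model, coefficients = coefficients,
                   converged = converged, notes = notes), extra),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, digits = 3, ...) {
  cat(x$model, if (!x$converged) " [non-convergent]", "\n", sep = "")
  if (NROW(x$coefficients) > 0) {
    tab <- x$coefficients
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], signif, digits)
    print(tab, row.names = FALSE)
  } else cat("  (no estimable coefficients)\n")
  for (nt in x$notes) cat("note: ", nt, "\n", sep = "")
  invisible(x)
}

# Coefficient rows from a summary()$coefficients matrix, intercept dropped;
# character indexing of a single row would drop names, so extract explicitly.
ct_from_summary <- function(sm, or = FALSE) {
  keep <- setdiff(rownames(sm), "(Intercept)")
  coef_table(stats::setNames(sm[keep, 1], keep),
             stats::setNames(sm[keep, 2], keep), or = or)
}

coef_table <- function(est, se, or = FALSE) {
  z <- est / se
  out <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se), z = unname(z),
                    p = 2 * stats::pnorm(-abs(unname(z))))
  if (or) {
    out$or <- exp(out$estimate)
    out$ci_lo <- exp(out$estimate - 1.96 * out$se)
    out$ci_hi <- exp(out$estimate + 1.96 * out$se)
  }
  rownames(out) <- NULL
  out
}

#' Group difference in daily backspace rates (linear mixed model)
#'
#' Tests whether daily backspace rates differ between clinical groups
#' (HC vs MD) on the continuous scale, with a random intercept per subject to
#' account for days nested in subjects. Fitted by maximum likelihood with
#' Wald inference on the group term. If the random-intercept variance is
#' estimated as singular, the model falls back to OLS with cluster-robust
#' (subject-clustered) standard errors and is flagged.
#'
#' @param daily daily rate table (`subject_id`, `rate`).
#' @param clinical clinical table with `subject_id` and `group`.
#' @return an `assoc_result` with the group coefficient, plus `varcomp`
#'   (between-subject SD, residual SD, intraclass correlation).
#' @export
lmm_group_test <- function(daily, clinical) {
  d <- merge(daily, clinical[, c("subject_id", "group")], by = "subject_id")
  d$group <- factor(d$group)
  if (nlevels(d$group) < 2) stop_keymix("need at least 2 groups")
  fit <- lme4::lmer(rate ~ group + (1 | subject_id), data = d, REML = FALSE)
  if (lme4::isSingular(fit)) {
    warn_keymix("singular random-intercept variance; falling back to cluster-robust OLS")
    ols <- stats::lm(rate ~ group, data = d)
    vc <- sandwich::vcovCL(ols, cluster = d$subject_id)
    est <- stats::coef(ols)
    se <- sqrt(diag(vc))
    return(new_assoc_result(
      "group difference in daily rates (cluster-robust OLS fallback)",
      coef_table(est[-1], se[-1]), converged = FALSE,
      notes = "singular LMM; OLS with subject-clustered SE",
      extra = list(fit = ols)))
  }
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_b <- vc$sdcor[vc$grp == "subject_id"]
  sd_w <- vc$sdcor[vc$grp == "Residual"]
  new_assoc_result(
    "group difference in daily rates (LMM, random intercepts)",
    ct_from_summary(sm),
    extra = list(fit = fit,
                 varcomp = c(sd_between = sd_b, sd_within = sd_w,
                             icc = sd_b^2 / (sd_b^2 + sd_w^2))))
}

#' Severity regression of a clinical total on phenotype membership
#'
#' Least-squares regression of a symptom severity total (HAM-D by default) on
#' phenotype, Low as reference, optionally adjusting for medication and
#' diagnosis. Collinear covariates are dropped with a warning.
#'
#' @param clinical clinical table with the outcome and covariate columns.
#' @param assignments phenotype assignments from [assign_subjects()]
#'   (`subject_id`, `label`).
#' @param covariates `"none"` (unadjusted) or `"adjusted"`
#'   (medication + diagnosis).
#' @param outcome name of the outcome column (default `"hamd_total"`).
#' @return an `assoc_result` with one coefficient per non-reference phenotype
#'   (and covariates when adjusted).
#' @export
severity_regression <- function(clinical, assignments,
                                covariates = c("none", "adjusted"),
                                outcome = "hamd_total") {
  covariates <- match.arg(covariates)
  d <- merge(clinical, assignments[, c("subject_id", "label")],
             by = "subject_id")
  if (!outcome %in% names(d)) stop_keymix("no column %s", dQuote(outcome))
  d$label <- phenotype_factor(d$label)
  form <- stats::reformulate(
    c("label", if (covariates == "adjusted") c("medication", "diagnosis")),
    response = outcome)
  fit <- stats::lm(form, data = d)
  est <- stats::coef(fit)
  dropped <- names(est)[is.na(est)]
  if (length(dropped) > 0)
    warn_keymix("dropping collinear term(s): %s", toString(dropped))
  sm <- summary(fit)$coefficients
  new_assoc_result(
    sprintf("severity regression: %s ~ phenotype%s", outcome,
            if (covariates == "adjusted") " + medication + diagnosis" else ""),
    ct_from_summary(sm),
    notes = if (length(dropped) > 0)
      sprintf("collinear terms dropped: %s", toString(dropped))
    else character(),
    extra = list(fit = fit))
}

# Gamma log-likelihood at the MLE shape for a fitted Gamma(log) glm.
gamma_part_loglik <- function(fit) {
  shape <- MASS::gamma.shape(fit)$alpha
  mu <- stats::fitted(fit)
  y <- stats::model.response(stats::model.frame(fit))
  list(shape = shape,
       loglik = sum(stats::dgamma(y, shape = shape, rate = shape / mu,
                                  log = TRUE)))
}

#' Hurdle gamma model for zero-inflated severity totals
#'
#' Mania totals are zero for most subjects and right-skewed when positive, so
#' they are modelled in two parts: a logistic regression for whether the
#' rating is nonzero, and a gamma regression with log link on the positive
#' ratings. Because a gamma density carries no mass at zero, this hurdle
#' formulation has exactly the likelihood of a "zero-inflated" gamma, without
#' an unidentifiable latent mixture: the total log-likelihood is the sum of
#' the two parts. Both coefficient blocks are returned, Low as reference.
#'
#' @param clinical clinical table with the outcome and covariate columns.
#' @param assignments phenotype assignments (`subject_id`, `label`).
#' @param covariates `"none"` or `"adjusted"` (medication + diagnosis).
#' @param outcome name of the nonnegative outcome column
#'   (default `"ymrs_total"`).
#' @return an `assoc_result` whose coefficient table has a `part` column
#'   (`"nonzero"` / `"positive"`), plus `loglik` (total and per part, and the
#'   MLE gamma shape). If the outcome is all zero or all positive the
#'   corresponding part is skipped and flagged.
#' @export
hurdle_gamma <- function(clinical, assignments,
                         covariates = c("none", "adjusted"),
                         outcome = "ymrs_total") {
  covariates <- match.arg(covariates)
  d <- merge(clinical, assignments[, c("subject_id", "label")],
             by = "subject_id")
  if (!outcome %in% names(d)) stop_keymix("no column %s", dQuote(outcome))
  y <- d[[outcome]]
  if (any(y < 0)) stop_keymix("%s must be nonnegative", outcome)
  d$label <- phenotype_factor(d$label)
  rhs <- c("label", if (covariates == "adjusted") c("medication", "diagnosis"))
  notes <- character()
  tabs <- list()
  ll <- list(nonzero = NA_real_, positive = NA_real_, shape = NA_real_)
  fits <- list()

  if (all(y > 0) || all(y == 0)) {
    notes <- c(notes, sprintf("outcome is all %s: nonzero part skipped",
                              if (all(y > 0)) "positive" else "zero"))
  } else {
    d$.nonzero <- as.integer(y > 0)
    fb <- stats::glm(stats::reformulate(rhs, ".nonzero"), data = d,
                     family = stats::binomial())
    tb <- cbind(part = "nonzero", ct_from_summary(summary(fb)$coefficients))
    tabs <- c(tabs, list(tb))
    ll$nonzero <- as.numeric(stats::logLik(fb))
    fits$nonzero <- fb
  }

  if (!any(y > 0)) {
    notes <- c(notes, "no positive outcomes: positive part skipped")
  } else {
    dp <- d[y > 0, , drop = FALSE]
    if (any(vapply(dp[rhs[1]], function(v) length(unique(v)) < 2, TRUE)))
      notes <- c(notes, "phenotype constant among positives")
    fg <- stats::glm(stats::reformulate(rhs, outcome), data = dp,
                     family = stats::Gamma(link = "log"))
    tg <- cbind(part = "positive", ct_from_summary(summary(fg)$coefficients))
    tabs <- c(tabs, list(tg))
    gp <- gamma_part_loglik(fg)
    ll$positive <- gp$loglik
    ll$shape <- gp$shape
    fits$positive <- fg
  }

  ll$total <- sum(unlist(ll[c("nonzero", "positive")]), na.rm = TRUE)
  new_assoc_result(
    sprintf("hurdle gamma: %s ~ phenotype%s", outcome,
            if (covariates == "adjusted") " + medication + diagnosis" else ""),
    do.call(rbind, tabs), converged = length(notes) == 0, notes = notes,
    extra = list(loglik = ll, fits = fits))
}

#' Proportional-odds model for a single symptom item
#'
#' Cumulative-logit (proportional odds) regression of one ordinal HAM-D/YMRS
#' item on phenotype membership, Low as reference; effects are reported as
#' odds ratios with Wald 95% CIs. Structural zeros are handled the way the
#' study handled its non-converging item models: if any phenotype group shows
#' a single observed category for the item, the full model is marked
#' non-convergent, the offending group(s) are dropped, the model is refit on
#' the remaining groups and the dropped groups are recorded in the notes. An
#' item constant in the whole sample yields a descriptive note and no model.
#'
#' @param item vector of ordinal item scores.
#' @param phenotype phenotype labels aligned with `item` (factor; first level
#'   is the reference).
#' @param item_name label used in the result.
#' @return an `assoc_result`; `thresholds` holds the fitted cutpoints of the
#'   final model.
#' @export
ordinal_item_model <- function(item, phenotype, item_name = "item") {
  stopifnot(length(item) == length(phenotype))
  phenotype <- droplevels(phenotype_factor(phenotype))
  ok <- !is.na(item) & !is.na(phenotype)
  item <- item[ok]
  phenotype <- phenotype[ok]

  if (length(unique(item)) < 2)
    return(new_assoc_result(
      sprintf("ordinal model: %s ~ phenotype", item_name),
      data.frame(), converged = FALSE,
      notes = sprintf("%s is constant (= %s) in the whole sample; no model",
                      item_name, unique(item)[1])))

  notes <- character()
  converged <- TRUE
  repeat {
    per_group <- tapply(item, phenotype, function(v) length(unique(v)))
    degen <- names(per_group)[per_group < 2]
    if (length(degen) == 0) break
    converged <- FALSE
    for (g in degen)
      notes <- c(notes, sprintf(
        "group %s shows a single category (%s) for %s; dropped and refit",
        g, unique(item[phenotype == g]), item_name))
    keep <- !(phenotype %in% degen)
    item <- item[keep]
    phenotype <- droplevels(phenotype[keep])
    if (nlevels(phenotype) < 2 || length(unique(item)) < 2)
      return(new_assoc_result(
        sprintf("ordinal model: %s ~ phenotype", item_name),
        data.frame(), converged = FALSE,
        notes = c(notes, "fewer than 2 informative groups remain; no model")))
  }

  d <- data.frame(y = factor(item, ordered = TRUE), label = phenotype)
  if (nlevels(d$y) == 2) {
    # with one threshold the cumulative-logit model is logistic regression
    d$y2 <- as.integer(d$y == levels(d$y)[2])
    fit <- stats::glm(y2 ~ label, data = d, family = stats::binomial())
    sm <- summary(fit)$coefficients
    return(new_assoc_result(
      sprintf("ordinal model: %s ~ phenotype (binary item)", item_name),
      ct_from_summary(sm, or = TRUE), converged = converged, notes = notes,
      extra = list(fit = fit,
                   thresholds = c(`1|2` = -unname(sm["(Intercept)", 1])))))
  }
  fit <- tryCatch(
    MASS::polr(y ~ label, data = d, Hess = TRUE),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new_assoc_result(
      sprintf("ordinal model: %s ~ phenotype", item_name),
      data.frame(), converged = FALSE,
      notes = c(notes, paste("fit failed:", conditionMessage(fit)))))

  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[names(est)]
  new_assoc_result(
    sprintf("ordinal model: %s ~ phenotype", item_name),
    coef_table(est, se, or = TRUE), converged = converged, notes = notes,
    extra = list(fit = fit, thresholds = fit$zeta))
}

#' Proportional-odds scan over all items of a rating scale
#'
#' Runs [ordinal_item_model()] for every item column of the chosen scale and
#' collects the odds ratios in one table. No multiple-testing correction is
#' applied by default (none was applied in the source analyses); `adjust =
#' "BH"` adds Benjamini-Hochberg adjusted p-values across items.
#'
#' @param clinical clinical table with `hamd_1..17` / `ymrs_1..11` columns.
#' @param assignments phenotype assignments (`subject_id`, `label`).
#' @param scale `"hamd"` or `"ymrs"`.
#' @param adjust `"none"` or `"BH"`.
#' @return list with `results` (one `assoc_result` per item) and `table`
#'   (combined coefficient rows, with `p_adj` when requested).
#' @export
symptom_item_scan <- function(clinical, assignments,
                              scale = c("hamd", "ymrs"),
                              adjust = c("none", "BH")) {
  scale <- match.arg(scale)
  adjust <- match.arg(adjust)
  d <- merge(clinical, assignments[, c("subject_id", "label")],
             by = "subject_id")
  cols <- grep(paste0("^", scale, "_[0-9]+$"), names(d), value = TRUE)
  cols <- cols[order(as.integer(sub(".*_", "", cols)))]
  if (length(cols) == 0) stop_keymix("no %s_* item columns found", scale)
  results <- lapply(cols, function(cl)
    ordinal_item_model(d[[cl]], d$label, item_name = cl))
  names(results) <- cols
  rows <- lapply(cols, function(cl) {
    tb <- results[[cl]]$coefficients
    if (NROW(tb) == 0) return(NULL)
    cbind(item = cl, tb)
  })
  tab <- do.call(rbind, rows)
  if (adjust == "BH" && NROW(tab) > 0)
    tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  list(results = results, table = tab)
}
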
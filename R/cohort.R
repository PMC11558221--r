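# Synthetic cohort generator. Emulates the statistical structure of the
# smartphone keystroke study -- 128 community adults (27 healthy controls,
# 101 with mood disorders), ~23 daily backspace rates each drawn from a
# 3-component equal-variance truncated-normal mixture, phenotype-dependent
# clinical outcomes -- so every pipeline stage is testable without raw data.

# Per-item proportional-odds truths. `pattern` encodes the structural-zero
# behaviour observed in the study: "free" items vary in all groups with the
# tabulated odds ratios; "high_zero" items are identically 0 in the High
# group; "low_zero" in the Low group; "medium_only"/"high_only" are nonzero
# in a single group; "all_zero" never vary.
hamd_item_truth <- function() {
  data.frame(
    item = paste0("hamd_", 1:17),
    name = c("depressed_mood", "guilt", "suicide", "initial_insomnia",
             "middle_insomnia", "terminal_insomnia", "work_activities",
             "retardation", "agitation", "psychic_anxiety", "somatic_anxiety",
             "gastrointestinal", "general_somatic", "genital",
             "hypochondriasis", "loss_of_weight", "insight"),
    ncat = c(5, 5, 5, 3, 3, 3, 5, 5, 5, 5, 5, 3, 3, 3, 5, 3, 3),
    or_medium = c(1.58, 1.50, 1.50, 1.69, 2.12, 1.26, 1.51, 3.14, 0.93,
                  3.30, 3.64, 2.05, 2.78, 5.24, 1.50, 1.50, NA),
    or_high = c(0.49, NA, NA, 4.20, 6.82, 7.61, 0.65, 1.34, 6.87, 4.62,
                2.08, 1.05, 0.58, 1.76, 1.50, NA, NA),
    pattern = c("free", "high_zero", "high_zero", "free", "free", "free",
                "free", "free", "free", "free", "free", "free", "free",
                "free", "low_zero", "high_zero", "medium_only"),
    stringsAsFactors = FALSE
  )
}

ymrs_item_truth <- function() {
  data.frame(
    item = paste0("ymrs_", 1:11),
    name = c("elevated_mood", "motor_activity", "sexual_interest", "sleep",
             "irritability", "speech", "language_thought", "content",
             "disruptive", "appearance", "insight"),
    ncat = rep(5L, 11),
    or_medium = c(1.99, 2.71, 1.00, 1.09, 6.61, 1.00, NA, NA, NA, NA, NA),
    or_high = c(16.12, 15.22, 1.00, 4.74, 12.83, 1.00, NA, NA, NA, NA, NA),
    pattern = c("free", "free", "low_zero", "free", "free", "low_zero",
                "high_only", "medium_only", "all_zero", "all_zero",
                "all_zero"),
    stringsAsFactors = FALSE
  )
}

# Baseline (reference-group) category probabilities by scale and item width.
item_baseline <- function(scale, ncat) {
  if (scale == "hamd") {
    if (ncat == 3) c(0.70, 0.20, 0.10) else c(0.60, 0.20, 0.10, 0.07, 0.03)
  } else {
    c(0.92, 0.04, 0.02, 0.01, 0.01)[seq_len(ncat)] /
      sum(c(0.92, 0.04, 0.02, 0.01, 0.01)[seq_len(ncat)])
  }
}

# Sample ordinal scores under a cumulative-logit shift of `logor` relative
# to the baseline category probabilities.
gen_ordinal <- function(n, base_probs, logor = 0) {
  if (n == 0) return(integer())
  cum <- cumsum(base_probs)
  cum <- cum[-length(cum)]
  cum_shift <- stats::plogis(stats::qlogis(cum) - logor)
  probs <- diff(c(0, cum_shift, 1))
  sample.int(length(base_probs), n, replace = TRUE, prob = probs) - 1L
}

#' Configuration of the synthetic keystroke cohort
#'
#' Defaults reproduce the source study's structure: 128 subjects (27 healthy
#' controls, 87 unipolar, 14 bipolar), phenotype class drawn conditional on
#' diagnosis from the published class-by-diagnosis counts, daily backspace
#' rates from the 3-component truncated-normal mixture (means
#' 0.112/0.180/0.268, shared SD 0.048), Poisson(23) observation days per
#' subject (~2948 subject-days in expectation), medication probability 22.2%
#' (HC) / 59.4% (MD), depression totals with a Medium-vs-Low effect of 2.32
#' HAM-D points, mania totals from a hurdle gamma with High-vs-Low effects
#' 1.91 (nonzero part, logit) and 1.46 (positive part, log), and per-item
#' proportional-odds truths with the published odds ratios including the
#' structural-zero items.
#'
#' @param n_subjects total cohort size; diagnosis counts are rescaled
#'   proportionally (largest remainder) when it differs from their sum.
#' @param diagnosis_counts named counts for HC / unipolar / bipolar.
#' @param class_probs matrix of P(class | diagnosis), rows HC / unipolar /
#'   bipolar, columns Low / Medium / High; rows must sum to 1.
#' @param means,sigma mixture truth: ascending component means and shared SD.
#' @param days_mean mean of the Poisson day count per subject (minimum 1 day).
#' @param keypresses_mean mean daily keypress volume (Poisson, minimum 20).
#' @param medication_prob probability of medication by group (HC, MD).
#' @param depression linear truth for HAM-D totals: intercept (Low mean),
#'   `b_medium`, `b_high`, residual `sd`; totals are floored at 0 and rounded.
#' @param mania_zero logit truth for P(YMRS > 0): intercept, `b_medium`,
#'   `b_high`.
#' @param mania_positive log-scale truth for positive YMRS totals: intercept,
#'   `b_medium`, `b_high`, gamma `shape`.
#' @param hamd_items,ymrs_items per-item proportional-odds truth tables; see
#'   the package source for the encoding of structural-zero patterns.
#' @param timezone IANA zone used for generated keystroke events.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = NULL,
                          diagnosis_counts = c(HC = 27, unipolar = 87,
                                               bipolar = 14),
                          class_probs = rbind(
                            HC = c(13, 14, 0) / 27,
                            unipolar = c(27, 54, 6) / 87,
                            bipolar = c(7, 4, 3) / 14),
                          means = c(0.112, 0.180, 0.268),
                          sigma = 0.048,
                          days_mean = 23,
                          keypresses_mean = 500,
                          medication_prob = c(HC = 0.222, MD = 0.594),
                          depression = list(intercept = 4.5,
                                            b_medium = 2.32, b_high = 0.5,
                                            sd = 4.5),
                          mania_zero = list(intercept = stats::qlogis(0.25),
                                            b_medium = 0.5, b_high = 1.91),
                          mania_positive = list(intercept = log(1.5),
                                                b_medium = 0.79,
                                                b_high = 1.46, shape = 1.5),
                          hamd_items = hamd_item_truth(),
                          ymrs_items = ymrs_item_truth(),
                          timezone = "America/Chicago") {
  stopifnot(all(diagnosis_counts >= 0), sigma > 0, !is.unsorted(means),
            all(means > 0 & means < 1), days_mean > 0,
            depression$sd > 0, mania_positive$shape > 0)
  if (nrow(class_probs) != length(diagnosis_counts) ||
      ncol(class_probs) != length(means))
    stop_keymix("class_probs must be %d diagnoses x %d classes",
                length(diagnosis_counts), length(means))
  if (any(abs(rowSums(class_probs) - 1) > 1e-8))
    stop_keymix("each row of class_probs must sum to 1")
  if (!is.null(n_subjects) && n_subjects != sum(diagnosis_counts)) {
    # largest-remainder rescaling keeps the diagnosis mix
    raw <- diagnosis_counts / sum(diagnosis_counts) * n_subjects
    cnt <- floor(raw)
    rem <- n_subjects - sum(cnt)
    if (rem > 0) {
      add <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[add] <- cnt[add] + 1
    }
    diagnosis_counts <- stats::setNames(as.integer(cnt),
                                        names(diagnosis_counts))
  }
  structure(list(diagnosis_counts = diagnosis_counts,
                 class_probs = class_probs, means = means, sigma = sigma,
                 days_mean = days_mean, keypresses_mean = keypresses_mean,
                 medication_prob = medication_prob, depression = depression,
                 mania_zero = mania_zero, mania_positive = mania_positive,
                 hamd_items = hamd_items, ymrs_items = ymrs_items,
                 timezone = timezone),
            class = "cohort_config")
}

gen_items <- function(truth, scale, z, labels) {
  n <- length(z)
  out <- matrix(0L, n, nrow(truth), dimnames = list(NULL, truth$item))
  grp <- labels[z]
  for (r in seq_len(nrow(truth))) {
    base <- item_baseline(scale, truth$ncat[r])
    pat <- truth$pattern[r]
    v <- integer(n)
    if (pat %in% c("free", "high_zero", "low_zero")) {
      gen_for <- switch(pat,
        free = c("Low", "Medium", "High"),
        high_zero = c("Low", "Medium"),
        low_zero = c("Medium", "High"))
      for (g in gen_for) {
        lo <- switch(g, Low = 0,
                     Medium = log(truth$or_medium[r] %||% 1),
                     High = log(truth$or_high[r] %||% 1))
        if (is.na(lo)) lo <- 0
        sel <- grp == g
        v[sel] <- gen_ordinal(sum(sel), base, lo)
      }
    } else if (pat == "medium_only") {
      sel <- grp == "Medium"
      v[sel] <- gen_ordinal(sum(sel), base, 0)
    } else if (pat == "high_only") {
      sel <- grp == "High"
      v[sel] <- gen_ordinal(sum(sel), base, 0)
    } # all_zero: leave 0
    out[, r] <- v
  }
  as.data.frame(out)
}

#' Generate a synthetic keystroke-study cohort
#'
#' Draws a full cohort under the configured truth: per subject a diagnosis,
#' a latent phenotype class (from the class-given-diagnosis table), a
#' medication indicator, a Poisson number of observation days with daily
#' backspace rates from the truncated-normal mixture, HAM-D and YMRS totals
#' from the severity and hurdle truths, and ordinal item scores from the
#' per-item proportional-odds truths (honouring the structural-zero
#' patterns). Every latent value is kept in the returned truth record so
#' recovery can be checked exactly.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the same configuration and seed reproduce the
#'   cohort exactly.
#' @return list with `daily` (subject_id, date, n_keypresses, n_backspaces,
#'   rate), `clinical` (group, diagnosis, medication, item scores, totals)
#'   and `truth` (per-subject latent classes plus the full config).
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 30), seed = 7)
#' head(coh$daily)
#' table(coh$truth$subjects$class, coh$truth$subjects$diagnosis)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- length(config$means)
  labels <- phenotype_labels(K)
  n <- sum(config$diagnosis_counts)
  ids <- sprintf("S%04d", seq_len(n))
  diagnosis <- rep(names(config$diagnosis_counts), config$diagnosis_counts)
  group <- ifelse(diagnosis == "HC", "HC", "MD")
  z <- vapply(diagnosis, function(d)
    sample.int(K, 1, prob = config$class_probs[d, ]), 0L)
  medication <- ifelse(
    stats::runif(n) < config$medication_prob[ifelse(group == "HC", "HC",
                                                    "MD")],
    "yes", "no")

  days <- pmax(1L, stats::rpois(n, config$days_mean))
  daily <- do.call(rbind, lapply(seq_len(n), function(i) {
    nd <- days[i]
    r <- rtruncnorm(nd, config$means[z[i]], config$sigma)
    nk <- pmax(20L, stats::rpois(nd, config$keypresses_mean))
    nb <- pmin(pmax(as.integer(round(r * nk)), 0L), nk)
    data.frame(subject_id = ids[i],
               date = format(as.Date("2024-03-01") + seq_len(nd) - 1),
               n_keypresses = nk, n_backspaces = nb, rate = nb / nk,
               stringsAsFactors = FALSE)
  }))
  rownames(daily) <- NULL

  dep <- config$depression
  hamd_total <- as.integer(round(pmax(0,
    dep$intercept + dep$b_medium * (z == 2) + dep$b_high * (z == 3) +
      stats::rnorm(n, 0, dep$sd))))
  mz <- config$mania_zero
  p_nz <- stats::plogis(mz$intercept + mz$b_medium * (z == 2) +
                          mz$b_high * (z == 3))
  nonzero <- stats::rbinom(n, 1, p_nz) == 1
  mp <- config$mania_positive
  mu_pos <- exp(mp$intercept + mp$b_medium * (z == 2) +
                  mp$b_high * (z == 3))
  ymrs_total <- numeric(n)
  ymrs_total[nonzero] <- stats::rgamma(sum(nonzero), shape = mp$shape,
                                       rate = mp$shape / mu_pos[nonzero])

  clinical <- data.frame(subject_id = ids, group = group,
                         diagnosis = diagnosis, medication = medication,
                         stringsAsFactors = FALSE)
  clinical <- cbind(clinical,
                    gen_items(config$hamd_items, "hamd", z, labels),
                    gen_items(config$ymrs_items, "ymrs", z, labels))
  clinical$hamd_total <- hamd_total
  clinical$ymrs_total <- ymrs_total

  truth <- list(
    subjects = data.frame(subject_id = ids, diagnosis = diagnosis,
                          group = group, medication = medication,
                          class = factor(labels[z], levels = labels),
                          days = days, p_nonzero = p_nz,
                          mu_positive = mu_pos,
                          stringsAsFactors = FALSE),
    config = config
  )
  list(daily = daily, clinical = clinical, truth = truth)
}

#' Expand daily rate records into raw keypress events
#'
#' The inverse of [aggregate_daily()]: for every subject-day it emits exactly
#' `n_keypresses` events -- `n_backspaces` of them backspace-category -- in
#' typing sessions that respect the 6-second rule (integer within-session
#' gaps of 0-2 s, between-session gaps of 8-30 s), all inside the local
#' calendar day, so `aggregate_daily(generate_keystroke_events(d))`
#' reproduces `d` exactly. Intended to exercise the raw-event path of the
#' pipeline with data of known truth.
#'
#' @param daily daily rate table (`subject_id`, `date`, `n_keypresses`,
#'   `n_backspaces`).
#' @param timezone IANA zone for the emitted events.
#' @param start_hour local hour of the first keypress of each day.
#' @param session_size_mean mean events per session (Poisson, minimum 1).
#' @return an event table as in [read_keystroke_events()], with an attribute
#'   `session_counts` (data.frame subject_id, date, n_sessions) recording the
#'   generator's own session bookkeeping.
#' @export
generate_keystroke_events <- function(daily, timezone = "America/Chicago",
                                      start_hour = 9,
                                      session_size_mean = 25) {
  stopifnot(all(c("subject_id", "date", "n_keypresses", "n_backspaces")
                %in% names(daily)))
  other_cat <- c("alphanumeric", "punctuation", "autocorrection",
                 "autosuggestion", "special")
  other_p <- c(0.80, 0.10, 0.04, 0.04, 0.02)
  out <- vector("list", nrow(daily))
  scounts <- integer(nrow(daily))
  for (i in seq_len(nrow(daily))) {
    nk <- daily$n_keypresses[i]
    nb <- daily$n_backspaces[i]
    sizes <- integer()
    while (sum(sizes) < nk)
      sizes <- c(sizes, pmax(1L, stats::rpois(8, session_size_mean)))
    sizes <- sizes[cumsum(sizes) - sizes < nk]
    sizes[length(sizes)] <- nk - sum(sizes[-length(sizes)])
    scounts[i] <- length(sizes)
    first <- rep(FALSE, nk)
    first[cumsum(sizes) - sizes + 1] <- TRUE
    gaps <- ifelse(first, sample(8:30, nk, replace = TRUE),
                   sample(0:2, nk, replace = TRUE, prob = c(.3, .5, .2)))
    gaps[1] <- 0
    secs <- cumsum(gaps)
    if (secs[nk] > (23 - start_hour) * 3600)
      stop_keymix("day %s/%s too full to fit %d events inside one local day",
                  daily$subject_id[i], daily$date[i], nk)
    origin <- as.POSIXct(paste(daily$date[i],
                               sprintf("%02d:00:00", start_hour)),
                         tz = timezone)
    cat_vec <- sample(other_cat, nk, replace = TRUE, prob = other_p)
    if (nb > 0) cat_vec[sample.int(nk, nb)] <- "backspace"
    out[[i]] <- data.frame(
      subject_id = daily$subject_id[i],
      session_id = sprintf("%s-%s-s%03d", daily$subject_id[i],
                           daily$date[i], rep(seq_along(sizes), sizes)),
      timestamp_utc = format(origin + secs, "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC"),
      timezone = timezone, category = cat_vec, stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  attr(events, "session_counts") <- data.frame(
    subject_id = daily$subject_id, date = daily$date,
    n_sessions = scounts, stringsAsFactors = FALSE)
  events
}
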
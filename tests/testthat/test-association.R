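# Association models: LMM group test, severity regression, hurdle gamma,
# proportional-odds item models.

make_assignments <- function(labels) {
  data.frame(subject_id = sprintf("S%04d", seq_along(labels)),
             label = factor(labels, levels = c("Low", "Medium", "High")))
}

make_clinical <- function(n, hamd_total = NULL, ymrs_total = NULL,
                          medication = NULL, diagnosis = NULL) {
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             group = "MD",
             diagnosis = diagnosis %||% rep("unipolar", n),
             medication = medication %||% rep("no", n),
             hamd_total = hamd_total %||% rep(0, n),
             ymrs_total = ymrs_total %||% rep(0, n),
             stringsAsFactors = FALSE)
}

test_that("a noise-free phenotype effect is recovered exactly", {
  labels <- rep(c("Low", "Medium", "High"), times = c(20, 20, 10))
  y <- 5 + 2.32 * (labels == "Medium")
  res <- severity_regression(make_clinical(50, hamd_total = y),
                             make_assignments(labels))
  est <- res$coefficients
  expect_equal(est$estimate[est$term == "labelMedium"], 2.32,
               tolerance = 1e-12)
  expect_equal(est$estimate[est$term == "labelHigh"], 0, tolerance = 1e-12)
})

test_that("severity coefficients equal the normal-equations oracle", {
  set.seed(31)
  labels <- sample(c("Low", "Medium", "High"), 80, TRUE)
  y <- rnorm(80, 6, 3)
  med <- sample(c("yes", "no"), 80, TRUE)
  dg <- sample(c("unipolar", "bipolar"), 80, TRUE)
  res <- severity_regression(
    make_clinical(80, hamd_total = y, medication = med, diagnosis = dg),
    make_assignments(labels), covariates = "adjusted")
  # oracle: direct matrix solve of the normal equations
  X <- cbind(1, labels == "Medium", labels == "High", med == "yes",
             dg == "unipolar")
  beta <- solve(t(X) %*% X, t(X) %*% y)
  est <- res$coefficients
  expect_equal(est$estimate[est$term == "labelMedium"], beta[2],
               tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "labelHigh"], beta[3],
               tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "medicationyes"], beta[4],
               tolerance = 1e-8)
})

test_that("LMM intraclass correlation matches the balanced ANOVA estimator", {
  set.seed(41)
  n_subj <- 200; n_day <- 8
  tau <- 0.03; sw <- 0.05
  subj_eff <- rnorm(n_subj, 0, tau)
  daily <- data.frame(
    subject_id = rep(sprintf("S%04d", 1:n_subj), each = n_day),
    rate = 0.15 + rep(subj_eff, each = n_day) + rnorm(n_subj * n_day, 0, sw))
  clinical <- make_clinical(n_subj)
  clinical$group <- rep(c("HC", "MD"), each = n_subj / 2)
  res <- lmm_group_test(daily, clinical)
  # method-of-moments oracle on the balanced one-way layout; ML and MoM
  # agree to O(1/n), hence the loose tolerance at this design size
  ybar_i <- tapply(daily$rate, daily$subject_id, mean)
  grp <- clinical$group[match(names(ybar_i), clinical$subject_id)]
  resid_b <- unlist(lapply(split(ybar_i, grp), function(v) v - mean(v)))
  msw <- sum((daily$rate -
                ave(daily$rate, daily$subject_id))^2) /
    (n_subj * (n_day - 1))
  msb <- n_day * sum(resid_b^2) / (n_subj - 2)
  tau2_hat <- (msb - msw) / n_day
  icc_oracle <- tau2_hat / (tau2_hat + msw)
  icc_truth <- tau^2 / (tau^2 + sw^2)
  expect_equal(unname(res$varcomp["icc"]), icc_oracle, tolerance = 0.05)
  expect_lt(abs(unname(res$varcomp["icc"]) - icc_truth), 0.1)
  expect_true(res$converged)
})

test_that("LMM group test is calibrated under the null and powered at 0.02", {
  null_reject <- logical(50)
  alt_reject <- logical(50)
  for (r in 1:50) {
    set.seed(500 + r)
    n_subj <- 128; n_day <- 23
    clinical <- make_clinical(n_subj)
    clinical$group <- rep(c("HC", "MD"), times = c(27, 101))
    subj <- rep(clinical$subject_id, each = n_day)
    eff <- rep(rnorm(n_subj, 0, 0.02), each = n_day)
    noise <- rnorm(n_subj * n_day, 0, 0.048)
    is_md <- rep(clinical$group == "MD", each = n_day)
    d0 <- data.frame(subject_id = subj, rate = 0.15 + eff + noise)
    d1 <- data.frame(subject_id = subj,
                     rate = 0.15 + 0.02 * is_md + eff + noise)
    null_reject[r] <- suppressWarnings(
      lmm_group_test(d0, clinical))$coefficients$p < 0.05
    alt_reject[r] <- suppressWarnings(
      lmm_group_test(d1, clinical))$coefficients$p < 0.05
  }
  # nominal 5% level: allow binomial slack around it over 50 replicates
  expect_lte(mean(null_reject), 0.12)
  expect_gte(mean(alt_reject), 0.9)    # Monte-Carlo power oracle
})

test_that("singular random intercepts fall back to cluster-robust OLS", {
  # identical within-subject patterns: between-subject variance is exactly 0
  daily <- data.frame(subject_id = rep(sprintf("S%04d", 1:30), each = 3),
                      rate = 0.15 + rep(c(-0.01, 0, 0.01), 30))
  clinical <- make_clinical(30)
  clinical$group <- rep(c("HC", "MD"), 15)
  expect_warning(res <- lmm_group_test(daily, clinical), "singular")
  expect_false(res$converged)
  expect_match(res$model, "OLS")
})

test_that("hurdle gamma decomposes its log-likelihood exactly", {
  set.seed(61)
  labels <- rep(c("Low", "Medium", "High"), times = c(47, 72, 9))
  n <- length(labels)
  p <- plogis(-1 + 1.9 * (labels == "High"))
  y <- ifelse(runif(n) < p,
              rgamma(n, 1.5, rate = 1.5 / exp(0.4 + 1.46 * (labels == "High"))),
              0)
  res <- hurdle_gamma(make_clinical(n, ymrs_total = y),
                      make_assignments(labels))
  ll <- res$loglik
  expect_equal(ll$total, ll$nonzero + ll$positive, tolerance = 1e-10)
  # independent total: explicit hurdle density over all observations
  fb <- res$fits$nonzero; fg <- res$fits$positive
  p_hat <- fitted(fb)
  mu_hat <- fitted(fg)
  shape <- ll$shape
  tot <- sum(log(1 - p_hat[y == 0])) + sum(log(p_hat[y > 0])) +
    sum(dgamma(y[y > 0], shape, rate = shape / mu_hat, log = TRUE))
  expect_equal(ll$total, tot, tolerance = 1e-8)
  expect_setequal(unique(res$coefficients$part), c("nonzero", "positive"))
})

test_that("hurdle gamma skips degenerate parts with a note", {
  labels <- rep(c("Low", "Medium"), 20)
  res0 <- hurdle_gamma(make_clinical(40, ymrs_total = rep(0, 40)),
                       make_assignments(labels))
  expect_false(res0$converged)
  expect_match(res0$notes, "all zero", all = FALSE)
  expect_null(res0$coefficients)

  resp <- hurdle_gamma(make_clinical(40, ymrs_total = rgamma(40, 2, 1) + 0.1),
                       make_assignments(labels))
  expect_match(resp$notes, "all positive", all = FALSE)
  expect_true(all(resp$coefficients$part == "positive"))
})

test_that("hurdle null effects stay within 2 SE in most replicates", {
  ok_zero <- logical(20); ok_pos <- logical(20)
  for (r in 1:20) {
    set.seed(700 + r)
    labels <- rep(c("Low", "Medium", "High"), times = c(47, 72, 9))
    n <- length(labels)
    y <- ifelse(runif(n) < 0.35, rgamma(n, 1.5, rate = 1), 0)
    res <- hurdle_gamma(make_clinical(n, ymrs_total = y),
                        make_assignments(labels))
    ct <- res$coefficients
    hz <- ct[ct$part == "nonzero" & ct$term == "labelHigh", ]
    hp <- ct[ct$part == "positive" & ct$term == "labelHigh", ]
    ok_zero[r] <- abs(hz$estimate) < 2 * hz$se
    ok_pos[r] <- nrow(hp) == 0 || abs(hp$estimate) < 2 * hp$se
  }
  expect_gte(mean(ok_zero), 0.9)
  expect_gte(mean(ok_pos), 0.9)
})

test_that("identical item distributions give odds ratios near 1", {
  set.seed(71)
  labels <- rep(c("Low", "Medium"), each = 60)
  item <- sample(0:3, 120, TRUE, prob = c(0.5, 0.3, 0.15, 0.05))
  res <- ordinal_item_model(item, labels, "toy")
  ct <- res$coefficients
  expect_true(abs(ct$estimate) < 2 * ct$se)
  expect_equal(exp(log(ct$or)), ct$or, tolerance = 1e-12)
  expect_true(ct$ci_lo < ct$or && ct$or < ct$ci_hi)
})

test_that("a binary item reduces to plain logistic regression", {
  set.seed(72)
  labels <- rep(c("Low", "Medium", "High"), times = c(40, 40, 20))
  p <- plogis(-0.8 + 0.9 * (labels == "Medium") + 1.4 * (labels == "High"))
  item <- rbinom(100, 1, p)
  res <- ordinal_item_model(item, labels, "binary")
  orc <- oracle_logistic(cbind(1, labels == "Medium", labels == "High"),
                         item)
  ct <- res$coefficients
  expect_equal(ct$estimate, orc$beta[-1], tolerance = 1e-5)
  expect_equal(ct$se, orc$se[-1], tolerance = 1e-4)
  # the single threshold is minus the logistic intercept
  expect_equal(unname(res$thresholds), -orc$beta[1], tolerance = 1e-5)
})

test_that("proportional-odds thresholds increase and cumulative probs are monotone", {
  set.seed(73)
  labels <- rep(c("Low", "Medium", "High"), times = c(50, 50, 20))
  item <- gen <- sample(0:4, 120, TRUE, prob = c(0.4, 0.25, 0.2, 0.1, 0.05))
  item[labels == "High"] <- sample(0:4, 20, TRUE,
                                   prob = c(0.1, 0.15, 0.25, 0.25, 0.25))
  res <- ordinal_item_model(item, labels, "mono")
  expect_true(all(diff(res$thresholds) > 0))
  pr <- predict(res$fit,
                newdata = data.frame(label = factor("High",
                                                    levels(res$fit$model$label))),
                type = "probs")
  expect_true(all(diff(cumsum(pr)) >= -1e-12))
})

test_that("structural zeros trigger drop-and-refit that matches a fresh fit", {
  set.seed(74)
  labels <- rep(c("Low", "Medium", "High"), times = c(50, 60, 12))
  item <- sample(0:2, 122, TRUE, prob = c(0.5, 0.3, 0.2))
  item[labels == "High"] <- 0L   # injected structural zero
  res <- ordinal_item_model(item, labels, "szero")
  expect_false(res$converged)
  expect_match(res$notes, "High.*dropped", all = FALSE)
  expect_false(any(grepl("High", res$coefficients$term)))
  # the refit equals a fresh fit on the reduced data exactly
  keep <- labels != "High"
  fresh <- ordinal_item_model(item[keep], labels[keep], "szero")
  expect_equal(res$coefficients, fresh$coefficients, tolerance = 1e-10)
})

test_that("constant items yield a descriptive note only", {
  res <- ordinal_item_model(rep(0L, 50), rep(c("Low", "Medium"), 25), "flat")
  expect_false(res$converged)
  expect_equal(nrow(res$coefficients), 0)
  expect_match(res$notes, "constant")
})

test_that("the item scan collects odds ratios with optional BH adjustment", {
  coh <- generate_cohort(cohort_config(), seed = 81)
  asg <- data.frame(subject_id = coh$truth$subjects$subject_id,
                    label = coh$truth$subjects$class)
  scan <- symptom_item_scan(coh$clinical, asg, scale = "ymrs",
                            adjust = "BH")
  expect_true(all(c("item", "term", "or", "p_adj") %in% names(scan$table)))
  # structural-zero YMRS items carry notes instead of estimates
  expect_false(any(scan$table$item == "ymrs_9"))
  expect_match(scan$results$ymrs_9$notes, "constant")
})
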
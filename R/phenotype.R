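# Density-based Low/Medium/High phenotype scoring.

phenotype_labels <- function(K) {
  if (K == 3) c("Low", "Medium", "High") else paste0("Class", seq_len(K))
}

#' Score a backspace rate against the fitted mixture components
#'
#' The practitioner-facing classification rule: given the fitted component
#' means and shared SD, the score of each class for an observed rate is the
#' plain normal density `f(rate | mu_k, sigma)`. By default no mixture weight
#' is applied and no truncation normalizer is used -- with the published
#' parameters (means 0.112/0.180/0.268, SD 0.048) a rate of 0.14 then scores
#' (7.01, 5.87, 0.24), i.e. (0.53, 0.45, 0.02) after dividing by the score
#' sum, and the modal phenotype is Low. Turning `use_weights` on multiplies
#' each density by its mixture weight, which makes the normalized scores the
#' standard single-observation posterior class probabilities; `use_truncation`
#' swaps in the (0,1)-truncated density.
#'
#' @param rate observed backspace rate, strictly inside (0, 1).
#' @param means ascending component means (or a fitted [bgmm()] in place of
#'   `means`, from which means, sigma and weights are taken).
#' @param sigma shared component SD (> 0).
#' @param weights mixture weights; required only when `use_weights = TRUE`.
#' @param use_weights multiply densities by mixture weights (default off).
#' @param use_truncation use (0,1)-truncated densities (default off).
#' @return an object of class `phenotype_scores`: list with `unnormalized`
#'   and `normalized` score vectors (named by class label), and `label`, the
#'   argmax class (ties broken toward the lower class).
#' @examples
#' class_density_scores(0.14, means = c(0.112, 0.180, 0.268), sigma = 0.048)
#' @export
class_density_scores <- function(rate, means, sigma, weights = NULL,
                                 use_weights = FALSE,
                                 use_truncation = FALSE) {
  if (inherits(means, "bgmm")) {
    fit <- means
    means <- fit$posterior$means
    sigma <- fit$posterior$sigma
    if (is.null(weights)) weights <- fit$posterior$weights
  }
  stopifnot(length(rate) == 1, is.finite(rate))
  if (rate <= 0 || rate >= 1)
    stop_keymix("rate must lie strictly inside (0, 1), got %g", rate)
  if (!is.numeric(sigma) || sigma <= 0)
    stop_keymix("sigma must be a positive number")
  if (is.unsorted(means))
    stop_keymix("component means must be sorted ascending (relabel first)")
  K <- length(means)
  scores <- if (use_truncation) dtruncnorm(rate, means, sigma)
            else stats::dnorm(rate, means, sigma)
  if (use_weights) {
    if (is.null(weights) || length(weights) != K)
      stop_keymix("`weights` of length %d required when use_weights = TRUE",
                  K)
    scores <- scores * weights
  }
  labels <- phenotype_labels(K)
  names(scores) <- labels
  normalized <- scores / sum(scores)
  structure(list(unnormalized = scores, normalized = normalized,
                 label = labels[which.max(scores)]),
            class = "phenotype_scores")
}

#' @export
print.phenotype_scores <- function(x, digits = 2, ...) {
  cat("Phenotype density scores\n")
  print(round(rbind(unnormalized = x$unnormalized,
                    normalized = x$normalized), digits))
  cat("Label:", x$label, "\n")
  invisible(x)
}

#' Assign cohort subjects to phenotypes from a fitted mixture
#'
#' Each subject is assigned the class with the highest MCMC posterior
#' probability (ties toward the lower class), labelled Low/Medium/High for a
#' 3-class fit. This is the cohort-level assignment rule; the single-rate
#' density rule in [class_density_scores()] is the companion for scoring a
#' new individual without refitting.
#'
#' @param fit a fitted [bgmm()]; a warning is issued if it has not converged.
#' @return a data.frame with one row per subject: `subject_id`, the posterior
#'   probability of each class (`prob_Low`, ... or `prob_Class1`, ...),
#'   `label` (factor, levels in class order).
#' @export
assign_subjects <- function(fit) {
  stopifnot(inherits(fit, "bgmm"))
  if (!fit$converged)
    warn_keymix("assigning phenotypes from a fit whose chains have not converged")
  prob <- fit$class_prob
  labels <- phenotype_labels(fit$K)
  out <- data.frame(subject_id = rownames(prob), stringsAsFactors = FALSE)
  for (k in seq_len(fit$K)) out[[paste0("prob_", labels[k])]] <- prob[, k]
  out$label <- factor(labels[max.col(prob, ties.method = "first")],
                      levels = labels)
  rownames(out) <- NULL
  out
}
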
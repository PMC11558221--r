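# S3 methods for fitted bounded Gaussian mixtures.

#' @export
print.bgmm <- function(x, digits = 3, ...) {
  cat("Bounded Gaussian mixture (", x$K, " components, ",
      x$mixing, "-level classes)\n", sep = "")
  cat("  ", x$n_obs, " daily rates from ", x$n_units, " units; ",
      x$n_chains, " chain(s) x ", x$n_iter, " retained draws\n", sep = "")
  tab <- rbind(mean = x$posterior$means, weight = x$posterior$weights,
               `n (modal)` = x$class_sizes)
  colnames(tab) <- x$labels
  print(round(tab, digits))
  cat("Shared sigma:", format(x$posterior$sigma, digits = digits),
      "  DIC:", format(x$dic$DIC, digits = 7), "\n")
  cat("Max split R-hat:", format(max(x$rhat, na.rm = TRUE), digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.bgmm <- function(object, ...) {
  p <- object$posterior
  params <- data.frame(
    parameter = c(paste0("mu_", seq_len(object$K)), "sigma",
                  paste0("pi_", seq_len(object$K))),
    estimate = c(p$means, p$sigma, p$weights),
    sd = c(p$means_sd, p$sigma_sd, p$weights_sd),
    rhat = unname(object$rhat)
  )
  out <- list(params = params, K = object$K, labels = object$labels,
              class_sizes = object$class_sizes, dic = object$dic,
              converged = object$converged, n_obs = object$n_obs,
              n_units = object$n_units)
  class(out) <- "summary.bgmm"
  out
}

#' @export
print.summary.bgmm <- function(x, digits = 4, ...) {
  cat("Bounded Gaussian mixture, K =", x$K, "\n\n")
  print(transform(x$params, estimate = signif(estimate, digits),
                  sd = signif(sd, digits), rhat = round(rhat, 3)),
        row.names = FALSE)
  cat("\nModal class sizes:",
      paste(x$labels, x$class_sizes, sep = " = ", collapse = ", "), "\n")
  cat(sprintf("DIC = %.3f (Dbar = %.3f, pD = %.3f)\n",
              x$dic$DIC, x$dic$Dbar, x$dic$pD))
  invisible(x)
}

#' @export
coef.bgmm <- function(object, ...) {
  p <- object$posterior
  stats::setNames(c(p$means, p$sigma, p$weights),
                  c(paste0("mu_", seq_len(object$K)), "sigma",
                    paste0("pi_", seq_len(object$K))))
}

#' @export
logLik.bgmm <- function(object, ...) {
  p <- object$posterior
  units <- make_units(object$data, object$mixing,
                      truncation = object$truncation)
  ll <- marginal_loglik(units, p$means, p$sigma, p$weights,
                        object$truncation)
  structure(ll, df = 2 * object$K, nobs = object$n_obs, class = "logLik")
}

#' Posterior class probabilities or labels for new rates
#'
#' With `newdata`, scores each rate against the posterior-mean components via
#' Bayes' rule (weighted, truncation matching the fit); without, returns the
#' MCMC posterior class memberships of the fitted units.
#'
#' @param object a fitted [bgmm()].
#' @param newdata optional numeric vector of rates in (0, 1).
#' @param type `"prob"` for a matrix of class probabilities, `"class"` for
#'   modal labels (ties to the lower class).
#' @param ... unused.
#' @export
predict.bgmm <- function(object, newdata = NULL,
                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    prob <- object$class_prob
  } else {
    p <- object$posterior
    prob <- t(vapply(as.numeric(newdata), function(r) {
      class_density_scores(r, means = p$means, sigma = p$sigma,
                           weights = p$weights, use_weights = TRUE,
                           use_truncation = object$truncation)$normalized
    }, numeric(object$K)))
    rownames(prob) <- names(newdata)
  }
  colnames(prob) <- object$labels
  if (type == "prob") return(prob)
  factor(object$labels[max.col(prob, ties.method = "first")],
         levels = object$labels)
}

#' @export
fitted.bgmm <- function(object, ...) {
  # expected rate per observation: subject class probabilities x comp. means
  prob <- object$class_prob[match(as.character(object$data$subject_id),
                                  rownames(object$class_prob)), ,
                            drop = FALSE]
  if (object$mixing == "observation")
    prob <- object$class_prob
  as.numeric(prob %*% object$posterior$means)
}

#' @export
residuals.bgmm <- function(object, ...) {
  object$data$rate - fitted(object)
}

#' Simulate daily-rate tables from a fitted mixture
#'
#' Draws new cohorts of the same shape as the fitted data (same subjects,
#' same day counts) from the posterior-mean parameters: each subject gets a
#' class from the posterior-mean weights, then truncated-normal daily rates.
#'
#' @param object a fitted [bgmm()].
#' @param nsim number of simulated tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `nsim` data.frames with columns `subject_id`, `rate`.
#' @export
simulate.bgmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$posterior
  days <- table(factor(as.character(object$data$subject_id),
                       levels = unique(as.character(object$data$subject_id))))
  replicate(nsim, simplify = FALSE, {
    rows <- lapply(names(days), function(id) {
      k <- sample.int(object$K, 1, prob = p$weights)
      data.frame(subject_id = id,
                 rate = rtruncnorm(days[[id]], p$means[k], p$sigma))
    })
    do.call(rbind, rows)
  })
}

#' Histogram of daily rates with fitted mixture components
#'
#' @param x a fitted [bgmm()].
#' @param breaks histogram breaks.
#' @param ... passed to [graphics::hist()].
#' @export
plot.bgmm <- function(x, breaks = 30, ...) {
  p <- x$posterior
  graphics::hist(x$data$rate, breaks = breaks, freq = FALSE,
                 main = "Daily backspace rates and fitted components",
                 xlab = "daily backspace rate", border = "grey40", ...)
  xx <- seq(1e-4, max(x$data$rate) * 1.2, length.out = 400)
  tot <- rep(0, length(xx))
  for (k in seq_len(x$K)) {
    dk <- p$weights[k] * (if (x$truncation)
      dtruncnorm(xx, p$means[k], p$sigma) else
        stats::dnorm(xx, p$means[k], p$sigma))
    graphics::lines(xx, dk, col = k + 1, lwd = 1.5)
    tot <- tot + dk
  }
  graphics::lines(xx, tot, lwd = 2)
  graphics::legend("topright", bty = "n", lwd = 1.5,
                   col = c(seq_len(x$K) + 1, 1),
                   legend = c(x$labels, "mixture"))
  invisible(x)
}
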
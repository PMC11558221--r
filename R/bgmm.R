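# Bounded Gaussian mixture for daily backspace rates, fitted by Gibbs
# sampling with subject-level latent classes.
#
# Model (subject-level mixing, the default):
#   y_ij | z_i = k  ~  Normal(mu_k, sigma^2) truncated to (0, 1)
#   z_i             ~  Categorical(pi_1, ..., pi_K)   (one class per subject)
#   pi              ~  Dirichlet(alpha, ..., alpha)
#   mu_k            ~  Normal(m0, s0^2) restricted to the ordered region
#                      0 < mu_1 < ... < mu_K < 1
#   sigma^2         ~  Inverse-Gamma(a0, b0)
# Days j are conditionally iid given the subject's class. The ordered prior
# identifies the component labels (means are rates, so they live on (0,1),
# and ordering them resolves the label-switching symmetry inside the
# sampler); it also pins any empty component between its neighbours instead
# of letting it wander the diffuse prior, which keeps posterior means, modal
# class sizes and the plug-in deviance D(theta_bar) meaningful when K
# exceeds the number of clusters the data support. The truncation
# normalizer Phi((1-mu)/sigma) - Phi(-mu/sigma) breaks exact conjugacy: at
# ~3000 observations the normalizer contributes a factor C^{-n} that shifts
# and re-shapes the full conditionals of mu and sigma^2, and a Metropolis
# step proposing from the conjugate (untruncated) conditional freezes
# whenever the chain sits outside the proposal's narrow support. The mu_k and
# log sigma^2 updates therefore slice-sample their exact full conditionals
# (conjugate kernel times the C^{-n} correction); with `truncation = FALSE`
# the updates are pure conjugate Gibbs.

#' Prior specification for the bounded Gaussian mixture
#'
#' Conjugate, effectively noninformative defaults: component means are
#' `Normal(m0 = 0.5, s0sq = 10)` (flat over the unit interval; the sampler
#' restricts them jointly to the ordered region of (0, 1)), the shared
#' variance is `Inverse-Gamma(a0 = 0.001, b0 = 0.001)`, and the mixture
#' weights are `Dirichlet(alpha = 1)`.
#'
#' @param m0,s0sq prior mean and variance of each component mean.
#' @param a0,b0 inverse-gamma shape and rate for the shared variance.
#' @param alpha Dirichlet concentration shared by all components.
#' @return an object of class `bgmm_prior`.
#' @export
bgmm_prior <- function(m0 = 0.5, s0sq = 10, a0 = 0.001, b0 = 0.001,
                       alpha = 1) {
  stopifnot(s0sq > 0, a0 > 0, b0 > 0, alpha > 0)
  structure(list(m0 = m0, s0sq = s0sq, a0 = a0, b0 = b0, alpha = alpha),
            class = "bgmm_prior")
}

# Per-unit sufficient statistics. A "unit" is the thing that carries the
# latent class: a subject (default) or a single observation.
make_units <- function(data, mixing = "subject", eps = 1e-6,
                       truncation = TRUE) {
  if (is.numeric(data)) {
    data <- data.frame(subject_id = as.character(seq_along(data)),
                       rate = data)
  }
  stopifnot(all(c("subject_id", "rate") %in% names(data)))
  y <- data$rate
  if (any(!is.finite(y)) || any(y < 0 | y > 1))
    stop_keymix("rates must be finite and within [0, 1]")
  on_boundary <- y <= 0 | y >= 1
  if (any(on_boundary) && truncation) {
    warn_keymix("%d rate(s) on the boundary of (0,1) clamped to [%g, %g]",
                sum(on_boundary), eps, 1 - eps)
    y <- pmin(pmax(y, eps), 1 - eps)
  }
  id <- if (mixing == "subject") as.character(data$subject_id)
        else sprintf("obs%06d", seq_along(y))
  uid <- unique(id)
  f <- factor(id, levels = uid)
  list(
    unit_ids = uid,
    subject_of_unit = if (mixing == "subject") uid
                      else as.character(data$subject_id),
    n = as.numeric(tapply(rep(1, length(y)), f, sum)),
    t1 = as.numeric(tapply(y, f, sum)),
    t2 = as.numeric(tapply(y^2, f, sum)),
    y = y, n_obs = length(y)
  )
}

# N x K matrix of per-unit log-likelihood contributions
# ll[i, k] = sum_j log f(y_ij | mu_k, sigma), f truncated-normal if requested.
unit_loglik_matrix <- function(units, means, sigma, truncation = TRUE) {
  K <- length(means)
  quad <- matrix(units$t2, length(units$n), K) -
    2 * outer(units$t1, means) + outer(units$n, means^2)
  ll <- -quad / (2 * sigma^2) -
    outer(units$n, rep(log(sigma) + 0.5 * log(2 * pi), K))
  if (truncation)
    ll <- ll - outer(units$n, log_trunc_mass(means, sigma))
  ll
}

# Marginal (z integrated out) log-likelihood of the mixture.
marginal_loglik <- function(units, means, sigma, weights,
                            truncation = TRUE) {
  lw <- sweep(unit_loglik_matrix(units, means, sigma, truncation), 2,
              log(weights), "+")
  sum(row_logsumexp(lw))
}

#' Mixture log-likelihood of daily backspace rates
#'
#' Subject-level mixture likelihood: `log L = sum_i log sum_k pi_k prod_j
#' f(y_ij | mu_k, sigma)`, where `f` is the normal density, truncated to
#' (0, 1) when `truncation = TRUE`, and all days `j` of subject `i` share one
#' latent class. Computed with the log-sum-exp shift, so it is finite for any
#' admissible parameters. Rates lying exactly on the boundary of (0,1) are
#' clamped to `(eps, 1 - eps)` with a warning when the truncated density is
#' requested.
#'
#' @param data daily rate table with columns `subject_id` and `rate`, or a
#'   numeric rate vector (each element then its own subject).
#' @param means ascending component means.
#' @param sigma shared component standard deviation (> 0).
#' @param weights mixture weights, summing to 1.
#' @param truncation use the (0,1)-truncated normal component density.
#' @param mixing `"subject"` (all days of a subject share a class) or
#'   `"observation"` (each day mixes independently).
#' @param eps boundary clamp.
#' @return the log-likelihood (scalar).
#' @export
mixture_loglik <- function(data, means, sigma, weights,
                           truncation = TRUE,
                           mixing = c("subject", "observation"),
                           eps = 1e-6) {
  mixing <- match.arg(mixing)
  stopifnot(sigma > 0, length(weights) == length(means), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8)
    stop_keymix("mixture weights must sum to 1")
  units <- make_units(data, mixing, eps, truncation)
  marginal_loglik(units, means, sigma, weights, truncation)
}

# Univariate slice sampler with stepping out and shrinkage (Neal 2003).
slice_sample1 <- function(x0, logf, w, max_steps = 100) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  y <- f0 - stats::rexp(1)
  L <- x0 - w * stats::runif(1)
  R <- L + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > y) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# One MCMC chain. Returns matrices of retained draws only.
run_chain <- function(units, K, prior, n_burn, n_iter, truncation,
                      chain_id) {
  N <- length(units$n)
  n_tot <- sum(units$n)
  ybar <- units$t1 / units$n
  # dispersed start: class-quantile means with chain-specific jitter,
  # forced strictly increasing inside (0, 1)
  means <- sort(stats::quantile(ybar, probs = (seq_len(K) - 0.5) / K,
                                names = FALSE) +
                  stats::rnorm(K, 0, 0.25 * stats::sd(ybar) / K + 1e-4))
  means <- pmin(pmax(means, 1e-4), 1 - 1e-4)
  means <- cummax(means + (seq_len(K) - 1) * 1e-6)
  # start sigma at the pooled within-unit SD (falls back to the marginal SD
  # when units are single observations), with chain-specific jitter
  wss <- sum(units$t2 - units$t1^2 / units$n)
  dfw <- units$n_obs - N
  sigma <- (if (dfw > 0 && wss > 0) sqrt(wss / dfw)
            else stats::sd(units$y)) * stats::runif(1, 0.8, 1.25)
  weights <- rep(1 / K, K)

  keep <- n_iter
  mu_d <- matrix(NA_real_, keep, K)
  w_d <- matrix(NA_real_, keep, K)
  sig_d <- numeric(keep)
  z_d <- matrix(NA_integer_, keep, N)
  ll_d <- numeric(keep)

  for (it in seq_len(n_burn + n_iter)) {
    ## latent classes and (in passing) the marginal log-likelihood
    ll <- unit_loglik_matrix(units, means, sigma, truncation)
    lw <- sweep(ll, 2, log(weights), "+")
    m <- lw[cbind(seq_len(N), max.col(lw, ties.method = "first"))]
    p <- exp(lw - m)
    rs <- rowSums(p)
    if (any(!is.finite(rs)))
      stop_keymix("non-finite component density at iteration %d (chain %d)",
                  it, chain_id)
    marg <- sum(m + log(rs))
    p <- p / rs
    u <- stats::runif(N)
    z <- rep(1L, N)
    cp <- p[, 1]
    for (k in seq_len(K - 1)) {
      z <- z + (u > cp)
      cp <- cp + p[, k + 1]
    }

    if (it > n_burn) {
      s <- it - n_burn
      mu_d[s, ] <- means
      w_d[s, ] <- weights
      sig_d[s] <- sigma
      z_d[s, ] <- z
      ll_d[s] <- marg
    }

    ## weights | z
    weights <- rdirichlet1(prior$alpha + tabulate(z, K))

    ## means | z, sigma: conjugate normal kernel x truncation correction
    nk_obs <- as.numeric(tapply(units$n, factor(z, levels = seq_len(K)),
                                sum))
    nk_obs[is.na(nk_obs)] <- 0
    sy <- as.numeric(tapply(units$t1, factor(z, levels = seq_len(K)), sum))
    sy[is.na(sy)] <- 0
    for (k in seq_len(K)) {
      v <- 1 / (1 / prior$s0sq + nk_obs[k] / sigma^2)
      mm <- v * (prior$m0 / prior$s0sq + sy[k] / sigma^2)
      lo <- if (k > 1) means[k - 1] else 0
      hi <- if (k < K) means[k + 1] else 1
      nk <- nk_obs[k]
      means[k] <- slice_sample1(
        means[k],
        function(mu) {
          if (mu <= lo || mu >= hi) return(-Inf)
          -(mu - mm)^2 / (2 * v) -
            (if (truncation && nk > 0) nk * log_trunc_mass(mu, sigma)
             else 0)
        },
        w = min(3 * sqrt(v), (hi - lo) / 2))
    }

    ## sigma^2 | z, means: inverse-gamma kernel x truncation correction,
    ## slice-sampled on log sigma^2
    muz <- means[z]
    ss <- sum(units$t2) - 2 * sum(units$t1 * muz) + sum(units$n * muz^2)
    ap <- prior$a0 + n_tot / 2
    bp <- prior$b0 + ss / 2
    if (truncation) {
      th <- slice_sample1(
        2 * log(sigma),
        function(th) -ap * th - bp * exp(-th) -
          sum(nk_obs * log_trunc_mass(means, exp(th / 2))),
        w = 3 * sqrt(1 / ap) + 1e-3)
      sigma <- exp(th / 2)
    } else {
      sigma <- sqrt(1 / stats::rgamma(1, shape = ap, rate = bp))
    }
  }

  list(mu = mu_d, weight = w_d, sigma = sig_d, z = z_d, loglik = ll_d,
       chain = rep.int(chain_id, keep))
}

#' Relabel posterior draws by ascending component mean
#'
#' Finite mixtures are invariant to permuting component labels, so MCMC
#' chains can switch labels between draws. This resolves the symmetry by
#' sorting, within every draw, the components by their mean (ascending) and
#' permuting the weights and latent class indicators consistently. Idempotent.
#'
#' @param draws a `bgmm_draws` object (see [bgmm()]).
#' @return the relabeled `bgmm_draws` object.
#' @export
relabel_draws <- function(draws) {
  stopifnot(inherits(draws, "bgmm_draws"))
  K <- ncol(draws$mu)
  if (K == 1) return(draws)
  ord <- t(apply(draws$mu, 1, order))        # ord[s,j] = old index of new j
  rk <- t(apply(draws$mu, 1, rank, ties.method = "first")) # new index of old k
  S <- nrow(draws$mu)
  idx <- cbind(rep(seq_len(S), K), as.vector(ord))
  draws$mu <- matrix(draws$mu[idx], S, K)
  draws$weight <- matrix(draws$weight[idx], S, K)
  draws$z <- matrix(rk[cbind(rep(seq_len(S), ncol(draws$z)),
                             as.vector(draws$z))],
                    S, ncol(draws$z))
  draws
}

# Split-R-hat for one scalar parameter across chains.
split_rhat <- function(x, chain) {
  halves <- list()
  for (cc in unique(chain)) {
    xs <- x[chain == cc]
    m <- floor(length(xs) / 2)
    halves <- c(halves, list(xs[seq_len(m)], xs[m + seq_len(m)]))
  }
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  mns <- vapply(halves, mean, 0)
  vrs <- vapply(halves, stats::var, 0)
  w <- mean(vrs)
  b <- n * stats::var(mns)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Deviance information criterion of a fitted mixture
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean of the deviance
#' `D(theta) = -2 log L(y | theta)`, `pD = Dbar - D(theta_hat)` the effective
#' number of parameters, and `theta_hat` a plug-in central value of the
#' (relabeled) parameters -- the posterior mean by default. Lower values
#' indicate better fit; for continuous densities the deviance, hence the
#' DIC, is routinely negative. Draws with a non-finite deviance are excluded
#' with a warning.
#'
#' A negative `pD` is an impossible effective parameter count and the
#' textbook symptom that the posterior-mean plug-in sits between posterior
#' modes (in a mixture this happens when the draws alternate between
#' different ways of splitting the data, so the averaged parameters fit
#' nothing). When that occurs the plug-in falls back to the posterior mode --
#' the highest-likelihood draw -- whose deviance lower-bounds the draws and
#' guarantees `pD >= 0`; the `plug_in` field records which estimate was
#' used and `pD_mean` always reports the raw posterior-mean version.
#'
#' @param draws a `bgmm_draws` object.
#' @param data the daily rate table the draws were fitted to.
#' @param truncation,mixing as in [mixture_loglik()]; must match the fit.
#' @return a list with elements `DIC`, `Dbar`, `Dhat`, `pD`, `pD_mean`,
#'   `plug_in` (`"posterior_mean"` or `"posterior_mode"`) and `n_dropped`.
#' @export
dic <- function(draws, data, truncation = TRUE,
                mixing = c("subject", "observation")) {
  mixing <- match.arg(mixing)
  stopifnot(inherits(draws, "bgmm_draws"), length(draws$loglik) >= 2)
  draws <- relabel_draws(draws)
  dev <- -2 * draws$loglik
  ok <- is.finite(dev)
  if (any(!ok))
    warn_keymix("%d draw(s) with non-finite deviance excluded from the DIC",
                sum(!ok))
  dbar <- mean(dev[ok])
  units <- make_units(data, mixing, truncation = truncation)
  w_bar <- colMeans(draws$weight[ok, , drop = FALSE])
  dhat_mean <- -2 * marginal_loglik(
    units,
    means = colMeans(draws$mu[ok, , drop = FALSE]),
    sigma = mean(draws$sigma[ok]),
    weights = w_bar / sum(w_bar),
    truncation = truncation)
  pd_mean <- dbar - dhat_mean
  if (pd_mean >= 0) {
    dhat <- dhat_mean
    pd <- pd_mean
    plug_in <- "posterior_mean"
  } else {
    dhat <- min(dev[ok])
    pd <- dbar - dhat
    plug_in <- "posterior_mode"
  }
  list(DIC = dbar + pd, Dbar = dbar, Dhat = dhat, pD = pd,
       pD_mean = pd_mean, plug_in = plug_in, n_dropped = sum(!ok))
}

#' Fit a bounded Gaussian mixture to daily backspace rates
#'
#' Fits a K-component, equal-variance Gaussian mixture on (0, 1) to
#' per-subject daily backspace rates by MCMC, with the latent class living at
#' the subject level: all days of a subject share one class, and days are
#' conditionally iid given it. Updates are conjugate Gibbs steps where exact
#' (latent classes, weights) and slice samplers on the exact full
#' conditionals for the means and shared variance, whose conjugate kernels
#' pick up a normalizer correction when the components are truncated to
#' (0, 1) (the default). Component means carry an ordered prior restricted to
#' `0 < mu_1 < ... < mu_K < 1`, which identifies the labels inside the
#' sampler and keeps any empty component pinned between its neighbours;
#' [relabel_draws()] is still applied defensively before summaries.
#' Convergence is monitored with the split R-hat; a warning is issued when
#' any parameter has R-hat above 1.05.
#'
#' @param data daily rate table with columns `subject_id` and `rate` (e.g.
#'   from [aggregate_daily()] or [generate_cohort()]), or a numeric vector.
#' @param K number of components.
#' @param prior a [bgmm_prior()].
#' @param n_iter retained iterations per chain (default 10000).
#' @param n_burn burn-in iterations per chain, discarded (default 5000).
#' @param n_chains number of chains (default 2).
#' @param seed integer RNG seed; identical seed and configuration give
#'   bit-identical draws.
#' @param truncation use (0,1)-truncated component densities (default TRUE).
#' @param mixing `"subject"` (default) or `"observation"`; the latter lets
#'   every daily observation mix independently, for sensitivity analysis.
#' @param eps boundary clamp for rates at exactly 0 or 1.
#' @return an object of class `bgmm`: a list with the relabeled `draws`,
#'   `posterior` means and SDs, per-subject `class_prob` and `modal` class,
#'   `labels` (`Low`/`Medium`/`High` when `K == 3`), `dic`, `rhat` and
#'   `converged`. Methods: `print`, `summary`, `coef`, `plot`, `predict`,
#'   `fitted`, `residuals`, `simulate`, `logLik`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 40), seed = 1)
#' fit <- bgmm(coh$daily, K = 3, n_burn = 200, n_iter = 400, seed = 1)
#' coef(fit)
#' @export
bgmm <- function(data, K, prior = bgmm_prior(), n_iter = 10000,
                 n_burn = 5000, n_chains = 2, seed = NULL,
                 truncation = TRUE, mixing = c("subject", "observation"),
                 eps = 1e-6) {
  mixing <- match.arg(mixing)
  stopifnot(K >= 1, n_iter > 0, n_burn >= 0, n_chains >= 1)
  if (!is.null(seed)) set.seed(seed)
  units <- make_units(data, mixing, eps, truncation)
  if (length(units$n) < K)
    stop_keymix("need at least K = %d units, got %d", K, length(units$n))

  chains <- lapply(seq_len(n_chains), function(cc)
    run_chain(units, K, prior, n_burn, n_iter, truncation, cc))
  draws <- structure(
    list(mu = do.call(rbind, lapply(chains, `[[`, "mu")),
         weight = do.call(rbind, lapply(chains, `[[`, "weight")),
         sigma = unlist(lapply(chains, `[[`, "sigma")),
         z = do.call(rbind, lapply(chains, `[[`, "z")),
         loglik = unlist(lapply(chains, `[[`, "loglik")),
         chain = unlist(lapply(chains, `[[`, "chain")),
         unit_ids = units$unit_ids, K = K, mixing = mixing),
    class = "bgmm_draws")
  draws <- relabel_draws(draws)

  post <- list(
    means = colMeans(draws$mu),
    means_sd = apply(draws$mu, 2, stats::sd),
    sigma = mean(draws$sigma),
    sigma_sd = stats::sd(draws$sigma),
    weights = colMeans(draws$weight),
    weights_sd = apply(draws$weight, 2, stats::sd)
  )
  post$weights <- post$weights / sum(post$weights)

  N <- length(units$n)
  class_prob <- vapply(seq_len(K),
                       function(k) colMeans(draws$z == k),
                       numeric(N))
  class_prob <- matrix(class_prob, N, K,
                       dimnames = list(units$unit_ids, NULL))
  modal <- max.col(class_prob, ties.method = "first")

  rhat <- c(
    stats::setNames(vapply(seq_len(K), function(k)
      split_rhat(draws$mu[, k], draws$chain), 0),
      paste0("mu", seq_len(K))),
    sigma = split_rhat(draws$sigma, draws$chain),
    stats::setNames(vapply(seq_len(K), function(k)
      split_rhat(draws$weight[, k], draws$chain), 0),
      paste0("pi", seq_len(K)))
  )
  converged <- all(is.na(rhat) | rhat < 1.05)
  if (!converged)
    warn_keymix("split R-hat above 1.05 for: %s -- treat results with care",
                toString(names(rhat)[!is.na(rhat) & rhat >= 1.05]))

  labels <- if (K == 3) c("Low", "Medium", "High")
            else paste0("Class", seq_len(K))

  out <- list(
    call = match.call(), K = K, mixing = mixing, truncation = truncation,
    prior = prior, n_iter = n_iter, n_burn = n_burn, n_chains = n_chains,
    seed = seed, data = if (is.numeric(data))
      data.frame(subject_id = as.character(seq_along(data)), rate = data)
      else data,
    unit_ids = units$unit_ids, n_units = N, n_obs = units$n_obs,
    draws = draws, posterior = post,
    class_prob = class_prob, modal = modal, labels = labels,
    class_sizes = tabulate(modal, K),
    dic = dic(draws, data, truncation = truncation, mixing = mixing),
    rhat = rhat, converged = converged
  )
  class(out) <- "bgmm"
  out
}
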
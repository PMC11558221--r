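# Shared fixture builders. Everything is generated in code; no data files.

# Build an event table from numeric second offsets relative to a base instant.
make_events <- function(offsets, subject = "S1", category = "alphanumeric",
                        tz = "UTC", base = "2024-01-15 12:00:00",
                        session = "sess1") {
  base_t <- as.POSIXct(base, tz = "UTC")
  data.frame(
    subject_id = rep_len(subject, length(offsets)),
    session_id = rep_len(session, length(offsets)),
    timestamp_utc = format(base_t + offsets, "%Y-%m-%dT%H:%M:%S",
                           tz = "UTC"),
    timezone = rep_len(tz, length(offsets)),
    category = rep_len(category, length(offsets)),
    stringsAsFactors = FALSE
  )
}

# Independent linear-scan session counter: one pass, split on gap > gap_s.
oracle_session_count <- function(offsets, gap_s = 6) {
  offsets <- sort(offsets)
  if (length(offsets) == 0) return(0L)
  sum(c(TRUE, diff(offsets) > gap_s))
}

# A small daily-rate table drawn from a given class structure.
toy_daily <- function(n_subj, days, means, sigma, seed = 1) {
  set.seed(seed)
  z <- rep(seq_along(means), length.out = n_subj)
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    data.frame(subject_id = sprintf("T%03d", i),
               rate = keymix::rtruncnorm(days, means[z[i]], sigma))
  }))
}

# Independent logistic MLE by plain iteratively reweighted least squares,
# used as the oracle for binary-item ordinal fits.
oracle_logistic <- function(X, y, iters = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iters)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    W <- p * (1 - p)
    beta <- beta + solve(t(X) %*% (X * W), t(X) %*% (y - p))
  }
  list(beta = drop(beta), se = sqrt(diag(solve(t(X) %*% (X * W)))))
}

# Hand-rolled bgmm_draws object for relabel/DIC unit tests.
manual_draws <- function(mu, weight, sigma, z, loglik = NULL,
                         chain = NULL) {
  S <- nrow(mu)
  structure(list(mu = mu, weight = weight, sigma = sigma, z = z,
                 loglik = loglik %||% rep(0, S),
                 chain = chain %||% rep(1L, S),
                 unit_ids = as.character(seq_len(ncol(z))),
                 K = ncol(mu), mixing = "subject"),
            class = "bgmm_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
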
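#' @keywords internal
"_PACKAGE"

# Row-wise log(sum(exp(x))) with the usual max shift; x is a matrix.
row_logsumexp <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  m + log(rowSums(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_keymix <- function(...) stop(sprintf(...), call. = FALSE)

warn_keymix <- function(...) warning(sprintf(...), call. = FALSE)

# Single draw from Dirichlet(alpha) via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}
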
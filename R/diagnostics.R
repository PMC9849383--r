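# Convergence diagnostics for the NUTS chains: split R-hat and a
# bulk effective sample size from pooled autocorrelations.

split_chains <- function(mat_list) {
  out <- list()
  for (m in mat_list) {
    n <- nrow(m); h <- n %/% 2L
    if (h < 2L) { out <- c(out, list(m)); next }
    out <- c(out, list(m[seq_len(h), , drop = FALSE],
                       m[(n - h + 1L):n, , drop = FALSE]))
  }
  out
}

#' Split R-hat for one scalar parameter across chains
#' @param chains List of numeric vectors, one per chain (equal length).
#' @return Potential scale reduction factor (1 = converged).
#' @keywords internal
split_rhat <- function(chains) {
  mats <- split_chains(lapply(chains, function(x) matrix(x, ncol = 1L)))
  means <- vapply(mats, function(m) mean(m[, 1L]), 0)
  vars <- vapply(mats, function(m) stats::var(m[, 1L]), 0)
  m <- length(mats); n <- nrow(mats[[1L]])
  if (m < 2L || n < 3L) return(NA_real_)
  W <- mean(vars); B <- n * stats::var(means)
  if (W <= 0) return(if (B <= 1e-300) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Crude bulk effective sample size for one parameter
#' @inheritParams split_rhat
#' @return Estimated effective number of independent draws.
#' @keywords internal
ess_basic <- function(chains) {
  n <- length(chains[[1L]]); m <- length(chains)
  if (n < 8L) return(NA_real_)
  # mean autocorrelation across chains, Geyer initial positive sequence
  max_lag <- min(n - 2L, 200L)
  rhos <- rowMeans(vapply(chains, function(x) {
    v <- stats::var(x)
    if (v <= 0) return(rep(0, max_lag))
    a <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1L]
    as.numeric(a)
  }, numeric(max_lag)))
  s <- 0; k <- 1L
  while (k + 1L <= max_lag) {
    pair <- rhos[k] + rhos[k + 1L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  ess <- m * n / (1 + 2 * s)
  max(1, min(ess, m * n))
}

fit_diagnostics <- function(chain_draws, par_names) {
  d <- ncol(chain_draws[[1L]])
  rhat <- ess <- numeric(d)
  for (j in seq_len(d)) {
    xs <- lapply(chain_draws, function(m) m[, j])
    rhat[j] <- split_rhat(xs)
    ess[j] <- ess_basic(xs)
  }
  data.frame(parameter = par_names, rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}
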
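#' Pooled ordinary least squares prefit of the double-exponential curve
#'
#' Fits \eqn{p(t) = a e^{-bt} + c e^{dt}} to a standardized training
#' table by nonlinear least squares, pooling all individuals. The fit
#' centers the priors of the Bayesian hierarchical model and serves as
#' the "no random effects" baseline for the R-squared comparison.
#'
#' The curve is linear in (a, c) given (b, d), so the multistart
#' profiles a grid of rate pairs, solves the conditional linear
#' least-squares problem, and polishes the best starts with
#' Levenberg-Marquardt (via \pkg{minpack.lm}) on the log-rate scale.
#'
#' @param std_table Data frame with columns `age_std`, `score_std`
#'   (from [standardize_records()]); at least 8 rows spanning at least 4
#'   distinct ages.
#' @return List with elements `params` (a [moore()] object), `rss`
#'   (residual sum of squares), `sigma` (residual sd), `r_squared`, and
#'   `n` (records used).
#' @export
ols_prefit <- function(std_table) {
  stopifnot(is.data.frame(std_table),
            all(c("age_std", "score_std") %in% names(std_table)))
  t <- std_table$age_std; y <- std_table$score_std
  if (length(y) < 8L || length(unique(round(t, 8))) < 4L)
    stop("under-determined: need >= 8 records spanning >= 4 distinct ages")

  cond_ls <- function(b, d) {
    X <- cbind(exp(-b * t), exp(d * t))
    fit <- tryCatch(stats::lsfit(X, y, intercept = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    ac <- fit$coefficients
    list(a = ac[1L], c = ac[2L], rss = sum(fit$residuals^2))
  }

  starts <- expand.grid(b = c(0.3, 0.7, 1.5, 2.5, 4), d = c(0.05, 0.15, 0.4, 1))
  cand <- lapply(seq_len(nrow(starts)), function(i) {
    s <- cond_ls(starts$b[i], starts$d[i])
    if (is.null(s) || !is.finite(s$rss)) return(NULL)
    c(a = unname(s$a), b = starts$b[i], c = unname(s$c), d = starts$d[i],
      rss = s$rss)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand)) stop("OLS prefit failed: no admissible starting values")
  cand <- cand[order(cand[, "rss"]), , drop = FALSE]

  best <- NULL
  for (i in seq_len(min(5L, nrow(cand)))) {
    st <- cand[i, ]
    # amplitudes floored at a tiny positive value: log-scale polish below
    st["a"] <- max(st["a"], 1e-6); st["c"] <- max(st["c"], 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ exp(la) * exp(-exp(lb) * t) + exp(lc) * exp(exp(ld) * t),
        data = data.frame(t = t, y = y),
        start = list(la = log(st[["a"]]), lb = log(st[["b"]]),
                     lc = log(st[["c"]]), ld = log(st[["d"]])),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # fall back to the best conditional-linear candidate
    st <- cand[1L, ]
    params <- moore(max(st[["a"]], 1e-6), st[["b"]], max(st[["c"]], 1e-6),
                    st[["d"]])
    rss <- st[["rss"]]
  } else {
    cf <- exp(stats::coef(best$fit))
    params <- moore(cf[["la"]], cf[["lb"]], cf[["lc"]], cf[["ld"]])
    rss <- best$rss
  }
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - rss / ss_tot else 0
  if (r2 < 0.01 || min(params$a, params$c) < 1e-4)
    warning("degenerate fit: data show no curvature ",
            "(an amplitude collapsed to the boundary)")
  list(params = params, rss = rss,
       sigma = sqrt(rss / max(1L, n - 4L)),
       r_squared = r2,
       n = n)
}
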
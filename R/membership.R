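# log multivariate normal density via Cholesky (own implementation;
# cross-checked in tests against mclust's E-step)
log_dmvnorm <- function(x, mean, sigma) {
  x <- as.matrix(x)
  L <- chol(sigma)
  z <- forwardsolve(t(L), t(x) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * ncol(x) * log(2 * pi)
}

#' Posterior cluster responsibilities of parameter quadruplets
#'
#' Probability that each point belongs to each mixture component:
#' weighted component densities, normalized (computed with a
#' log-sum-exp guard).
#'
#' @param model A fitted mixture candidate (the `selected` element of a
#'   [cluster_progressions()] result, or any list with `weights`,
#'   `means` (4 x K) and `sigma` (4 x 4 x K)).
#' @param x Numeric matrix (points x 4) or a single quadruplet.
#' @return Matrix (points x K) of probabilities; rows sum to 1.
#' @export
draw_responsibilities <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  K <- length(model$weights)
  lp <- vapply(seq_len(K), function(k)
    log(model$weights[k]) + log_dmvnorm(x, model$means[, k],
                                        model$sigma[, , k]),
    numeric(nrow(x)))
  lp <- matrix(lp, nrow = nrow(x))
  m <- apply(lp, 1L, max)
  w <- exp(lp - m)
  w / rowSums(w)
}

#' Per-individual cluster membership with uncertainty
#'
#' Propagates posterior uncertainty through the clustering: for each of
#' an individual's retained parameter quadruplets the mixture
#' responsibilities are computed; the profile is their mean, with
#' central quantile intervals of the per-draw probabilities.
#'
#' @param clusters A `"progression_clusters"`.
#' @param fit The `"potential_fit"` the clustering came from.
#' @param individuals Ids to profile (default all in `fit`).
#' @param level Interval level (default 0.95).
#' @return An object of class `"membership_profile"`: data frame with
#'   columns `individual_id`, `cluster`, `mean_prob`, `lower`, `upper`.
#' @export
membership_profile <- function(clusters, fit, individuals = NULL,
                               level = 0.95) {
  stopifnot(inherits(clusters, "progression_clusters"),
            inherits(fit, "potential_fit"), level > 0, level < 1)
  if (is.null(individuals)) individuals <- fit$individuals
  model <- clusters$selected
  K <- model$K
  alpha <- (1 - level) / 2
  rows <- vector("list", length(individuals))
  for (ii in seq_along(individuals)) {
    id <- individuals[ii]
    i <- match(id, fit$individuals)
    if (is.na(i)) stop("unknown individual: ", id)
    q <- fit$draws$individual[, i, , drop = TRUE]
    z <- draw_responsibilities(model, q)
    rows[[ii]] <- data.frame(
      individual_id = id, cluster = seq_len(K),
      mean_prob = colMeans(z),
      lower = apply(z, 2, stats::quantile, probs = alpha, names = FALSE),
      upper = apply(z, 2, stats::quantile, probs = 1 - alpha, names = FALSE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("membership_profile", "data.frame")
  out
}

#' @export
print.membership_profile <- function(x, ...) {
  cat(sprintf("Cluster membership profiles (%d individuals, %.0f%% intervals)\n",
              length(unique(x$individual_id)), 100 * attr(x, "level")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Plot a membership profile as bars with intervals
#'
#' @param x A `"membership_profile"`.
#' @param individual Id to plot (default the first in `x`).
#' @param ... Ignored.
#' @export
plot.membership_profile <- function(x, individual = NULL, ...) {
  if (is.null(individual)) individual <- x$individual_id[1L]
  d <- x[x$individual_id == individual, ]
  if (!nrow(d)) stop("individual not in profile: ", individual)
  bp <- graphics::barplot(d$mean_prob, names.arg = d$cluster,
                          ylim = c(0, max(d$upper, 1)),
                          xlab = "cluster", ylab = "membership probability",
                          main = paste("Individual", individual),
                          col = "steelblue3")
  graphics::arrows(bp, d$lower, bp, d$upper, angle = 90, code = 3,
                   length = 0.05)
  invisible(x)
}

#' Write membership profiles as CSV
#' @param profile A `"membership_profile"`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_membership <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
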
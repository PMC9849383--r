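#' Per-individual median parameter quadruplets
#'
#' Component-wise posterior median of each individual's effective
#' quadruplets (a + a_i, b + b_i, c + c_i, d + d_i); the clustering
#' input.
#'
#' @param fit A `"potential_fit"`.
#' @return Matrix (individuals x 4), columns `a, b, c, d`, rownames the
#'   individual ids.
#' @export
median_params <- function(fit) {
  stopifnot(inherits(fit, "potential_fit"))
  out <- apply(fit$draws$individual, c(2L, 3L), stats::median)
  dimnames(out) <- list(fit$individuals, c("a", "b", "c", "d"))
  out
}

#' The 14-member Gaussian-mixture covariance parameterization family
#'
#' Model names in the volume/shape/orientation decomposition of
#' component covariances (Banfield-Raftery / Celeux-Govaert), as
#' implemented by \pkg{mclust}: each letter states whether volume,
#' shape and orientation are Equal, Variable, or Identity-constrained
#' (`"EEE"` = equal volume, shape and orientation; `"VVV"` =
#' unconstrained).
#'
#' @return Character vector of the 14 multivariate model names.
#' @export
covariance_family <- function() mclust::mclust.options("emModelNames")

#' Fit the Gaussian-mixture candidate family by EM
#'
#' Expectation-maximization fits over the covariance parameterization
#' family, using \pkg{mclust}'s constrained M-steps. Each
#' (parameterization, K) fit is started from both the model-based
#' agglomerative partition and a multi-restart k-means partition, and
#' the higher-likelihood EM solution is kept — a single hierarchical
#' initialization is easily trapped when one component dominates the
#' cohort. With `K_by = "bic"` (the default) the number of components
#' is then chosen per parameterization by BIC — the standard
#' model-based-clustering route — yielding one candidate per covariance
#' structure, which the overlap score ranks. With `K_by = "overlap"`
#' one candidate is returned per (parameterization, K) pair so the
#' overlap score drives the K choice as well. Candidates that fail to
#' converge, produce a degenerate component (empty or vanishing weight,
#' singular covariance), or return a non-finite log-likelihood are
#' discarded with a message.
#'
#' @param x Numeric matrix (individuals x 4) of median quadruplets.
#' @param K Integer vector of candidate component counts (default
#'   `2:8`).
#' @param parameterizations Covariance structures to try; default the
#'   full 14-member family, see [covariance_family()].
#' @param K_by `"bic"` (K chosen by BIC within each parameterization)
#'   or `"overlap"` (all (parameterization, K) pairs returned).
#' @return List of candidate models; each has `parameterization`, `K`,
#'   `loglik`, `bic`, `n_params`, `weights`, `means` (4 x K), `sigma`
#'   (4 x 4 x K array), `classification`, `z`.
#' @export
fit_mixture_family <- function(x, K = 2:8, parameterizations = NULL,
                               K_by = c("bic", "overlap")) {
  x <- as.matrix(x)
  K_by <- match.arg(K_by)
  if (is.null(parameterizations)) parameterizations <- covariance_family()
  K <- K[K * 5L <= nrow(x)]
  if (!length(K))
    stop("too few individuals: need at least 5 per candidate component")
  n <- nrow(x); d <- ncol(x)

  hcp <- tryCatch(mclust::hc(x), error = function(e) NULL)
  init_partitions <- function(k) {
    parts <- list()
    if (!is.null(hcp))
      parts$hc <- as.integer(mclust::hclass(hcp, k))
    km <- tryCatch(stats::kmeans(x, centers = k, nstart = 10,
                                 iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km)) parts$kmeans <- km$cluster
    parts
  }
  em_once <- function(m, z) {
    # mclust::me() dispatches "me<MODEL>" in the caller's search path;
    # fetch the constrained-EM worker from the namespace directly
    worker <- get(paste0("me", m), envir = asNamespace("mclust"))
    fit <- tryCatch(suppressWarnings(worker(data = x, z = z)),
                    error = function(e) NULL)
    if (is.null(fit) || is.null(fit$loglik) || !is.finite(fit$loglik))
      return(NULL)
    fit
  }
  best_fit <- function(m, k) {
    best <- NULL
    for (part in init_partitions(k)) {
      if (length(unique(part)) < k) next
      fit <- em_once(m, mclust::unmap(part, groups = seq_len(k)))
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
        best <- fit
    }
    best
  }

  as_candidate <- function(m, k, fit) {
    pro <- fit$parameters$pro
    cl <- mclust::map(fit$z)
    sig <- fit$parameters$variance$sigma
    if (length(dim(sig)) == 2L) sig <- array(sig, dim = c(d, d, k))
    degenerate <- any(pro < 1e-8) ||
      any(tabulate(cl, nbins = k) == 0L) ||
      any(apply(sig, 3L, function(s) {
        ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
        min(ev) <= 1e-12 * max(ev)
      }))
    if (degenerate) {
      message("candidate ", m, " K=", k, " discarded (degenerate component)")
      return(NULL)
    }
    npar <- mclust::nMclustParams(m, d = d, G = k)
    list(parameterization = m, K = k, loglik = fit$loglik,
         bic = 2 * fit$loglik - npar * log(n),
         n_params = npar, weights = pro, means = fit$parameters$mean,
         sigma = unname(sig), classification = cl, z = fit$z)
  }

  out <- list()
  for (m in parameterizations) {
    cands_m <- list()
    for (k in K) {
      fit <- best_fit(m, k)
      if (is.null(fit)) {
        message("candidate ", m, " K=", k, " discarded (EM failure)")
        next
      }
      cand <- as_candidate(m, k, fit)
      if (!is.null(cand)) cands_m[[length(cands_m) + 1L]] <- cand
    }
    if (!length(cands_m)) next
    if (K_by == "bic") {
      bics <- vapply(cands_m, `[[`, 0, "bic")
      out[[length(out) + 1L]] <- cands_m[[which.max(bics)]]
    } else {
      out <- c(out, cands_m)
    }
  }
  out
}

#' Progression slopes of cluster members at a raw age
#'
#' Derivative of each member's median curve with respect to raw age
#' (points per year), by the chain rule through the age/score
#' standardization.
#'
#' @param medians Matrix (individuals x 4) of quadruplets.
#' @param spec A `"standardization"` object.
#' @param age Raw age (years), scalar or vector.
#' @return Matrix (individuals x length(age)) of raw slopes.
#' @export
raw_slopes <- function(medians, spec, age) {
  t <- standardize_age(spec, age)
  scale <- spec$score_sd / spec$age_sd
  m <- as.matrix(medians)
  s <- (-m[, 1L] * m[, 2L] * exp(-m[, 2L] %o% t) +
        m[, 3L] * m[, 4L] * exp(m[, 4L] %o% t)) * scale
  s
}

# Gaussian KDE evaluated on an explicit grid, Silverman bandwidth with
# a floor of 1e-6 x slope scale (zero-variance guard).
kde_on_grid <- function(x, grid, scale_floor) {
  bw <- if (length(x) >= 2L) stats::bw.nrd0(x) else 0
  bw <- max(bw, 1e-6 * scale_floor, 1e-12)
  f <- vapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = bw)), 0)
  list(grid = grid, density = f, bw = bw)
}

#' Kernel densities of per-cluster progression slopes
#'
#' For each scoring age, the slopes of all cluster members are computed
#' with [raw_slopes()] and smoothed with a Gaussian kernel (Silverman
#' bandwidth, floored); all clusters share a common grid spanning the
#' pooled slope support plus five bandwidths, so densities are directly
#' comparable and integrable against each other.
#'
#' @param medians Matrix (individuals x 4).
#' @param classification Integer cluster labels, one per row of
#'   `medians`.
#' @param spec A `"standardization"` object.
#' @param ages Scoring ages in raw years (default `10:20`).
#' @param n_grid Minimum grid resolution per age (default 512; refined
#'   automatically so the spacing resolves the narrowest bandwidth).
#' @return List with one element per age: a list of per-cluster
#'   `list(grid, density, bw)` entries (named by cluster label).
#' @export
slope_densities <- function(medians, classification, spec, ages = 10:20,
                            n_grid = 512L) {
  medians <- as.matrix(medians)
  stopifnot(nrow(medians) == length(classification))
  clusters <- sort(unique(classification))
  sizes <- vapply(clusters, function(cl) sum(classification == cl), 0L)
  if (any(sizes < 2L))
    stop("each cluster needs at least 2 members for a slope density ",
         "(singleton clusters have no spread to smooth)")
  slopes <- raw_slopes(medians, spec, ages)   # individuals x ages
  out <- vector("list", length(ages))
  names(out) <- as.character(ages)
  for (j in seq_along(ages)) {
    s <- slopes[, j]
    scale_floor <- max(stats::sd(s), 1e-8)
    per <- lapply(clusters, function(cl) s[classification == cl])
    bws <- vapply(per, function(x)
      max(if (length(x) >= 2L) stats::bw.nrd0(x) else 0,
          1e-6 * scale_floor, 1e-12), 0)
    lo <- min(s) - 5 * max(bws); hi <- max(s) + 5 * max(bws)
    # resolve the narrowest kernel: spacing <= min bw / 3 (capped)
    n_pts <- max(n_grid, min(16384L, ceiling((hi - lo) / (min(bws) / 3))))
    grid <- seq(lo, hi, length.out = n_pts)
    out[[j]] <- lapply(per, kde_on_grid, grid = grid,
                       scale_floor = scale_floor)
    names(out[[j]]) <- as.character(clusters)
  }
  out
}

#' Overlap coefficient of two densities on a shared grid
#'
#' \eqn{\int \min(f_1, f_2)\,dx} by the trapezoid rule; 1 for identical
#' densities, 0 for disjoint supports.
#'
#' @param grid Increasing numeric grid.
#' @param f1,f2 Density values on `grid`.
#' @return Scalar in `[0, 1]` (up to quadrature error).
#' @export
overlap_coefficient <- function(grid, f1, f2) {
  m <- pmin(f1, f2)
  sum(diff(grid) * (m[-length(m)] + m[-1L]) / 2)
}

#' Overlap score of a clustering on slope densities
#'
#' The model-selection criterion: the mean, over scoring ages and over
#' all cluster pairs, of the overlap coefficient between the two
#' clusters' slope densities. Lower means more distinct progression
#' typologies. Normalized by the number of (age, pair) terms so scores
#' are in `[0, 1]` and comparable across K.
#'
#' @inheritParams slope_densities
#' @return Scalar overlap score in `[0, 1]`.
#' @export
overlap_score <- function(medians, classification, spec, ages = 10:20,
                          n_grid = 512L) {
  clusters <- sort(unique(classification))
  if (length(clusters) < 2L)
    stop("overlap score undefined for a single cluster")
  dens <- slope_densities(medians, classification, spec, ages, n_grid)
  total <- 0; n_terms <- 0L
  for (da in dens) {
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        total <- total + overlap_coefficient(da[[i]]$grid, da[[i]]$density,
                                             da[[j]]$density)
        n_terms <- n_terms + 1L
      }
    }
  }
  total / n_terms
}

#' Select the mixture model with the lowest overlap score
#'
#' @param candidates List of candidates carrying an `overlap_score`
#'   element (see [cluster_progressions()]).
#' @return The winning candidate: lowest overlap score, ties broken by
#'   fewer free parameters, then smaller K.
#' @export
select_model <- function(candidates) {
  stopifnot(length(candidates) >= 1L)
  scores <- vapply(candidates, `[[`, 0, "overlap_score")
  npar <- vapply(candidates, `[[`, 0, "n_params")
  k <- vapply(candidates, function(x) as.numeric(x$K), 0)
  candidates[[order(scores, npar, k)[1L]]]
}

#' Cluster individuals into progression typologies
#'
#' Fits Gaussian mixtures over the covariance parameterization family to
#' the per-individual median quadruplets, scores every converged
#' candidate with the slope-density [overlap_score()], and selects the
#' candidate with the lowest score. By default the number of components
#' of each candidate is chosen by BIC within its parameterization (see
#' [fit_mixture_family()]), so the overlap score arbitrates between the
#' covariance structures; `K_by = "overlap"` lets it arbitrate over K as
#' well. Unequal cluster sizes are natural: the mixture weights are
#' free. Candidates assigning fewer than two members to some cluster
#' cannot be slope-scored (a singleton has no spread to smooth) and are
#' dropped from the ranking.
#'
#' @param fit A `"potential_fit"`, or a matrix (individuals x 4) of
#'   median quadruplets (then `spec` is required).
#' @param K Candidate component counts (default `2:8`).
#' @param parameterizations Covariance structures (default all 14).
#' @param ages Scoring ages for the overlap score (default `10:20`).
#' @param spec Standardization, only when `fit` is a matrix.
#' @param K_by How K is selected; see [fit_mixture_family()].
#' @return An object of class `"progression_clusters"`: list with
#'   `selected` (winning candidate), `candidates` (data frame of scores
#'   for every converged candidate), `classification` (named integer
#'   vector), `medians`, `spec`, `ages`.
#' @export
cluster_progressions <- function(fit, K = 2:8, parameterizations = NULL,
                                 ages = 10:20, spec = NULL,
                                 K_by = c("bic", "overlap")) {
  if (inherits(fit, "potential_fit")) {
    medians <- median_params(fit)
    spec <- fit$standardization
  } else {
    medians <- as.matrix(fit)
    stopifnot(!is.null(spec))
  }
  cands <- fit_mixture_family(medians, K, parameterizations, K_by = K_by)
  if (!length(cands)) stop("no mixture candidate converged")
  keep <- logical(length(cands))
  for (i in seq_along(cands)) {
    sc <- tryCatch(overlap_score(medians, cands[[i]]$classification, spec,
                                 ages),
                   error = function(e) NA_real_)
    cands[[i]]$overlap_score <- sc
    keep[i] <- is.finite(sc)
  }
  cands <- cands[keep]
  if (!length(cands)) stop("no mixture candidate could be scored")
  selected <- select_model(cands)
  tab <- data.frame(
    parameterization = vapply(cands, `[[`, "", "parameterization"),
    K = vapply(cands, function(x) as.integer(x$K), 0L),
    loglik = vapply(cands, `[[`, 0, "loglik"),
    bic = vapply(cands, `[[`, 0, "bic"),
    n_params = vapply(cands, `[[`, 0, "n_params"),
    overlap_score = vapply(cands, `[[`, 0, "overlap_score"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$overlap_score, tab$n_params, tab$K), ]
  rownames(tab) <- NULL
  cl <- selected$classification
  names(cl) <- rownames(medians)
  structure(list(selected = selected, candidates = tab,
                 classification = cl, medians = medians, spec = spec,
                 ages = ages),
            class = "progression_clusters")
}

#' @export
print.progression_clusters <- function(x, ...) {
  s <- x$selected
  cat(sprintf(
    "Progression typologies: %s mixture, K = %d (overlap score %.4f)\n",
    s$parameterization, s$K, s$overlap_score))
  cat("cluster sizes:", paste(tabulate(x$classification, nbins = s$K),
                              collapse = ", "), "\n")
  cat(sprintf("%d candidates scored; next best: %s K=%d (%.4f)\n",
              nrow(x$candidates),
              x$candidates$parameterization[2L], x$candidates$K[2L],
              x$candidates$overlap_score[2L]))
  invisible(x)
}

#' Plot mean progression curves and slopes per typology
#'
#' Two panels: the mean potential curve of each cluster (raw points vs
#' age) and the mean progression slope (points per year).
#'
#' @param x A `"progression_clusters"`.
#' @param ages Raw-age grid (default the scoring span in 0.1 steps).
#' @param ... Ignored.
#' @export
plot.progression_clusters <- function(x, ages = NULL, ...) {
  if (is.null(ages)) ages <- seq(min(x$ages), max(x$ages), by = 0.1)
  K <- x$selected$K
  cols <- grDevices::hcl.colors(K, "Dark 3")
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  t <- standardize_age(x$spec, ages)
  curves <- lapply(seq_len(K), function(k) {
    m <- colMeans(x$medians[x$classification == k, , drop = FALSE])
    destandardize_score(x$spec, moore_eval(moore(m[1], m[2], m[3], m[4]), t))
  })
  graphics::matplot(ages, do.call(cbind, curves), type = "l", lty = 1,
                    col = cols, xlab = "age (years)", ylab = "points",
                    main = "Mean trajectory per typology")
  graphics::legend("topright", legend = paste("cluster", seq_len(K)),
                   col = cols, lty = 1, cex = 0.8)
  slopes <- lapply(seq_len(K), function(k) {
    s <- raw_slopes(x$medians[x$classification == k, , drop = FALSE],
                    x$spec, ages)
    colMeans(s)
  })
  graphics::matplot(ages, do.call(cbind, slopes), type = "l", lty = 1,
                    col = cols, xlab = "age (years)",
                    ylab = "slope (points / year)",
                    main = "Mean progression slope")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Write the cluster report
#'
#' @param clusters A `"progression_clusters"`.
#' @param path Output CSV path (`individual_id, assigned_cluster, a, b,
#'   c, d`); a JSON model card (parameterization, K, weights, means,
#'   overlap score, candidate table) is written as `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- data.frame(individual_id = names(clusters$classification),
                   assigned_cluster = as.integer(clusters$classification),
                   clusters$medians, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  s <- clusters$selected
  card <- list(parameterization = s$parameterization, K = s$K,
               weights = s$weights, means = s$means,
               overlap_score = s$overlap_score,
               candidates = clusters$candidates)
  jsonlite::write_json(card, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
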
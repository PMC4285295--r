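## PCA-based prior- and posterior-predictive adequacy checks -------------

## is `pt` inside (or on the boundary of) the convex hull of `pts` (2D)?
point_in_hull2d <- function(pt, pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3) {
    rng1 <- range(pts[, 1]); rng2 <- range(pts[, 2])
    return(pt[1] >= rng1[1] && pt[1] <= rng1[2] &&
           pt[2] >= rng2[1] && pt[2] <= rng2[2])
  }
  h <- chull(pts)
  v <- pts[h, , drop = FALSE]
  m <- nrow(v)
  eps <- 1e-9 * max(abs(v), 1)
  crosses <- vapply(seq_len(m), function(i) {
    a <- v[i, ]; b <- v[if (i == m) 1 else i + 1, ]
    (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
  }, 0)
  # inside iff the point is on the same side of every hull edge
  all(crosses >= -eps) || all(crosses <= eps)
}

pca_check <- function(stats, observed, model = NULL, n_components = 2L) {
  sd0 <- apply(stats, 2, sd)
  keep <- sd0 > 0
  if (!any(keep)) stop("all statistics are constant; no PCA possible")
  z <- scale(stats[, keep, drop = FALSE])
  nc <- min(n_components, ncol(z), nrow(z) - 1)
  if (nc < n_components)
    warning("fewer usable dimensions than requested components; truncating to ", nc)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  zo <- (observed[keep] - attr(z, "scaled:center")) / attr(z, "scaled:scale")
  so <- as.numeric(zo %*% pc$rotation[, seq_len(nc), drop = FALSE])

  per_cloud <- function(sc) {
    inside <- if (ncol(sc) >= 2) point_in_hull2d(so[1:2], sc[, 1:2, drop = FALSE])
              else so[1] >= min(sc[, 1]) && so[1] <= max(sc[, 1])
    S <- stats::cov(sc)
    d_sims <- mahalanobis(sc, colMeans(sc), S)
    d_obs <- mahalanobis(matrix(so, 1), colMeans(sc), S)
    list(inside = inside, percentile = 100 * mean(d_sims <= d_obs))
  }
  pooled <- per_cloud(scores)
  by_model <- NULL
  if (!is.null(model)) {
    by_model <- lapply(split(seq_len(nrow(scores)), model), function(ix) {
      if (length(ix) < 3) return(list(inside = NA, percentile = NA_real_))
      per_cloud(scores[ix, , drop = FALSE])
    })
  }
  structure(list(loadings = pc$rotation[, seq_len(nc), drop = FALSE],
                 sdev = pc$sdev[seq_len(nc)],
                 scores = scores, observed_score = so,
                 model = model,
                 inside = pooled$inside, percentile = pooled$percentile,
                 by_model = by_model, n_components = nc),
            class = "abc_pca_check")
}

#' Prior-predictive adequacy check by PCA of summary statistics
#'
#' Standardizes the table's statistics, extracts the leading principal
#' components and projects the observed vector onto them. The check is
#' reported two ways: whether the observed point lies inside the convex
#' region covered by the simulations on the two leading components, and
#' the Mahalanobis-distance percentile of the observed point in the
#' leading-component subspace (pooled over models and, when the table is
#' multi-model, per model).
#'
#' @param table a `reference_table`.
#' @param observed statistic vector matching the table's configuration.
#' @param n_components leading components used for the Mahalanobis
#'   percentile.
#' @return an object of class `abc_pca_check` with `loadings`, `scores`,
#'   `observed_score`, an `inside` indicator, a `percentile`, and a
#'   `by_model` list.
#' @export
prior_predictive_check <- function(table, observed, n_components = 2L) {
  stopifnot(inherits(table, "reference_table"))
  if (nrow(table$stats) == 0) stop("empty reference table")
  obs <- check_observed(observed, table)
  pca_check(table$stats, obs, model = table$model, n_components = n_components)
}

#' Posterior-predictive adequacy check
#'
#' Re-simulates datasets at (model, parameter) combinations resampled
#' (with the rejection kernel weights, with replacement) from the
#' accepted set, computes their statistics, and runs the same PCA check
#' as [prior_predictive_check()] against the observed vector, per model
#' represented in the accepted set and pooled.
#'
#' @param accepted an [abc_reject()] result.
#' @param table the `reference_table` it came from (must carry the
#'   sampling design; its rows supply the parameter combinations).
#' @param observed the observed statistic vector.
#' @param n_sims number of posterior-predictive simulations.
#' @param seed integer seed.
#' @param n_components leading components for the check.
#' @return an `abc_pca_check` (pooled; per-model results in `by_model`).
#' @export
posterior_predictive_check <- function(accepted, table, observed,
                                       n_sims = 1001L, seed = 1L,
                                       n_components = 2L) {
  stopifnot(inherits(accepted, "abc_rejection"), inherits(table, "reference_table"))
  if (!length(accepted$indices)) stop("empty accepted set")
  if (is.null(table$config)) stop("the table must carry its sampling design")
  obs <- check_observed(observed, table)
  w <- accepted$weights
  if (sum(w) <= 0) w <- rep(1, length(w))
  set.seed(derive_seed(seed, 13L))
  pick <- sample(accepted$indices, n_sims, replace = TRUE, prob = w / sum(w))
  sc <- table$stat_config
  stats <- matrix(NA_real_, n_sims, length(stat_names(sc)),
                  dimnames = list(NULL, stat_names(sc)))
  labs <- character(n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(derive_seed(seed, 17L, i))
    mod <- as.character(table$model[pick[i]])
    pars <- table$params[pick[i], , drop = FALSE]
    pars <- pars[, !is.na(pars[1, ]), drop = FALSE]
    amode <- if (!is.null(table$priors)) table$priors$admixture_mode
             else if ("F" %in% names(pars)) "pulse" else "continuous_window"
    plan <- build_demography(model_spec(mod, amode), pars)
    stats[i, ] <- simulate_stats(plan, table$config, pars$theta, sc)
    labs[i] <- mod
  }
  pca_check(stats, obs, model = factor(labs), n_components = n_components)
}

#' @export
print.abc_pca_check <- function(x, ...) {
  cat(sprintf("PCA adequacy check (%d components)\n", x$n_components))
  cat(sprintf("  observed inside simulated cloud (2 leading PCs): %s\n",
              x$inside))
  cat(sprintf("  Mahalanobis percentile of observed point: %.1f\n", x$percentile))
  if (!is.null(x$by_model)) {
    for (m in names(x$by_model))
      cat(sprintf("    model %s: inside = %s, percentile = %.1f\n",
                  m, x$by_model[[m]]$inside, x$by_model[[m]]$percentile))
  }
  invisible(x)
}

#' @export
plot.abc_pca_check <- function(x, ...) {
  if (ncol(x$scores) < 2) stop("need at least two components to plot")
  cols <- if (!is.null(x$model)) as.integer(factor(x$model)) else 1
  plot(x$scores[, 1], x$scores[, 2], col = cols, pch = 16, cex = 0.4,
       xlab = "PC1", ylab = "PC2", ...)
  points(x$observed_score[1], x$observed_score[2], pch = 8, cex = 2, col = "red")
  invisible(x)
}
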
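# Parametric empirical-Bayes batch correction (ComBat), batch-only design.
#
# Model per gene g, batch i, sample j:  x_gij = alpha_g + gamma_ig +
# delta_ig * eps_gij.  Genes are standardized with the pooled variance,
# per-batch location (gamma) and scale (delta^2) estimates are shrunk
# toward normal / inverse-gamma priors fitted across genes by the method of
# moments, and the shrunken effects are removed. Fully deterministic.

# moment estimators of the inverse-gamma prior on delta^2; the variance is
# floored so that an (exactly) constant delta^2 across genes degenerates to
# a point-mass prior instead of dividing by zero
ig_aprior <- function(d2) {
  m <- mean(d2); s2 <- max(stats::var(d2), 1e-12)
  (2 * s2 + m^2) / s2
}
ig_bprior <- function(d2) {
  m <- mean(d2); s2 <- max(stats::var(d2), 1e-12)
  (m * s2 + m^3) / s2
}

eb_postmean <- function(g_hat, g_bar, n, d_star, t2) {
  (t2 * n * g_hat + d_star * g_bar) / (t2 * n + d_star)
}
eb_postvar <- function(sum2, n, a, b) {
  (0.5 * sum2 + b) / (n / 2 + a - 1)
}

# fixed-point iteration for the EB-shrunken per-gene location/scale of one
# batch; tolerance on the max relative change, warning on non-convergence
eb_iterate <- function(z_batch, g_hat, d_hat, g_bar, t2, a, b,
                       tol = 1e-4, max_iter = 100L) {
  n <- ncol(z_batch)
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- eb_postmean(g_hat, g_bar, n, d_old, t2)
    sum2 <- rowSums((z_batch - g_new)^2)
    d_new <- eb_postvar(sum2, n, a, b)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / abs(d_old))
    g_old <- g_new
    d_old <- d_new
    if (change < tol) {
      return(list(gamma_star = g_new, delta_star = d_new, iterations = it))
    }
  }
  warning("ComBat EB iteration did not converge in ", max_iter,
          " iterations; using last iterate", call. = FALSE)
  list(gamma_star = g_old, delta_star = d_old, iterations = max_iter)
}

#' ComBat empirical-Bayes batch correction
#'
#' Adjusts a merged expression matrix for additive and multiplicative
#' batch effects using the parametric empirical-Bayes location/scale
#' model: per-gene batch means and variances are estimated, shrunk across
#' genes toward a normal (location) and inverse-gamma (scale) prior fitted
#' by the method of moments, and removed. Batch is the only covariate.
#'
#' @param matrix a [tx_matrix()] of merged log-scale data (genes x
#'   samples).
#' @param batch integer or factor batch label per column; every batch
#'   needs at least two samples.
#' @param eb use empirical-Bayes shrinkage (`TRUE`, default) or the raw
#'   per-batch estimates (`FALSE`, useful for diagnostics).
#' @param tol,max_iter fixed-point iteration control.
#' @return a `tx_integrated` object (method `"combat"`); the corrected
#'   matrix keeps the input's scale tag.
#' @export
combat_integration <- function(matrix, batch, eb = TRUE, tol = 1e-4,
                               max_iter = 100L) {
  x <- unclass(matrix)
  if (nrow(x) < 2L) stop("ComBat needs >= 2 genes", call. = FALSE)
  batch <- as.integer(factor(batch)) - 1L
  batches <- sort(unique(batch))
  if (length(batches) < 2L) stop("ComBat needs >= 2 batches", call. = FALSE)
  n_b <- vapply(batches, function(b) sum(batch == b), integer(1))
  if (any(n_b < 2L)) {
    stop("every batch needs >= 2 samples (got: ",
         paste(n_b, collapse = ", "), ")", call. = FALSE)
  }
  n <- ncol(x)
  cols <- lapply(batches, function(b) which(batch == b))

  # grand mean = sample-size weighted mean of batch means; pooled variance
  # of residuals about the batch means with the unbiased ANOVA divisor
  # n - B, so data whose per-batch gene variances all equal the pooled
  # variance standardize to exactly unit per-batch variance
  batch_means <- vapply(cols, function(j) rowMeans(x[, j, drop = FALSE]),
                        numeric(nrow(x)))
  grand_mean <- as.numeric(batch_means %*% (n_b / n))
  resid <- x - batch_means[, batch + 1L, drop = FALSE]
  var_pooled <- rowSums(resid^2) / (n - length(batches))
  var_pooled <- pmax(var_pooled, 1e-18)
  z <- (x - grand_mean) / sqrt(var_pooled)

  corrected <- z
  estimates <- vector("list", length(batches))
  for (k in seq_along(batches)) {
    j <- cols[[k]]
    zb <- z[, j, drop = FALSE]
    g_hat <- rowMeans(zb)
    d_hat <- apply(zb, 1L, stats::var)
    d_hat <- pmax(d_hat, 1e-18)
    if (eb) {
      g_bar <- mean(g_hat)
      t2 <- max(stats::var(g_hat), 1e-12)
      a <- ig_aprior(d_hat)
      b <- ig_bprior(d_hat)
      sol <- eb_iterate(zb, g_hat, d_hat, g_bar, t2, a, b,
                        tol = tol, max_iter = max_iter)
      g_star <- sol$gamma_star
      d_star <- sol$delta_star
    } else {
      g_star <- g_hat
      d_star <- d_hat
    }
    corrected[, j] <- (zb - g_star) / sqrt(d_star)
    estimates[[k]] <- list(gamma_hat = g_hat, delta_hat = d_hat,
                           gamma_star = g_star, delta_star = d_star)
  }
  corrected <- corrected * sqrt(var_pooled) + grand_mean

  out <- new_integrated(corrected, tx_scale(matrix), NULL, batch, "combat")
  out$eb_estimates <- estimates
  out
}
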
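# Cross-platform normalization (XPN). Genes and samples are clustered into
# blocks on the combined standardized data; within each platform the block
# model
#     x_gs = A[alpha(g), beta(s)] * b_g + c_g + sigma_g * eps_gs
# is fitted by alternating least squares, and the platform-specific block
# parameters A, b, c, sigma are replaced by their sample-size-weighted
# cross-platform averages before reconstruction. The whole procedure is
# repeated over several random clusterings and the reconstructions
# averaged.

count_distinct_rows <- function(m) sum(!duplicated(round(m, 10)))

# joint k-means of the combined samples; every cluster must be non-empty in
# both platforms, retrying with fresh starts and falling back to fewer
# clusters when necessary
cluster_samples_joint <- function(z_combined, n1, L, max_retry = 30L) {
  S <- ncol(z_combined)
  pts <- t(z_combined)
  L <- min(L, count_distinct_rows(pts))
  platform <- rep(c(1L, 2L), c(n1, S - n1))
  while (L > 1L) {
    for (r in seq_len(max_retry)) {
      km <- suppressWarnings(stats::kmeans(pts, centers = L, iter.max = 50L,
                                           nstart = 1L))
      tab <- table(factor(km$cluster, levels = seq_len(L)), platform)
      if (all(tab > 0L)) return(km$cluster)
    }
    L <- L - 1L
  }
  rep(1L, S)
}

cluster_genes <- function(z_combined, K) {
  K <- min(K, count_distinct_rows(z_combined))
  if (K <= 1L || nrow(z_combined) <= K) {
    if (nrow(z_combined) <= K) return(seq_len(nrow(z_combined)))
    return(rep(1L, nrow(z_combined)))
  }
  suppressWarnings(stats::kmeans(z_combined, centers = K, iter.max = 50L,
                                 nstart = 1L))$cluster
}

# alternating-least-squares fit of the block model within one platform.
# Identifiability: block rows of A are centered (weighted by cluster size,
# absorbed into c) and b has RMS 1 within each gene cluster with positive
# cluster sum.
xpn_fit_platform <- function(x, gene_cl, sample_cl, L = max(sample_cl),
                             tol = 1e-8, max_iter = 100L) {
  G <- nrow(x); S <- ncol(x)
  K <- max(gene_cl)
  n_l <- vapply(seq_len(L), function(l) sum(sample_cl == l), numeric(1))
  w_l <- n_l / S
  # per-gene cluster means over each sample cluster
  M <- vapply(seq_len(L), function(l) {
    j <- which(sample_cl == l)
    if (length(j) == 0L) return(rep(0, G))
    rowMeans(x[, j, drop = FALSE])
  }, numeric(G))
  present <- n_l > 0

  b <- rep(1, G)
  c_g <- rowMeans(x)
  A <- matrix(0, K, L)
  gene_groups <- split(seq_len(G), gene_cl)

  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    # A update (per block)
    for (k in seq_len(K)) {
      g <- gene_groups[[k]]
      denom <- sum(b[g]^2)
      if (denom < 1e-12) { A[k, ] <- 0; next }
      A[k, present] <- colSums(b[g] * (M[g, present, drop = FALSE] -
                                         c_g[g])) / denom
    }
    # center A rows (weighted), compensate in c
    rowc <- as.numeric(A %*% w_l)
    A <- A - rowc
    c_g <- c_g + b * rowc[gene_cl]
    # b update (per gene)
    Ag <- A[gene_cl, , drop = FALSE]
    num <- rowSums(sweep((M - c_g) * Ag, 2L, n_l, `*`))
    den <- rowSums(sweep(Ag^2, 2L, n_l, `*`))
    b <- ifelse(den < 1e-12, 0, num / den)
    # rescale per gene cluster so b has RMS 1, positive sum
    for (k in seq_len(K)) {
      g <- gene_groups[[k]]
      f <- sqrt(mean(b[g]^2))
      if (f > 1e-12) {
        b[g] <- b[g] / f
        A[k, ] <- A[k, ] * f
      }
      if (sum(b[g]) < 0) {
        b[g] <- -b[g]
        A[k, ] <- -A[k, ]
      }
    }
    # c update
    Ag <- A[gene_cl, , drop = FALSE]
    c_g <- rowMeans(x) - b * as.numeric(Ag %*% w_l)
    fit_M <- Ag * b + c_g
    obj <- sum(sweep((M - fit_M)^2, 2L, n_l, `*`))
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol * (abs(obj_old) + 1e-12)) break
    obj_old <- obj
  }
  Ag <- A[gene_cl, , drop = FALSE]
  fit <- Ag[, sample_cl, drop = FALSE] * b + c_g
  resid <- x - fit
  sigma <- sqrt(rowSums(resid^2) / max(S - 1L, 1L))
  list(A = A, b = b, c = c_g, sigma = sigma, fit = fit, resid = resid)
}

#' XPN cross-platform block normalization
#'
#' Pairwise integration of two platforms on their shared genes. Genes and
#' (jointly) samples are clustered by k-means on the combined
#' row-standardized data; a block-linear model is fitted per platform and
#' its parameters replaced by their sample-size-weighted cross-platform
#' averages before reconstructing each platform. The procedure is averaged
#' over `n_repeats` random clusterings and is deterministic given `seed`.
#'
#' @param matrix_a,matrix_b [tx_matrix()] objects on a shared gene
#'   namespace, each with at least 2 samples.
#' @param n_gene_clusters,n_sample_clusters k-means block counts; clamped
#'   to half the available genes/samples with a warning when inputs are
#'   small.
#' @param n_repeats number of random clusterings averaged.
#' @param seed integer seed.
#' @return a `tx_integrated` object (method `"xpn"`).
#' @export
xpn_integration <- function(matrix_a, matrix_b, n_gene_clusters = 25L,
                            n_sample_clusters = 5L, n_repeats = 30L,
                            seed = 1L) {
  if (ncol(matrix_a) < 2L || ncol(matrix_b) < 2L) {
    stop("xpn needs >= 2 samples in each platform", call. = FALSE)
  }
  merged <- merge_matrices(list(matrix_a, matrix_b))
  x <- unclass(merged$matrix)
  n1 <- ncol(matrix_a)
  n2 <- ncol(matrix_b)
  G <- nrow(x)

  K <- n_gene_clusters
  L <- n_sample_clusters
  max_K <- max(1L, G %/% 2L)
  max_L <- max(1L, min(n1, n2) %/% 2L)
  if (K > max_K) {
    warning("clamping gene clusters from ", K, " to ", max_K, call. = FALSE)
    K <- max_K
  }
  if (L > max_L) {
    warning("clamping sample clusters from ", L, " to ", max_L,
            call. = FALSE)
    L <- max_L
  }

  x1 <- x[, seq_len(n1), drop = FALSE]
  x2 <- x[, n1 + seq_len(n2), drop = FALSE]
  z1 <- standardize_rows(x1)
  z2 <- standardize_rows(x2)
  z <- cbind(z1, z2)
  w1 <- n1 / (n1 + n2)
  w2 <- n2 / (n1 + n2)

  acc <- matrix(0, G, n1 + n2)
  for (r in seq_len(n_repeats)) {
    set.seed((seed + 104729L * r) %% .Machine$integer.max)
    gene_cl <- cluster_genes(z, K)
    sample_cl <- cluster_samples_joint(z, n1, L)
    gene_cl <- as.integer(factor(gene_cl))
    sample_cl <- as.integer(factor(sample_cl))

    L_eff <- max(sample_cl)
    fit1 <- xpn_fit_platform(x1, gene_cl, sample_cl[seq_len(n1)], L = L_eff)
    fit2 <- xpn_fit_platform(x2, gene_cl, sample_cl[n1 + seq_len(n2)],
                             L = L_eff)

    # sign-align the platform-specific b vectors per gene cluster before
    # averaging (the block model is invariant to a joint sign flip)
    for (k in seq_len(max(gene_cl))) {
      g <- which(gene_cl == k)
      if (sum(fit1$b[g] * fit2$b[g]) < 0) {
        fit2$b[g] <- -fit2$b[g]
        fit2$A[k, ] <- -fit2$A[k, ]
      }
    }

    A_bar <- w1 * fit1$A + w2 * fit2$A
    b_bar <- w1 * fit1$b + w2 * fit2$b
    c_bar <- w1 * fit1$c + w2 * fit2$c
    s_bar <- sqrt(w1 * fit1$sigma^2 + w2 * fit2$sigma^2)

    recon <- function(fit, s_cl) {
      eps <- fit$resid / ifelse(fit$sigma < 1e-12, 1, fit$sigma)
      eps[fit$sigma < 1e-12, ] <- 0
      A_bar[gene_cl, , drop = FALSE][, s_cl, drop = FALSE] * b_bar +
        c_bar + s_bar * eps
    }
    acc <- acc + cbind(recon(fit1, sample_cl[seq_len(n1)]),
                       recon(fit2, sample_cl[n1 + seq_len(n2)]))
  }
  out <- acc / n_repeats
  dimnames(out) <- dimnames(x)
  new_integrated(out, tx_scale(merged$matrix), NULL, merged$batch, "xpn")
}
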
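# Synthetic benchmark of the integration algorithms: simulate microarray-
# and NGS-like datasets with known DEGs, randomly partition into two
# halves, integrate, call DEGs with a moderated t-test and score by
# ROC/AUC against the simulated truth.

#' Convert counts to log2 counts per million
#'
#' `log2((x + 0.5) / (libsize + 1) * 1e6)`, the usual light-touch
#' transform that moves negative-binomial counts onto an approximately
#' Gaussian log scale before the integration algorithms and the moderated
#' t-test.
#'
#' @param matrix a [tx_matrix()] with scale `"linear_count"`.
#' @return a [tx_matrix()] with scale `"log2_cpm"`.
#' @export
cpm_log2 <- function(matrix) {
  if (tx_scale(matrix) != "linear_count") return(matrix)
  x <- unclass(matrix)
  lib <- colSums(x)
  out <- log2(t((t(x) + 0.5) / (lib + 1)) * 1e6)
  dimnames(out) <- dimnames(x)
  tx_matrix(out, scale = "log2_cpm")
}

make_sim <- function(values, scale, condition, truth_ids, truth_dir) {
  list(matrix = tx_matrix(values, scale = scale),
       condition = condition,
       truth = data.frame(gene = truth_ids, direction = truth_dir,
                          stringsAsFactors = FALSE))
}

de_assignment <- function(n_genes, frac_de) {
  n_de <- round(frac_de * n_genes)
  n_up <- ceiling(n_de / 2)
  idx <- seq_len(n_de)  # first n_de genes are DE; ids carry no information
  list(idx = idx,
       dir = c(rep("up", n_up), rep("down", n_de - n_up)))
}

#' Simulate a microarray-like expression dataset with known DEGs
#'
#' Gaussian log2-intensity model: per-gene baselines are drawn from
#' Normal(7, 1.5); `round(frac_de * n_genes)` genes (half up, half down)
#' receive a group-mean offset of magnitude `|Normal(0, lfc_sd)|` clamped
#' at 0.5 or more; independent per-sample noise is Normal(0, noise_sd).
#'
#' @param n_genes,n_per_group,frac_de,lfc_sd,noise_sd generator parameters.
#' @param seed integer seed; the generator is deterministic given it.
#' @return a simulated dataset: list with `matrix` (a [tx_matrix()]),
#'   `condition` (named vector, `"case"`/`"control"` per sample) and
#'   `truth` (data frame of DE gene ids with `direction`).
#' @export
simulate_microarray <- function(n_genes = 10000L, n_per_group = 7L,
                                frac_de = 0.1, lfc_sd = 1.0,
                                noise_sd = 0.5, seed = 1L) {
  stopifnot(n_genes > 0, n_per_group > 0, frac_de >= 0, frac_de <= 1,
            lfc_sd > 0, noise_sd > 0)
  set.seed(seed)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  n <- 2L * n_per_group
  samples <- sprintf("S%02d", seq_len(n))
  condition <- stats::setNames(
    rep(c("case", "control"), each = n_per_group), samples)

  baseline <- stats::rnorm(n_genes, mean = 7, sd = 1.5)
  de <- de_assignment(n_genes, frac_de)
  offset <- numeric(n_genes)
  if (length(de$idx) > 0L) {
    mag <- pmax(abs(stats::rnorm(length(de$idx), 0, lfc_sd)), 0.5)
    offset[de$idx] <- ifelse(de$dir == "up", mag, -mag)
  }
  means <- matrix(baseline, n_genes, n)
  means[, condition == "case"] <- means[, condition == "case"] + offset
  values <- means + matrix(stats::rnorm(n_genes * n, 0, noise_sd),
                           n_genes, n)
  dimnames(values) <- list(genes, samples)
  make_sim(values, "log2_intensity", condition, genes[de$idx], de$dir)
}

#' Simulate an NGS-like count dataset with known DEGs
#'
#' Negative-binomial count model: per-gene means are log-normal with
#' median about 100; per-gene dispersions are Gamma-distributed around
#' 0.2; DE genes have their case-group mean multiplied (up) or divided
#' (down) by `effect`.
#'
#' @param n_genes,n_per_group,frac_de,effect generator parameters;
#'   `effect` must exceed 1.
#' @param dispersion_mean mean of the Gamma-distributed per-gene NB
#'   dispersions.
#' @param seed integer seed.
#' @return a simulated dataset as in [simulate_microarray()], scale tag
#'   `"linear_count"`.
#' @export
simulate_counts <- function(n_genes = 12500L, n_per_group = 7L,
                            frac_de = 0.1, effect = 1.5,
                            dispersion_mean = 0.2, seed = 1L) {
  stopifnot(n_genes > 0, n_per_group > 0, frac_de >= 0, frac_de <= 1,
            effect > 1, dispersion_mean > 0)
  set.seed(seed)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  n <- 2L * n_per_group
  samples <- sprintf("S%02d", seq_len(n))
  condition <- stats::setNames(
    rep(c("case", "control"), each = n_per_group), samples)

  mu <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1)
  phi <- stats::rgamma(n_genes, shape = 4, scale = dispersion_mean / 4)
  de <- de_assignment(n_genes, frac_de)
  fold <- rep(1, n_genes)
  if (length(de$idx) > 0L) {
    fold[de$idx] <- ifelse(de$dir == "up", effect, 1 / effect)
  }
  mu_mat <- matrix(mu, n_genes, n)
  mu_mat[, condition == "case"] <- mu_mat[, condition == "case"] * fold
  values <- matrix(
    stats::rnbinom(n_genes * n, mu = as.vector(mu_mat),
                   size = rep(1 / phi, n)),
    n_genes, n)
  dimnames(values) <- list(genes, samples)
  make_sim(values, "linear_count", condition, genes[de$idx], de$dir)
}

#' Randomly split a simulated dataset into two halves
#'
#' Samples are shuffled and split floor(n/2) / ceiling(n/2), stratified by
#' condition so both halves keep both conditions. Both halves keep every
#' gene and inherit the DEG truth.
#'
#' @param dataset a simulated dataset.
#' @param seed integer seed.
#' @return list of two simulated datasets.
#' @export
random_partition <- function(dataset, seed = 1L) {
  cond <- dataset$condition
  tab <- table(cond)
  if (any(tab < 2L)) {
    stop("each condition needs >= 2 samples to partition", call. = FALSE)
  }
  set.seed(seed)
  # per-condition floor(n_c/2), topping up from odd-sized conditions so the
  # two halves have floor(n/2) and ceiling(n/2) samples overall
  take <- tab %/% 2L
  leftover <- sum(tab) %/% 2L - sum(take)
  if (leftover > 0L) {
    odd <- names(tab)[tab %% 2L == 1L]
    take[odd[seq_len(leftover)]] <- take[odd[seq_len(leftover)]] + 1L
  }
  ids_a <- character(0)
  for (lev in names(tab)) {
    ids <- sample(names(cond)[cond == lev])
    ids_a <- c(ids_a, ids[seq_len(take[[lev]])])
  }
  all_ids <- sample_ids(dataset$matrix)
  in_a <- all_ids %in% ids_a
  half <- function(keep) {
    list(matrix = dataset$matrix[, keep, drop = FALSE],
         condition = cond[all_ids[keep]],
         truth = dataset$truth)
  }
  list(half(in_a), half(!in_a))
}

# limma-style Newton inversion of the trigamma function
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Moderated t-test for two-group differential expression
#'
#' Per-gene two-sample comparison with empirical-Bayes variance
#' moderation: residual variances are shrunk toward a prior variance
#' `s0^2` with prior degrees of freedom `d0`, both estimated across genes
#' by the method of moments on `log s_g^2` (digamma/trigamma inversion).
#' Count matrices are converted to log2-CPM first.
#'
#' @param matrix a [tx_matrix()].
#' @param condition vector of two group labels, named by sample id or
#'   aligned with the matrix columns; the first level (alphabetical, or
#'   factor order) minus the second defines the sign of the fold change.
#' @param d0_override force the prior degrees of freedom (0 recovers the
#'   ordinary pooled two-sample t-test); `NULL` estimates them.
#' @return data frame (class `tx_deg`) with columns `gene`, `lfc`, `t`,
#'   `p`, plus attributes `d0` and `s0_2`.
#' @export
moderated_t_test <- function(matrix, condition, d0_override = NULL) {
  matrix <- cpm_log2(matrix)
  x <- unclass(matrix)
  if (!is.null(names(condition))) {
    condition <- condition[colnames(x)]
  }
  f <- factor(condition)
  if (nlevels(f) != 2L) stop("need exactly two condition levels",
                             call. = FALSE)
  g1 <- which(f == levels(f)[1L])
  g2 <- which(f == levels(f)[2L])
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples",
                               call. = FALSE)

  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  lfc <- m1 - m2
  ss1 <- rowSums((x[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, g2, drop = FALSE] - m2)^2)
  d_g <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / d_g

  if (is.null(d0_override)) {
    # method of moments on log s^2 (Fisher's log-variance distribution)
    s2f <- pmax(s2, 1e-12)
    e_g <- log(s2f) - digamma(d_g / 2) + log(d_g / 2)
    e_bar <- mean(e_g)
    n <- length(e_g)
    evar <- stats::var(e_g) * (n - 1) / n - trigamma(d_g / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- 1e6  # effectively equal variances across genes
      s0_2 <- exp(e_bar)
    }
  } else {
    d0 <- d0_override
    s0_2 <- if (d0 > 0) mean(s2) else 0
  }
  d0 <- min(d0, 1e6)
  s2_mod <- (d0 * s0_2 + d_g * s2) / (d0 + d_g)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(t_stat), df = d0 + d_g)
  out <- data.frame(gene = rownames(x), lfc = lfc, t = t_stat, p = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  class(out) <- c("tx_deg", "data.frame")
  out
}

#' ROC curve and AUC against a DEG truth set
#'
#' Genes are ranked by ascending p-value; the ROC runs over the full
#' ranking with midrank tie handling, so the AUC equals the Mann-Whitney
#' concordance probability. A secondary threshold-sweep curve at p-value
#' cutoffs 0.001..0.05 is also returned for reporting.
#'
#' @param result a `tx_deg` from [moderated_t_test()].
#' @param truth character vector of true DEG gene ids (a strict non-empty
#'   subset of the genes).
#' @param sweep_thresholds p-value cutoffs for the secondary curve.
#' @return list with `points` (data frame fpr/tpr over the full ranking),
#'   `auc`, and `sweep` (data frame threshold/fpr/tpr).
#' @export
roc_auc <- function(result, truth,
                    sweep_thresholds = seq(0.001, 0.05, by = 0.001)) {
  genes <- result$gene
  truth <- unique(truth)
  is_pos <- genes %in% truth
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("truth must be a non-empty strict subset of the genes",
         call. = FALSE)
  }
  score <- -result$p
  # Mann-Whitney AUC with midranks
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(score, decreasing = TRUE)
  sp <- score[ord]; pos <- is_pos[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- c(sp[-1] != sp[-length(sp)], TRUE)  # keep one point per tie group
  points <- data.frame(fpr = c(0, fp[last] / n_neg),
                       tpr = c(0, tp[last] / n_pos))

  sweep <- do.call(rbind, lapply(sweep_thresholds, function(th) {
    called <- result$p < th
    data.frame(threshold = th,
               fpr = sum(called & !is_pos) / n_neg,
               tpr = sum(called & is_pos) / n_pos)
  }))
  list(points = points, auc = auc, sweep = sweep)
}

simulate_dataset <- function(kind, seed, ...) {
  switch(kind,
         microarray = simulate_microarray(seed = seed, ...),
         ngs = simulate_counts(seed = seed, ...),
         stop("unknown simulation kind '", kind, "'", call. = FALSE))
}

integrate_halves <- function(halves, method, seed) {
  sels <- lapply(halves, function(h) list(matrix = h$matrix,
                                          metadata = NULL))
  integrate_selections(sels, method = method, seed = seed)
}

#' Run the simulation benchmark of the integration algorithms
#'
#' Per replicate: simulate a dataset with known DEGs; compute a baseline
#' AUC on the unsplit matrix; then for each integration method, randomly
#' partition the samples into two halves, integrate them, run the
#' moderated-t pipeline on the combined matrix and score the full-ranking
#' AUC against the truth.
#'
#' @param kind `"microarray"` or `"ngs"`.
#' @param methods subset of `c("baseline", "none", "sims", "genestd",
#'   "combat", "xpn")`.
#' @param n_replicates number of independent simulations.
#' @param seed integer master seed; replicate r uses `seed + r`.
#' @param ... forwarded to the simulator (e.g. `n_genes`).
#' @return list with `results` (data frame: method, replicate, auc) and
#'   `summary` (data frame: method, mean_auc, sd_auc).
#' @export
run_benchmark <- function(kind = c("ngs", "microarray"),
                          methods = c("baseline", "none", "sims",
                                      "genestd", "combat", "xpn"),
                          n_replicates = 10L, seed = 1L, ...) {
  kind <- match.arg(kind)
  methods <- match.arg(methods, c("baseline", "none", "sims", "genestd",
                                  "combat", "xpn"), several.ok = TRUE)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- seed + r
    sim <- simulate_dataset(kind, seed = rep_seed, ...)
    truth <- sim$truth$gene
    halves <- NULL
    for (m in methods) {
      if (m == "baseline") {
        deg <- moderated_t_test(sim$matrix, sim$condition)
      } else {
        if (is.null(halves)) halves <- random_partition(sim, seed = rep_seed)
        integ <- integrate_halves(halves, m, seed = rep_seed)
        cond <- sim$condition[sample_ids(integ$matrix)]
        deg <- moderated_t_test(integ$matrix, cond)
      }
      auc <- roc_auc(deg, truth)$auc
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, replicate = r, auc = auc, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$method),
    function(d) data.frame(method = d$method[1L],
                           mean_auc = mean(d$auc),
                           sd_auc = stats::sd(d$auc),
                           stringsAsFactors = FALSE)))
  summary <- summary[match(unique(results$method), summary$method), ]
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
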
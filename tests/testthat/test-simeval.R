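test_that("microarray simulator honours its stated world", {
  sim <- simulate_microarray(n_genes = 10000, frac_de = 0.1, seed = 61)
  expect_equal(nrow(sim$truth), 1000L)
  expect_equal(sum(sim$truth$direction == "up"), 500L)
  expect_equal(sum(sim$truth$direction == "down"), 500L)
  expect_equal(dim(sim$matrix), c(10000L, 14L))
  expect_identical(tx_scale(sim$matrix), "log2_intensity")

  empty <- simulate_microarray(n_genes = 100, frac_de = 0, seed = 62)
  expect_equal(nrow(empty$truth), 0L)

  # Monte-Carlo: a non-DE gene across many samples has mean ~= baseline
  # distribution and a small t statistic
  big <- simulate_microarray(n_genes = 50, n_per_group = 500, frac_de = 0,
                             noise_sd = 0.5, seed = 63)
  x <- vals(big$matrix)
  # grand mean across genes within 3 SE of the baseline mean 7
  expect_lt(abs(mean(x) - 7), 3 * 1.5 / sqrt(nrow(x)))
  g <- x[1, ]
  tt <- t.test(g[big$condition == "case"], g[big$condition == "control"])
  expect_lt(abs(tt$statistic), 4)
})

test_that("count simulator follows the NB model", {
  sim <- simulate_counts(n_genes = 12500, frac_de = 0.1, seed = 64)
  expect_equal(nrow(sim$truth), 1250L)
  expect_identical(tx_scale(sim$matrix), "linear_count")
  expect_true(all(vals(sim$matrix) >= 0))
  expect_true(all(vals(sim$matrix) == round(vals(sim$matrix))))

  # near-zero dispersion approaches the Poisson variance/mean limit
  pois <- simulate_counts(n_genes = 50, n_per_group = 1000, frac_de = 0,
                          dispersion_mean = 1e-6, seed = 65)
  x <- vals(pois$matrix)
  ratio <- apply(x, 1, var) / rowMeans(x)
  expect_lt(abs(median(ratio) - 1), 0.15)

  # NB moments: with dispersion phi, var = mu + phi mu^2; at mu ~ 100 and
  # 2000 samples the empirical mean lands within [95, 105] for most genes
  big <- simulate_counts(n_genes = 200, n_per_group = 1000, frac_de = 0,
                         seed = 66)
  mu_hat <- rowMeans(vals(big$matrix))
  mid <- mu_hat[mu_hat > 50 & mu_hat < 200]
  expect_gt(length(mid), 20)
})

test_that("random_partition splits evenly, stratified, deterministically", {
  sim <- simulate_counts(n_genes = 40, n_per_group = 7, seed = 67)
  halves <- random_partition(sim, seed = 7)
  n1 <- ncol(halves[[1]]$matrix); n2 <- ncol(halves[[2]]$matrix)
  expect_equal(sort(c(n1, n2)), c(7L, 7L))
  expect_setequal(c(sample_ids(halves[[1]]$matrix),
                    sample_ids(halves[[2]]$matrix)),
                  sample_ids(sim$matrix))
  expect_length(intersect(sample_ids(halves[[1]]$matrix),
                          sample_ids(halves[[2]]$matrix)), 0L)
  for (h in halves) {
    expect_gte(sum(h$condition == "case"), 1L)
    expect_gte(sum(h$condition == "control"), 1L)
    expect_equal(nrow(h$matrix), 40L)
    expect_identical(h$truth, sim$truth)
  }
  again <- random_partition(sim, seed = 7)
  expect_identical(sample_ids(again[[1]]$matrix),
                   sample_ids(halves[[1]]$matrix))

  tiny <- sim
  tiny$condition <- setNames(c("case", rep("control", 13)),
                             names(sim$condition))
  expect_error(random_partition(tiny, seed = 1), ">= 2 samples")
})

test_that("moderated t matches the pooled two-sample t when d0 = 0", {
  # 5-gene hand-made matrix, 3 vs 3
  set.seed(68)
  x <- matrix(c(5, 6, 7, 9, 8, 10,
                2, 2, 2, 2, 2, 2,
                1, 4, 2, 8, 9, 7,
                10, 9, 11, 5, 4, 6,
                3, 3.5, 2.5, 3.1, 2.9, 3.0), 5, 6, byrow = TRUE)
  m <- make_matrix(x, samples = sprintf("s%d", 1:6))
  cond <- setNames(rep(c("case", "control"), each = 3), sample_ids(m))
  got <- moderated_t_test(m, cond, d0_override = 0)
  for (g in 1:5) {
    a <- x[g, 1:3]; b <- x[g, 4:6]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
    t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    if (sp2 == 0) t_hand <- 0
    expect_equal(got$t[g], t_hand, tolerance = 1e-12)
    if (sp2 > 0) {
      expect_equal(got$p[g], 2 * pt(-abs(t_hand), df = 4),
                   tolerance = 1e-12)
    }
  }
  # identical case/control values give t = 0, p = 1
  expect_equal(got$t[2], 0)
  expect_equal(got$p[2], 1)
})

test_that("moderated t agrees with the limma oracle on simulated counts", {
  skip_if_not_installed("limma")
  sim <- simulate_counts(n_genes = 400, seed = 69)
  got <- moderated_t_test(sim$matrix, sim$condition)
  lcpm <- vals(cpm_log2(sim$matrix))
  f <- factor(sim$condition, levels = c("control", "case"))
  design <- stats::model.matrix(~ f)
  fit <- limma::eBayes(limma::lmFit(lcpm, design))
  expect_gt(cor(got$t, fit$t[, 2]), 0.999)
  expect_equal(attr(got, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(got, "s0_2"), fit$s2.prior, tolerance = 0.01)
})

test_that("null simulation p-values are calibrated", {
  sim <- simulate_microarray(n_genes = 10000, frac_de = 0, seed = 70)
  deg <- moderated_t_test(sim$matrix, sim$condition)
  rate <- mean(deg$p < 0.05)
  expect_gte(rate, 0.04); expect_lte(rate, 0.06)
  ks <- suppressWarnings(stats::ks.test(deg$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("roc_auc matches the exhaustive concordance oracle", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    p <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    truth_n <- sample(seq_len(n - 1), 1)
    genes <- sprintf("g%d", seq_len(n))
    deg <- structure(data.frame(gene = genes, lfc = 0, t = 0, p = p,
                                stringsAsFactors = FALSE),
                     class = c("tx_deg", "data.frame"))
    truth <- sample(genes, truth_n)
    got <- roc_auc(deg, truth)
    expect_equal(got$auc, oracle_auc(p, genes %in% truth),
                 tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_equal(got$points[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(got$points[nrow(got$points), ]),
                 c(fpr = 1, tpr = 1))
    expect_true(all(diff(got$points$fpr) >= 0))
    expect_true(all(diff(got$points$tpr) >= 0))
  }
})

test_that("roc_auc degenerate and edge behaviour", {
  genes <- sprintf("g%d", 1:10)
  mk_deg <- function(p) structure(
    data.frame(gene = genes, lfc = 0, t = 0, p = p,
               stringsAsFactors = FALSE),
    class = c("tx_deg", "data.frame"))
  # perfect separation
  perfect <- mk_deg(c(rep(0.001, 3), rep(0.9, 7)))
  expect_equal(roc_auc(perfect, genes[1:3])$auc, 1.0)
  # all tied
  tied <- mk_deg(rep(0.5, 10))
  expect_equal(roc_auc(tied, genes[1:3])$auc, 0.5)
  # sweep curve covers the 0.001..0.05 thresholds
  expect_equal(nrow(roc_auc(perfect, genes[1:3])$sweep), 50L)
  # truth must be a strict non-empty subset
  expect_error(roc_auc(perfect, character(0)), "non-empty")
  expect_error(roc_auc(perfect, genes), "strict subset")
})

test_that("benchmark: 'none' equals baseline per replicate; deterministic", {
  b <- run_benchmark("ngs", c("baseline", "none"), n_replicates = 3,
                     seed = 9, n_genes = 300)
  expect_equal(nrow(b$results), 6L)
  base <- b$results$auc[b$results$method == "baseline"]
  none <- b$results$auc[b$results$method == "none"]
  expect_identical(base, none)  # permutation invariance, exact

  b2 <- run_benchmark("ngs", c("baseline", "none"), n_replicates = 3,
                      seed = 9, n_genes = 300)
  expect_identical(b$results, b2$results)
})

test_that("benchmark runs all methods on both kinds at toy scale", {
  for (kind in c("ngs", "microarray")) {
    b <- suppressWarnings(
      run_benchmark(kind, c("baseline", "sims", "genestd", "combat", "xpn"),
                    n_replicates = 1, seed = 10, n_genes = 250))
    expect_equal(nrow(b$results), 5L)
    expect_true(all(b$results$auc >= 0 & b$results$auc <= 1))
    expect_identical(b$summary$method,
                     c("baseline", "sims", "genestd", "combat", "xpn"))
  }
})
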
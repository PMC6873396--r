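md_of <- function(ids, ...) {
  cols <- list(...)
  tx_metadata(ids, if (length(cols)) as.data.frame(cols,
                                                   stringsAsFactors = FALSE))
}

test_that("merge_metadata unions attributes, renames duplicates, adds batch", {
  a <- md_of(c("s1", "s2"), a = c("x", "y"), b = c("1", "2"))
  b <- md_of(c("s3", "s4"), b = c("3", "4"), c = c("u", "v"))
  merged <- merge_metadata(list(a, b))
  expect_identical(names(merged), c("sample_id", "a", "b", "c", "batch"))
  expect_identical(merged$batch, c("0", "0", "1", "1"))
  expect_identical(merged$a, c("x", "y", "", ""))

  # duplicate ids get _k suffixes
  dup <- merge_metadata(list(md_of("GSM1", a = "x"), md_of("GSM1", a = "y")))
  expect_identical(dup$sample_id, c("GSM1", "GSM1_1"))

  # single input: identity plus a zero batch column
  one <- merge_metadata(list(a))
  expect_identical(one$batch, c("0", "0"))
  expect_identical(one$a, a$a)
})

test_that("merge_matrices intersects rows in first-input order", {
  a <- make_matrix(matrix(1:6, 3, 2), probes = c("g1", "g2", "g3"),
                   samples = c("s1", "s2"))
  b <- make_matrix(matrix(7:12, 3, 2), probes = c("g2", "g3", "g4"),
                   samples = c("t1", "t2"))
  got <- merge_matrices(list(a, b))
  expect_identical(probe_ids(got$matrix), c("g2", "g3"))
  expect_identical(sample_ids(got$matrix), c("s1", "s2", "t1", "t2"))
  expect_identical(got$batch, c(0L, 0L, 1L, 1L))

  # identical row sets concatenate unchanged
  b2 <- make_matrix(matrix(7:12, 3, 2), probes = c("g1", "g2", "g3"),
                    samples = c("t1", "t2"))
  got2 <- merge_matrices(list(a, b2))
  expect_equal(unname(vals(got2$matrix)), unname(cbind(vals(a), vals(b2))))

  # disjoint rows fail with per-input counts
  c3 <- make_matrix(matrix(1:4, 2, 2), probes = c("h1", "h2"))
  expect_error(merge_matrices(list(a, c3)), "3, 2")
})

test_that("mean-centering integration zeroes per-dataset gene means", {
  a <- make_matrix(matrix(c(2, 4, 6), 1, 3), probes = "g",
                   samples = c("s1", "s2", "s3"))
  out <- mean_center_integration(list(a, a))
  expect_equal(unname(vals(out$matrix)[1, 1:3]), c(-2, 0, 2))

  # hand example: A=[1,3], B=[10,14] -> [-1,1,-2,2]
  a2 <- make_matrix(matrix(c(1, 3), 1, 2), probes = "g",
                    samples = c("s1", "s2"))
  b2 <- make_matrix(matrix(c(10, 14), 1, 2), probes = "g",
                    samples = c("t1", "t2"))
  got <- mean_center_integration(list(a2, b2))
  expect_equal(unname(vals(got$matrix)[1, ]), c(-1, 1, -2, 2))

  # idempotence
  twice <- mean_center_integration(
    list(got$matrix[, 1:2], got$matrix[, 3:4]))
  expect_equal(vals(twice$matrix), vals(got$matrix), tolerance = 1e-12)
})

test_that("gene standardization yields per-dataset mean 0 / sd 1", {
  a <- make_matrix(matrix(c(1, 3), 1, 2), probes = "g",
                   samples = c("s1", "s2"))
  out <- gene_standardize_integration(list(a, a))
  expect_equal(unname(vals(out$matrix)[1, 1:2]),
               c(-0.70710678, 0.70710678), tolerance = 1e-8)

  const <- make_matrix(matrix(5, 1, 3), probes = "g")
  out2 <- gene_standardize_integration(list(const, const))
  expect_equal(unname(vals(out2$matrix)[1, ]), rep(0, 6))

  # idempotence within 1e-9
  m <- gauss_matrix(10, 6, seed = 31)
  std <- gene_standardize_integration(list(m, gauss_matrix(10, 5, seed = 32,
                                                           prefix = "t")))
  restd <- gene_standardize_integration(
    list(std$matrix[, 1:6], std$matrix[, 7:11]))
  expect_equal(vals(restd$matrix), vals(std$matrix), tolerance = 1e-9)

  one_sample <- make_matrix(matrix(1, 2, 1))
  expect_error(gene_standardize_integration(list(one_sample, m)),
               ">= 2 samples")
})

test_that("sims/genestd invariants hold on random fixtures", {
  set.seed(33)
  for (i in 1:10) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    a <- gauss_matrix(15, n1, seed = 400 + i)
    b <- gauss_matrix(15, n2, seed = 500 + i, prefix = "t")
    ms <- mean_center_integration(list(a, b))
    x <- vals(ms$matrix)
    expect_lt(max(abs(rowMeans(x[, 1:n1]))), 1e-9)
    expect_lt(max(abs(rowMeans(x[, n1 + 1:n2]))), 1e-9)

    gs <- gene_standardize_integration(list(a, b))
    y <- vals(gs$matrix)
    expect_lt(max(abs(rowMeans(y[, 1:n1]))), 1e-9)
    expect_lt(max(abs(apply(y[, 1:n1], 1, sd) - 1)), 1e-9)
    expect_lt(max(abs(apply(y[, n1 + 1:n2], 1, sd) - 1)), 1e-9)
  }
})

test_that("integrate_selections dispatches and preserves the contracts", {
  a <- gauss_matrix(12, 4, seed = 34)
  b <- gauss_matrix(12, 5, seed = 35, prefix = "t")
  md_a <- md_of(sample_ids(a), cond = rep("x", 4))
  md_b <- md_of(sample_ids(b), cond = rep("y", 5))
  sels <- list(list(matrix = a, metadata = md_a),
               list(matrix = b, metadata = md_b))

  none <- integrate_selections(sels, "none")
  expect_equal(unname(vals(none$matrix)), unname(cbind(vals(a), vals(b))))
  expect_equal(nrow(none$metadata), 9L)

  sims <- integrate_selections(sels, "sims")
  direct <- mean_center_integration(list(a, b))
  expect_equal(vals(sims$matrix), vals(direct$matrix))

  expect_error(integrate_selections(sels[1], "sims"), ">= 2 selections")
  expect_error(integrate_selections(c(sels, sels[1]), "xpn"), "pairwise")

  # all methods preserve shape: rows = intersection, cols = concatenation
  for (m in c("sims", "genestd", "combat")) {
    out <- integrate_selections(sels, m)
    expect_equal(dim(out$matrix), c(12L, 9L))
    expect_identical(out$batch, c(rep(0L, 4), rep(1L, 5)))
  }
})

test_that("integrated datasets are written with the export conventions", {
  a <- gauss_matrix(5, 3, seed = 36)
  b <- gauss_matrix(5, 3, seed = 37, prefix = "t")
  out <- integrate_selections(list(list(matrix = a, metadata = NULL),
                                   list(matrix = b, metadata = NULL)),
                              "none")
  dir <- withr::local_tempdir()
  write_integrated(out, dir, dialect = "tsv")
  rt <- read_table(file.path(dir, "matrix.tsv"))
  expect_equal(vals(rt), vals(out$matrix), tolerance = 1e-9)
})
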
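# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

make_matrix <- function(values, probes = NULL, samples = NULL,
                        scale = "log2_intensity") {
  if (is.null(probes)) probes <- sprintf("p%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  tx_matrix(values, scale = scale)
}

gauss_matrix <- function(n_probes, n_samples, seed = 1, mean = 7, sd = 1,
                         prefix = "s") {
  set.seed(seed)
  make_matrix(matrix(rnorm(n_probes * n_samples, mean, sd),
                     n_probes, n_samples),
              samples = sprintf("%s%d", prefix, seq_len(n_samples)))
}

# matrix values stripped of class/attributes, for value comparisons
vals <- function(m) {
  x <- unclass(m)
  attr(x, "scale") <- NULL
  x
}

# independent tokenizer for the full-text search oracle (kept separate from
# the package's tokenize())
oracle_tokens <- function(x) {
  toks <- regmatches(tolower(x), gregexpr("[[:alnum:]]+", tolower(x)))
  lapply(toks, unique)
}

oracle_search <- function(metadata, query, attribute = NULL) {
  attrs <- if (is.null(attribute)) metadata_attributes(metadata) else attribute
  q <- oracle_tokens(query)[[1L]]
  hit <- vapply(seq_len(nrow(metadata)), function(i) {
    toks <- unique(unlist(oracle_tokens(
      unlist(metadata[i, attrs, drop = FALSE]))))
    all(q %in% toks)
  }, logical(1))
  metadata$sample_id[hit]
}

# brute-force pairwise-concordance AUC (Mann-Whitney identity), used as the
# oracle for roc_auc on small instances
oracle_auc <- function(p, is_pos) {
  pos <- which(is_pos); neg <- which(!is_pos)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (p[i] < p[j]) + 0.5 * (p[i] == p[j])
  }
  total / (length(pos) * length(neg))
}

# per-batch gene-mean shift statistics
batch_shift_signed <- function(x, batch) {
  b <- sort(unique(batch))
  mean(rowMeans(x[, batch == b[2L], drop = FALSE]) -
         rowMeans(x[, batch == b[1L], drop = FALSE]))
}
batch_shift_abs <- function(x, batch) {
  b <- sort(unique(batch))
  mean(abs(rowMeans(x[, batch == b[2L], drop = FALSE]) -
             rowMeans(x[, batch == b[1L], drop = FALSE])))
}
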
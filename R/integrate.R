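# Combining selections into one dataset: metadata merge with duplicate-id
# renaming, gene-set intersection on the matrices, and dispatch to the
# integration algorithms (mean-centering, gene standardization, ComBat,
# XPN) or a value-preserving passthrough.

disambiguate_ids <- function(ids) {
  out <- ids
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(ids)) {
    id <- ids[i]
    k <- if (is.null(seen[[id]])) 0L else seen[[id]]
    if (k > 0L) out[i] <- paste0(id, "_", k)
    assign(id, k + 1L, envir = seen)
  }
  out
}

#' Merge per-selection metadata tables
#'
#' Attribute list is the union of the inputs' attributes in first-seen
#' order; values missing for a sample stay empty. Duplicate sample ids are
#' disambiguated by appending `_k` to the k-th repeat. A `batch` attribute
#' recording the 0-based source-selection ordinal is appended.
#'
#' @param metadatas non-empty list of [tx_metadata()].
#' @return a [tx_metadata()].
#' @export
merge_metadata <- function(metadatas) {
  if (length(metadatas) == 0L) stop("no metadata to merge", call. = FALSE)
  attrs <- unique(unlist(lapply(metadatas, metadata_attributes)))
  rows <- lapply(seq_along(metadatas), function(b) {
    md <- metadatas[[b]]
    for (a in setdiff(attrs, names(md))) md[[a]] <- ""
    md <- md[, c("sample_id", attrs), drop = FALSE]
    md$batch <- as.character(b - 1L)
    md
  })
  merged <- do.call(rbind, rows)
  merged$sample_id <- disambiguate_ids(merged$sample_id)
  out <- tx_metadata(merged$sample_id, merged[, c(attrs, "batch"),
                                              drop = FALSE])
  names(out) <- c("sample_id", attrs, "batch")
  out
}

#' Merge expression matrices on their shared gene set
#'
#' Rows are the intersection of the inputs' row-id sets, ordered as in the
#' first input; columns are the inputs concatenated in order, sample ids
#' disambiguated as in [merge_metadata()].
#'
#' @param matrices list of two or more [tx_matrix()] sharing an identifier
#'   namespace (i.e. post-mapping).
#' @return list with `matrix` (a [tx_matrix()]) and `batch` (integer
#'   vector of 0-based input ordinals, one per output column).
#' @export
merge_matrices <- function(matrices) {
  if (length(matrices) < 2L) stop("need at least two matrices", call. = FALSE)
  shared <- Reduce(intersect, lapply(matrices, rownames))
  if (length(shared) == 0L) {
    counts <- vapply(matrices, nrow, integer(1))
    stop("empty row-id intersection across inputs (per-input row counts: ",
         paste(counts, collapse = ", "), ")", call. = FALSE)
  }
  shared <- rownames(matrices[[1L]])[rownames(matrices[[1L]]) %in% shared]
  parts <- lapply(matrices, function(m) unclass(m)[shared, , drop = FALSE])
  combined <- do.call(cbind, parts)
  colnames(combined) <- disambiguate_ids(colnames(combined))
  batch <- rep(seq_along(matrices) - 1L,
               vapply(matrices, ncol, integer(1)))
  list(matrix = tx_matrix(combined, scale = tx_scale(matrices[[1L]])),
       batch = batch)
}

# Count matrices are moved to log2-CPM (+0.5 offset) before any of the
# Gaussian-scale integration algorithms.
ensure_log_scale <- function(m) {
  if (tx_scale(m) == "linear_count") cpm_log2(m) else m
}

center_rows <- function(values) values - rowMeans(values)

standardize_rows <- function(values, sd_floor = 1e-12) {
  mu <- rowMeans(values)
  sdv <- apply(values, 1L, stats::sd)
  z <- (values - mu) / sdv
  z[sdv < sd_floor, ] <- 0
  z
}

new_integrated <- function(values, scale, metadata, batch, method) {
  structure(
    list(matrix = tx_matrix(values, scale = scale), metadata = metadata,
         batch = batch, method = method),
    class = "tx_integrated")
}

#' @export
print.tx_integrated <- function(x, ...) {
  cat(sprintf("<tx_integrated> method=%s, %d genes x %d samples, %d batches\n",
              x$method, nrow(x$matrix), ncol(x$matrix),
              length(unique(x$batch))))
  invisible(x)
}

#' Mean-centering integration
#'
#' Within each input dataset, subtracts each gene's within-dataset mean
#' (z-score-like normalization through mean-centering), then merges.
#'
#' @param matrices list of [tx_matrix()].
#' @param metadatas optional list of [tx_metadata()] merged alongside.
#' @return a `tx_integrated` object.
#' @export
mean_center_integration <- function(matrices, metadatas = NULL) {
  matrices <- lapply(matrices, ensure_log_scale)
  centered <- lapply(matrices, function(m) {
    tx_matrix(center_rows(unclass(m)), scale = "standardized")
  })
  merged <- merge_matrices(centered)
  md <- if (is.null(metadatas)) NULL else merge_metadata(metadatas)
  new_integrated(unclass(merged$matrix), "standardized", md, merged$batch,
                 "sims")
}

#' Gene-standardization integration
#'
#' Within each input dataset, transforms each gene row to mean 0 and
#' sample standard deviation 1 (divisor n-1); rows with near-zero sd are
#' set to all zeros. The standardized datasets are then merged.
#'
#' @inheritParams mean_center_integration
#' @return a `tx_integrated` object.
#' @export
gene_standardize_integration <- function(matrices, metadatas = NULL) {
  matrices <- lapply(matrices, ensure_log_scale)
  lapply(matrices, function(m) {
    if (ncol(m) < 2L) stop("gene standardization needs >= 2 samples per dataset",
                           call. = FALSE)
  })
  std <- lapply(matrices, function(m) {
    tx_matrix(standardize_rows(unclass(m)), scale = "standardized")
  })
  merged <- merge_matrices(std)
  md <- if (is.null(metadatas)) NULL else merge_metadata(metadatas)
  new_integrated(unclass(merged$matrix), "standardized", md, merged$batch,
                 "genestd")
}

#' Integrate selections with a chosen algorithm
#'
#' Merges metadata and matrices, then applies the chosen cross-platform
#' normalization: `"none"` (values bit-unchanged), `"sims"`
#' (mean-centering), `"genestd"` (per-gene z-scoring), `"combat"`
#' (empirical-Bayes batch correction) or `"xpn"` (block normalization,
#' exactly two inputs).
#'
#' @param selections list of `list(matrix =, metadata =)` pairs.
#' @param method integration method.
#' @param seed integer seed forwarded to stochastic methods (XPN).
#' @param xpn_params list of XPN parameters
#'   (`gene_clusters`, `sample_clusters`, `repeats`).
#' @return a `tx_integrated` object.
#' @export
integrate_selections <- function(selections,
                                 method = c("none", "sims", "genestd",
                                            "combat", "xpn"),
                                 seed = 1L, xpn_params = list()) {
  method <- match.arg(method)
  if (length(selections) < 1L) stop("no selections", call. = FALSE)
  if (length(selections) < 2L && method != "none") {
    stop("need >= 2 selections for method '", method, "'", call. = FALSE)
  }
  matrices <- lapply(selections, `[[`, "matrix")
  metadatas <- lapply(selections, `[[`, "metadata")
  has_md <- all(!vapply(metadatas, is.null, logical(1)))
  md <- if (has_md) merge_metadata(metadatas) else NULL

  if (method == "none") {
    if (length(matrices) == 1L) {
      m <- matrices[[1L]]
      return(new_integrated(unclass(m), tx_scale(m), md,
                            rep(0L, ncol(m)), "none"))
    }
    merged <- merge_matrices(matrices)
    return(new_integrated(unclass(merged$matrix), tx_scale(merged$matrix),
                          md, merged$batch, "none"))
  }
  if (method == "sims") {
    out <- mean_center_integration(matrices)
  } else if (method == "genestd") {
    out <- gene_standardize_integration(matrices)
  } else if (method == "combat") {
    matrices <- lapply(matrices, ensure_log_scale)
    merged <- merge_matrices(matrices)
    out <- combat_integration(merged$matrix, merged$batch)
  } else {
    if (length(matrices) != 2L) {
      stop("xpn is pairwise: exactly 2 selections required", call. = FALSE)
    }
    matrices <- lapply(matrices, ensure_log_scale)
    out <- do.call(xpn_integration,
                   c(list(matrix_a = matrices[[1L]],
                          matrix_b = matrices[[2L]], seed = seed),
                     xpn_params))
  }
  out$metadata <- md
  out
}

#' Write an integrated dataset to disk
#'
#' The combined matrix and merged metadata are written with the
#' [write_table()]/[write_metadata()] conventions.
#'
#' @param integrated a `tx_integrated`.
#' @param dir output directory (created if missing).
#' @param dialect,delimiter export dialect.
#' @return character vector of the written paths, invisibly.
#' @export
write_integrated <- function(integrated, dir, dialect = "tsv",
                             delimiter = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (match.arg(dialect, c("tsv", "csv")) == "tsv") "tsv" else "csv"
  mp <- file.path(dir, paste0("matrix.", ext))
  write_table(integrated$matrix, mp, dialect, delimiter)
  paths <- mp
  if (!is.null(integrated$metadata)) {
    dp <- file.path(dir, paste0("metadata.", ext))
    write_metadata(integrated$metadata, dp, dialect, delimiter)
    paths <- c(paths, dp)
  }
  invisible(paths)
}
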
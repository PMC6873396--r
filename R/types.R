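#' @keywords internal
"_PACKAGE"

VALID_SCALES <- c("linear_count", "log2_intensity", "log2_cpm", "standardized")

#' Construct an expression matrix
#'
#' The unit every pipeline stage transforms: a dense probes-by-samples
#' numeric matrix with unique ordered row (probe) and column (sample)
#' identifiers, plus a `scale` tag recording the expression units.
#'
#' @param values numeric matrix with rownames (probe ids) and colnames
#'   (sample ids). Missing values are not allowed; the readers impute them
#'   with row means at import time.
#' @param scale one of `"linear_count"`, `"log2_intensity"`, `"log2_cpm"`,
#'   `"standardized"`.
#' @return an object of class `tx_matrix` (a numeric matrix carrying a
#'   `scale` attribute).
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' em <- tx_matrix(m, scale = "log2_intensity")
#' probe_ids(em)
#' @export
tx_matrix <- function(values, scale = "log2_intensity") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  scale <- match.arg(scale, VALID_SCALES)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stop("`values` must have row and column names", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicated probe id: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop("duplicated sample id: ", dup, call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression matrix contains missing values; impute before construction",
         call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(values, scale = scale, class = c("tx_matrix", "matrix", "array"))
}

#' @rdname tx_matrix
#' @param x a `tx_matrix`
#' @export
probe_ids <- function(x) rownames(x)

#' @rdname tx_matrix
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname tx_matrix
#' @export
tx_scale <- function(x) attr(x, "scale")

#' Replace the scale tag of an expression matrix
#' @param x a `tx_matrix`
#' @param value new scale tag
#' @export
`tx_scale<-` <- function(x, value) {
  attr(x, "scale") <- match.arg(value, VALID_SCALES)
  x
}

#' @export
`[.tx_matrix` <- function(x, i, j, ..., drop = FALSE) {
  sc <- attr(x, "scale")
  y <- NextMethod(drop = drop)
  if (is.matrix(y)) {
    y <- structure(y, scale = sc, class = c("tx_matrix", "matrix", "array"))
  }
  y
}

#' @export
print.tx_matrix <- function(x, ...) {
  cat(sprintf("<tx_matrix> %d probes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "scale")))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  if (n > 0L && m > 0L) print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  invisible(x)
}

#' Construct a sample metadata table
#'
#' Per-sample attribute table. Stored as a data frame whose first column is
#' `sample_id`; the remaining columns are the attributes, all character.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param table data frame (or NULL) of attribute columns, one row per
#'   sample, all coerced to character; empty strings denote missing values.
#' @return a data frame of class `tx_metadata`.
#' @export
tx_metadata <- function(sample_ids, table = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ",
         sample_ids[duplicated(sample_ids)][1L], call. = FALSE)
  }
  if (is.null(table)) {
    table <- data.frame(row.names = seq_along(sample_ids))
  }
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (nrow(table) != length(sample_ids) && ncol(table) > 0L) {
    stop("metadata table has ", nrow(table), " rows but ",
         length(sample_ids), " sample ids", call. = FALSE)
  }
  table[] <- lapply(table, function(v) {
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  })
  out <- cbind(data.frame(sample_id = sample_ids, stringsAsFactors = FALSE),
               table)
  rownames(out) <- NULL
  class(out) <- c("tx_metadata", "data.frame")
  out
}

#' @rdname tx_metadata
#' @param x a `tx_metadata`
#' @export
metadata_attributes <- function(x) setdiff(names(x), "sample_id")

#' Construct a platform annotation object
#'
#' Holds the probe-to-gene identifier mappings of one platform (array
#' design), e.g. probe set to Entrez Gene id for an Affymetrix chip.
#'
#' @param platform_id platform accession string (e.g. "GPL570").
#' @param probe_ids unique probe identifiers.
#' @param mapping data frame with one character column per identifier
#'   namespace, rows aligned with `probe_ids`; `NA` means no identifier.
#' @return an object of class `tx_platform` with fields `platform_id`,
#'   `probe_ids`, `namespaces`, `mapping`.
#' @export
tx_platform <- function(platform_id, probe_ids, mapping) {
  probe_ids <- as.character(probe_ids)
  if (anyDuplicated(probe_ids)) {
    stop("duplicated probe id in annotation: ",
         probe_ids[duplicated(probe_ids)][1L], call. = FALSE)
  }
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  if (nrow(mapping) != length(probe_ids)) {
    stop("annotation mapping rows do not match probe ids", call. = FALSE)
  }
  mapping[] <- lapply(mapping, as.character)
  rownames(mapping) <- NULL
  structure(
    list(platform_id = as.character(platform_id),
         probe_ids = probe_ids,
         namespaces = names(mapping),
         mapping = mapping),
    class = "tx_platform"
  )
}

#' @export
print.tx_platform <- function(x, ...) {
  cat(sprintf("<tx_platform> %s: %d probes, namespaces: %s\n",
              x$platform_id, length(x$probe_ids),
              paste(x$namespaces, collapse = ", ")))
  invisible(x)
}

# internal: consistent condition for malformed input files
format_error <- function(...) {
  stop(structure(
    class = c("tx_format_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
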
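# Probe-to-gene identifier mapping: build a mapping table from platform
# annotation, then rewrite matrix row ids, dropping unmapped probes and
# collapsing many-to-one mappings by a configurable policy.

#' Build a probe-to-identifier mapping table
#'
#' Keeps exactly the probes that carry a non-missing identifier in the
#' chosen namespace.
#'
#' @param annotation a [tx_platform()].
#' @param namespace one of `annotation$namespaces`.
#' @return a `tx_mapping` object: list with `namespace` and `map` (named
#'   character vector, probe id -> target identifier).
#' @export
build_mapping_table <- function(annotation, namespace) {
  if (!(namespace %in% annotation$namespaces)) {
    stop("unknown namespace '", namespace, "'; available: ",
         paste(annotation$namespaces, collapse = ", "), call. = FALSE)
  }
  ids <- annotation$mapping[[namespace]]
  keep <- !is.na(ids)
  structure(
    list(namespace = namespace,
         map = stats::setNames(ids[keep], annotation$probe_ids[keep])),
    class = "tx_mapping")
}

#' @export
print.tx_mapping <- function(x, ...) {
  cat(sprintf("<tx_mapping> %d probes -> %s\n", length(x$map), x$namespace))
  invisible(x)
}

#' Write / read a mapping table as two-column TSV
#' @param table a `tx_mapping`.
#' @param path file path.
#' @export
write_mapping_table <- function(table, path) {
  utils::write.table(
    data.frame(probe_id = names(table$map), target = unname(table$map),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping_table
#' @param namespace namespace label for the loaded table.
#' @export
read_mapping_table <- function(path, namespace = "custom") {
  tbl <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  structure(list(namespace = namespace,
                 map = stats::setNames(tbl$target, tbl$probe_id)),
            class = "tx_mapping")
}

#' Apply a mapping table to an expression matrix
#'
#' Replaces each mapped probe's row id with its target identifier and
#' removes probes without a mapping entry. When several probes map to the
#' same target, their rows are combined according to `collision_policy`:
#' `"mean"` (element-wise mean), `"first"` (first probe in matrix order) or
#' `"max_mean"` (the probe with the highest row mean). Output rows follow
#' the first-occurrence order of the targets; the scale tag is preserved.
#'
#' @param matrix a [tx_matrix()].
#' @param table a `tx_mapping` from [build_mapping_table()].
#' @param collision_policy `"mean"`, `"first"` or `"max_mean"`.
#' @return a [tx_matrix()] with gene-level row ids.
#' @export
apply_mapping <- function(matrix, table, collision_policy = "mean") {
  collision_policy <- match.arg(collision_policy,
                                c("mean", "first", "max_mean"))
  targets <- table$map[rownames(matrix)]
  keep <- !is.na(targets)
  if (!any(keep)) stop("no probes mapped", call. = FALSE)
  sub <- matrix[keep, , drop = FALSE]
  targets <- unname(targets[keep])

  uniq <- unique(targets)
  out <- matrix(NA_real_, length(uniq), ncol(sub),
                dimnames = list(uniq, colnames(sub)))
  groups <- split(seq_along(targets), factor(targets, levels = uniq))
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    if (length(idx) == 1L) {
      out[k, ] <- sub[idx, ]
    } else {
      out[k, ] <- switch(collision_policy,
        mean = colMeans(unclass(sub)[idx, , drop = FALSE]),
        first = sub[idx[1L], ],
        max_mean = sub[idx[which.max(rowMeans(unclass(sub)[idx, ,
                                                           drop = FALSE]))], ])
    }
  }
  tx_matrix(out, scale = tx_scale(matrix))
}
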
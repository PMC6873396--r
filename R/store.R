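# File-backed dataset repository. One directory per accession holding the
# matrix (TSV), metadata (TSV), and three JSON index files:
#   sample_index.json    sample id -> 0-based column position
#   metadata_index.json  ordered attribute names
#   fulltext_index.json  attribute -> token -> sample ids
# plus descriptor.json. Everything is plain text and diff-able; there is no
# database and operations run synchronously.

dataset_dir <- function(store_root, accession) file.path(store_root, accession)

#' Tokenize a metadata value for full-text indexing
#'
#' Splits on runs of non-alphanumeric characters and lowercases; no
#' stemming. Deterministic and language-agnostic.
#'
#' @param x character vector.
#' @return list of character vectors of tokens, one per input element.
#' @export
tokenize <- function(x) {
  lapply(strsplit(tolower(x), "[^a-z0-9]+"), function(t) t[nzchar(t)])
}

build_fulltext_index <- function(metadata) {
  idx <- list()
  for (a in metadata_attributes(metadata)) {
    toks <- tokenize(metadata[[a]])
    inv <- list()
    for (i in seq_along(toks)) {
      for (t in unique(toks[[i]])) {
        inv[[t]] <- c(inv[[t]], metadata$sample_id[i])
      }
    }
    idx[[a]] <- inv
  }
  idx
}

#' Import a dataset into a file-backed store
#'
#' Persists the expression matrix (row-streamable TSV) and metadata, and
#' builds the three indexes used by later stages: the sample index (sample
#' id to matrix column position), the metadata index (attribute list) and a
#' full-text index over every metadata attribute.
#'
#' @param matrix a [tx_matrix()].
#' @param metadata a [tx_metadata()]; its sample ids must equal the matrix
#'   sample ids as sets.
#' @param accession unique dataset accession (directory name).
#' @param store_root store directory (created if missing).
#' @param source one of `"geo"`, `"arrayexpress"`, `"custom"`.
#' @param platform_id optional platform accession; when `annotation` is
#'   supplied it is stored alongside the dataset.
#' @param annotation optional [tx_platform()].
#' @param visibility `"public"` or `"private"`.
#' @param overwrite replace an existing accession.
#' @return the dataset descriptor (list), invisibly readable later with
#'   [read_descriptor()].
#' @export
import_dataset <- function(matrix, metadata, accession, store_root,
                           source = "custom", platform_id = NULL,
                           annotation = NULL, visibility = "public",
                           overwrite = FALSE) {
  source <- match.arg(source, c("geo", "arrayexpress", "custom"))
  visibility <- match.arg(visibility, c("public", "private"))
  extra <- setdiff(metadata$sample_id, colnames(matrix))
  missing <- setdiff(colnames(matrix), metadata$sample_id)
  if (length(extra) + length(missing) > 0L) {
    stop("matrix/metadata sample id mismatch; only in metadata: [",
         paste(extra, collapse = ", "), "]; only in matrix: [",
         paste(missing, collapse = ", "), "]", call. = FALSE)
  }
  dir <- dataset_dir(store_root, accession)
  if (dir.exists(dir)) {
    if (!overwrite) stop("accession '", accession,
                         "' already exists (use overwrite = TRUE)",
                         call. = FALSE)
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE)

  # metadata rows reordered to matrix column order for reproducible files
  metadata <- metadata[match(colnames(matrix), metadata$sample_id), ,
                       drop = FALSE]
  class(metadata) <- c("tx_metadata", "data.frame")

  write_table(matrix, file.path(dir, "matrix.tsv"), dialect = "tsv")
  write_metadata(metadata, file.path(dir, "metadata.tsv"), dialect = "tsv")

  sample_index <- as.list(stats::setNames(seq_len(ncol(matrix)) - 1L,
                                          colnames(matrix)))
  jsonlite::write_json(sample_index, file.path(dir, "sample_index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(metadata_attributes(metadata),
                       file.path(dir, "metadata_index.json"), pretty = TRUE)
  jsonlite::write_json(build_fulltext_index(metadata),
                       file.path(dir, "fulltext_index.json"), pretty = TRUE)

  if (!is.null(annotation)) {
    ann_df <- cbind(data.frame(probe_id = annotation$probe_ids,
                               stringsAsFactors = FALSE),
                    annotation$mapping)
    utils::write.table(ann_df, file.path(dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    if (is.null(platform_id)) platform_id <- annotation$platform_id
  }

  descriptor <- list(accession = accession, source = source,
                     platform_id = platform_id, visibility = visibility,
                     n_probes = nrow(matrix), n_samples = ncol(matrix),
                     scale = tx_scale(matrix),
                     paths = list(matrix = "matrix.tsv",
                                  metadata = "metadata.tsv",
                                  sample_index = "sample_index.json",
                                  metadata_index = "metadata_index.json",
                                  fulltext_index = "fulltext_index.json"))
  jsonlite::write_json(descriptor, file.path(dir, "descriptor.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(descriptor)
}

#' Read a stored dataset descriptor
#' @param store_root store directory.
#' @param accession dataset accession.
#' @return descriptor list.
#' @export
read_descriptor <- function(store_root, accession) {
  path <- file.path(dataset_dir(store_root, accession), "descriptor.json")
  if (!file.exists(path)) stop("no dataset '", accession, "' in store ",
                               store_root, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

read_store_index <- function(store_root, accession, which) {
  jsonlite::read_json(file.path(dataset_dir(store_root, accession),
                                paste0(which, ".json")),
                      simplifyVector = FALSE)
}

#' Search samples by metadata full-text query
#'
#' Returns the samples whose metadata contains every query token
#' (case-insensitive), using the inverted index built at import. With
#' `attribute = NULL` tokens may match in any attribute.
#'
#' @inheritParams read_descriptor
#' @param query query string; tokenized like the index ([tokenize()]).
#' @param attribute restrict matching to one attribute, or `NULL` for all.
#' @return character vector of matching sample ids (matrix column order).
#' @export
search_samples <- function(store_root, accession, query, attribute = NULL) {
  ft <- read_store_index(store_root, accession, "fulltext_index")
  attrs <- names(ft)
  if (!is.null(attribute)) {
    if (!(attribute %in% attrs)) {
      stop("unknown attribute '", attribute, "'; metadata index: ",
           paste(attrs, collapse = ", "), call. = FALSE)
    }
    ft <- ft[attribute]
  }
  tokens <- tokenize(query)[[1L]]
  if (length(tokens) == 0L) return(character(0))
  hit_sets <- lapply(tokens, function(t) {
    unique(unlist(lapply(ft, function(inv) unlist(inv[[t]])),
                  use.names = FALSE))
  })
  hits <- Reduce(intersect, hit_sets)
  if (is.null(hits) || length(hits) == 0L) return(character(0))
  si <- read_store_index(store_root, accession, "sample_index")
  hits[order(unlist(si[hits]))]
}

#' Stream the stored matrix one probe row at a time
#'
#' Low-level sequential reader used by [select_samples()]; visits every
#' data row in file order and calls `fun(probe_id, values)` once per row.
#' Peak memory is one row plus whatever `fun` retains.
#'
#' @inheritParams read_descriptor
#' @param fun callback `function(probe_id, values)`; `values` is the full
#'   numeric row named by sample id.
#' @return number of rows visited, invisibly.
#' @export
stream_matrix_rows <- function(store_root, accession, fun) {
  path <- file.path(dataset_dir(store_root, accession), "matrix.tsv")
  con <- file(path, open = "r")
  on.exit(close(con))
  header <- strsplit(sub("\r$", "", readLines(con, n = 1L)), "\t",
                     fixed = TRUE)[[1L]]
  samples <- header[-1L]
  n <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    fields <- strsplit(sub("\r$", "", line), "\t", fixed = TRUE)[[1L]]
    vals <- as.numeric(fields[-1L])
    names(vals) <- samples
    fun(fields[1L], vals)
    n <- n + 1L
  }
  invisible(n)
}

#' Extract a sample selection from a stored dataset
#'
#' Looks the requested samples up in the sample index and streams the
#' stored matrix one probe row at a time, writing only the selected columns
#' in request order; memory stays bounded by a single row. The extracted
#' matrix and metadata follow the [write_table()]/[write_metadata()]
#' contracts.
#'
#' @inheritParams read_descriptor
#' @param sample_ids_sel ordered sample ids to extract.
#' @param name selection name; files go to
#'   `<store_root>/<accession>/selections/<name>/`.
#' @param dialect,delimiter export dialect, as in [write_table()].
#' @return list with `name`, `accession`, `sample_ids`, `matrix_path`,
#'   `metadata_path`.
#' @export
select_samples <- function(store_root, accession, sample_ids_sel, name,
                           dialect = "tsv", delimiter = NULL) {
  if (length(sample_ids_sel) == 0L) stop("empty sample selection",
                                         call. = FALSE)
  si <- read_store_index(store_root, accession, "sample_index")
  unknown <- setdiff(sample_ids_sel, names(si))
  if (length(unknown) > 0L) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids_sel)) {
    stop("duplicated sample id in selection", call. = FALSE)
  }
  d <- resolve_delim(dialect, delimiter)
  out_dir <- file.path(dataset_dir(store_root, accession), "selections", name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (d$dialect == "tsv") "tsv" else "csv"
  matrix_path <- file.path(out_dir, paste0("matrix.", ext))
  metadata_path <- file.path(out_dir, paste0("metadata.", ext))

  con <- file(matrix_path, open = "wb")
  writeLines(join_fields(c("", sample_ids_sel), d$delimiter, d$dialect),
             con, sep = "\n")
  stream_matrix_rows(store_root, accession, function(probe, vals) {
    writeLines(join_fields(c(probe,
                             format(vals[sample_ids_sel], digits = 15L,
                                    trim = TRUE, scientific = FALSE)),
                           d$delimiter, d$dialect), con, sep = "\n")
  })
  close(con)

  md <- read_metadata(file.path(dataset_dir(store_root, accession),
                                "metadata.tsv"))
  md_sel <- md[match(sample_ids_sel, md$sample_id), , drop = FALSE]
  class(md_sel) <- c("tx_metadata", "data.frame")
  write_metadata(md_sel, metadata_path, dialect = d$dialect,
                 delimiter = d$delimiter)

  list(name = name, accession = accession,
       sample_ids = as.character(sample_ids_sel),
       matrix_path = matrix_path, metadata_path = metadata_path)
}

#' Load a selection back into memory
#' @param selection result of [select_samples()].
#' @param dialect,delimiter dialect the selection was written with.
#' @param scale scale tag for the loaded matrix.
#' @return list with `matrix` and `metadata`.
#' @export
load_selection <- function(selection, dialect = "tsv", delimiter = NULL,
                           scale = "log2_intensity") {
  list(matrix = read_table(selection$matrix_path, dialect, delimiter,
                           scale = scale),
       metadata = read_metadata(selection$metadata_path, dialect, delimiter))
}
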
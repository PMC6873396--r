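# Readers/writers for the formats the pipeline touches: GEO-style series
# matrix, MAGE-TAB (SDRF + data matrix), platform annotation tables, and the
# TSV/CSV export dialect. All readers accept LF and CRLF; writers emit LF.

read_lines_lf <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", x)
}

strip_quotes <- function(x) {
  q <- grepl('^".*"$', x)
  x[q] <- substr(x[q], 2L, nchar(x[q]) - 1L)
  x
}

# Replace NAs in a numeric matrix by their row means, warning with a count.
impute_row_means <- function(values) {
  na_n <- sum(is.na(values))
  if (na_n > 0L) {
    rm <- rowMeans(values, na.rm = TRUE)
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- rm[idx[, 1L]]
    warning(sprintf("imputed %d missing matrix values with row means", na_n),
            call. = FALSE)
  }
  values
}

parse_numeric_cells <- function(cells, line_no, path) {
  suppressWarnings(v <- as.numeric(cells))
  bad <- which(is.na(v) & !(cells %in% c("", "NA", "null", "NULL")))
  if (length(bad) > 0L) {
    format_error("non-numeric matrix cell '", cells[bad[1L]], "' at line ",
                 line_no, ", column ", bad[1L] + 1L, " of ", path)
  }
  v
}

#' Read a GEO-style series matrix file
#'
#' Parses the subset of the series-matrix dialect made of `!Sample_*`
#' metadata lines and the `!series_matrix_table_begin` /
#' `!series_matrix_table_end` expression block. The first row of the block
#' lists the sample accessions; subsequent rows are one probe each.
#'
#' @param path path to a series matrix file (uncompressed text).
#' @return a list with elements `matrix` (a [tx_matrix()], scale tag
#'   `"log2_intensity"`) and `metadata` (a [tx_metadata()] with one
#'   attribute per `!Sample_<attr>` line).
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- read_lines_lf(path)

  begin <- which(lines == "!series_matrix_table_begin")
  end <- which(lines == "!series_matrix_table_end")
  if (length(begin) != 1L || length(end) != 1L || end <= begin) {
    format_error("missing or malformed series_matrix table block in ", path)
  }

  # !Sample_<attr>\t"v1"\t"v2"... lines, in file order
  meta_lines <- grep("^!Sample_", lines[seq_len(begin - 1L)], value = TRUE)
  attrs <- character(0)
  meta_vals <- list()
  for (ln in meta_lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    attr_name <- sub("^!Sample_", "", fields[1L])
    vals <- strip_quotes(fields[-1L])
    if (attr_name %in% attrs) {
      # repeated lines (e.g. characteristics_ch1) get a numeric suffix
      k <- sum(startsWith(attrs, attr_name))
      attr_name <- paste0(attr_name, "_", k)
    }
    attrs <- c(attrs, attr_name)
    meta_vals[[attr_name]] <- vals
  }

  header_line <- begin + 1L
  if (header_line >= end) format_error("empty series_matrix table block in ", path)
  header <- strip_quotes(strsplit(lines[header_line], "\t", fixed = TRUE)[[1L]])
  samples <- header[-1L]
  n_s <- length(samples)

  data_rows <- lines[seq.int(header_line + 1L, length.out = end - header_line - 1L)]
  n_p <- length(data_rows)
  probes <- character(n_p)
  values <- matrix(NA_real_, nrow = n_p, ncol = n_s)
  for (i in seq_len(n_p)) {
    fields <- strsplit(data_rows[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != n_s + 1L) {
      format_error("ragged row at line ", header_line + i,
                   " of ", path, ": expected ", n_s + 1L, " fields, got ",
                   length(fields))
    }
    probes[i] <- strip_quotes(fields[1L])
    values[i, ] <- parse_numeric_cells(strip_quotes(fields[-1L]),
                                       header_line + i, path)
  }
  if (anyDuplicated(probes)) {
    format_error("duplicated probe id in table block: ",
                 probes[duplicated(probes)][1L])
  }
  dimnames(values) <- list(probes, samples)
  values <- impute_row_means(values)

  meta_tbl <- lapply(meta_vals, function(v) {
    length(v) <- n_s
    v[is.na(v)] <- ""
    v
  })
  metadata <- tx_metadata(samples, as.data.frame(meta_tbl, optional = TRUE,
                                                 stringsAsFactors = FALSE))
  names(metadata) <- c("sample_id", attrs)

  list(matrix = tx_matrix(values, scale = "log2_intensity"),
       metadata = metadata)
}

#' Read a MAGE-TAB sample table plus data matrix
#'
#' The SDRF (Sample and Data Relationship Format) file is a tab-delimited
#' table with one row per sample whose first column holds the sample name;
#' the data matrix is tab-delimited with probe ids in the first column and
#' sample names as the remaining headers. Samples listed in the SDRF but
#' absent from the matrix are dropped with a warning.
#'
#' @param sdrf_path path to the SDRF file.
#' @param matrix_path path to the tab-delimited data matrix.
#' @return a list with elements `matrix` and `metadata` as in
#'   [read_series_matrix()].
#' @export
read_magetab <- function(sdrf_path, matrix_path) {
  sdrf_lines <- read_lines_lf(sdrf_path)
  sdrf_lines <- sdrf_lines[nzchar(sdrf_lines)]
  if (length(sdrf_lines) < 2L) format_error("SDRF has no sample rows: ", sdrf_path)
  sdrf_rows <- strsplit(sdrf_lines, "\t", fixed = TRUE)
  header <- sdrf_rows[[1L]]
  body <- sdrf_rows[-1L]
  body <- lapply(body, function(r) { length(r) <- length(header); r })
  sdrf <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(sdrf) <- header
  sdrf_ids <- sdrf[[1L]]

  mat_lines <- read_lines_lf(matrix_path)
  mat_lines <- mat_lines[nzchar(mat_lines)]
  mat_header <- strsplit(mat_lines[[1L]], "\t", fixed = TRUE)[[1L]]
  mat_samples <- mat_header[-1L]
  n_s <- length(mat_samples)
  data_rows <- mat_lines[-1L]
  probes <- character(length(data_rows))
  values <- matrix(NA_real_, nrow = length(data_rows), ncol = n_s)
  for (i in seq_along(data_rows)) {
    fields <- strsplit(data_rows[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != n_s + 1L) {
      format_error("ragged row at line ", i + 1L, " of ", matrix_path)
    }
    probes[i] <- fields[1L]
    values[i, ] <- parse_numeric_cells(fields[-1L], i + 1L, matrix_path)
  }
  dimnames(values) <- list(probes, mat_samples)
  values <- impute_row_means(values)

  keep <- sdrf_ids %in% mat_samples
  if (!any(keep)) {
    stop("no overlapping sample names between SDRF and data matrix",
         call. = FALSE)
  }
  if (any(!keep)) {
    warning(sprintf("dropping %d SDRF sample(s) absent from matrix: %s",
                    sum(!keep), paste(sdrf_ids[!keep], collapse = ", ")),
            call. = FALSE)
  }
  sdrf <- sdrf[keep, , drop = FALSE]
  # columns of the output matrix follow matrix-file order restricted to SDRF
  ord <- match(sdrf[[1L]], mat_samples)
  values <- values[, ord, drop = FALSE]

  metadata <- tx_metadata(sdrf[[1L]], sdrf[-1L])
  names(metadata) <- c("sample_id", header[-1L])
  list(matrix = tx_matrix(values, scale = "log2_intensity"),
       metadata = metadata)
}

#' Read a platform annotation table
#'
#' Parses an Affymetrix-style tab-delimited annotation table mapping probe
#' ids to gene-level identifiers. Comment lines starting with `#` or `!`
#' are skipped. Empty, `"---"` and `"NA"` cells become missing identifiers;
#' multi-valued cells separated by `" /// "` keep the first token.
#'
#' @param path path to the annotation file.
#' @param probe_column name of the column holding probe ids.
#' @param id_columns named character vector `c(column_name = namespace)`
#'   selecting identifier columns and naming their namespaces, e.g.
#'   `c("ENTREZ_GENE_ID" = "ENTREZ_GENE_ID")`.
#' @param platform_id platform accession recorded in the result.
#' @return a [tx_platform()].
#' @export
read_platform_annotation <- function(path, probe_column, id_columns,
                                     platform_id = "custom") {
  lines <- read_lines_lf(path)
  lines <- lines[!grepl("^[#!]", lines) & nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  header <- rows[[1L]]
  if (!(probe_column %in% header)) {
    stop("probe column '", probe_column, "' not found; available: ",
         paste(header, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(names(id_columns), header)
  if (length(missing_cols) > 0L) {
    stop("annotation column(s) not found: ",
         paste(missing_cols, collapse = ", "),
         "; available: ", paste(header, collapse = ", "), call. = FALSE)
  }
  body <- lapply(rows[-1L], function(r) { length(r) <- length(header); r })
  tbl <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(tbl) <- header

  clean_ids <- function(v) {
    v <- vapply(strsplit(v, " /// ", fixed = TRUE),
                function(x) if (length(x) == 0L) "" else x[1L], character(1))
    v[v %in% c("", "---", "NA") | is.na(v)] <- NA_character_
    v
  }
  mapping <- lapply(names(id_columns), function(col) clean_ids(tbl[[col]]))
  names(mapping) <- unname(id_columns)
  tx_platform(platform_id, tbl[[probe_column]],
              as.data.frame(mapping, optional = TRUE,
                            stringsAsFactors = FALSE))
}

join_fields <- function(fields, delimiter, dialect) {
  has_delim <- grepl(delimiter, fields, fixed = TRUE)
  if (dialect == "tsv" && any(has_delim)) {
    stop("delimiter found inside identifier '",
         fields[has_delim][1L], "'; ids are never quoted in TSV",
         call. = FALSE)
  }
  if (dialect == "csv") {
    need_quote <- has_delim | grepl('"', fields, fixed = TRUE)
    fields[need_quote] <- paste0('"', gsub('"', '""', fields[need_quote]), '"')
  }
  paste(fields, collapse = delimiter)
}

resolve_delim <- function(dialect, delimiter) {
  dialect <- match.arg(dialect, c("tsv", "csv"))
  if (is.null(delimiter)) delimiter <- if (dialect == "tsv") "\t" else ","
  if (nchar(delimiter) != 1L) stop("delimiter must be a single character",
                                   call. = FALSE)
  list(dialect = dialect, delimiter = delimiter)
}

#' Write an expression matrix as TSV/CSV
#'
#' Line 1 holds an empty leading field followed by the sample names, so
#' every line has the same field count; each later line holds one probe id
#' and its expression values at full double precision (at least 15
#' significant digits).
#'
#' @param matrix a [tx_matrix()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param delimiter single delimiter character; defaults to tab for TSV
#'   and `","` for CSV.
#' @return `path`, invisibly.
#' @export
write_table <- function(matrix, path, dialect = "tsv", delimiter = NULL) {
  d <- resolve_delim(dialect, delimiter)
  ids_check <- c(rownames(matrix), colnames(matrix))
  if (any(grepl(d$delimiter, ids_check, fixed = TRUE)) && d$dialect == "tsv") {
    stop("delimiter found inside identifier; ids are never quoted in TSV",
         call. = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- join_fields(c("", colnames(matrix)), d$delimiter, d$dialect)
  writeLines(header, con, sep = "\n")
  if (nrow(matrix) > 0L) {
    vals <- format(unclass(matrix), digits = 15L, trim = TRUE,
                   scientific = FALSE)
    lines <- vapply(seq_len(nrow(matrix)), function(i) {
      join_fields(c(rownames(matrix)[i], vals[i, ]), d$delimiter, d$dialect)
    }, character(1))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

split_dsv_line <- function(line, delimiter, quoting = FALSE) {
  if (!quoting || !grepl('"', line, fixed = TRUE)) {
    out <- strsplit(line, delimiter, fixed = TRUE)[[1L]]
    # a trailing empty field is dropped by strsplit; restore it
    if (endsWith(line, delimiter)) out <- c(out, "")
    return(out)
  }
  # RFC-style quoted fields (CSV dialect only)
  out <- character(0)
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  field <- character(0)
  in_q <- FALSE
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_q) {
      if (ch == '"') {
        if (i < length(chars) && chars[i + 1L] == '"') {
          field <- c(field, '"'); i <- i + 1L
        } else in_q <- FALSE
      } else field <- c(field, ch)
    } else if (ch == '"') {
      in_q <- TRUE
    } else if (ch == delimiter) {
      out <- c(out, paste(field, collapse = "")); field <- character(0)
    } else field <- c(field, ch)
    i <- i + 1L
  }
  c(out, paste(field, collapse = ""))
}

#' Read a matrix written by [write_table()]
#' @inheritParams write_table
#' @param scale scale tag to attach to the result.
#' @return a [tx_matrix()].
#' @export
read_table <- function(path, dialect = "tsv", delimiter = NULL,
                       scale = "log2_intensity") {
  d <- resolve_delim(dialect, delimiter)
  lines <- read_lines_lf(path)
  if (length(lines) == 0L) format_error("empty file: ", path)
  header <- split_dsv_line(lines[1L], d$delimiter, quoting = d$dialect == "csv")
  samples <- header[-1L]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  probes <- character(length(body))
  values <- matrix(NA_real_, length(body), length(samples))
  for (i in seq_along(body)) {
    fields <- split_dsv_line(body[i], d$delimiter, quoting = d$dialect == "csv")
    if (length(fields) != length(samples) + 1L) {
      format_error("ragged row at line ", i + 1L, " of ", path)
    }
    probes[i] <- fields[1L]
    values[i, ] <- parse_numeric_cells(fields[-1L], i + 1L, path)
  }
  dimnames(values) <- list(probes, samples)
  tx_matrix(values, scale = scale)
}

#' Write sample metadata as TSV/CSV
#'
#' Header row is `sample_id` followed by the attribute names; one row per
#' sample. In the CSV dialect, values containing the delimiter or quotes
#' are RFC-quoted.
#'
#' @param metadata a [tx_metadata()].
#' @inheritParams write_table
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path, dialect = "tsv", delimiter = NULL) {
  d <- resolve_delim(dialect, delimiter)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(join_fields(names(metadata), d$delimiter, d$dialect), con,
             sep = "\n")
  for (i in seq_len(nrow(metadata))) {
    writeLines(join_fields(unlist(metadata[i, ], use.names = FALSE),
                           d$delimiter, d$dialect), con, sep = "\n")
  }
  invisible(path)
}

#' Read metadata written by [write_metadata()]
#' @inheritParams read_table
#' @return a [tx_metadata()].
#' @export
read_metadata <- function(path, dialect = "tsv", delimiter = NULL) {
  d <- resolve_delim(dialect, delimiter)
  lines <- read_lines_lf(path)
  if (length(lines) == 0L) format_error("empty metadata file: ", path)
  header <- split_dsv_line(lines[1L], d$delimiter, quoting = d$dialect == "csv")
  body <- lines[-1L]
  rows <- lapply(body, function(ln) {
    f <- split_dsv_line(ln, d$delimiter, quoting = d$dialect == "csv")
    length(f) <- length(header)
    f
  })
  tbl <- as.data.frame(do.call(rbind, c(rows, list(deparse.level = 0))),
                       stringsAsFactors = FALSE)
  if (length(body) == 0L) {
    tbl <- as.data.frame(matrix(character(0), 0, length(header)),
                         stringsAsFactors = FALSE)
  }
  names(tbl) <- header
  md <- tx_metadata(tbl[[1L]], tbl[-1L])
  names(md) <- c("sample_id", header[-1L])
  md
}
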
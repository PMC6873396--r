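# Toy-file generators used by the test-suite and the examples: emit small
# datasets in every supported input format, so no real downloads are needed.

#' Generate a random toy dataset
#'
#' @param n_probes,n_samples dimensions.
#' @param n_attrs number of metadata attributes.
#' @param seed RNG seed.
#' @param prefix prefix for probe/sample ids.
#' @return list with `matrix` ([tx_matrix()]) and `metadata`
#'   ([tx_metadata()]).
#' @export
random_dataset <- function(n_probes = 10, n_samples = 4, n_attrs = 3,
                           seed = 1L, prefix = "GSM") {
  set.seed(seed)
  probes <- sprintf("p%03d", seq_len(n_probes))
  samples <- sprintf("%s%d", prefix, seq_len(n_samples))
  values <- matrix(round(stats::rnorm(n_probes * n_samples, 7, 1.5), 4),
                   n_probes, n_samples, dimnames = list(probes, samples))
  vocab <- c("H460", "H125", "lung", "liver", "control", "treated",
             "non-small cell", "adenocarcinoma")
  tbl <- as.data.frame(
    replicate(n_attrs, sample(vocab, n_samples, replace = TRUE),
              simplify = FALSE),
    stringsAsFactors = FALSE)
  names(tbl) <- sprintf("attr_%d", seq_len(n_attrs))
  list(matrix = tx_matrix(values, scale = "log2_intensity"),
       metadata = tx_metadata(samples, tbl))
}

#' Write a dataset as a GEO-style series matrix file
#'
#' @param matrix a [tx_matrix()].
#' @param metadata a [tx_metadata()]; each attribute becomes one
#'   `!Sample_<attr>` line.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_matrix_fixture <- function(matrix, metadata, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("!Series_title\t\"toy series\"", con, sep = "\n")
  for (a in metadata_attributes(metadata)) {
    vals <- paste0('"', metadata[[a]], '"', collapse = "\t")
    writeLines(paste0("!Sample_", a, "\t", vals), con, sep = "\n")
  }
  writeLines("!series_matrix_table_begin", con, sep = "\n")
  writeLines(paste(c("\"ID_REF\"",
                     paste0('"', colnames(matrix), '"')), collapse = "\t"),
             con, sep = "\n")
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(c(paste0('"', rownames(matrix)[i], '"'),
                       format(unclass(matrix)[i, ], digits = 15, trim = TRUE,
                              scientific = FALSE)), collapse = "\t"),
               con, sep = "\n")
  }
  writeLines("!series_matrix_table_end", con, sep = "\n")
  invisible(path)
}

#' Write a dataset as a MAGE-TAB SDRF plus data matrix pair
#'
#' @inheritParams write_series_matrix_fixture
#' @param sdrf_path,matrix_path output paths.
#' @param id_column name of the first SDRF column (the sample name column).
#' @return `c(sdrf_path, matrix_path)`, invisibly.
#' @export
write_magetab_fixture <- function(matrix, metadata, sdrf_path, matrix_path,
                                  id_column = "Source Name") {
  con <- file(sdrf_path, open = "wb")
  writeLines(paste(c(id_column, metadata_attributes(metadata)),
                   collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(metadata))) {
    writeLines(paste(unlist(metadata[i, ], use.names = FALSE),
                     collapse = "\t"), con, sep = "\n")
  }
  close(con)

  con <- file(matrix_path, open = "wb")
  writeLines(paste(c("ID_REF", colnames(matrix)), collapse = "\t"), con,
             sep = "\n")
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(c(rownames(matrix)[i],
                       format(unclass(matrix)[i, ], digits = 15, trim = TRUE,
                              scientific = FALSE)), collapse = "\t"),
               con, sep = "\n")
  }
  close(con)
  invisible(c(sdrf_path, matrix_path))
}

#' Write a toy Affymetrix-style platform annotation table
#'
#' @param probe_ids probe identifiers (rows).
#' @param entrez,symbol character vectors aligned with `probe_ids`; use
#'   `NA` or `""` for unannotated probes. Multi-valued entries may use the
#'   `" /// "` separator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_fixture <- function(probe_ids, entrez, symbol, path) {
  entrez[is.na(entrez)] <- ""
  symbol[is.na(symbol)] <- ""
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# toy annotation table", con, sep = "\n")
  writeLines("ID\tENTREZ_GENE_ID\tGENE_SYMBOL", con, sep = "\n")
  for (i in seq_along(probe_ids)) {
    writeLines(paste(c(probe_ids[i], entrez[i], symbol[i]), collapse = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}
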
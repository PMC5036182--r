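#' Read an OTU count table
#'
#' Reads either the classic tab-separated OTU table dialect (first column =
#' OTU id, header row = sample ids, optional trailing `taxonomy` column,
#' UTF-8, `.` decimal, no quoting) or a BIOM file (via the \pkg{biomformat}
#' package).
#'
#' @param path file path
#' @param dialect `"classic_tsv"` or `"biom"`
#' @return a [count_table]
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path, dialect = c("classic_tsv", "biom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stopf("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(count_table(m))
  }
  # tolerate a QIIME-style "# Constructed from biom file" banner line
  first <- readLines(path, n = 1L)
  skip <- if (grepl("^#\\s*Constructed", first)) 1L else 0L
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE, skip = skip)
  if (ncol(df) < 2L) stopf("malformed header in %s: need id + >=1 sample", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stopf("duplicate OTU id: %s", ids[duplicated(ids)][1L])
  df <- df[, -1L, drop = FALSE]
  taxonomy <- NULL
  taxcol <- which(tolower(names(df)) == "taxonomy")
  if (length(taxcol)) {
    taxonomy <- stats::setNames(as.character(df[[taxcol[1L]]]), ids)
    df <- df[, -taxcol, drop = FALSE]
  }
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v))
      stopf("non-numeric cell in sample column '%s'", names(df)[j])
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  count_table(m, taxonomy = taxonomy)
}

#' Write an OTU count table as classic TSV
#'
#' Round-trips bit-exactly through [read_count_table()]: tab separated,
#' header row `#OTU ID` plus sample ids, optional trailing taxonomy column.
#'
#' @param x a [count_table]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(`#OTU ID` = otu_ids(x), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy[otu_ids(x)])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read or validate per-sample metadata
#'
#' Sample metadata is a TSV with columns `sample_id`, `environment`
#' (`AS` or `AD`), `digester_id` (required for AD samples, empty for AS),
#' `date` (ISO-8601) and `molecule` (`rDNA` or `rRNA`). `sample_info()`
#' validates a data frame already in memory; `read_sample_info()` reads and
#' validates a file.
#'
#' @param path TSV path
#' @return a validated `data.frame` of class `sample_info`.
#' @export
read_sample_info <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  sample_info(df)
}

#' @rdname read_sample_info
#' @param df data.frame with the columns described above
#' @export
sample_info <- function(df) {
  need <- c("sample_id", "environment", "molecule")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("metadata is missing column '%s'", miss[1L])
  if (!"digester_id" %in% names(df)) df$digester_id <- NA_character_
  if (!"date" %in% names(df)) df$date <- NA_character_
  df$sample_id <- as.character(df$sample_id)
  df$digester_id <- as.character(df$digester_id)
  df$digester_id[!nzchar(df$digester_id) | is.na(df$digester_id)] <- NA_character_
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample_id '%s' in metadata",
          df$sample_id[duplicated(df$sample_id)][1L])
  bad <- setdiff(unique(df$environment), c("AS", "AD"))
  if (length(bad)) stopf("unknown environment '%s'", bad[1L])
  bad <- setdiff(unique(df$molecule), c("rDNA", "rRNA"))
  if (length(bad)) stopf("unknown molecule '%s'", bad[1L])
  no_dig <- df$environment == "AD" & is.na(df$digester_id)
  if (any(no_dig))
    stopf("AD sample '%s' has no digester_id", df$sample_id[no_dig][1L])
  df$date <- as.character(df$date)
  class(df) <- c("sample_info", "data.frame")
  df
}

#' @rdname read_sample_info
#' @param x a `sample_info` data frame
#' @export
write_sample_info <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select sample ids by metadata
#'
#' Convenience filter used to form groups such as "the AS rDNA samples" or
#' "digester 6, rRNA". `NULL` arguments are unconstrained.
#'
#' @param meta a [sample_info()] data frame
#' @param environment,molecule,digester_id optional values to match
#' @return character vector of matching sample ids.
#' @export
samples_where <- function(meta, environment = NULL, molecule = NULL,
                          digester_id = NULL) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(environment)) keep <- keep & meta$environment %in% environment
  if (!is.null(molecule)) keep <- keep & meta$molecule %in% molecule
  if (!is.null(digester_id)) keep <- keep & meta$digester_id %in% digester_id
  meta$sample_id[keep]
}

# Check that every sample column of a table has exactly one metadata row.
check_table_meta <- function(table, meta) {
  miss <- setdiff(sample_ids(table), meta$sample_id)
  if (length(miss))
    stopf("sample '%s' has no metadata record", miss[1L])
  invisible(TRUE)
}
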
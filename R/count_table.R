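#' OTU count tables
#'
#' A `count_table` holds non-negative integer counts of OTUs (rows) by
#' samples (columns), with unique identifiers on both margins and an
#' optional per-OTU taxonomy string. It is the raw substrate of every
#' downstream stage: occupancy analysis, rarefaction, activity ratios and
#' growth-rate estimation.
#'
#' @param counts integer matrix (OTU x sample) with unique, non-empty
#'   rownames (OTU ids) and colnames (sample ids). All entries must be
#'   non-negative integers and every sample column must have a positive sum.
#' @param taxonomy optional character vector of taxonomy strings, either
#'   named by OTU id or in row order.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (named character or `NULL`).
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 2L, 1L, 9L), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' ct <- count_table(m)
#' ct
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix must have OTU rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate OTU id: %s",
          rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample id: %s",
          colnames(counts)[duplicated(colnames(counts))][1L])
  if (any(!is.finite(counts)))
    stopf("counts contain missing or non-finite values")
  if (any(counts < 0))
    stopf("negative count in row '%s'",
          rownames(counts)[which(counts < 0, arr.ind = TRUE)[1L, 1L]])
  if (any(abs(counts - round(counts)) > 1e-8))
    stopf("non-integer count in row '%s'",
          rownames(counts)[which(abs(counts - round(counts)) > 1e-8,
                                 arr.ind = TRUE)[1L, 1L]])
  storage.mode(counts) <- "integer"
  cs <- colSums(counts)
  if (any(cs == 0L))
    stopf("sample '%s' has zero total count", colnames(counts)[cs == 0L][1L])
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (is.null(names(taxonomy))) {
      if (length(taxonomy) != nrow(counts))
        stopf("taxonomy length does not match number of OTUs")
      names(taxonomy) <- rownames(counts)
    }
    taxonomy <- taxonomy[rownames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d OTUs x %d samples, total %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  if (!is.null(x$taxonomy)) cat("  taxonomy: present\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' @export
as.matrix.count_table <- function(x, ...) x$counts

#' OTU and sample identifiers of a count table
#' @param x a [count_table]
#' @return character vector of identifiers.
#' @export
otu_ids <- function(x) rownames(x$counts)

#' @rdname otu_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Subset a count table
#'
#' Retains the given OTUs and/or samples. Samples whose column sum becomes
#' zero after OTU subsetting are dropped (a count table never carries empty
#' samples).
#'
#' @param x a [count_table]
#' @param otus,samples character vectors of ids to keep (default: all)
#' @param drop_empty_otus drop OTU rows that become all-zero
#' @return a [count_table]
#' @export
subset_table <- function(x, otus = NULL, samples = NULL,
                         drop_empty_otus = FALSE) {
  m <- x$counts
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing)) stopf("unknown sample id: %s", missing[1L])
    m <- m[, samples, drop = FALSE]
  }
  if (!is.null(otus)) {
    missing <- setdiff(otus, rownames(m))
    if (length(missing)) stopf("unknown OTU id: %s", missing[1L])
    m <- m[otus, , drop = FALSE]
  }
  if (drop_empty_otus) m <- m[rowSums(m) > 0L, , drop = FALSE]
  m <- m[, colSums(m) > 0L, drop = FALSE]
  count_table(m, taxonomy = x$taxonomy[rownames(m)])
}
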
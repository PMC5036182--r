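#' Convert counts to relative abundance
#'
#' Divides every sample column by its total so that each column sums to 1.
#'
#' @param x a [count_table], or a numeric matrix of counts
#' @return numeric matrix (OTU x sample) of fractions; columns sum to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  cs <- colSums(m)
  if (any(cs <= 0))
    stopf("sample '%s' has zero total count", colnames(m)[cs <= 0][1L])
  sweep(m, 2L, cs, "/")
}

#' Pooled relative-abundance profile of a sample group
#'
#' Forms the group profile as the arithmetic mean of the per-sample
#' fraction vectors (not as pooled raw counts), so that samples with
#' unequal residual depths carry equal weight. This is how the package
#' forms "the AS community" and per-digester AD profiles.
#'
#' @param x a [count_table]
#' @param samples character vector of sample ids defining the group
#' @return named numeric vector over OTUs; sums to 1.
#' @seealso [samples_where()] to build `samples` from metadata.
#' @export
pool_profile <- function(x, samples) {
  if (length(samples) == 0L) stopf("empty sample group")
  miss <- setdiff(samples, sample_ids(x))
  if (length(miss)) stopf("unknown sample id: %s", miss[1L])
  p <- relative_abundance(x)[, samples, drop = FALSE]
  rowMeans(p)
}

#' Rarefy a count table to even depth
#'
#' Subsamples every sample column to exactly `depth` reads without
#' replacement (multivariate hypergeometric), the subsampling semantics of
#' the classic amplicon toolchains. Samples with fewer than `depth` total
#' reads are dropped with a message. A fixed `seed` makes the draw
#' reproducible; the caller's RNG state is left untouched.
#'
#' @param x a [count_table]
#' @param depth positive integer target depth
#' @param seed integer RNG seed (default 1833)
#' @return a [count_table] in which every retained column sums to `depth`.
#' @export
rarefy <- function(x, depth, seed = 1833L) {
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    stopf("`depth` must be a positive integer")
  depth <- as.integer(depth)
  m <- x$counts
  totals <- colSums(m)
  drop <- totals < depth
  if (any(drop)) {
    message(sprintf("rarefy: dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(colnames(m)[drop], collapse = ", ")))
    m <- m[, !drop, drop = FALSE]
    totals <- totals[!drop]
  }
  if (ncol(m) == 0L) stopf("no sample reaches depth %d", depth)
  out <- with_seed(seed, {
    apply_cols <- vapply(seq_len(ncol(m)), function(j) {
      cnt <- m[, j]
      if (totals[j] == depth) return(cnt)
      picked <- sample.int(totals[j], depth)
      # map sampled read indices back to OTUs via cumulative counts
      tabulate(findInterval(picked - 1L, cumsum(cnt), left.open = FALSE) + 1L,
               nbins = length(cnt))
    }, integer(nrow(m)))
    apply_cols
  })
  out <- matrix(out, nrow = nrow(m))
  dimnames(out) <- dimnames(m)
  count_table(out[rowSums(out) > 0L, , drop = FALSE],
              taxonomy = x$taxonomy)
}
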
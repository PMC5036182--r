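#' Occupancy and abundance summary per OTU
#'
#' Occupancy of an OTU is the number of samples in which it is detected
#' (count > 0). Together with mean relative abundance it is the basis of
#' the core-community analysis: digester communities typically show a
#' bimodal occupancy distribution (transient feed-derived OTUs at low
#' occupancy, resident populations detected in every sample) and a strong
#' positive occupancy-abundance correlation.
#'
#' @param x a [count_table]
#' @return `data.frame` with columns `otu_id`, `occupancy`,
#'   `total_abundance` (summed per-sample fractions) and `mean_abundance`.
#' @export
occupancy_distribution <- function(x) {
  m <- x$counts
  if (nrow(m) == 0L || ncol(m) == 0L) stopf("empty count table")
  p <- relative_abundance(m)
  data.frame(otu_id = rownames(m),
             occupancy = as.integer(rowSums(m > 0L)),
             total_abundance = rowSums(p),
             mean_abundance = rowMeans(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Occupancy-abundance correlation
#'
#' Spearman rank correlation between occupancy and log10 mean relative
#' abundance across OTUs (the log transform does not change ranks; it is
#' kept for plotting consistency).
#'
#' @param records output of [occupancy_distribution()]
#' @return list with `rho` and `p_value`.
#' @export
occupancy_abundance_correlation <- function(records) {
  if (nrow(records) < 3L) stopf("need at least 3 OTUs")
  occ <- records$occupancy
  ab <- log10(records$mean_abundance)
  if (length(unique(occ)) < 2L || length(unique(ab)) < 2L)
    stopf("correlation undefined for constant input")
  ct <- suppressWarnings(
    stats::cor.test(occ, ab, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Abundant OTUs of a single sample profile
#'
#' Sorts OTUs by descending abundance and returns the minimal prefix whose
#' cumulative abundance reaches `quantile` (default: the top 80% of reads).
#' The OTU that crosses the threshold is included. Ties are broken by
#' lexicographic OTU id so the set is deterministic.
#'
#' @param profile named numeric vector of relative abundances (sums to 1)
#' @param quantile cumulative abundance threshold in (0, 1]
#' @return character vector of OTU ids.
#' @export
abundant_set <- function(profile, quantile = 0.80) {
  if (is.null(names(profile))) stopf("profile must be named by OTU id")
  if (abs(sum(profile) - 1) > 1e-6)
    stopf("profile does not sum to 1 (sum = %g)", sum(profile))
  ord <- order(-profile, names(profile), method = "radix")
  p <- profile[ord]
  k <- which(cumsum(p) >= quantile - 1e-9)[1L]
  if (is.na(k)) k <- length(p)
  names(p)[seq_len(k)]
}

#' Select core populations
#'
#' Core populations are OTUs detected in every sample in scope (full
#' occupancy) that also belong to the abundant set (top `quantile`
#' cumulative abundance) of samples, either of every sample (default,
#' `rule = "every_sample"`) or of at least one (`rule = "any_sample"`).
#' The table passed in should already be restricted to the samples in
#' scope (e.g. the AD rDNA samples).
#'
#' @param x a [count_table] restricted to the samples in scope
#' @param quantile per-sample cumulative abundance threshold (default 0.80)
#' @param rule abundance rule: `"every_sample"` or `"any_sample"`
#' @return object of class `core_set`: list with `otu_ids`, `abundant`
#'   (per-sample abundant OTU lists), `occupancy` (the occupancy table),
#'   `summed_mean_abundance` (summed mean relative abundance of the core)
#'   and `params`.
#' @export
select_core <- function(x, quantile = 0.80,
                        rule = c("every_sample", "any_sample")) {
  rule <- match.arg(rule)
  m <- x$counts
  n <- ncol(m)
  p <- relative_abundance(m)
  abundant <- lapply(seq_len(n), function(j) abundant_set(p[, j], quantile))
  names(abundant) <- colnames(m)
  occ <- occupancy_distribution(x)
  full <- occ$otu_id[occ$occupancy == n]
  in_sets <- table(unlist(abundant, use.names = FALSE))
  needed <- if (rule == "every_sample") n else 1L
  abundant_enough <- names(in_sets)[in_sets >= needed]
  core <- sort(intersect(full, abundant_enough))
  structure(list(
    otu_ids = core,
    abundant = abundant,
    occupancy = occ,
    summed_mean_abundance =
      sum(occ$mean_abundance[occ$otu_id %in% core]),
    params = list(quantile = quantile, rule = rule,
                  required_occupancy = n)),
    class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf(paste0(
    "<core_set> %d core OTUs (occupancy %d/%d, top-%.0f%% rule '%s')\n",
    "  summed mean relative abundance: %.1f%%\n"),
    length(x$otu_ids), x$params$required_occupancy,
    x$params$required_occupancy, 100 * x$params$quantile, x$params$rule,
    100 * x$summed_mean_abundance))
  invisible(x)
}

#' Alpha diversity of a sample
#'
#' Observed OTUs, bias-corrected Chao1 (via \pkg{vegan}) and the Shannon
#' index. Shannon is reported in both natural-log and log2 units because
#' different toolchains default to different bases.
#'
#' @param counts non-negative integer vector of one sample's counts, or a
#'   [count_table] (one result row per sample)
#' @return for a vector, a named numeric vector with `observed`, `chao1`,
#'   `shannon` (ln) and `shannon_log2`; for a table, a data.frame.
#' @export
alpha_diversity <- function(counts) {
  if (inherits(counts, "count_table")) {
    res <- t(apply(counts$counts, 2L, alpha_diversity))
    return(data.frame(sample_id = sample_ids(counts), res,
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  v <- counts
  if (any(v < 0) || sum(v) <= 0)
    stopf("counts must be non-negative with positive sum")
  v <- round(v)
  est <- vegan::estimateR(v)
  sh <- vegan::diversity(v, index = "shannon")
  c(observed = unname(est["S.obs"]),
    chao1 = unname(est["S.chao1"]),
    shannon = unname(sh),
    shannon_log2 = unname(sh) / log(2))
}
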
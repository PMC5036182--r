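#' Per-OTU rRNA/rDNA activity ratios
#'
#' For each OTU, the ratio of its relative abundance in the 16S rRNA
#' (transcript) library to its relative abundance in the 16S rRNA gene
#' (rDNA) library — a widely used per-cell activity proxy. Ratios are
#' computed from pooled (group-mean) profiles of one environment. OTUs
#' with a zero in either molecule get `NA` (flagged, never silently zero);
#' alternatively a pseudocount can be added to both profiles.
#'
#' @param rdna,rrna named relative-abundance vectors over the same OTU
#'   universe (e.g. from [pool_profile()])
#' @param pseudocount abundance added to both profiles before the ratio
#'   (default 0 = zeros excluded)
#' @return `data.frame` with `otu_id`, `rdna`, `rrna`, `ratio`, `defined`.
#' @export
compute_ratio <- function(rdna, rrna, pseudocount = 0) {
  if (is.null(names(rdna)) || is.null(names(rrna)))
    stopf("profiles must be named by OTU id")
  if (!setequal(names(rdna), names(rrna)))
    stopf("rDNA and rRNA profiles cover different OTU universes")
  rrna <- rrna[names(rdna)]
  if (pseudocount > 0) {
    d <- rdna + pseudocount
    r <- rrna + pseudocount
    ratio <- r / d
  } else {
    ratio <- ifelse(rdna > 0 & rrna > 0, rrna / rdna, NA_real_)
  }
  data.frame(otu_id = names(rdna), rdna = unname(rdna),
             rrna = unname(rrna), ratio = unname(ratio),
             defined = !is.na(ratio),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-environment activity index
#'
#' The index of an OTU is its rRNA/rDNA ratio in the digester divided by
#' its ratio in the feed, `[rRNA/rDNA]_AD : [rRNA/rDNA]_AS`. An index
#' above 1 is conventionally read as "more active in AD", below 1 as
#' "more active in AS". The package reproduces this reading while the
#' growth model shows why it can mislabel decaying feed populations whose
#' residual rRNA is carried into the digester.
#'
#' @param records_as,records_ad outputs of [compute_ratio()] for the AS
#'   and AD environments
#' @return `data.frame` with `otu_id`, `r_as`, `r_ad`, `index`, `label`
#'   (`"more_active_in_AD"`, `"more_active_in_AS"`, `"boundary"` or
#'   `"undefined"`).
#' @export
activity_index <- function(records_as, records_ad) {
  if (!setequal(records_as$otu_id, records_ad$otu_id))
    stopf("AS and AD ratio records cover different OTU universes")
  ad <- records_ad[match(records_as$otu_id, records_ad$otu_id), ]
  idx <- ad$ratio / records_as$ratio
  label <- rep("undefined", length(idx))
  ok <- !is.na(idx)
  label[ok & idx > 1] <- "more_active_in_AD"
  label[ok & idx < 1] <- "more_active_in_AS"
  label[ok & idx == 1] <- "boundary"
  data.frame(otu_id = records_as$otu_id,
             r_as = records_as$ratio, r_ad = ad$ratio,
             index = idx, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-regime rRNA-rDNA correlation diagnostic
#'
#' The rRNA/rDNA ratio is only comparable across environments when rRNA
#' and rDNA relative abundances follow a single common correlation. In a
#' digester fed by activated sludge two regimes coexist: natively growing
#' populations and decaying feed-derived populations with different rRNA
#' yield per gene copy. This diagnostic fits per-group ordinary least
#' squares of log10 rRNA on log10 rDNA abundance and tests slope
#' homogeneity with the F test on the interaction term of the two-group
#' linear model (an ANCOVA).
#'
#' @param rdna,rrna named relative-abundance vectors over one environment
#' @param groups factor or character vector (named by OTU id, or in the
#'   order of `rdna`) partitioning OTUs, e.g. by the sign of the estimated
#'   growth rate
#' @param log10 fit on log10 abundances (default) or raw abundances
#' @return object of class `ratio_diagnostic`: list with `pooled_r`,
#'   `group_r`, `group_slope`, `group_n`, `F_statistic`, `p_value`.
#' @export
correlation_diagnostic <- function(rdna, rrna, groups, log10 = TRUE) {
  if (!setequal(names(rdna), names(rrna)))
    stopf("rDNA and rRNA profiles cover different OTU universes")
  rrna <- rrna[names(rdna)]
  if (!is.null(names(groups))) groups <- groups[names(rdna)]
  if (length(groups) != length(rdna))
    stopf("`groups` must cover every OTU")
  keep <- rdna > 0 & rrna > 0 & !is.na(groups)
  x <- rdna[keep]; y <- rrna[keep]; g <- factor(groups[keep])
  if (log10) { x <- base::log10(x); y <- base::log10(y) }
  if (nlevels(g) < 2L) stopf("need at least 2 groups with detected OTUs")
  if (any(table(g) < 3L))
    stopf("need at least 3 OTUs with both molecules detected per group")
  for (lev in levels(g)) {
    if (stats::sd(x[g == lev]) == 0 || stats::sd(y[g == lev]) == 0)
      stopf("group '%s' is degenerate (constant abundances)", lev)
  }
  pooled <- stats::cor(x, y)
  by_group <- vapply(levels(g), function(lev) {
    i <- g == lev
    c(r = stats::cor(x[i], y[i]),
      slope = unname(stats::coef(stats::lm(y[i] ~ x[i]))[2L]),
      n = sum(i))
  }, numeric(3))
  m0 <- stats::lm(y ~ x + g)
  m1 <- stats::lm(y ~ x * g)
  an <- stats::anova(m0, m1)
  structure(list(pooled_r = pooled,
                 group_r = by_group["r", ],
                 group_slope = by_group["slope", ],
                 group_n = by_group["n", ],
                 F_statistic = an$F[2L],
                 p_value = an$`Pr(>F)`[2L],
                 log10 = log10),
            class = "ratio_diagnostic")
}

#' @export
print.ratio_diagnostic <- function(x, ...) {
  cat(sprintf("<ratio_diagnostic> pooled r = %.3f (%s scale)\n",
              x$pooled_r, if (x$log10) "log10" else "raw"))
  for (lev in names(x$group_r))
    cat(sprintf("  group %-10s r = %.3f, slope = %.3f, n = %d\n",
                lev, x$group_r[lev], x$group_slope[lev],
                as.integer(x$group_n[lev])))
  cat(sprintf("  slope homogeneity: F = %.2f, p = %.3g\n",
              x$F_statistic, x$p_value))
  invisible(x)
}
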
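#' Activity-based digestion efficiency, part 1: undetected feed OTUs
#'
#' The summed feed relative abundance of OTUs never detected in the
#' digester — populations digested (or diluted) below the detection limit.
#'
#' @param as_profile named feed relative-abundance vector
#' @param ad_otus character vector of OTU ids detected in the digester
#' @return fraction in \[0, 1\].
#' @export
part1_undetected <- function(as_profile, ad_otus) {
  if (is.null(names(as_profile))) stopf("profile must be named by OTU id")
  sum(as_profile[!(names(as_profile) %in% ad_otus)])
}

#' Activity-based digestion efficiency, part 2: digested negative-mu biomass
#'
#' For each shared OTU with negative growth, the digested biomass is its
#' feed biomass flux minus its remaining effluent flux,
#' `feed_flux * p_AS - ad_flux * p_AD` (fluxes in Q*TS*VS units). The sum
#' over the negative-mu set, divided by the total feed flux, is the
#' fraction of the feed community digested while still detectable.
#'
#' @param as_profile,ad_profile named relative-abundance vectors over a
#'   common OTU universe
#' @param negative_otus OTU ids with negative growth (must be shared OTUs)
#' @param feed_flux,ad_flux scalar biomass fluxes `Q*TS*VS` of the feed
#'   and the digester effluent
#' @return fraction of the feed community.
#' @export
part2_negative_growth <- function(as_profile, ad_profile, negative_otus,
                                  feed_flux, ad_flux) {
  if (feed_flux <= 0 || ad_flux <= 0) stopf("flux scalars must be positive")
  miss <- setdiff(negative_otus, intersect(names(as_profile),
                                           names(ad_profile)))
  if (length(miss))
    stopf("negative-mu OTU '%s' is not in both profiles", miss[1L])
  terms <- feed_flux * as_profile[negative_otus] -
    ad_flux * ad_profile[negative_otus]
  bad <- terms < -1e-12 * feed_flux
  if (any(bad))
    stopf(paste0("negative digested-biomass term for OTU '%s': ",
                 "mu sign and profiles are inconsistent"),
          negative_otus[bad][1L])
  sum(terms) / feed_flux
}

#' Total activity-based digestion efficiency
#'
#' The digested fraction of the feed community: undetected feed OTUs
#' (part 1) plus the digested biomass of detectable negative-mu OTUs
#' (part 2).
#'
#' @param part1,part2 fractions in \[0, 1\]
#' @return their sum, a fraction in \[0, 1\].
#' @export
total_model_efficiency <- function(part1, part2) {
  if (part1 < 0 || part1 > 1 || part2 < 0 || part2 > 1)
    stopf("parts must be fractions in [0, 1]")
  tot <- part1 + part2
  if (tot > 1 + 1e-9)
    stopf("part1 + part2 = %.4f exceeds 1: inconsistent inputs", tot)
  min(tot, 1)
}

#' Van Kleeck volatile solids reduction
#'
#' The conventional VSR estimator that assumes fixed (non-volatile) solids
#' are conserved through digestion:
#' `VSR = (VS_feed - VS_dig) / (VS_feed - VS_feed * VS_dig)` with both VS
#' values expressed as fractions of total solids.
#'
#' @param vs_feed,vs_digested volatile solids fractions of TS, in (0, 1)
#' @return VSR fraction.
#' @export
vsr_vankleeck <- function(vs_feed, vs_digested) {
  if (any(c(vs_feed, vs_digested) <= 0) || any(c(vs_feed, vs_digested) >= 1))
    stopf("VS fractions must lie strictly in (0, 1)")
  (vs_feed - vs_digested) / (vs_feed - vs_feed * vs_digested)
}

#' Approximate mass-balance volatile solids reduction
#'
#' `VSR = 1 - out_flux / feed_flux` with fluxes in `Q*TS*VS` units. Noisy
#' measurements can make the effluent flux exceed the feed flux; the
#' negative VSR is then returned with a warning rather than masked.
#'
#' @param feed_flux,out_flux volatile solids mass fluxes
#' @return VSR fraction (possibly negative, with a warning).
#' @export
vsr_massbalance <- function(feed_flux, out_flux) {
  if (feed_flux <= 0) stopf("feed flux must be positive")
  v <- 1 - out_flux / feed_flux
  if (v < 0)
    warning("effluent flux exceeds feed flux: negative VSR", call. = FALSE)
  v
}

#' New-growth fraction of the digested sludge
#'
#' Summed digester relative abundance of OTUs with positive growth —
#' biomass grown in the digester rather than surviving from the feed.
#' OTUs absent from the feed are included (their mu equals the dilution
#' rate, hence positive).
#'
#' @param ad_profile named digester relative-abundance vector
#' @param positive_otus OTU ids with positive mu
#' @return fraction in \[0, 1\].
#' @export
new_growth_fraction <- function(ad_profile, positive_otus) {
  if (is.null(names(ad_profile))) stopf("profile must be named by OTU id")
  sum(ad_profile[names(ad_profile) %in% positive_otus])
}

#' Digestion-efficiency report from a fitted growth model
#'
#' Combines the activity-based decomposition with the two conventional
#' VSR estimators. Part 1 sums the feed abundance of OTUs never detected
#' in any digester; part 2 aggregates, flux-weighted across digesters,
#' the digested biomass of OTUs whose mean mu is negative. OTUs whose
#' aggregate digested-biomass term comes out negative (a mu-sign /
#' profile disagreement possible under sampling noise) are excluded and
#' counted in `n_inconsistent`. The Van Kleeck estimate uses the
#' flow-weighted mean digester VS fraction against the feed VS fraction;
#' the mass-balance estimate compares total effluent and feed
#' volatile-solids fluxes.
#'
#' @param fit a [fit_growth()] object whose table covered the full OTU
#'   universe (feed-only OTUs included)
#' @return object of class `efficiency_report`: list with `part1`,
#'   `part2`, `total_model`, `vsr_vankleeck`, `vsr_massbalance`,
#'   `new_growth_fraction`, `n_negative`, `n_positive`, `n_undetected`,
#'   `n_inconsistent`.
#' @export
efficiency_report <- function(fit) {
  est <- fit$estimates
  rs <- fit$reactors
  p_as <- fit$p_as
  p_ad <- fit$p_ad

  undetected <- est$otu_id[est$status == "feed_only"]
  part1 <- part1_undetected(p_as, setdiff(est$otu_id, undetected))

  feed_flux_d <- rs$flow_mgd * rs$ts_as * rs$vs_as
  ad_flux_d <- rs$flow_out_mgd * rs$ts_ad * rs$vs_ad
  neg <- est$otu_id[!is.na(est$mu) & est$mu < 0 & est$status == "estimated"]
  # flux-weighted aggregate digested biomass per negative-mu OTU
  terms <- as.numeric(p_as[neg] %o% feed_flux_d -
                        p_ad[neg, , drop = FALSE] %*% diag(ad_flux_d, nrow(rs)))
  terms <- matrix(terms, nrow = length(neg))
  agg <- rowSums(terms)
  inconsistent <- agg < 0
  part2 <- sum(agg[!inconsistent]) / sum(feed_flux_d)

  pos <- est$otu_id[!is.na(est$mu) & est$mu > 0]
  mean_ad <- rowMeans(p_ad)

  vk <- sum(rs$flow_out_mgd * vsr_vankleeck(rs$vs_as, rs$vs_ad)) /
    sum(rs$flow_out_mgd)
  mb <- vsr_massbalance(sum(feed_flux_d), sum(ad_flux_d))

  structure(list(part1 = part1, part2 = part2,
                 total_model = total_model_efficiency(part1, part2),
                 vsr_vankleeck = vk, vsr_massbalance = mb,
                 new_growth_fraction = new_growth_fraction(mean_ad, pos),
                 n_negative = length(neg), n_positive = length(pos),
                 n_undetected = length(undetected),
                 n_inconsistent = sum(inconsistent)),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f%%", 100 * v)
  cat("<efficiency_report>\n")
  cat(sprintf("  part 1 (feed OTUs undetected in AD, %d OTUs): %s\n",
              x$n_undetected, pct(x$part1)))
  cat(sprintf("  part 2 (digested negative-mu biomass, %d OTUs): %s\n",
              x$n_negative, pct(x$part2)))
  cat(sprintf("  total activity-based efficiency: %s\n", pct(x$total_model)))
  cat(sprintf("  Van Kleeck VSR: %s\n", pct(x$vsr_vankleeck)))
  cat(sprintf("  approximate mass-balance VSR: %s\n", pct(x$vsr_massbalance)))
  cat(sprintf("  new-growth fraction of digested sludge (%d OTUs): %s\n",
              x$n_positive, pct(x$new_growth_fraction)))
  if (x$n_inconsistent > 0)
    cat(sprintf("  (%d OTUs with inconsistent flux terms excluded)\n",
                x$n_inconsistent))
  invisible(x)
}
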
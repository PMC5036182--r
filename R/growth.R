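#' Per-OTU specific growth rate from the steady-state mass balance
#'
#' Treats the digester as a completely mixed chemostat for each OTU x:
#' the standing stock N changes by growth (mu * N), feed influx and
#' effluent washout. Approximating cell mass by volatile solids and
#' relative abundance p by the OTU's share of that mass,
#' influx = Q_in * TS_AS * VS_AS * p_AS, efflux = Q_out * TS_AD * VS_AD *
#' p_AD and stock = V * TS_AD * VS_AD * p_AD. Closing the balance at
#' steady state (dN/dt = 0) gives
#'
#'   mu = D * (1 - (Q_in * TS_AS * VS_AS * p_AS) /
#'                 (Q_out * TS_AD * VS_AD * p_AD))
#'
#' with D the dilution rate. mu is capped above by D: an OTU absent from
#' the feed (p_AS = 0) must grow at exactly D to persist (`status
#' "ad_only"`), while an OTU present in the feed but undetected in the
#' digester (p_AD = 0) has been washed out or digested faster than it can
#' be observed (`status "feed_only"`, mu undefined). Negative mu means the
#' population is being digested: its feed influx exceeds its effluent
#' flux.
#'
#' @param p_as,p_ad relative abundances of the OTU(s) in the feed and the
#'   digester (vectors of equal length, values in \[0, 1\])
#' @param spec a single-row `reactor_spec`
#' @param mode how the dilution rate is formed, see [dilution_rate()]
#' @param feed_scale multiplier on the influx term; values below 1 model a
#'   feed only partially made of the profiled AS community (default 1)
#' @return `data.frame` with columns `mu`, `status`, `influx`, `efflux`,
#'   `stock` (flux terms in Q*TS*VS units).
#' @export
specific_growth_rate <- function(p_as, p_ad, spec,
                                 mode = c("srt", "v_over_q"),
                                 feed_scale = 1) {
  mode <- match.arg(mode)
  if (nrow(spec) != 1L) stopf("`spec` must be a single reactor")
  if (length(p_as) != length(p_ad))
    stopf("p_as and p_ad must have equal length")
  if (any(p_as < 0 | p_as > 1 | p_ad < 0 | p_ad > 1))
    stopf("relative abundances must lie in [0, 1]")
  D <- unname(dilution_rate(spec, mode))
  influx <- feed_scale * spec$flow_mgd * spec$ts_as * spec$vs_as * p_as
  efflux <- spec$flow_out_mgd * spec$ts_ad * spec$vs_ad * p_ad
  stock <- spec$volume_mg * spec$ts_ad * spec$vs_ad * p_ad
  mu <- ifelse(p_ad > 0, D * (1 - influx / efflux), NA_real_)
  status <- ifelse(p_ad == 0, "feed_only",
                   ifelse(p_as == 0, "ad_only", "estimated"))
  data.frame(mu = mu, status = status,
             influx = influx, efflux = efflux, stock = stock,
             stringsAsFactors = FALSE)
}

#' Fit the steady-state growth model to a community
#'
#' The main model-fitting entry point. Pools the feed (AS, rDNA) samples
#' into one profile and each digester's AD rDNA samples into per-digester
#' profiles, applies the steady-state mass balance per digester
#' (see [specific_growth_rate()]) and averages mu across the digesters in
#' which the OTU is detected. Returns a `growth_fit` object with `print`,
#' `summary`, `coef`, `plot` and `simulate` methods.
#'
#' `fit_growth_profiles()` is the profile-level interface used when the
#' pooled profiles are already known (e.g. noise-free expected abundances
#' from a simulation).
#'
#' @param table a [count_table] of rDNA counts covering both environments
#' @param meta a [sample_info()] data frame describing every sample
#' @param reactors a `reactor_spec` data frame, one row per digester; every
#'   digester must have AD rDNA samples in `table`
#' @param mode dilution-rate mode, see [dilution_rate()]
#' @param feed_scale influx multiplier, see [specific_growth_rate()]
#' @return object of class `growth_fit`: list with `estimates` (data.frame
#'   `otu_id`, `mu`, `status`, `n_digesters`), `mu_digester`, `influx`,
#'   `efflux`, `stock` (OTU x digester matrices), `p_as`, `p_ad`,
#'   `reactors`, `D`, `mode`, `feed_scale`, `call`.
#' @examples
#' sim <- simulate_community(sim_config(n_feed_otus = 60, n_ad_only_otus = 10,
#'                                      seed = 7))
#' fit <- fit_growth(sim$rdna, sim$meta, sim$reactors)
#' summary(fit)
#' @export
fit_growth <- function(table, meta, reactors, mode = c("srt", "v_over_q"),
                       feed_scale = 1) {
  mode <- match.arg(mode)
  check_table_meta(table, meta)
  as_samples <- intersect(samples_where(meta, "AS", "rDNA"),
                          sample_ids(table))
  if (length(as_samples) == 0L) stopf("no AS rDNA samples in table")
  p_as <- pool_profile(table, as_samples)
  p_ad <- vapply(reactors$digester_id, function(d) {
    s <- intersect(samples_where(meta, "AD", "rDNA", digester_id = d),
                   sample_ids(table))
    if (length(s) == 0L)
      stopf("no AD rDNA samples for digester '%s'", d)
    pool_profile(table, s)
  }, numeric(nrow(table$counts)))
  fit <- fit_growth_profiles(p_as, p_ad, reactors, mode = mode,
                             feed_scale = feed_scale)
  fit$call <- match.call()
  fit
}

#' @rdname fit_growth
#' @param p_as named feed relative-abundance vector over the OTU universe
#' @param p_ad matrix of digester relative abundances (OTU x digester,
#'   columns in the order of `reactors$digester_id`), or a vector for a
#'   single digester
#' @export
fit_growth_profiles <- function(p_as, p_ad, reactors,
                                mode = c("srt", "v_over_q"),
                                feed_scale = 1) {
  mode <- match.arg(mode)
  if (is.null(dim(p_ad))) p_ad <- matrix(p_ad, ncol = 1L,
                                         dimnames = list(names(p_ad), NULL))
  if (is.null(rownames(p_ad)) || is.null(names(p_as)))
    stopf("profiles must be named by OTU id")
  if (!identical(rownames(p_ad), names(p_as))) {
    if (!setequal(rownames(p_ad), names(p_as)))
      stopf("feed and digester profiles cover different OTU universes")
    p_ad <- p_ad[names(p_as), , drop = FALSE]
  }
  if (ncol(p_ad) != nrow(reactors))
    stopf("p_ad must have one column per reactor")
  colnames(p_ad) <- reactors$digester_id
  nd <- nrow(reactors)
  otus <- names(p_as)
  mu_d <- influx <- efflux <- stock <-
    matrix(NA_real_, length(otus), nd, dimnames = list(otus, reactors$digester_id))
  for (k in seq_len(nd)) {
    g <- specific_growth_rate(p_as, p_ad[, k], reactors[k, ], mode = mode,
                              feed_scale = feed_scale)
    mu_d[, k] <- g$mu
    influx[, k] <- g$influx
    efflux[, k] <- g$efflux
    stock[, k] <- g$stock
  }
  detected <- p_ad > 0
  n_det <- rowSums(detected)
  mu <- ifelse(n_det > 0, rowSums(mu_d * detected, na.rm = TRUE) / n_det,
               NA_real_)
  status <- ifelse(n_det == 0L, "feed_only",
                   ifelse(p_as == 0, "ad_only", "estimated"))
  est <- data.frame(otu_id = otus, mu = unname(mu), status = unname(status),
                    n_digesters = unname(n_det),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(estimates = est, mu_digester = mu_d,
                 influx = influx, efflux = efflux, stock = stock,
                 p_as = p_as, p_ad = p_ad, reactors = reactors,
                 D = dilution_rate(reactors, mode),
                 mode = mode, feed_scale = feed_scale,
                 call = match.call()),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  tab <- table(x$estimates$status)
  cat(sprintf("<growth_fit> %d OTUs across %d digester(s), mode '%s'\n",
              nrow(x$estimates), ncol(x$p_ad), x$mode))
  cat(sprintf("  dilution rates D: %s (1/day)\n",
              paste(sprintf("%.4f", x$D), collapse = ", ")))
  cat(sprintf("  status: %s\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  mu <- x$estimates$mu
  cat(sprintf("  mu range: [%.3f, %.3f] 1/day\n",
              min(mu, na.rm = TRUE), max(mu, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  stats::setNames(object$estimates$mu, object$estimates$otu_id)
}

#' Classify growing and digested populations
#'
#' Splits OTUs by the sign of the mean specific growth rate and reports
#' counts and summed digester relative abundance of each class, optionally
#' restricted to a subset (e.g. the core populations). OTUs absent from
#' the feed count as positive (their mu equals the dilution rate).
#'
#' @param fit a `growth_fit`
#' @param subset optional character vector of OTU ids
#' @param profile named abundance vector used for the shares (default: the
#'   across-digester mean AD profile of the fit)
#' @return `data.frame` with rows `positive` and `negative`: `n`,
#'   `abundance_share`.
#' @export
classify_growth <- function(fit, subset = NULL, profile = NULL) {
  est <- fit$estimates
  if (is.null(profile)) profile <- rowMeans(fit$p_ad)
  if (!is.null(subset)) {
    est <- est[est$otu_id %in% subset, , drop = FALSE]
  }
  est <- est[est$status != "feed_only", , drop = FALSE]
  pos <- est$otu_id[est$mu > 0]
  neg <- est$otu_id[est$mu < 0]
  data.frame(group = c("positive", "negative"),
             n = c(length(pos), length(neg)),
             abundance_share = c(sum(profile[pos]), sum(profile[neg])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
summary.growth_fit <- function(object, ...) {
  cls <- classify_growth(object)
  mu <- object$estimates$mu
  out <- list(n_otus = nrow(object$estimates),
              status = table(object$estimates$status),
              classes = cls,
              mu_max = max(mu, na.rm = TRUE),
              mu_min = min(mu, na.rm = TRUE),
              D = object$D, mode = object$mode)
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat(sprintf("Steady-state growth model fit (%d OTUs, mode '%s')\n",
              x$n_otus, x$mode))
  cat(sprintf("  dilution rates: %s 1/day (mean %.4f)\n",
              paste(sprintf("%.4f", x$D), collapse = ", "), mean(x$D)))
  st <- x$status
  cat(sprintf("  status: %s\n",
              paste(sprintf("%s %d", names(st), st), collapse = ", ")))
  cat(sprintf("  mu in [%.3f, %.3f] 1/day (washout bound %.4f)\n",
              x$mu_min, x$mu_max, mean(x$D)))
  cls <- x$classes
  for (i in seq_len(nrow(cls)))
    cat(sprintf("  %s mu: %d OTUs, %.1f%% of AD sequences\n",
                cls$group[i], cls$n[i], 100 * cls$abundance_share[i]))
  invisible(x)
}

#' @export
plot.growth_fit <- function(x, ...) {
  est <- x$estimates
  ab <- rowMeans(x$p_ad)[est$otu_id]
  keep <- !is.na(est$mu) & ab > 0
  cols <- ifelse(est$mu[keep] > 0, "#4B0082", "#1F78B4")
  graphics::plot(est$mu[keep], log10(ab[keep]), col = cols, pch = 16,
                 xlab = expression(mu ~ (day^-1)),
                 ylab = "log10 mean AD relative abundance", ...)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  graphics::abline(v = mean(x$D), lty = 3, col = "grey60")
  invisible(x)
}

#' Simulate digester count tables from a fitted growth model
#'
#' Parametric-bootstrap style: draws multinomial rDNA count tables whose
#' expected per-digester profiles are the fitted ones.
#'
#' @param object a `growth_fit`
#' @param nsim number of replicate tables
#' @param seed RNG seed
#' @param depth sequencing depth per sample (default 30000)
#' @param ... unused
#' @return list of [count_table]s of length `nsim` (one AD sample per
#'   digester each).
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = 1L,
                                depth = 30000L, ...) {
  p <- object$p_ad
  with_seed(seed, {
    lapply(seq_len(nsim), function(r) {
      m <- vapply(seq_len(ncol(p)), function(k)
        as.integer(stats::rmultinom(1L, depth, p[, k])),
        integer(nrow(p)))
      dimnames(m) <- list(rownames(p),
                          sprintf("sim%d_AD%s", r, colnames(p)))
      count_table(m[rowSums(m) > 0L, , drop = FALSE])
    })
  })
}
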
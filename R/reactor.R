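#' Reactor specifications
#'
#' Physical parameters of each digester and its feed, the constants of the
#' steady-state mass balance: reactor volume `volume_mg` (million gallons),
#' feed flow `flow_mgd` (million gallons per day; effluent flow defaults to
#' the feed flow, i.e. constant liquid volume), digester total solids
#' `ts_ad` (fraction of wet mass), digester volatile solids `vs_ad`
#' (fraction of TS), sludge retention time `srt_d` (days), and the feed
#' solids `ts_as`, `vs_as` on the same scales. Sludge density is assumed
#' identical in feed and digester, so it cancels from every flux ratio.
#'
#' @param digester_id character id
#' @param volume_mg reactor volume, million gallons
#' @param flow_mgd feed flow, million gallons per day
#' @param ts_ad,vs_ad digester total solids (fraction of wet mass) and
#'   volatile solids (fraction of TS)
#' @param srt_d sludge retention time, days
#' @param ts_as,vs_as feed solids on the same scales
#' @param flow_out_mgd effluent flow (default `flow_mgd`)
#' @return one-row `data.frame` of class `reactor_spec`; several can be
#'   combined with `rbind`.
#' @export
reactor_spec <- function(digester_id, volume_mg, flow_mgd, ts_ad, vs_ad,
                         srt_d, ts_as, vs_as, flow_out_mgd = flow_mgd) {
  df <- data.frame(digester_id = as.character(digester_id),
                   volume_mg = volume_mg, flow_mgd = flow_mgd,
                   flow_out_mgd = flow_out_mgd,
                   ts_ad = ts_ad, vs_ad = vs_ad, srt_d = srt_d,
                   ts_as = ts_as, vs_as = vs_as,
                   stringsAsFactors = FALSE)
  validate_reactors(df)
}

validate_reactors <- function(df) {
  need <- c("digester_id", "volume_mg", "flow_mgd", "ts_ad", "vs_ad",
            "srt_d", "ts_as", "vs_as")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("reactor table is missing column '%s'", miss[1L])
  if (!"flow_out_mgd" %in% names(df)) df$flow_out_mgd <- df$flow_mgd
  num <- setdiff(names(df), "digester_id")
  for (cn in num) {
    if (any(!is.finite(df[[cn]]) | df[[cn]] <= 0))
      stopf("reactor column '%s' must be positive and finite", cn)
  }
  for (cn in c("ts_ad", "vs_ad", "ts_as", "vs_as")) {
    if (any(df[[cn]] >= 1))
      stopf("reactor column '%s' must be a fraction in (0, 1)", cn)
  }
  if (anyDuplicated(df$digester_id))
    stopf("duplicate digester_id '%s'",
          df$digester_id[duplicated(df$digester_id)][1L])
  class(df) <- c("reactor_spec", "data.frame")
  df
}

#' Read reactor specifications from TSV
#'
#' Expects columns `digester_id`, `volume_mg`, `flow_mgd`, `ts_ad`,
#' `vs_ad`, `srt_d`, `ts_as`, `vs_as` and optionally `flow_out_mgd`.
#'
#' @param path TSV path
#' @return a `reactor_spec` data frame (one row per digester).
#' @export
read_reactor_specs <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  df$digester_id <- as.character(df$digester_id)
  validate_reactors(df)
}

#' Stickney-style digester specifications
#'
#' The three mesophilic full-scale digesters used throughout the package
#' examples: volumes 2.3/2.3/2.8 million gallons, feed flows
#' 0.106/0.106/0.120 million gallons per day, digester total solids
#' 2.57/2.25/2.65% with volatile solids 51.5/53.5/52.9% of TS, and sludge
#' retention times 24.2/24.2/25.2 days. Feed solids are not part of that
#' characterisation; `ts_as` and `vs_as` default to nominal values typical
#' of blended primary/waste activated sludge fed to municipal digesters
#' and can be overridden when measurements are available.
#'
#' @param ts_as feed total solids fraction (default 0.04)
#' @param vs_as feed volatile solids fraction of TS (default 0.75)
#' @return a `reactor_spec` data frame with three rows.
#' @export
stickney_digesters <- function(ts_as = 0.04, vs_as = 0.75) {
  path <- system.file("extdata", "stickney_digesters.tsv",
                      package = "addigest", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$digester_id <- as.character(df$digester_id)
  df$ts_as <- ts_as
  df$vs_as <- vs_as
  validate_reactors(df)
}

#' Dilution rate of a digester
#'
#' `D = 1/SRT` (`mode = "srt"`) or `D = Q_out/V` (`mode = "v_over_q"`).
#' At constant volume and fully mixed withdrawal the two coincide; they are
#' kept selectable because operator-reported SRTs and nominal flows often
#' disagree slightly. The dilution rate is the washout bound: no population
#' can sustain a specific growth rate above `D` at steady state, and a
#' population absent from the feed persists only by growing at exactly `D`.
#'
#' @param spec a `reactor_spec` data frame (any number of rows)
#' @param mode `"srt"` or `"v_over_q"`
#' @return numeric vector of dilution rates (1/day), named by digester.
#' @export
dilution_rate <- function(spec, mode = c("srt", "v_over_q")) {
  mode <- match.arg(mode)
  d <- switch(mode,
              srt = 1 / spec$srt_d,
              v_over_q = spec$flow_out_mgd / spec$volume_mg)
  stats::setNames(d, spec$digester_id)
}
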
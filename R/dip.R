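#' Dip statistic of unimodality
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and the class of unimodal CDFs (convex up to the mode,
#' concave after, with at most one atom at the mode). Large dips indicate
#' multimodality; the smallest achievable value for a sample with n
#' distinct points is 1/(2n) and the largest (two balanced, well-separated
#' point masses) is 1/4.
#'
#' The implementation scans candidate mode placements at each distinct
#' value (a zero-size atom makes this cover continuous modes as well).
#' For a fixed mode the two CDF branches must thread interval constraints
#' derived from the ECDF at the data points; a convex (concave) branch
#' exists iff the greatest convex minorant (least concave majorant) of the
#' constraint envelope violates the opposite envelope by at most twice the
#' band width. The per-mode objective is the larger of the two branch
#' requirements; because the left requirement is non-decreasing and the
#' right non-increasing along the ordered mode candidates, the minimum is
#' found by bisection on their crossing.
#'
#' @param x numeric vector (NAs removed)
#' @return the dip statistic, a number in \[0, 0.25\].
#' @seealso [dip_bimodality()] for a Monte-Carlo p-value.
#' @export
dip_stat <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 1L) stopf("empty sample")
  r <- rle(x)
  v <- r$values
  K <- length(v)
  if (K == 1L) return(0)
  Fl <- cumsum(r$lengths) / n        # ECDF at v_j (right limit)
  Fu <- c(0, Fl[-K])                 # ECDF just below v_j (left limit)

  eps_left <- function(j) {
    # mode (possibly zero-size atom) at v_j: the left branch is convex
    # through the standard bands at v_1..v_{j-1} and ends at v_j within
    # eps of F(v_j-)
    U <- Fu[seq_len(j)]; L <- Fl[seq_len(j)]
    L[j] <- Fu[j]
    .dip_band_violation(v[seq_len(j)], U, L, TRUE) / 2
  }
  eps_right <- function(j) {
    # right branch: concave from (v_j, F(v_j)) through the bands above
    idx <- j:K
    U <- Fu[idx]; L <- Fl[idx]
    U[1L] <- Fl[j]
    .dip_band_violation(v[idx], U, L, FALSE) / 2
  }

  lo <- 1L; hi <- K
  # bisect on the crossing of eps_left (nondecreasing) and eps_right
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (eps_left(mid) - eps_right(mid) >= 0) hi <- mid else lo <- mid
  }
  cand <- unique(pmax(1L, pmin(K, (lo - 2L):(hi + 2L))))
  min(vapply(cand, function(m) max(eps_left(m), eps_right(m)), numeric(1)))
}

#' Dip test of unimodality with a Monte-Carlo null
#'
#' Computes the dip statistic and a p-value against the uniform null: the
#' dip of a continuous sample is invariant under monotone transforms of the
#' axis, so the null distribution depends only on the sample size and is
#' estimated by simulating `n_null` uniform samples of the same size. Small
#' p-values reject unimodality. Note that for heavily tied data (such as
#' integer occupancies) the continuous uniform reference is the
#' conventional, slightly conservative choice.
#'
#' @param x numeric vector with at least 4 finite observations
#' @param n_null number of Monte-Carlo null replicates (default 2000)
#' @param seed RNG seed for the null draws
#' @return list with `dip`, `p_value`, `n`, `n_null`.
#' @export
dip_bimodality <- function(x, n_null = 2000L, seed = 1L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stopf("dip test needs at least 4 observations")
  if (n_null < 1L) stopf("`n_null` must be positive")
  obs <- dip_stat(x)
  null <- with_seed(seed, {
    vapply(seq_len(n_null), function(b) dip_stat(stats::runif(n)),
           numeric(1))
  })
  list(dip = obs,
       p_value = (1 + sum(null >= obs - 1e-12)) / (n_null + 1),
       n = n, n_null = as.integer(n_null))
}
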
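test_that("per-OTU ratios follow the definition and flag zeros", {
  rdna <- c(a = 0.01, b = 0.5, c = 0, d = 0.49)
  rrna <- c(a = 0.02, b = 0.5, c = 0.08, d = 0.40)
  rec <- compute_ratio(rdna, rrna)
  expect_equal(rec$ratio[rec$otu_id == "a"], 2)
  expect_equal(rec$ratio[rec$otu_id == "b"], 1)
  expect_true(is.na(rec$ratio[rec$otu_id == "c"]))
  expect_false(rec$defined[rec$otu_id == "c"])
  # identical profiles give all-1 ratios
  expect_equal(compute_ratio(rdna, rdna)$ratio[rdna > 0],
               rep(1, sum(rdna > 0)))
  expect_error(compute_ratio(rdna, rrna[c("a", "b", "c")]),
               "different OTU universes")
  # pseudocount path defines every ratio
  expect_true(all(compute_ratio(rdna, rrna, pseudocount = 1e-6)$defined))
})

test_that("ratios are scale-free in the underlying counts", {
  ct <- random_table(25, 4, seed = 21, lambda = 40)
  scaled <- ct$counts
  scaled[, 3] <- scaled[, 3] * 13L
  p1 <- pool_profile(ct, sample_ids(ct))
  p2 <- pool_profile(tiny_table(scaled), sample_ids(ct))
  rr <- pool_profile(random_table(25, 2, seed = 22, lambda = 40),
                     c("s1", "s2"))
  expect_equal(compute_ratio(p1, rr)$ratio, compute_ratio(p2, rr)$ratio)
})

test_that("activity index compares environments and labels direction", {
  as_rec <- compute_ratio(c(a = .1, b = .2, c = .1),
                          c(a = .15, b = .2, c = .1))
  ad_rec <- compute_ratio(c(a = .1, b = .2, c = .1),
                          c(a = .30, b = .2, c = .1))
  idx <- activity_index(as_rec, ad_rec)
  expect_equal(idx$index[idx$otu_id == "a"], 2)     # 3.0 / 1.5
  expect_equal(idx$label[idx$otu_id == "a"], "more_active_in_AD")
  expect_equal(idx$index[idx$otu_id == "b"], 1)
  expect_equal(idx$label[idx$otu_id == "b"], "boundary")
})

test_that("decaying OTUs with rRNA carryover get misleading indices", {
  # the documented failure mode of the relative-abundance ratio: an OTU
  # that is being digested (mu < 0) but carries elevated rRNA into the
  # digester shows index > 1, i.e. "more active in AD"
  sim <- simulate_community(small_sim(31))
  tr <- sim$truth
  as_idx <- compute_ratio(pool_profile(sim$rdna,
                                       samples_where(sim$meta, "AS", "rDNA")),
                          pool_profile(sim$rrna,
                                       samples_where(sim$meta, "AS", "rRNA")))
  ad_idx <- compute_ratio(pool_profile(sim$rdna,
                                       samples_where(sim$meta, "AD", "rDNA")),
                          pool_profile(sim$rrna,
                                       samples_where(sim$meta, "AD", "rRNA")))
  idx <- activity_index(as_idx, ad_idx)
  neg <- tr$otu$otu_id[tr$otu$sign == "negative"]
  vals <- idx$index[match(neg, idx$otu_id)]
  expect_gte(mean(vals > 1, na.rm = TRUE), 0.5)
})

test_that("slope-homogeneity diagnostic: identity, null calibration, power", {
  # a single cloud split arbitrarily in two: identical slopes, F ~ 0
  x <- with_seed_local(4, runif(60, -4, -1))
  y <- 1.3 * x + with_seed_local(5, rnorm(60, 0, 0.1))
  names(x) <- names(y) <- sprintf("o%02d", 1:60)
  g <- rep(c("A", "B"), 30)
  d <- correlation_diagnostic(10^x, 10^y, setNames(g, names(x)))
  expect_equal(unname(d$group_slope["A"]), unname(d$group_slope["B"]),
               tolerance = 0.15)
  expect_gt(d$p_value, 0.001)

  # exact duplication gives exactly equal slopes and F = 0
  x2 <- c(x, x); y2 <- c(y, y)
  names(x2) <- names(y2) <- sprintf("o%03d", seq_along(x2))
  g2 <- rep(c("A", "B"), each = 60)
  d2 <- correlation_diagnostic(10^x2, 10^y2, setNames(g2, names(x2)))
  expect_equal(unname(diff(d2$group_slope)), 0)
  expect_lt(d2$F_statistic, 1e-10)

  # null calibration: common slope, rejection rate ~ alpha
  rej <- vapply(1:200, function(s) {
    with_seed_local(5000 + s, {
      xx <- runif(80, -5, -1)
      yy <- 0.9 * xx + rnorm(80, 0, 0.3)
      names(xx) <- names(yy) <- sprintf("o%02d", 1:80)
      gg <- setNames(rep(c("A", "B"), 40), names(xx))
      correlation_diagnostic(10^xx, 10^yy, gg)$p_value < 0.05
    })
  }, logical(1))
  expect_lt(mean(rej), 0.12)
  expect_gt(mean(rej), 0.005)

  # power: slopes 1.0 vs 0.5, n = 500 per group, noise sd 0.2
  rej2 <- vapply(1:60, function(s) {
    with_seed_local(7000 + s, {
      xa <- runif(500, -5, -1); xb <- runif(500, -5, -1)
      ya <- 1.0 * xa + rnorm(500, 0, 0.2)
      yb <- 0.5 * xb + rnorm(500, 0, 0.2)
      xx <- c(xa, xb); yy <- c(ya, yb)
      names(xx) <- names(yy) <- sprintf("o%04d", seq_along(xx))
      gg <- setNames(rep(c("A", "B"), each = 500), names(xx))
      correlation_diagnostic(10^xx, 10^yy, gg)$p_value < 0.001
    })
  }, logical(1))
  expect_gte(mean(rej2), 0.95)

  expect_error(correlation_diagnostic(c(a = .1, b = .2), c(a = .1, b = .2),
                                      c(a = "A", b = "B")),
               "at least 3")
})

test_that("when rRNA equals rDNA exactly the diagnostic finds one unit slope", {
  p <- pool_profile(random_table(40, 3, seed = 77, lambda = 30),
                    c("s1", "s2", "s3"))
  g <- setNames(rep(c("A", "B"), 20), names(p))
  d <- correlation_diagnostic(p, p, g)
  expect_equal(unname(d$group_slope), c(1, 1))
  expect_equal(d$pooled_r, 1)
})
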
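test_that("dilution rates reproduce the digester operating figures", {
  rs <- stickney_digesters()
  D <- dilution_rate(rs, "srt")
  expect_equal(unname(D), c(1 / 24.2, 1 / 24.2, 1 / 25.2))
  expect_equal(unname(D[1]), 0.041322, tolerance = 1e-4)
  expect_equal(unname(D[3]), 0.039683, tolerance = 1e-4)
  Dq <- dilution_rate(rs, "v_over_q")
  expect_equal(unname(Dq[1]), 0.106 / 2.3)
  expect_equal(unname(Dq[1]), 0.046087, tolerance = 1e-4)
})

test_that("the steady-state balance gives the closed-form mu", {
  spec <- reactor_spec("d", volume_mg = 2, flow_mgd = 0.08,
                       ts_ad = 0.025, vs_ad = 0.52, srt_d = 25,
                       ts_as = 0.04, vs_as = 0.75)
  D <- unname(dilution_rate(spec, "srt"))
  # influx flux equal to efflux flux -> mu = 0
  p_ad <- 0.2
  p_as <- p_ad * (spec$flow_out_mgd * spec$ts_ad * spec$vs_ad) /
    (spec$flow_mgd * spec$ts_as * spec$vs_as)
  g <- specific_growth_rate(p_as, p_ad, spec)
  expect_equal(g$mu, 0)
  expect_equal(g$influx, g$efflux)
  # influx twice the efflux -> mu = -D
  g2 <- specific_growth_rate(2 * p_as, p_ad, spec)
  expect_equal(g2$mu, -D)
  # absent from the feed -> mu = D exactly (washout balance)
  g3 <- specific_growth_rate(0, 0.1, spec)
  expect_equal(g3$mu, D)
  expect_equal(g3$status, "ad_only")
  # present in feed, washed out of the digester
  g4 <- specific_growth_rate(0.1, 0, spec)
  expect_true(is.na(g4$mu))
  expect_equal(g4$status, "feed_only")
  # feed_scale scales the influx term only
  g5 <- specific_growth_rate(2 * p_as, p_ad, spec, feed_scale = 0.5)
  expect_equal(g5$mu, 0)
})

test_that("mu is invariant to common scaling and bounded by washout", {
  spec <- stickney_digesters()[1, ]
  D <- unname(dilution_rate(spec, "srt"))
  p_as <- with_seed_local(1, runif(50, 0, 0.02))
  p_ad <- with_seed_local(2, runif(50, 0, 0.02))
  g <- specific_growth_rate(p_as, p_ad, spec)
  g_scaled <- specific_growth_rate(p_as / 3, p_ad / 3, spec)
  expect_equal(g$mu, g_scaled$mu)
  expect_true(all(g$mu <= D + 1e-12))
  # mu < 0 exactly when influx exceeds efflux
  expect_equal(g$mu < 0, g$influx > g$efflux)
})

test_that("noise-free synthetic communities invert exactly", {
  sim <- simulate_community(small_sim(11))
  tr <- sim$truth
  for (mode in c("srt", "v_over_q")) {
    fit <- fit_growth_profiles(tr$p_as_true, tr$p_ad_true, tr$reactors,
                               mode = mode)
    feed <- tr$otu$type == "feed"
    expect_lt(max(abs(fit$estimates$mu[feed] - tr$otu$mu_true[feed])), 1e-9)
    # OTUs absent from the feed recover the mean dilution rate
    expect_lt(max(abs(fit$estimates$mu[!feed] - mean(tr$D))), 1e-12)
    expect_true(all(fit$estimates$status[!feed] == "ad_only"))
  }
})

test_that("fitting from counts agrees with fitting from pooled profiles", {
  sim <- simulate_community(small_sim(12))
  fit_tab <- fit_growth(sim$rdna, sim$meta, sim$reactors)
  p_as <- pool_profile(sim$rdna, samples_where(sim$meta, "AS", "rDNA"))
  p_ad <- vapply(sim$reactors$digester_id, function(d)
    pool_profile(sim$rdna, samples_where(sim$meta, "AD", "rDNA", d)),
    numeric(nrow(sim$rdna$counts)))
  fit_prof <- fit_growth_profiles(p_as, p_ad, sim$reactors)
  expect_equal(fit_tab$estimates$mu, fit_prof$estimates$mu)
  expect_equal(coef(fit_tab), coef(fit_prof))
})

test_that("per-digester estimates average as specified", {
  rs <- stickney_digesters()
  p_as <- c(x = 0.02, y = 0, z = 0.05)
  # identical relative flux terms in all digesters for OTU x
  p_ad <- cbind(c(0.03, 0.01, 0), c(0.03, 0.01, 0), c(0.03, 0.01, 0))
  rownames(p_ad) <- names(p_as)
  fit <- fit_growth_profiles(p_as, p_ad, rs)
  est <- fit$estimates
  # ad_only OTU y: mean mu equals the mean of the three dilution rates
  expect_equal(est$mu[est$otu_id == "y"],
               mean(dilution_rate(rs, "srt")))
  # feed-only OTU z is excluded everywhere
  expect_equal(est$status[est$otu_id == "z"], "feed_only")
  expect_true(is.na(est$mu[est$otu_id == "z"]))
  # x: mean of per-digester values equals each per-digester value when the
  # digesters are configured identically
  rs_same <- rs
  rs_same[, c("volume_mg", "flow_mgd", "flow_out_mgd", "srt_d")] <-
    rs[rep(1, 3), c("volume_mg", "flow_mgd", "flow_out_mgd", "srt_d")]
  rs_same[, c("ts_ad", "vs_ad")] <- rs[rep(1, 3), c("ts_ad", "vs_ad")]
  fit_same <- fit_growth_profiles(p_as, p_ad, rs_same)
  expect_equal(fit_same$estimates$mu[1], fit_same$mu_digester[1, 1])
})

test_that("classification sums abundance by mu sign and ignores order", {
  rs <- stickney_digesters()[1, ]
  p_as <- c(a = 0.01, b = 0.02, c = 0.30, d = 0.20)
  p_ad <- c(a = 0.40, b = 0.30, c = 0.20, d = 0.10)
  fit <- fit_growth_profiles(p_as, matrix(p_ad, ncol = 1,
                                          dimnames = list(names(p_ad))), rs)
  expect_equal(sign(fit$estimates$mu), c(1, 1, -1, -1))
  cls <- classify_growth(fit, profile = p_ad)
  expect_equal(cls$abundance_share[cls$group == "negative"], 0.3)
  expect_equal(cls$abundance_share[cls$group == "positive"], 0.7)
  # permuted input gives the same classification
  perm <- c("d", "b", "a", "c")
  fit2 <- fit_growth_profiles(p_as[perm],
                              matrix(p_ad[perm], ncol = 1,
                                     dimnames = list(perm)), rs)
  cls2 <- classify_growth(fit2, profile = p_ad)
  expect_equal(cls2, cls)
  # subsetting restricts the tally
  cls3 <- classify_growth(fit, subset = c("a", "c"), profile = p_ad)
  expect_equal(cls3$n, c(1L, 1L))
})

test_that("growth_fit methods expose the estimates coherently", {
  sim <- simulate_community(small_sim(13))
  fit <- fit_growth(sim$rdna, sim$meta, sim$reactors)
  expect_s3_class(fit, "growth_fit")
  expect_named(coef(fit), fit$estimates$otu_id)
  s <- summary(fit)
  expect_output(print(s), "washout bound")
  expect_output(print(fit), "growth_fit")
  sims <- simulate(fit, nsim = 2, seed = 3, depth = 1000)
  expect_length(sims, 2)
  expect_true(all(colSums(sims[[1]]$counts) == 1000))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
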
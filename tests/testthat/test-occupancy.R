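test_that("occupancy counts samples with nonzero counts", {
  # presence patterns (110), (010), (111) over 3 samples
  m <- matrix(c(3L, 0L, 5L,
                9L, 2L, 1L,
                0L, 0L, 4L), nrow = 3)
  ct <- tiny_table(m)
  occ <- occupancy_distribution(ct)
  expect_equal(occ$occupancy, c(2L, 1L, 3L))
  # an all-zero row has occupancy 0; full row has occupancy n
  m2 <- rbind(m, 0L)
  occ2 <- occupancy_distribution(tiny_table(m2))
  expect_equal(occ2$occupancy[4], 0L)
  expect_equal(max(occ2$occupancy), ncol(m2))
})

test_that("occupancy-abundance correlation matches the rank formula", {
  occ <- data.frame(otu_id = letters[1:5],
                    occupancy = c(1L, 2L, 3L, 4L, 5L),
                    mean_abundance = c(0.01, 0.03, 0.02, 0.2, 0.5))
  got <- occupancy_abundance_correlation(occ)
  # independent oracle: Spearman rho by the rank-difference formula
  d <- rank(occ$occupancy) - rank(log10(occ$mean_abundance))
  rho_hand <- 1 - 6 * sum(d^2) / (5 * (25 - 1))
  expect_equal(got$rho, rho_hand)
  mono <- data.frame(otu_id = letters[1:4], occupancy = 1:4,
                     mean_abundance = c(.1, .2, .3, .4))
  expect_equal(occupancy_abundance_correlation(mono)$rho, 1)
  rev <- transform(mono, mean_abundance = rev(mean_abundance))
  expect_equal(occupancy_abundance_correlation(rev)$rho, -1)
  expect_error(occupancy_abundance_correlation(
    transform(mono, occupancy = 2L)), "constant")
})

test_that("abundant_set takes the minimal prefix crossing the quantile", {
  p <- c(OTU1 = 0.5, OTU2 = 0.3, OTU3 = 0.2)
  expect_equal(abundant_set(p), c("OTU1", "OTU2"))
  expect_equal(abundant_set(c(only = 1)), "only")
  # uniform 10-OTU sample: 8 x 0.1 = 0.8, tie-break by id
  u <- setNames(rep(0.1, 10), sprintf("OTU%02d", 10:1))
  expect_equal(abundant_set(u), sprintf("OTU%02d", 1:8))
  # minimality: the returned set reaches the quantile, dropping its
  # weakest member falls below
  for (s in 1:5) {
    rt <- random_table(30, 1, seed = 200 + s)
    prof <- relative_abundance(rt)[, 1]
    a <- abundant_set(prof, 0.8)
    expect_gte(sum(prof[a]), 0.8 - 1e-9)
    expect_lt(sum(prof[a]) - min(prof[a]), 0.8)
  }
})

test_that("select_core matches brute-force enumeration on random fixtures", {
  for (s in 1:4) {
    ct <- random_table(20, 5, seed = 300 + s, lambda = 3)
    got <- select_core(ct, 0.8)$otu_ids
    # independent oracle: exhaustive check per OTU
    p <- sweep(ct$counts, 2, colSums(ct$counts), "/")
    expected <- character(0)
    for (o in otu_ids(ct)) {
      if (any(ct$counts[o, ] == 0)) next
      in_all <- all(vapply(seq_len(ncol(p)), function(j) {
        v <- sort(p[, j], decreasing = TRUE)
        # resolve ties like the implementation: by id after abundance
        ord <- order(-p[, j], rownames(p), method = "radix")
        top <- rownames(p)[ord][seq_len(which(cumsum(p[ord, j]) >=
                                                0.8 - 1e-9)[1])]
        o %in% top
      }, logical(1)))
      if (in_all) expected <- c(expected, o)
    }
    expect_setequal(got, expected)
  }
})

test_that("core selection requires full occupancy and is order invariant", {
  ct <- planted_core_table(core_k = 5, tail_k = 30, n_samp = 6, seed = 2)
  core <- select_core(ct)
  expect_setequal(core$otu_ids, sprintf("CORE%02d", 1:5))
  # knocking one core OTU out of one sample removes it from the core
  m <- ct$counts
  m["CORE03", 2] <- 0L
  expect_setequal(select_core(tiny_table(m, otus = otu_ids(ct)))$otu_ids,
                  sprintf("CORE%02d", c(1, 2, 4, 5)))
  # permuting rows and columns changes nothing
  perm <- ct$counts[sample(nrow(ct$counts)), sample(ncol(ct$counts))]
  expect_setequal(select_core(count_table(perm))$otu_ids, core$otu_ids)
  # any_sample rule is at least as inclusive
  expect_true(all(core$otu_ids %in%
                    select_core(ct, rule = "any_sample")$otu_ids))
})

test_that("alpha diversity matches hand-computed values", {
  a <- alpha_diversity(c(1, 1, 1, 1))
  expect_equal(unname(a["observed"]), 4)
  expect_equal(unname(a["chao1"]), 4 + 4 * 3 / 2)  # F1=4, F2=0
  expect_equal(unname(a["shannon"]), log(4))
  expect_equal(unname(a["shannon_log2"]), 2)
  # a single OTU has zero entropy
  expect_equal(unname(alpha_diversity(c(0, 17, 0))["shannon"]), 0)
  # no singletons or doubletons -> chao1 = observed
  b <- alpha_diversity(c(5, 9, 4))
  expect_equal(unname(b["chao1"]), unname(b["observed"]))
  expect_error(alpha_diversity(c(0, 0)), "positive sum")
  # table method returns one row per sample
  tab <- alpha_diversity(random_table(15, 3, seed = 8))
  expect_equal(nrow(tab), 3)
})
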
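# Small programmatic fixtures shared across the suite.

# count table from a plain matrix, auto-naming margins
tiny_table <- function(m, otus = NULL, samples = NULL, taxonomy = NULL) {
  if (is.null(otus)) otus <- sprintf("OTU%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(otus, samples)
  count_table(m, taxonomy = taxonomy)
}

# random table with fixed seed
random_table <- function(n_otu, n_samp, seed, lambda = 8) {
  m <- with_seed_local(seed, matrix(rpois(n_otu * n_samp, lambda),
                                    n_otu, n_samp))
  # guard against zero-sum columns
  m[1L, colSums(m) == 0] <- 1L
  tiny_table(m)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# a table with a planted core: `core_k` OTUs present and dominant in every
# sample, plus a tail of sparse rare OTUs
planted_core_table <- function(core_k = 6, tail_k = 40, n_samp = 8,
                               seed = 1) {
  with_seed_local(seed, {
    core <- matrix(rpois(core_k * n_samp, 500) + 200L, core_k, n_samp)
    # tail carries ~10% of reads so that the top-80% prefix needs every
    # core member but no tail member
    tail <- matrix(rbinom(tail_k * n_samp, 1, 0.5) *
                     (1L + rpois(tail_k * n_samp, 20)), tail_k, n_samp)
    m <- rbind(core, tail)
    tiny_table(m, otus = c(sprintf("CORE%02d", seq_len(core_k)),
                           sprintf("TAIL%02d", seq_len(tail_k))))
  })
}

# small, fast simulation configuration used where full size is not needed
small_sim <- function(seed, ...) {
  sim_config(n_feed_otus = 120L, n_ad_only_otus = 20L,
             n_as_samples = 4L, n_ad_samples = 2L,
             depth_rdna = 4000L, depth_rrna = 2000L,
             seed = seed, ...)
}
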
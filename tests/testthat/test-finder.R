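test_that("EM recovers an exactly planted word with full site recall", {
  gp <- exact_word_set(n = 16, L = 160, seed = 7)
  bg <- build_background(gp$Y, order = 0)
  cfg <- finder_config(wmin = 12, wmax = 12, rng_seed = 11)
  m <- zoops_em(gp$Y, bg, cfg)
  expect_equal(consensus(m), "GATTACAGATTA")
  expect_equal(nrow(m$sites), 16)
  tr <- gp$truth$sites
  mm <- merge(m$sites, tr, by = "entry_id")
  expect_equal(mm$start.x, mm$start.y)
  expect_lt(m$evalue, 1e-3)
})

test_that("EM is bit-reproducible under a fixed seed and rejects short input", {
  gp <- exact_word_set(n = 8, L = 90, seed = 21)
  bg <- build_background(gp$Y, order = 0)
  cfg <- finder_config(wmin = 12, wmax = 12, rng_seed = 5, null_reps = 99)
  m1 <- zoops_em(gp$Y, bg, cfg)
  m2 <- zoops_em(gp$Y, bg, cfg)
  expect_identical(m1$freqs, m2$freqs)
  expect_identical(m1$sites, m2$sites)
  expect_identical(m1$evalue, m2$evalue)

  Yshort <- seq_set(c(a = "ACGTACGT", b = "TTTTAAAA"))
  expect_error(zoops_em(Yshort, bg, finder_config(wmin = 12, wmax = 12)),
               "long enough")
})

test_that("the EM objective trace is non-decreasing", {
  gp <- generate_planted(N = 10, L = 150, consensi = "CCGATTACGG",
                         fraction = 0.6, mut_rate = 0.15, rng_seed = 31)
  bg <- build_background(gp$Y, order = 0)
  cfg <- finder_config(wmin = 10, wmax = 10, rng_seed = 3)
  m <- zoops_em(gp$Y, bg, cfg, assign_evalue = FALSE)
  expect_true(all(diff(m$em_trace) >= -1e-8))
})

test_that("motif E-values scale linearly in the candidate count", {
  gp <- exact_word_set(n = 8, L = 90, seed = 23)
  bg <- build_background(gp$Y, order = 0)
  cfg <- finder_config(wmin = 12, wmax = 12, null_reps = 99)
  m <- zoops_em(gp$Y, bg, cfg, assign_evalue = FALSE)
  cache <- new.env()
  e1 <- motif_evalue(m, gp$Y, bg, n_candidates = 1, null_reps = 99,
                     rng_seed = 9, cfg = cfg, null_cache = cache)
  e2 <- motif_evalue(m, gp$Y, bg, n_candidates = 2, null_reps = 99,
                     rng_seed = 9, cfg = cfg, null_cache = cache)
  expect_equal(e2, 2 * e1)
  expect_error(motif_evalue(m, gp$Y, bg, null_reps = 10, cfg = cfg),
               "too coarse")
})

test_that("E-values do not improve when planted sites are mutated", {
  cfg <- finder_config(wmin = 12, wmax = 12, null_reps = 199)
  cache <- new.env()
  evs <- vapply(c(0, 0.2), function(mu) {
    gp <- generate_planted(N = 14, L = 140, consensi = "GATTACAGATTA",
                           fraction = 1, mut_rate = mu, rng_seed = 7)
    bg <- build_background(gp$Y, order = 0)
    set.seed(2)
    zoops_em(gp$Y, bg, cfg, null_cache = cache)$evalue
  }, 0)
  expect_lte(evs[1], evs[2])
})

test_that("the Gibbs sampler agrees with EM on easy planted data", {
  gp <- exact_word_set(n = 10, L = 90, seed = 17)
  bg <- build_background(gp$Y, order = 0)
  cfg <- finder_config(wmin = 12, wmax = 12, rng_seed = 4, null_reps = 99,
                       gibbs_burnin = 60, gibbs_sweeps = 80)
  mg1 <- zoops_gibbs(gp$Y, bg, cfg)
  expect_equal(consensus(mg1), "GATTACAGATTA")
  expect_lt(mg1$evalue, 0.05)
  mg2 <- zoops_gibbs(gp$Y, bg, cfg)
  expect_identical(mg1$freqs, mg2$freqs)
  me <- zoops_em(gp$Y, bg, cfg)
  expect_equal(consensus(mg1), consensus(me))
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
  dimer_table <- function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    table(paste0(v[-length(v)], v[-1L]))
  }
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE,
                      prob = c(.4, .1, .2, .3)), collapse = "")
    sh <- dinuc_shuffle(s)
    expect_equal(dimer_table(sh), dimer_table(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 120, 120), substr(s, 120, 120))
  }
  # shuffles differ from a random input essentially always at this length
  set.seed(6)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  expect_true(any(replicate(5, dinuc_shuffle(s)) != s))
})
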
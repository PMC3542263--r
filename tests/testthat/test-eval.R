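test_that("the planted-motif generator matches its declared structure", {
  gp0 <- generate_planted(N = 10, L = 50, consensi = "ACGTACGT",
                          fraction = 0, rng_seed = 1)
  expect_length(gp0$truth$positives, 0)
  expect_equal(nrow(gp0$truth$sites), 0)

  # the toy layout: 14 entries of 68 nt, two motifs, 8 planted / 6 free
  toy <- generate_planted(N = 14, L = 68,
                          consensi = c("TATATATA", "CTGCAT"),
                          fraction = c(4 / 14, 4 / 14), mut_rate = 0,
                          rng_seed = 2)
  expect_equal(length(toy$Y$id), 14)
  expect_true(all(nchar(toy$Y$seq) == 68))
  expect_length(toy$truth$positives, 8)
  expect_equal(sum(!toy$Y$id %in% toy$truth$positives), 6)

  # identical parameters and seed give identical data
  a <- generate_planted(N = 20, L = 100, consensi = "GATTACA",
                        fraction = 0.5, mut_rate = 0.2, rng_seed = 9)
  b <- generate_planted(N = 20, L = 100, consensi = "GATTACA",
                        fraction = 0.5, mut_rate = 0.2, rng_seed = 9)
  expect_identical(a$Y$seq, b$Y$seq)
  expect_identical(a$truth$sites, b$truth$sites)
})

test_that("generator self-audit: site counts and mutation load", {
  w <- 10
  gp <- generate_planted(N = 40, L = 200,
                         consensi = paste(rep("ACGTT", 2), collapse = ""),
                         fraction = 0.5, mut_rate = 0.2, rng_seed = 3)
  expect_equal(nrow(gp$truth$sites), round(0.5 * 40))
  # count realized mutations against the planted consensus
  n_mut <- 0
  for (i in seq_len(nrow(gp$truth$sites))) {
    s <- gp$truth$sites[i, ]
    obs <- substr(gp$Y$seq[match(s$entry_id, gp$Y$id)], s$start + 1,
                  s$start + w)
    if (s$strand == "-") obs <- motifsieve:::revcomp_chr(obs)
    n_mut <- n_mut + sum(strsplit(obs, "")[[1]] !=
                           strsplit("ACGTTACGTT", "")[[1]])
  }
  expected <- 0.2 * w * nrow(gp$truth$sites)
  sd3 <- 3 * sqrt(w * nrow(gp$truth$sites) * 0.2 * 0.8)
  expect_lt(abs(n_mut - expected), sd3)
  # every true site lies within bounds
  expect_true(all(gp$truth$sites$start >= 0 &
                    gp$truth$sites$start + w <= 200))
})

test_that("entry-level statistics reproduce the printed worked examples", {
  perfect <- evaluate_entries(counts = list(tp = 28, tn = 8, fp = 0, fn = 0))
  expect_equal(unname(perfect$rounded), c(1, 1, 1))

  r1 <- evaluate_entries(counts = list(tp = 16, tn = 8, fp = 0, fn = 12))
  expect_equal(unname(r1$rounded), c(0.57, 1.00, 0.73))

  r2 <- evaluate_entries(counts = list(tp = 5.5, tn = 8, fp = 0, fn = 22.5))
  expect_equal(unname(r2$rounded), c(0.20, 1.00, 0.33))

  expect_error(evaluate_entries(counts = list(tp = 0, tn = 5, fp = 0, fn = 0)),
               "sensitivity undefined")
  expect_error(evaluate_entries(counts = list(tp = 5, tn = 0, fp = 0, fn = 0)),
               "specificity undefined")
})

test_that("prediction scoring is invariant to entry relabeling and
           supports half-discoveries", {
  gp <- generate_planted(N = 20, L = 60, consensi = "ACGTACGTAC",
                         fraction = 0.5, rng_seed = 4)
  pred <- gp$truth$positives[1:6]
  ev1 <- evaluate_entries(pred, gp$truth)
  # relabel every entry consistently
  map <- setNames(paste0("z", seq_along(gp$Y$id)), gp$Y$id)
  truth2 <- gp$truth
  truth2$positives <- unname(map[gp$truth$positives])
  ev2 <- evaluate_entries(unname(map[pred]), truth2,
                          all_ids = unname(map[gp$Y$id]))
  expect_equal(ev1$sensitivity, ev2$sensitivity)
  expect_equal(ev1$specificity, ev2$specificity)

  # a motif covering < 5% of entries is scored as half a discovery
  N <- 300
  truth3 <- list(params = list(N = N),
                 positives = sprintf("entry_%03d", 1:100))
  evh <- evaluate_entries(sprintf("entry_%03d", 1:10), truth3,
                          half_discovery = TRUE)
  expect_equal(evh$tp, 5)
  expect_equal(evh$fn, 95)
})

test_that("half-site annotation reproduces the published worked example", {
  expect_equal(lexa_half_site_mutations(lexa_canonical_site())$count, 0)
  rows <- list(ptrA = c("CTATGTTTATATAACCATCA", 2),
               yfaX = c("ATATGATCGTCTATCCAGTG", 1),
               ydjF = c("CCCTGTATCTTTTTACATCA", 1),
               ybeR = c("AAATGTATTTAGGTACATGC", 2),
               ynaE = c("ATATGTTGACTTATACATCG", 2),
               trs5 = c("GGATGTTTAGATGTCCATAC", 2))
  for (r in rows)
    expect_equal(lexa_half_site_mutations(r[1])$count, as.integer(r[2]))
  expect_error(lexa_half_site_mutations("ACGT"), "20-nt")
  expect_error(lexa_half_site_mutations(paste(rep("N", 20), collapse = "")),
               "20-nt")
})
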
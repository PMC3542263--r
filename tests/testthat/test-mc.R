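test_that("seed sampling is uniform-without-replacement and reproducible", {
  set.seed(1)
  Y <- seq_set(setNames(replicate(80, paste(
    sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")),
    paste0("e", 1:80)))
  seeds <- sample_seeds(Y, n = 50, size = 8, rng_seed = 3)
  expect_length(seeds, 50)
  expect_true(all(vapply(seeds, function(s)
    length(s) == 8 && !anyDuplicated(s) && all(s %in% Y$id), TRUE)))
  expect_identical(seeds, sample_seeds(Y, 50, 8, rng_seed = 3))

  capped <- sample_seeds(Y, n = 2, size = 500, rng_seed = 1)
  expect_true(all(vapply(capped, function(s) setequal(s, Y$id), TRUE)))
  expect_error(sample_seeds(seq_set(c(a = "ACGT")), 1, 2), "at least 2")
})

test_that("per-scheme defaults follow the convention", {
  expect_equal(motifsieve:::default_n_seeds("zoops_mc"), 500L)
  expect_equal(motifsieve:::default_n_seeds("single_mast"), 200L)
  expect_equal(motifsieve:::default_n_seeds("iterative"), 50L)
  # default seed size is max(8, 10% of N)
  Y <- seq_set(setNames(replicate(200, paste(
    sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")),
    paste0("e", 1:200)))
  s <- sample_seeds(Y, 1, rng_seed = 1)
  expect_length(s[[1]], 20)
  Y2 <- seq_set(Y$seq[1:30], Y$id[1:30])
  expect_length(sample_seeds(Y2, 1, rng_seed = 1)[[1]], 8)
})

test_that("the subset-only scheme never leaves its seed", {
  gp <- exact_word_set(n = 14, L = 100, seed = 41)
  bg <- build_background(gp$Y, order = 0)
  cfg <- finder_config(wmin = 12, wmax = 12, null_reps = 99)
  set.seed(2)
  ids <- sample(gp$Y$id, 6)
  rs <- scheme_zoops_mc(ids, gp$Y, bg, cfg, seed_id = 7)
  expect_true(all(rs$members %in% ids))
  expect_setequal(rs$members, ids)  # every seed entry carries the word
  expect_equal(rs$scheme, "zoops_mc")
  expect_equal(rs$seed_id, 7)
})

test_that("the single-scan scheme can grow beyond its seed", {
  gp <- exact_word_set(n = 16, L = 100, seed = 43)
  bg <- build_background(gp$Y, order = 0)
  cfg <- finder_config(wmin = 12, wmax = 12, null_reps = 99)
  set.seed(3)
  ids <- sort(sample(gp$Y$id, 5))
  rs <- scheme_single_mast(ids, gp$Y, bg, cfg, cache = new.env())
  expect_true(length(setdiff(rs$members, ids)) > 0)
  expect_setequal(rs$members, gp$Y$id)
  # provenance sites lie inside the members
  expect_true(all(rs$motif$sites$entry_id %in% rs$members))
})

test_that("iterative fixed points satisfy the in-and-only-in property", {
  gp <- generate_planted(N = 24, L = 150, consensi = "GCATTACGGTAC",
                         fraction = 0.5, mut_rate = 0.05, rng_seed = 47)
  bg <- build_background(gp$Y, order = 0)
  cfg <- finder_config(wmin = 12, wmax = 12, null_reps = 199)
  cache <- new.env()
  subs <- run_mc(gp$Y, bg, cfg, "iterative", n = 5, size = 6, rng_seed = 11,
                 null_cache = cache)
  expect_length(subs, 5)
  conv <- Filter(function(rs) isTRUE(rs$converged), subs)
  expect_gt(length(conv), 0)
  for (rs in conv) {
    sc <- scan_motif(rs$motif, gp$Y, bg, sig_evalue = 10)
    expect_identical(sort(sc$significant_ids), sort(rs$members))
    expect_true(all(rs$motif$sites$entry_id %in% rs$members))
  }
})

test_that("Monte Carlo runs are deterministic under a fixed master seed", {
  gp <- generate_planted(N = 20, L = 120, consensi = "GCATTACGGTAC",
                         fraction = 0.5, mut_rate = 0, rng_seed = 53)
  bg <- build_background(gp$Y, order = 0)
  cfg <- finder_config(wmin = 12, wmax = 12, null_reps = 99)
  r1 <- run_mc(gp$Y, bg, cfg, "iterative", n = 4, size = 5, rng_seed = 6,
               null_cache = new.env())
  r2 <- run_mc(gp$Y, bg, cfg, "iterative", n = 4, size = 5, rng_seed = 6,
               null_cache = new.env())
  expect_identical(lapply(r1, function(x) x$members),
                   lapply(r2, function(x) x$members))
  expect_identical(vapply(r1, function(x)
    if (is.null(x$motif)) NA_real_ else x$motif$evalue, 0),
    vapply(r2, function(x)
      if (is.null(x$motif)) NA_real_ else x$motif$evalue, 0))
  # n seeds in, n records out, flags partition them
  expect_length(r1, 4)
  expect_true(all(vapply(r1, function(x)
    is.logical(x$converged) && is.logical(x$significant), TRUE)))
})

test_that("related subsets serialize as JSON lines", {
  gp <- exact_word_set(n = 8, L = 90, seed = 59)
  bg <- build_background(gp$Y, order = 0)
  cfg <- finder_config(wmin = 12, wmax = 12, null_reps = 99)
  subs <- run_mc(gp$Y, bg, cfg, "zoops_mc", n = 2, size = 4, rng_seed = 2,
                 null_cache = new.env())
  f <- withr::local_tempfile(fileext = ".jsonl")
  motifsieve:::write_subsets_jsonl(subs, f)
  lines <- readLines(f)
  expect_length(lines, 2)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$seed_id, 1)
  expect_true(all(c("scheme", "members", "converged", "evalue") %in%
                    names(rec)))
})
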
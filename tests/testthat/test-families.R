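fam_of <- function(member_sets, motif = delta_motif("ACGTACGTAC", 8, 1)) {
  subs <- lapply(seq_along(member_sets), function(i) {
    structure(list(seed_id = i, scheme = "iterative",
                   members = member_sets[[i]], motif = motif,
                   iterations = 1L, converged = TRUE, significant = TRUE),
              class = "related_subset")
  })
  structure(list(family_id = 1L, members = subs), class = "motif_family")
}

test_that("entry re-occurrence frequencies count subset membership", {
  F1 <- fam_of(list(c("a", "b", "c")))
  expect_equal(entry_frequencies(F1), c(a = 1, b = 1, c = 1))

  F2 <- fam_of(list(c("a", "b"), c("a", "c"), c("a", "b"), c("b", "d")))
  fr <- entry_frequencies(F2)
  expect_equal(unname(fr["a"]), 0.75)
  expect_true(all(fr > 0 & fr <= 1))
  # conservation: frequencies times family size recover membership counts
  counts <- fr * 4
  expect_equal(unname(counts[c("a", "b", "c", "d")]), c(3, 3, 1, 1))
  expect_error(entry_frequencies(structure(list(family_id = 1,
                                                members = list()),
                                           class = "motif_family")),
               "empty")
})

test_that("familial profiles honor the frequency threshold", {
  gp <- generate_planted(N = 16, L = 100, consensi = "GCATTACGGTAC",
                         fraction = 0.75, mut_rate = 0, rng_seed = 61)
  bg <- build_background(gp$Y, order = 0)
  pos <- gp$truth$positives
  F <- fam_of(list(pos, pos[1:10], pos[1:10]),
              motif = delta_motif("GCATTACGGTAC", 10, 1))
  cfg <- finder_config(wmin = 12, wmax = 12, null_reps = 99)
  cache <- new.env()
  fp_hi <- familial_profile(F, gp$Y, bg, 1.0, cfg, null_cache = cache)
  fp_lo <- familial_profile(F, gp$Y, bg, 0.3, cfg, null_cache = cache)
  expect_setequal(fp_hi$contributing_entries, pos[1:10])
  # lowering the threshold never shrinks the contributing set
  expect_true(all(fp_hi$contributing_entries %in%
                    fp_lo$contributing_entries))
  # OOPS: one site per contributing entry
  expect_equal(fp_hi$motif$nsites, length(fp_hi$contributing_entries))
  expect_equal(consensus(fp_hi$motif), "GCATTACGGTAC")

  Fsmall <- fam_of(list(c(pos[1]), c(pos[2])))
  expect_message(fp_bad <- familial_profile(Fsmall, gp$Y, bg, 1.0, cfg),
                 "fewer than 2")
  expect_false(fp_bad$valid)
})

test_that("threshold selection minimizes the E-value over the grid", {
  gp <- generate_planted(N = 14, L = 100, consensi = "GCATTACGGTAC",
                         fraction = 0.7, mut_rate = 0, rng_seed = 67)
  bg <- build_background(gp$Y, order = 0)
  pos <- gp$truth$positives
  F <- fam_of(list(pos, pos[1:6], pos), delta_motif("GCATTACGGTAC", 10, 1))
  cfg <- finder_config(wmin = 12, wmax = 12, null_reps = 99)
  set.seed(5)
  sel <- choose_fp_threshold(F, gp$Y, bg, grid = c(0.5, 1.0), cfg = cfg,
                             null_cache = new.env())
  ev <- sel$grid_evalues
  best <- max(which(ev == min(ev[is.finite(ev)])))
  expect_equal(sel$threshold, c(0.5, 1.0)[best])
  # degenerate single-point grid returns that point
  set.seed(5)
  one <- choose_fp_threshold(F, gp$Y, bg, grid = 1.0, cfg = cfg,
                             null_cache = new.env())
  expect_equal(one$threshold, 1.0)
})

test_that("the MotifMap records in-bounds best-hit spans only for
           significant entries", {
  gp <- generate_planted(N = 18, L = 90, consensi = "GCATTACGGTAC",
                         fraction = 0.5, mut_rate = 0, rng_seed = 71)
  bg <- build_background(gp$Y, order = 0)
  pos <- gp$truth$positives
  F <- fam_of(list(pos, pos), delta_motif("GCATTACGGTAC", 10, 1))
  cfg <- finder_config(wmin = 12, wmax = 12, null_reps = 99)
  fp <- familial_profile(F, gp$Y, bg, 1.0, cfg, null_cache = new.env())
  map <- motif_map(gp$Y, list(fp), bg, sig_evalue = 10)
  expect_equal(map$entries, gp$Y$id)
  expect_length(map$profiles, 1)
  w <- fp$motif$width
  for (i in seq_along(map$entries)) {
    cell <- map$cells[[i, 1]]
    if (is.null(cell)) next
    expect_equal(cell$end - cell$start + 1L, w)
    expect_gte(cell$start, 1L)
    expect_lte(cell$end, nchar(gp$Y$seq[i]))
  }
  # planted entries are matched, and matched spans hit the true site
  hit_rows <- which(!vapply(map$cells[, 1], is.null, TRUE))
  expect_true(all(pos %in% map$entries[hit_rows]))

  f <- withr::local_tempfile(fileext = ".tsv")
  motifsieve:::write_motif_map_tsv(map, f)
  tab <- read.table(f, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(nrow(tab), length(map$entries))
})
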
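fake_subset <- function(id, motif, evalue = 1e-4, members = c("a", "b")) {
  motif$evalue <- evalue
  structure(list(seed_id = id, scheme = "iterative", members = members,
                 motif = motif, iterations = 1L, converged = TRUE,
                 significant = evalue <= 0.001),
            class = "related_subset")
}

test_that("E-value filtering keeps the lowest top_k and drops the rest", {
  m <- delta_motif("ACGTAC", n = 8, pseudo = 1)
  subs <- lapply(1:10, function(i) fake_subset(i, m, evalue = i * 1e-5))
  kept <- filter_subsets(subs, evalue_max = 0.001, top_k = 5)
  expect_equal(vapply(kept, function(x) x$seed_id, 0L), 1:5)

  high <- lapply(1:4, function(i) fake_subset(i, m, evalue = 0.5))
  expect_warning(out <- filter_subsets(high), "filter")
  expect_length(out, 0)
  expect_equal(formals(filter_subsets)$evalue_max, 0.001)
})

test_that("ALLR matches its closed forms and is symmetric", {
  q <- rep(0.25, 4)
  expect_equal(allr(c(10, 0, 0, 0), c(10, 0, 0, 0), q, pseudo = 0), 2)
  # hand evaluation for (5,5,0,0) vs (10,0,0,0), smoothed so all freqs > 0
  c1 <- c(5, 5, 0, 0); c2 <- c(10, 0, 0, 0)
  f1 <- (c1 + q) / 11; f2 <- (c2 + q) / 11
  hand <- (sum(c2 * log2(f1 / q)) + sum(c1 * log2(f2 / q))) / 20
  expect_equal(allr(c1, c2, q, pseudo = 1), hand)
  set.seed(8)
  for (i in 1:20) {
    a <- rpois(4, 3) + 1; b <- rpois(4, 3) + 1
    expect_equal(allr(a, b, q), allr(b, a, q), tolerance = 1e-12)
  }
  expect_error(allr(c(0, 0, 0, 0), c(1, 1, 1, 1), q), "zero-sum")
})

test_that("motif distance is zero on self and reverse complement", {
  m <- delta_motif("ACGGTT", n = 12)
  expect_equal(motif_distance(m, m, pseudo = 0), 0)
  expect_equal(motif_distance(m, motif_rc(m), pseudo = 0), 0)
  set.seed(9)
  counts <- matrix(rpois(4 * 6, 5) + 1, 4, 6)
  m2 <- new_motif(counts, pseudo_total = 1)
  expect_equal(motif_distance(m2, m2), 0)
  expect_equal(motif_distance(m, m2), motif_distance(m2, m),
               tolerance = 1e-12)
  expect_gte(motif_distance(m, m2), 0)
})

test_that("motif distance equals an exhaustive alignment search", {
  # independent oracle: enumerate every offset and strand directly
  oracle_dist <- function(m1, m2, q, pseudo) {
    sim <- function(cc1, cc2) {
      best <- -Inf
      w1 <- ncol(cc1); w2 <- ncol(cc2)
      min_ov <- ceiling(min(w1, w2) / 2)
      for (off in -(w2 - 1):(w1 - 1)) {
        j2 <- seq_len(w2); j1 <- off + j2
        keep <- j1 >= 1 & j1 <= w1
        if (sum(keep) < min_ov) next
        s <- mean(sapply(which(keep), function(j)
          allr(cc1[, j1[j]], cc2[, j2[j]], q, pseudo)))
        if (s > best) best <- s
      }
      best
    }
    rc <- function(M) M[4:1, ncol(M):1, drop = FALSE]
    s12 <- max(sim(m1$counts, m2$counts), sim(m1$counts, rc(m2$counts)))
    s11 <- mean(sapply(seq_len(ncol(m1$counts)), function(j)
      allr(m1$counts[, j], m1$counts[, j], q, pseudo)))
    s22 <- mean(sapply(seq_len(ncol(m2$counts)), function(j)
      allr(m2$counts[, j], m2$counts[, j], q, pseudo)))
    max(0, (s11 + s22) / 2 - s12)
  }
  set.seed(10)
  q <- rep(0.25, 4)
  for (i in 1:5) {
    m1 <- new_motif(matrix(rpois(16, 4) + 1, 4, 4), pseudo_total = 1)
    m2 <- new_motif(matrix(rpois(16, 4) + 1, 4, 4), pseudo_total = 1)
    expect_equal(motif_distance(m1, m2, q, 1), oracle_dist(m1, m2, q, 1),
                 tolerance = 1e-10)
  }
})

test_that("UPGMA reproduces hand-worked merges", {
  D <- matrix(c(0, 2, 0, 2, 0, 0, 0, 0, 0), 3, 3)
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- upgma_tree(D)
  expect_equal(t$height, c(1, 2))
  expect_equal(t$merge[1, ], c(-2L, -1L))

  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"),
                                                    c("x", "y")))
  t2 <- upgma_tree(D2)
  expect_equal(t2$height, 1.5)
})

test_that("UPGMA agrees with the reference average-linkage implementation", {
  set.seed(12)
  for (i in 1:50) {
    n <- 8
    M <- matrix(runif(n * n, 0.2, 3), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(paste0("L", 1:n), paste0("L", 1:n))
    ours <- upgma_tree(D)
    ref <- hclust(as.dist(D), method = "average")
    # heights: ours are half the merge distance
    expect_equal(sort(2 * ours$height), sort(ref$height), tolerance = 1e-9)
    # identical tree topology and heights via cophenetic distances
    co_ours <- stats::cophenetic(motifsieve:::tree_as_hclust(ours))
    co_ref <- stats::cophenetic(ref)
    expect_equal(as.matrix(co_ours)[rownames(as.matrix(co_ref)),
                                    colnames(as.matrix(co_ref))] * 2,
                 as.matrix(co_ref), tolerance = 1e-9)
  }
})

test_that("tree cutting respects the relative threshold and partitions", {
  D <- matrix(c(0, 0.1, 2, 2.2,
                0.1, 0, 2.1, 2.3,
                2, 2.1, 0, 0.15,
                2.2, 2.3, 0.15, 0), 4, 4,
              dimnames = list(paste0("L", 1:4), paste0("L", 1:4)))
  t <- upgma_tree(D)
  fam <- cut_tree(t, 0.05)
  expect_equal(length(unique(fam)), 2)
  expect_equal(unname(fam["L1"]), unname(fam["L2"]))
  expect_equal(unname(fam["L3"]), unname(fam["L4"]))

  expect_equal(length(unique(cut_tree(t, 0))), 4)
  expect_equal(length(unique(cut_tree(t, 1))), 1)
  expect_equal(formals(cut_tree)$cluster_frac, 0.05)
})

test_that("Newick export is readable and preserves leaf labels", {
  m1 <- delta_motif("ACGTA", n = 6); m2 <- delta_motif("TTTGA", n = 6)
  m3 <- delta_motif("ACGGA", n = 6)
  subs <- list(fake_subset(1, m1), fake_subset(2, m2), fake_subset(3, m3))
  D <- motif_distance_matrix(subs)
  t <- upgma_tree(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  tree_newick(t, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, c("seed1", "seed2", "seed3"))

  t1 <- upgma_tree(matrix(0, 1, 1, dimnames = list("seed9", "seed9")))
  expect_match(tree_newick(t1), "seed9")
})
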
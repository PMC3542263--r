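#' Filter related subsets by motif significance
#'
#' Drops subsets without a motif or with motif E-value above `evalue_max`
#' (default 0.001); if more than `top_k` survive, keeps the `top_k`
#' smallest E-values (ties broken by seed id).
#'
#' @param subsets list of `related_subset`.
#' @param evalue_max E-value cutoff.
#' @param top_k maximum number of retained subsets (default 200).
#' @return filtered list (possibly empty, with a warning).
#' @export
filter_subsets <- function(subsets, evalue_max = 0.001, top_k = 200L) {
  if (length(subsets) == 0L) stop("no related subsets supplied")
  ok <- vapply(subsets, function(rs)
    !is.null(rs$motif) && !is.na(rs$motif$evalue) &&
      rs$motif$evalue <= evalue_max && length(rs$members) >= 1L, TRUE)
  kept <- subsets[ok]
  if (length(kept) == 0L) {
    warning("no related subset passed the E-value filter")
    return(kept)
  }
  if (length(kept) > top_k) {
    ev <- vapply(kept, function(rs) rs$motif$evalue, 0)
    sid <- vapply(kept, function(rs) rs$seed_id, 0L)
    kept <- kept[order(ev, sid)][seq_len(top_k)]
    kept <- kept[order(vapply(kept, function(rs) rs$seed_id, 0L))]
  }
  kept
}

#' Average log-likelihood ratio between two motif columns
#'
#' ALLR(c1, c2) = (sum_b n2_b log2(f1_b/q_b) + sum_b n1_b log2(f2_b/q_b)) /
#' (n1 + n2), a symmetric per-column similarity relative to the background.
#' Frequencies come from the counts smoothed by `pseudo` background mass.
#'
#' @param c1,c2 length-4 nonnegative count vectors (A, C, G, T).
#' @param q strictly positive background marginals.
#' @param pseudo smoothing mass (0 for the raw formula).
#' @return a real number (2 = identical delta columns under uniform q).
#' @export
allr <- function(c1, c2, q = rep(0.25, 4), pseudo = 1) {
  n1 <- sum(c1); n2 <- sum(c2)
  if (n1 <= 0 || n2 <= 0) stop("zero-sum column in ALLR")
  if (any(q <= 0)) stop("background marginals must be strictly positive")
  f1 <- (c1 + pseudo * q) / (n1 + pseudo)
  f2 <- (c2 + pseudo * q) / (n2 + pseudo)
  # 0 * log(0) = 0; a positive count against a zero frequency is -Inf
  term <- function(cc, ff) sum(ifelse(cc > 0, cc * log2(ff / q), 0))
  (term(c2, f1) + term(c1, f2)) / (n1 + n2)
}

motif_counts <- function(m) {
  # stored counts when the motif was built from sites; otherwise recover
  # deterministically from the smoothed frequencies
  if (!is.null(m$counts) && sum(m$counts) > 0) m$counts
  else m$freqs * max(m$nsites, 1)
}

#' ALLR distance between two motifs
#'
#' Best ungapped alignment over all offsets, also trying the reverse
#' complement of `m2`, with overlap at least `ceil(min(w1, w2)/2)`; the
#' alignment similarity s12 is the mean ALLR over aligned columns.  The
#' distance subtracts it from the motifs' self-similarity baseline:
#' `d = max(0, (s11 + s22)/2 - s12)`, so identical motifs are at distance
#' zero whatever their entropy (a pure offset by the theoretical maximum
#' ALLR would leave realistically noisy motifs far from zero even from
#' themselves, defeating relative clustering thresholds).  Symmetric and
#' nonnegative; the triangle inequality is not claimed.
#'
#' @param m1,m2 `ms_motif` objects.
#' @param q background marginals.
#' @param pseudo ALLR smoothing mass.
#' @return nonnegative distance.
#' @export
motif_distance <- function(m1, m2, q = rep(0.25, 4), pseudo = 1) {
  s12 <- best_allr_alignment(m1, m2, q, pseudo)
  s11 <- self_allr(m1, q, pseudo)
  s22 <- self_allr(m2, q, pseudo)
  max(0, (s11 + s22) / 2 - s12)
}

# mean per-column ALLR of a motif against itself (full-width alignment)
self_allr <- function(m, q, pseudo) {
  cn <- motif_counts(m)
  mean(vapply(seq_len(ncol(cn)), function(j) allr(cn[, j], cn[, j], q,
                                                  pseudo), 0))
}

best_allr_alignment <- function(m1, m2, q, pseudo) {
  c1 <- motif_counts(m1)
  best <- -Inf
  for (m2v in list(m2, motif_rc(m2))) {
    c2 <- motif_counts(m2v)
    w1 <- ncol(c1); w2 <- ncol(c2)
    min_ov <- ceiling(min(w1, w2) / 2)
    for (off in (-w2 + min_ov):(w1 - min_ov)) {
      # column j of c2 aligns with column off + j of c1
      j2 <- seq_len(w2)
      j1 <- off + j2
      keep <- j1 >= 1L & j1 <= w1
      if (sum(keep) < min_ov) next
      sc <- mean(vapply(which(keep), function(j)
        allr(c1[, j1[j]], c2[, j2[j]], q, pseudo), 0))
      if (sc > best) best <- sc
    }
  }
  if (!is.finite(best)) stop("no legal ungapped overlap between motifs")
  best
}

#' Pairwise ALLR distance matrix for retained subsets
#'
#' @param subsets list of `related_subset` with motifs (e.g. from
#'   [filter_subsets()]).
#' @param q background marginals.
#' @param pseudo ALLR smoothing mass.
#' @return symmetric matrix with zero diagonal, labelled `seed<id>`.
#' @export
motif_distance_matrix <- function(subsets, q = rep(0.25, 4), pseudo = 1) {
  n <- length(subsets)
  D <- matrix(0, n, n)
  labs <- vapply(subsets, function(rs) paste0("seed", rs$seed_id), "")
  dimnames(D) <- list(labs, labs)
  if (n < 2L) return(D)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <-
        motif_distance(subsets[[i]]$motif, subsets[[j]]$motif, q, pseudo)
    }
  }
  D
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair-group agglomeration: repeatedly merge the
#' closest pair of clusters; distances to the merged cluster are
#' size-weighted averages; merge heights are half the merge distance.
#' Ties are broken deterministically by the smallest leaf index contained
#' in a cluster.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return object of class `motif_tree`: list with `labels`, `merge`
#'   (hclust-style matrix), `height` (merge heights, nondecreasing),
#'   `merge_dist` (the merge distances, i.e. 2 x height), and
#'   `max_dissimilarity` (largest entry of `D`).
#' @export
upgma_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("L", 1:n)
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  if (n == 1L) {
    return(structure(list(labels = labels,
                          merge = matrix(0L, 0L, 2L), height = numeric(),
                          merge_dist = numeric(), max_dissimilarity = 0),
                     class = "motif_tree"))
  }
  # active clusters: negative = leaf index, positive = merge row
  id <- -(1:n)          # hclust coding for current clusters
  size <- rep(1L, n)
  minleaf <- 1:n        # smallest leaf index per cluster, for tie-breaks
  act <- rep(TRUE, n)
  Dm <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in 1:(n - 1L)) {
    ij <- NULL; bestd <- Inf
    idx <- which(act)
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        d <- Dm[i, j]
        better <- d < bestd - 1e-12
        tie <- abs(d - bestd) <= 1e-12
        if (better || (tie && !is.null(ij) &&
                       (min(minleaf[i], minleaf[j]) <
                          min(minleaf[ij[1L]], minleaf[ij[2L]]) ||
                        (min(minleaf[i], minleaf[j]) ==
                           min(minleaf[ij[1L]], minleaf[ij[2L]]) &&
                         max(minleaf[i], minleaf[j]) <
                           max(minleaf[ij[1L]], minleaf[ij[2L]]))))) {
          bestd <- d; ij <- c(i, j)
        }
      }
    }
    i <- ij[1L]; j <- ij[2L]
    pair <- sort(c(id[i], id[j]))
    merge[step, ] <- pair
    height[step] <- bestd / 2
    # size-weighted average distances to the new cluster, stored in slot i
    for (k in which(act)) {
      if (k == i || k == j) next
      Dm[i, k] <- Dm[k, i] <-
        (size[i] * Dm[i, k] + size[j] * Dm[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
    act[j] <- FALSE
  }
  structure(list(labels = labels, merge = merge, height = height,
                 merge_dist = 2 * height, max_dissimilarity = max(D)),
            class = "motif_tree")
}

tree_as_hclust <- function(t) {
  n <- length(t$labels)
  if (n < 2L) stop("cannot convert a single-leaf tree to hclust")
  structure(list(merge = t$merge, height = t$height,
                 order = hclust_order(t$merge), labels = t$labels,
                 method = "average", call = NULL,
                 dist.method = "allr"),
            class = "hclust")
}

hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Cut a motif tree into families
#'
#' The clustering threshold is `cluster_frac` times the maximum
#' dissimilarity observed in the whole pairwise distance matrix; leaves
#' connected only through merges at height at most that threshold form one
#' family.  Families partition the leaves.
#'
#' @param t a `motif_tree`.
#' @param cluster_frac fraction of the maximum dissimilarity (default 0.05).
#' @return integer vector of family ids, named by leaf label, numbered in
#'   decreasing family size (family 1 is the largest).
#' @export
cut_tree <- function(t, cluster_frac = 0.05) {
  stopifnot(cluster_frac >= 0, cluster_frac <= 1)
  n <- length(t$labels)
  if (n == 1L) return(setNames(1L, t$labels))
  if (cluster_frac == 0) return(setNames(seq_len(n), t$labels))
  h <- cluster_frac * t$max_dissimilarity
  fam <- seq_len(n)
  memb <- lapply(1:n, identity)
  getm <- function(node) if (node < 0L) -node else memb[[n + node]]
  for (step in seq_along(t$height)) {
    members <- c(getm(t$merge[step, 1L]), getm(t$merge[step, 2L]))
    memb[[n + step]] <- members
    if (t$height[step] <= h + 1e-12)
      fam[members] <- min(fam[members])
  }
  # renumber by decreasing size, ties by first leaf
  sizes <- table(fam)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  map <- setNames(seq_along(ord), names(sizes)[ord])
  setNames(as.integer(map[as.character(fam)]), t$labels)
}

#' Newick export of a motif tree
#'
#' Branch lengths are height deltas of the UPGMA tree (an ultrametric
#' dendrogram).
#'
#' @param t a `motif_tree`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
tree_newick <- function(t, path = NULL) {
  if (length(t$labels) == 1L) {
    nwk <- paste0("(", t$labels, ":0);")
  } else {
    phy <- ape::as.phylo(tree_as_hclust(t))
    nwk <- ape::write.tree(phy)
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
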
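#' Generate a planted-motif data set with ground truth
#'
#' Emulates a corrupted motif-discovery input: `N` sequences of length `L`
#' are drawn from an order-`bg_order` background; for each consensus in
#' `consensi`, `round(fraction * N)` entries receive exactly one instance
#' of that consensus at a uniform random offset and strand, with each
#' position independently mutated to a uniform other base with probability
#' `mut_rate`; the remaining entries carry no motif (the zero-or-one
#' occurrence regime).
#'
#' @param N number of entries.
#' @param L entry length (>= the widest consensus).
#' @param consensi character vector of planted consensus words.
#' @param fraction fraction(s) of entries planted per consensus (recycled;
#'   the total must not exceed 1).
#' @param mut_rate per-position mutation probability.
#' @param bg_order background Markov order for the random sequence.
#' @param bg_q length-4 marginal for the order-0 background (default
#'   uniform); higher orders use a background estimated from sequences
#'   drawn from this marginal.
#' @param rng_seed integer seed; identical parameters and seed give a
#'   bit-identical data set.
#' @return list with `Y` (a [seq_set()]) and `truth`: a list holding
#'   `params`, `sites` (data frame entry_id, consensus_idx, start 0-based,
#'   strand), and `positives` (ids carrying a site).
#' @export
generate_planted <- function(N, L, consensi, fraction, mut_rate = 0,
                             bg_order = 0L, bg_q = rep(0.25, 4),
                             rng_seed = 1L) {
  stopifnot(N >= 1L, L >= max(nchar(consensi)), mut_rate >= 0, mut_rate <= 1)
  fraction <- rep_len(fraction, length(consensi))
  n_plant <- round(fraction * N)
  if (sum(n_plant) > N) stop("planting fractions exceed the data set size")
  set.seed(as.integer(rng_seed))
  bases <- c("A", "C", "G", "T")
  draw_bg <- function(len) {
    if (bg_order == 0L) {
      paste(sample(bases, len, replace = TRUE, prob = bg_q), collapse = "")
    } else {
      # order-k chain with uniform context start; transition rows drawn as
      # symmetric Dirichlet perturbations of the marginal, fixed by the seed
      k <- bg_order
      ctx <- sample(bases, k, replace = TRUE, prob = bg_q)
      out <- ctx
      trans <- trans_rows(k, bg_q)
      for (i in (k + 1L):len) {
        key <- paste(out[(i - k):(i - 1L)], collapse = "")
        out[i] <- sample(bases, 1L, prob = trans[key, ])
      }
      paste(out, collapse = "")
    }
  }
  seqs <- vapply(seq_len(N), function(i) draw_bg(L), "")
  ids <- sprintf("entry_%03d", seq_len(N))
  planted_ids <- character(); site_rows <- list()
  pool <- sample.int(N)  # random assignment of which entries get planted
  ptr <- 1L
  for (ci in seq_along(consensi)) {
    word <- toupper(consensi[ci])
    w <- nchar(word)
    if (n_plant[ci] == 0L) next
    take <- pool[ptr:(ptr + n_plant[ci] - 1L)]
    ptr <- ptr + n_plant[ci]
    for (e in take) {
      inst <- mutate_word(word, mut_rate)
      strand <- if (runif(1) < 0.5) "+" else "-"
      placed <- if (strand == "+") inst else revcomp_chr(inst)
      start <- sample.int(L - w + 1L, 1L) - 1L
      s <- seqs[e]
      seqs[e] <- paste0(substr(s, 1L, start), placed,
                        substr(s, start + w + 1L, L))
      planted_ids <- c(planted_ids, ids[e])
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(entry_id = ids[e], consensus_idx = ci, start = start,
                   strand = strand, width = w, stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows)
           else data.frame(entry_id = character(), consensus_idx = integer(),
                           start = integer(), strand = character(),
                           width = integer(), stringsAsFactors = FALSE)
  truth <- list(params = list(N = N, L = L, consensi = consensi,
                              fraction = fraction, mut_rate = mut_rate,
                              bg_order = bg_order, rng_seed = rng_seed),
                sites = sites, positives = sort(planted_ids))
  list(Y = seq_set(seqs, ids), truth = truth)
}

mutate_word <- function(word, rate) {
  if (rate <= 0) return(word)
  v <- strsplit(word, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  hit <- runif(length(v)) < rate
  if (any(hit))
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1L), "")
  paste(v, collapse = "")
}

trans_rows <- function(k, q) {
  ctx <- kmer_names(k)
  out <- matrix(rep(q, each = length(ctx)), nrow = length(ctx),
                dimnames = list(ctx, c("A", "C", "G", "T")))
  out
}

#' Entry-level recovery statistics
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp) and the F-measure
#' defined as the harmonic mean of sensitivity and specificity (note:
#' not of precision and recall).  Counts may be fractional: with
#' `half_discovery = TRUE`, a prediction covering fewer than 5% of the
#' input entries is scored as half a true-positive discovery (each
#' predicted positive counts 0.5 toward tp, the other 0.5 falling to fn).
#'
#' @param predicted character vector of predicted positive entry ids, or
#'   `NULL` when `counts` is given.
#' @param truth a truth object from [generate_planted()] (used for its
#'   `positives` and the universe of ids), or `NULL`.
#' @param counts optional explicit list/vector with tp, tn, fp, fn.
#' @param all_ids universe of entry ids (required with `predicted` unless
#'   `truth` carries params$N ids).
#' @param half_discovery apply the half-discovery convention.
#' @return list with `tp`, `tn`, `fp`, `fn`, `sensitivity`, `specificity`,
#'   `f_measure` (full precision) and `rounded` (2-decimal versions).
#' @export
evaluate_entries <- function(predicted = NULL, truth = NULL, counts = NULL,
                             all_ids = NULL, half_discovery = FALSE) {
  if (is.null(counts)) {
    if (is.null(truth)) stop("either counts or truth must be supplied")
    if (is.null(all_ids))
      all_ids <- sprintf("entry_%03d", seq_len(truth$params$N))
    predicted <- unique(predicted)
    if (!all(predicted %in% all_ids))
      stop("predicted ids outside the entry universe")
    pos <- truth$positives
    neg <- setdiff(all_ids, pos)
    tp <- length(intersect(predicted, pos))
    fp <- length(intersect(predicted, neg))
    fn <- length(setdiff(pos, predicted))
    tn <- length(setdiff(neg, predicted))
    if (half_discovery && length(predicted) < 0.05 * length(all_ids)) {
      fn <- fn + 0.5 * tp
      tp <- 0.5 * tp
    }
  } else {
    counts <- as.list(counts)
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
    if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  }
  if (tp + fn == 0) stop("sensitivity undefined: tp + fn = 0")
  if (tn + fp == 0) stop("specificity undefined: tn + fp = 0")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  f <- if (sens + spec == 0) 0 else 2 * sens * spec / (sens + spec)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = sens, specificity = spec, f_measure = f,
       rounded = c(sensitivity = round(sens, 2), specificity = round(spec, 2),
                   f_measure = round(f, 2)))
}

#' The canonical 20-nt LexA operator rendered as a string
#'
#' CTG and CAG half-sites flank an A/T-rich 10-base spacer; the spacer
#' filler is configurable since only its A/T-richness is conserved.
#'
#' @param spacer 10-character A/T filler between the half-sites.
#' @return a 20-character string.
#' @export
lexa_canonical_site <- function(spacer = "TATATATATA") {
  stopifnot(nchar(spacer) == 10L)
  paste0("TACTG", spacer, "CAGTA")
}

#' Count CTG-to-ATG half-site mutations in a 20-nt LexA operator
#'
#' The canonical operator carries a CTG half-site at positions 3-5 and its
#' reverse-complement CAG at positions 16-18 (1-based).  Returns how many
#' of the two half-sites read as the ATG-mutated form (ATG at 3-5, or CAT
#' at 16-18, the reverse complement of ATG).
#'
#' @param site20 a 20-character string over A, C, G, T.
#' @return list with `count` (0-2), and `half_sites`: a data frame naming
#'   each half-site, its observed triplet, and whether it is mutated.
#' @export
lexa_half_site_mutations <- function(site20) {
  site20 <- toupper(site20)
  if (nchar(site20) != 20L || grepl("[^ACGT]", site20))
    stop("input must be a 20-nt string over A, C, G, T")
  left <- substr(site20, 3L, 5L)
  right <- substr(site20, 16L, 18L)
  hs <- data.frame(
    half_site = c("positions 3-5 (canonical CTG)",
                  "positions 16-18 (canonical CAG)"),
    observed = c(left, right),
    mutated = c(left == "ATG", right == "CAT"),
    stringsAsFactors = FALSE)
  list(count = sum(hs$mutated), half_sites = hs)
}
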
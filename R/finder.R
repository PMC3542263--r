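#' Finder configuration
#'
#' Collects the tunables of the ZOOPS finders.  Width bounds delimit the
#' motif search; `n_starts` expectation-maximization runs are launched per
#' width from the most promising of `n_init_candidates` subsequence-seeded
#' starting points (candidate words are scored by one cheap PSSM pass and
#' the best are refined, the usual MEME-style start heuristic).
#'
#' @param wmin,wmax inclusive motif width bounds.
#' @param both_strands also search the reverse strand (default TRUE).
#' @param max_iter EM iteration cap per start.
#' @param tol absolute convergence tolerance on the penalized log2-likelihood.
#' @param n_starts refined starts per width.
#' @param n_init_candidates candidate subsequences pre-scored per width.
#' @param site_prior initial per-entry probability that a site is present.
#' @param pseudo_total Dirichlet smoothing mass per motif column.
#' @param rng_seed optional integer seed; `NA` uses the ambient RNG stream.
#' @param null_reps shuffle-null replicates for the motif E-value.
#' @param null_iters EM iteration cap inside each null replicate
#'   (`NA`, the default, mirrors `max_iter` so null refits match the
#'   observed fit's budget).
#' @param null_precands candidate subsequences prescored per null
#'   replicate (`NA` mirrors `n_init_candidates`), so the null refit
#'   start matches the quality of the observed fit's start.
#' @param max_shift phase-shift refinement window after EM (columns).
#' @param gibbs_burnin,gibbs_sweeps burn-in and sampling sweeps for
#'   [zoops_gibbs()].
#' @return a list of class `finder_config`.
#' @export
finder_config <- function(wmin = 8L, wmax = 12L, both_strands = TRUE,
                          max_iter = 50L, tol = 1e-4, n_starts = 2L,
                          n_init_candidates = 100L, site_prior = 0.5,
                          pseudo_total = 1, rng_seed = NA_integer_,
                          null_reps = 2499L, null_iters = NA_integer_,
                          null_precands = NA_integer_, max_shift = 3L,
                          gibbs_burnin = 200L, gibbs_sweeps = 300L) {
  stopifnot(wmin >= 1L, wmin <= wmax, max_iter >= 1L,
            site_prior > 0, site_prior <= 1, n_starts >= 1L)
  structure(list(wmin = as.integer(wmin), wmax = as.integer(wmax),
                 both_strands = both_strands, max_iter = as.integer(max_iter),
                 tol = tol, n_starts = as.integer(n_starts),
                 n_init_candidates = as.integer(n_init_candidates),
                 site_prior = site_prior, pseudo_total = pseudo_total,
                 rng_seed = rng_seed, null_reps = as.integer(null_reps),
                 null_iters = if (is.na(null_iters)) as.integer(max_iter)
                              else as.integer(null_iters),
                 null_precands = if (is.na(null_precands))
                                   as.integer(n_init_candidates)
                                 else as.integer(null_precands),
                 max_shift = as.integer(max_shift),
                 gibbs_burnin = as.integer(gibbs_burnin),
                 gibbs_sweeps = as.integer(gibbs_sweeps)),
            class = "finder_config")
}

maybe_seed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
}

# sum of log2-odds scores of a motif's provenance sites (the statistic T the
# E-value machinery compares against its shuffle null)
site_llr <- function(m, Y, bg) {
  if (is.null(m$sites) || nrow(m$sites) == 0L) return(0)
  S <- pssm_scores(m, bg)
  tot <- 0
  for (i in seq_len(nrow(m$sites))) {
    s <- extract_site_seq(Y, m$sites$entry_id[i], m$sites$start[i],
                          m$sites$strand[i], m$width)
    v <- encode_seq(s)
    if (any(v == 0L)) next
    tot <- tot + sum(S[cbind(v, seq_len(m$width))])
  }
  tot
}

# candidate subsequence words: uniform sample over all forward windows
sample_candidate_words <- function(codes, w, n_cand) {
  m_e <- vapply(codes, function(v) max(0L, length(v) - w + 1L), 0L)
  tot <- sum(m_e)
  if (tot == 0L) return(NULL)
  picks <- if (tot <= n_cand) seq_len(tot) else sort(sample.int(tot, n_cand))
  ends <- cumsum(m_e)
  words <- matrix(0L, length(picks), w)
  keep <- logical(length(picks))
  for (k in seq_along(picks)) {
    p <- picks[k]
    e <- which(p <= ends)[1L]
    i <- p - c(0L, ends)[e]  # 1-based start within entry e
    word <- codes[[e]][i:(i + w - 1L)]
    if (all(word > 0L)) {
      words[k, ] <- word
      keep[k] <- TRUE
    }
  }
  words[keep, , drop = FALSE]
}

init_freqs_from_word <- function(word) {
  w <- length(word)
  f <- matrix(0.1, 4L, w)
  f[cbind(word, seq_len(w))] <- 0.7
  f
}

em_result_to_motif <- function(res, Y_sub, bg, cfg, w, name, oops = FALSE) {
  called <- if (oops) res$best_start >= 0L else res$post > 0.5
  called <- called & res$best_start >= 0L
  if (!any(called)) return(NULL)
  sites <- data.frame(entry_id = Y_sub$id[called],
                      start = res$best_start[called],
                      strand = c("+", "-")[res$best_strand[called]],
                      width = w, stringsAsFactors = FALSE)
  build_motif_from_sites(Y_sub, sites, bg, pseudo_total = cfg$pseudo_total,
                         name = name)
}

run_em_width <- function(Y_sub, codes, bg, cfg, w, oops = FALSE,
                         extra_inits = NULL) {
  words <- sample_candidate_words(codes, w, cfg$n_init_candidates)
  if (is.null(words) || nrow(words) == 0L) return(NULL)
  sc <- cpp_score_candidates(codes, words, bg$q, cfg$both_strands)
  ord <- order(sc, decreasing = TRUE)
  starts <- head(ord, cfg$n_starts)
  inits <- lapply(starts, function(s) init_freqs_from_word(words[s, ]))
  for (f0 in extra_inits) {
    f0 <- pmax(f0, 1e-4)
    inits <- c(inits, list(sweep(f0, 2L, colSums(f0), "/")))
  }
  best <- NULL; best_T <- -Inf
  for (f0 in inits) {
    res <- cpp_zoops_em(codes, f0, bg$q,
                        gamma0 = cfg$site_prior, gamma_free = !oops,
                        pseudo = cfg$pseudo_total, max_iter = cfg$max_iter,
                        tol = cfg$tol, both = cfg$both_strands, oops = oops)
    m <- em_result_to_motif(res, Y_sub, bg, cfg, w,
                            name = sprintf("motif_w%d", w), oops = oops)
    if (is.null(m)) next
    T <- site_llr(m, Y_sub, bg)
    if (T > best_T) { best_T <- T; best <- m; best$em_trace <- res$obj }
  }
  if (!is.null(best)) best <- refine_shift(best, Y_sub, bg, cfg)
  best
}

# Phase-shift refinement: EM can converge to an off-register version of a
# motif (all sites offset by the same amount).  Slide all sites together by
# up to max_shift columns, keep the shift with the highest total site
# log-likelihood ratio, and repeat until no shift improves.  The in-register
# solution concentrates the informative columns, so it maximizes the
# statistic; this also makes independent seeds agree on one register.
refine_shift <- function(m, Y_sub, bg, cfg, max_pass = 4L) {
  if (is.null(m$sites) || nrow(m$sites) < 2L || cfg$max_shift < 1L) return(m)
  w <- m$width
  lens <- nchar(Y_sub$seq)
  best <- m
  best_T <- site_llr(m, Y_sub, bg)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (d in c(seq(-cfg$max_shift, -1L), seq_len(cfg$max_shift))) {
      s <- best$sites
      ns <- s
      ns$start <- ifelse(s$strand == "+", s$start + d, s$start - d)
      slen <- lens[match(ns$entry_id, Y_sub$id)]
      ok <- ns$start >= 0L & ns$start + w <= slen
      # require most sites to survive the shift so statistics stay comparable
      if (sum(ok) < max(2L, ceiling(0.8 * nrow(s)))) next
      ns <- ns[ok, , drop = FALSE]
      cand <- tryCatch(
        build_motif_from_sites(Y_sub, ns, bg, cfg$pseudo_total,
                               name = best$name),
        error = function(e) NULL)
      if (is.null(cand)) next
      Tc <- site_llr(cand, Y_sub, bg)
      if (Tc > best_T + 1e-9) {
        best <- cand; best_T <- Tc; improved <- TRUE
      }
    }
    if (!improved) break
  }
  best
}

check_finder_input <- function(Y, cfg) {
  if (n_entries(Y) < 2L) stop("need at least 2 sequence entries")
  if (sum(nchar(Y$seq) >= cfg$wmin) < 1L)
    stop("no entry long enough for the minimum motif width")
}

#' ZOOPS expectation-maximization motif finder
#'
#' Fits a zero-or-one-occurrence-per-sequence mixture: each entry either
#' contains no site or exactly one site at an unknown position and strand.
#' The E-step assigns each entry a posterior over \{no site\} and every
#' start x strand; the M-step re-estimates the frequency matrix from the
#' posterior-weighted counts and the site prior from the mean site-presence
#' posterior.  Runs multi-start over widths `wmin:wmax`; the reported motif
#' is the candidate with the smallest shuffle-null E-value (ties to the
#' smaller width).  Provenance sites are the entries whose site-presence
#' posterior exceeds 0.5, at their maximum-posterior position.
#'
#' @param Y a [seq_set()] with at least two entries.
#' @param bg a `bg_model`; its order-0 marginal supplies the per-position
#'   background likelihood.
#' @param cfg a [finder_config()].
#' @param assign_evalue attach the shuffle-null E-value to the returned
#'   motif.  With a single width this can be deferred (E-value left `NA`);
#'   with several widths the E-value is always computed because width
#'   selection ranks candidates by it.
#' @return an `ms_motif`, or an error if no start called any site.
#' @export
zoops_em <- function(Y, bg, cfg = finder_config(), assign_evalue = TRUE,
                     null_cache = NULL) {
  check_finder_input(Y, cfg)
  maybe_seed(cfg$rng_seed)
  widths <- cfg$wmin:cfg$wmax
  need_e <- assign_evalue || length(widths) > 1L
  n_candidates <- length(widths) * cfg$n_starts
  best <- NULL
  for (w in widths) {
    keep <- nchar(Y$seq) >= w
    if (sum(keep) < 2L) next
    Y_sub <- seq_set(Y$seq[keep], Y$id[keep])
    codes <- encode_set(Y_sub)
    m <- run_em_width(Y_sub, codes, bg, cfg, w)
    if (is.null(m)) next
    if (need_e)
      m$evalue <- motif_evalue(m, Y_sub, bg, n_candidates = n_candidates,
                               null_reps = cfg$null_reps, cfg = cfg,
                               null_cache = null_cache)
    if (is.null(best) ||
        (need_e && m$evalue < best$evalue)) best <- m
  }
  if (is.null(best)) stop("EM found no motif (all posteriors degenerate)")
  best$n_candidates <- n_candidates
  best
}

#' Gibbs-sampling ZOOPS motif finder
#'
#' A collapsed Gibbs sampler over the per-entry site assignment
#' (absent, or one start x strand).  Each sweep resamples every entry's
#' assignment from its full conditional under the hard counts of the other
#' entries; after burn-in, the assignment with the highest site
#' log-likelihood-ratio encountered is returned as the motif.  E-value
#' assignment is identical to [zoops_em()].
#'
#' @inheritParams zoops_em
#' @return an `ms_motif`.
#' @export
zoops_gibbs <- function(Y, bg, cfg = finder_config(), assign_evalue = TRUE,
                        null_cache = NULL) {
  check_finder_input(Y, cfg)
  maybe_seed(cfg$rng_seed)
  widths <- cfg$wmin:cfg$wmax
  need_e <- assign_evalue || length(widths) > 1L
  n_candidates <- length(widths) * cfg$n_starts
  best <- NULL
  for (w in widths) {
    keep <- nchar(Y$seq) >= w
    if (sum(keep) < 2L) next
    Y_sub <- seq_set(Y$seq[keep], Y$id[keep])
    codes <- encode_set(Y_sub)
    m <- gibbs_width(Y_sub, codes, bg, cfg, w)
    if (is.null(m)) next
    if (need_e)
      m$evalue <- motif_evalue(m, Y_sub, bg, n_candidates = n_candidates,
                               null_reps = cfg$null_reps, cfg = cfg,
                               null_cache = null_cache)
    if (is.null(best) ||
        (need_e && m$evalue < best$evalue)) best <- m
  }
  if (is.null(best)) stop("Gibbs sampler found no motif")
  best$n_candidates <- n_candidates
  best
}

gibbs_width <- function(Y_sub, codes, bg, cfg, w) {
  N <- length(codes)
  q <- bg$q
  gamma <- cfg$site_prior
  # init: best window per entry under the best-scoring candidate word
  words <- sample_candidate_words(codes, w, min(50L, cfg$n_init_candidates))
  if (is.null(words) || nrow(words) == 0L) return(NULL)
  sc <- cpp_score_candidates(codes, words, q, cfg$both_strands)
  S0 <- log2(init_freqs_from_word(words[which.max(sc), ]) / q)
  assign_i <- rep(-1L, N); assign_s <- rep(0L, N)
  counts <- matrix(0, 4L, w)
  add_site <- function(e, i, str, sign) {
    v <- codes[[e]][i:(i + w - 1L)]
    if (any(v == 0L)) return(counts)
    if (str == 2L) v <- rev(5L - v)
    counts[cbind(v, seq_len(w))] <- counts[cbind(v, seq_len(w))] + sign
    counts
  }
  for (e in seq_len(N)) {
    scw <- cpp_score_windows(codes[[e]], S0, cfg$both_strands)
    if (nrow(scw) == 0L) next
    k <- arrayInd(which.max(scw), dim(scw))
    assign_i[e] <- k[1L]; assign_s[e] <- k[2L]
    counts <- add_site(e, k[1L], k[2L], +1)
  }
  best_T <- -Inf; best_assign <- NULL
  n_sweeps <- cfg$gibbs_burnin + cfg$gibbs_sweeps
  for (sw in seq_len(n_sweeps)) {
    for (e in seq_len(N)) {
      if (assign_i[e] > 0L)
        counts <- add_site(e, assign_i[e], assign_s[e], -1)
      ns <- sum(assign_i[-e] > 0L)
      fr <- sweep(counts + cfg$pseudo_total * q, 2L, ns + cfg$pseudo_total,
                  "/")
      S <- log2(fr / q)
      scw <- cpp_score_windows(codes[[e]], S, cfg$both_strands)
      if (nrow(scw) == 0L) { assign_i[e] <- -1L; assign_s[e] <- 0L; next }
      npos <- if (cfg$both_strands) 2L * nrow(scw) else nrow(scw)
      lw <- as.vector(scw) + log2(gamma / npos)
      lw <- c(log2(1 - gamma), lw)
      lw[is.infinite(lw) & lw < 0] <- -745  # numerical floor
      pr <- 2^(lw - max(lw))
      k <- sample.int(length(pr), 1L, prob = pr)
      if (k == 1L) {
        assign_i[e] <- -1L; assign_s[e] <- 0L
      } else {
        k <- k - 1L
        assign_i[e] <- ((k - 1L) %% nrow(scw)) + 1L
        assign_s[e] <- ((k - 1L) %/% nrow(scw)) + 1L
        counts <- add_site(e, assign_i[e], assign_s[e], +1)
      }
    }
    if (sw > cfg$gibbs_burnin) {
      on <- assign_i > 0L
      if (any(on)) {
        sites <- data.frame(entry_id = Y_sub$id[on],
                            start = assign_i[on] - 1L,
                            strand = c("+", "-")[assign_s[on]],
                            width = w, stringsAsFactors = FALSE)
        m <- build_motif_from_sites(Y_sub, sites, bg,
                                    pseudo_total = cfg$pseudo_total,
                                    name = sprintf("motif_w%d", w))
        T <- site_llr(m, Y_sub, bg)
        if (T > best_T) { best_T <- T; best_assign <- m }
      }
    }
  }
  if (!is.null(best_assign))
    best_assign <- refine_shift(best_assign, Y_sub, bg, cfg)
  best_assign
}

#' Shuffle-null motif E-value
#'
#' The significance statistic is T, the total log2 likelihood ratio of the
#' motif's provenance sites against the background.  The null distribution
#' of T comes from refitting a same-width motif (single EM start, capped
#' iterations) on `null_reps` dinucleotide-shuffled copies of `Y`; the
#' E-value is `n_candidates` times the empirical tail probability
#' Pr(T_null >= T), estimated with the (r+1)/(n+1) rule so it is always
#' positive.
#'
#' When a `null_cache` environment is supplied, the null sample is reused
#' across motifs of the same width, model and entry-set size bucket
#' (buckets of 10 entries, rounded up): under shuffling, sets of
#' near-identical size drawn from one background have near-identical null
#' statistics, and sharing the sample makes a whole Monte Carlo run pay
#' for each null distribution once.
#'
#' @param m an `ms_motif` with provenance sites inside `Y`.
#' @param Y the [seq_set()] the motif was fitted to.
#' @param bg a `bg_model`.
#' @param n_candidates number of candidate motifs the search considered
#'   (widths tried x starts per width).
#' @param null_reps shuffle replicates (must be >= 20).
#' @param rng_seed optional seed for the null stream.
#' @param cfg [finder_config()] supplying the capped-EM settings.
#' @param oops refit under the one-occurrence-per-sequence model.
#' @param null_cache optional environment memoising null samples.
#' @return a nonnegative E-value.
#' @export
motif_evalue <- function(m, Y, bg, n_candidates = 1L,
                         null_reps = 1249L, rng_seed = NA_integer_,
                         cfg = finder_config(), oops = FALSE,
                         null_cache = NULL) {
  if (null_reps < 20L)
    stop("null_reps below 20 makes the tail estimator too coarse")
  maybe_seed(rng_seed)
  t_obs <- site_llr(m, Y, bg)
  codes <- encode_set(Y)
  codes <- codes[vapply(codes, length, 0L) >= m$width]
  if (length(codes) == 0L) stop("no entry long enough for the motif width")
  tnull <- NULL
  lens <- vapply(codes, length, 0L)
  key <- sprintf("w%d_%s_n%d_L%d_r%d", m$width,
                 if (oops) "oops" else "zoops",
                 10L * ceiling(length(codes) / 10),
                 50L * ceiling(stats::median(lens) / 50),
                 as.integer(null_reps))
  if (!is.null(null_cache)) tnull <- null_cache[[key]]
  if (is.null(tnull)) {
    tnull <- cpp_null_sample(codes, m$width, bg$q, cfg$pseudo_total,
                             cfg$site_prior, as.integer(null_reps),
                             cfg$null_iters, cfg$both_strands, oops,
                             cfg$null_precands)
    if (!is.null(null_cache)) null_cache[[key]] <- tnull
  }
  r <- sum(tnull >= t_obs - 1e-12)
  n_candidates * (r + 1) / (null_reps + 1)
}

#' Dinucleotide-preserving shuffle of a sequence
#'
#' Altschul-Erikson shuffle: returns a uniformly sampled sequence with
#' exactly the same dinucleotide counts as the input.
#'
#' @param s a character string over A, C, G, T, N.
#' @return a shuffled string.
#' @export
dinuc_shuffle <- function(s) {
  decode_seq(cpp_dinuc_shuffle(encode_seq(toupper(s))))
}
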
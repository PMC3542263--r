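#' Log2-odds score matrix of a motif
#'
#' s(b, j) = log2(f(b, j) / q_b) against the order-0 background marginal.
#' Windows overlapping N score -Inf during scanning.
#'
#' @param m an `ms_motif` with strictly positive frequencies.
#' @param bg a `bg_model`.
#' @return 4 x w numeric matrix (rows A, C, G, T).
#' @export
pssm_scores <- function(m, bg) {
  if (any(colSums(m$freqs > 0) == 0))
    stop("motif has an all-zero column; refit with a positive pseudocount")
  S <- log2(m$freqs / bg$q)  # zero frequencies score -Inf
  rownames(S) <- c("A", "C", "G", "T")
  S
}

#' Exact null distribution of PSSM scores
#'
#' Integerizes the score matrix at resolution 1/`scale` and convolves the
#' per-column score distributions under the order-0 background marginals,
#' yielding the exact p-value `p(s) = Pr(S >= s)` for every attainable
#' integerized score.  Used to assign each scanned window an exact position
#' p-value.
#'
#' @param m an `ms_motif`.
#' @param bg a `bg_model` (order-0 marginal used; exact dynamic programming
#'   requires positional independence).
#' @param scale integerization resolution (>= 100).
#' @return list with `S_int` (integerized score matrix), `scale`, `min`,
#'   and `pval` (vector such that `pval[s - min + 1]` = Pr(S >= s)).
#' @export
position_pvalue_table <- function(m, bg, scale = 1000L) {
  stopifnot(scale >= 100L)
  if (any(m$freqs <= 0))
    stop("exact p-values require strictly positive frequencies; ",
         "refit with a positive pseudocount")
  S_int <- round(pssm_scores(m, bg) * scale)
  storage.mode(S_int) <- "integer"
  cv <- cpp_pssm_convolve(S_int, bg$q)
  pv <- rev(cumsum(rev(cv$probs)))
  pv <- pmin(pv, 1)
  lo <- as.integer(cv$lo)
  list(S_int = S_int, scale = as.integer(scale), min = lo,
       max = lo + length(pv) - 1L, pval = pv)
}

lookup_pvalue <- function(tab, s_int) {
  i <- s_int - tab$min + 1L
  i[i < 1L] <- 1L
  i[i > length(tab$pval)] <- length(tab$pval)
  tab$pval[i]
}

#' Scan a motif over a sequence set
#'
#' Per entry, the best-hit log2-odds score over all starts and strands is
#' converted to an exact position p-value, then to a sequence-level p-value
#' `1 - (1 - p)^n_pos` with `n_pos` the number of scanned windows (both
#' strands), and to a sequence E-value `seq_pvalue * N`.  An entry is
#' significant iff its sequence E-value is `<= sig_evalue`.  Ties among
#' equal best scores go to the leftmost position, forward strand first.
#' Entries shorter than the motif width are skipped (never significant).
#'
#' @param m an `ms_motif`.
#' @param Y a [seq_set()].
#' @param bg a `bg_model`.
#' @param sig_evalue significance threshold on the sequence E-value
#'   (default 10, the conventional scanner display threshold).
#' @param hit_pvalue_max instance-level gate: the best hit must also reach
#'   this position p-value (default 1e-4, the conventional hit-display
#'   threshold) for the entry to count as containing a match.  Without it
#'   an exactly calibrated sequence E-value of 10 would admit about ten
#'   random entries per scan whatever the motif.
#' @param scale p-value integerization resolution.
#' @param both_strands scan the reverse strand too.
#' @return list with `hits` (data frame: entry_id, start (0-based), strand,
#'   score, pos_pvalue, seq_pvalue, seq_evalue, significant) and
#'   `significant_ids` (character vector).
#' @export
scan_motif <- function(m, Y, bg, sig_evalue = 10, hit_pvalue_max = 1e-4,
                       scale = 1000L, both_strands = TRUE) {
  N <- n_entries(Y)
  tab <- position_pvalue_table(m, bg, scale)
  w <- m$width
  Sn <- tab$S_int
  storage.mode(Sn) <- "double"
  v_id <- character(N); v_start <- integer(N); v_str <- character(N)
  v_best <- numeric(N); v_p <- numeric(N); v_seqp <- numeric(N)
  keep <- logical(N)
  for (e in seq_len(N)) {
    codes <- encode_seq(Y$seq[e])
    L <- length(codes)
    if (L < w) next
    sc <- cpp_score_windows(codes, Sn, both_strands)
    if (nrow(sc) == 0L) next
    best <- max(sc)
    if (!is.finite(best)) next
    # leftmost position, forward strand preferred on ties
    fwd_hit <- which(sc[, 1L] == best)
    if (length(fwd_hit)) {
      i <- fwd_hit[1L]; str <- "+"
    } else {
      i <- which(sc[, 2L] == best)[1L]; str <- "-"
    }
    n_pos <- if (both_strands) 2L * nrow(sc) else nrow(sc)
    p <- lookup_pvalue(tab, as.integer(round(best)))
    seq_p <- -expm1(n_pos * log1p(-min(p, 1 - 1e-16)))
    seq_p <- min(max(seq_p, p), 1)
    keep[e] <- TRUE
    v_id[e] <- Y$id[e]; v_start[e] <- i - 1L; v_str[e] <- str
    v_best[e] <- best / tab$scale; v_p[e] <- p; v_seqp[e] <- seq_p
  }
  hits <- data.frame(entry_id = v_id[keep], start = v_start[keep],
                     strand = v_str[keep], score = v_best[keep],
                     pos_pvalue = v_p[keep], seq_pvalue = v_seqp[keep],
                     seq_evalue = v_seqp[keep] * N,
                     stringsAsFactors = FALSE)
  # the instance gate never demands more than an exact match of a fully
  # specific motif of this width: short motifs (e.g. a 6-mer cannot beat
  # p = 4^-6) get a width-limited relaxation, while wide but degenerate
  # motifs -- whose best window is weak for reasons other than width --
  # do not
  gate <- max(hit_pvalue_max, max(bg$q)^w)
  hits$significant <- hits$seq_evalue <= sig_evalue &
    hits$pos_pvalue <= gate
  list(hits = hits, significant_ids = hits$entry_id[hits$significant])
}

#' Export hits as a BED-like table
#'
#' Columns: entry, 1-based start, end (inclusive), strand, score, sequence
#' E-value.
#'
#' @param scan result of [scan_motif()].
#' @param width motif width used in the scan.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @keywords internal
write_hits_tsv <- function(scan, width, path) {
  h <- scan$hits
  out <- data.frame(entry = h$entry_id, start = h$start + 1L,
                    end = h$start + width, strand = h$strand,
                    score = sprintf("%.4f", h$score),
                    seq_evalue = sprintf("%.6g", h$seq_evalue))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
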
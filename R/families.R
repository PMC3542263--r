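#' Group retained subsets into motif families
#'
#' Convenience assembly: pairs the family ids from [cut_tree()] with the
#' retained subsets.
#'
#' @param subsets retained `related_subset` list (tree leaves, same order
#'   as the distance matrix rows).
#' @param fam integer family assignment from [cut_tree()].
#' @return list of `motif_family` objects: `family_id`, `members` (the
#'   subsets), `entry_freq`.
#' @export
#' @keywords internal
make_families <- function(subsets, fam) {
  lapply(sort(unique(fam)), function(k) {
    F <- structure(list(family_id = k, members = subsets[fam == k]),
                   class = "motif_family")
    F$entry_freq <- entry_frequencies(F)
    F
  })
}

#' Entry re-occurrence frequencies within a motif family
#'
#' For each entry id, the fraction of the family's related subsets that
#' contain it.
#'
#' @param F a `motif_family` (list with `members`, a list of
#'   `related_subset`), or a plain list of `related_subset`.
#' @return named numeric vector in (0, 1].
#' @export
entry_frequencies <- function(F) {
  members <- if (inherits(F, "motif_family")) F$members else F
  if (length(members) == 0L) stop("empty motif family")
  tab <- table(unlist(lapply(members, function(rs) unique(rs$members))))
  freq <- as.numeric(tab) / length(members)
  setNames(freq, names(tab))
}

#' Condense a motif family into a familial profile
#'
#' Entries re-occurring in the family with frequency at or above
#' `fp_threshold` are collected and a motif is fitted to them under the
#' one-occurrence-per-sequence (OOPS) model — the ZOOPS machinery with the
#' site prior pinned at 1 and the no-site branch removed — then assigned a
#' shuffle-null E-value.
#'
#' @param F a `motif_family`.
#' @param Y the full [seq_set()].
#' @param bg a `bg_model`.
#' @param fp_threshold re-occurrence frequency threshold in [0, 1].
#' @param cfg a [finder_config()]; widths default to the family's motif
#'   width (single width).
#' @return object of class `familial_profile`: `family_id`, `fp_threshold`,
#'   `contributing_entries`, `motif` (or NULL), `evalue`, `valid`.
#' @export
familial_profile <- function(F, Y, bg, fp_threshold = 1.0,
                             cfg = NULL, null_cache = NULL) {
  stopifnot(fp_threshold >= 0, fp_threshold <= 1)
  freq <- entry_frequencies(F)
  contrib <- sort(names(freq)[freq >= fp_threshold])
  if (is.null(cfg)) {
    w <- stats::median(vapply(F$members, function(rs) rs$motif$width, 0))
    cfg <- finder_config(wmin = as.integer(w), wmax = as.integer(w))
  }
  out <- structure(list(family_id = F$family_id,
                        fp_threshold = fp_threshold,
                        contributing_entries = contrib,
                        motif = NULL, evalue = NA_real_, valid = FALSE),
                   class = "familial_profile")
  if (length(contrib) < 2L) {
    message("familial profile for family ", F$family_id, " at threshold ",
            fp_threshold, ": fewer than 2 contributing entries; invalid")
    return(out)
  }
  Y_sub <- subset_by_id(Y, contrib)
  keep <- nchar(Y_sub$seq) >= cfg$wmin
  if (sum(keep) < 2L) return(out)
  Y_sub <- seq_set(Y_sub$seq[keep], Y_sub$id[keep])
  codes <- encode_set(Y_sub)
  # warm-start the OOPS refit from the family's own best motif so the
  # profile condenses the family rather than rediscovering from scratch
  seed_inits <- list()
  cand <- Filter(function(rs) rs$motif$width == cfg$wmin, F$members)
  if (length(cand)) {
    evs <- vapply(cand, function(rs)
      if (is.na(rs$motif$evalue)) Inf else rs$motif$evalue, 0)
    seed_inits <- list(cand[[which.min(evs)]]$motif$freqs)
  }
  m <- run_em_width(Y_sub, codes, bg, cfg, cfg$wmin, oops = TRUE,
                    extra_inits = seed_inits)
  if (is.null(m)) return(out)
  m$name <- sprintf("FP%d_t%.2f", F$family_id, fp_threshold)
  m$evalue <- motif_evalue(m, Y_sub, bg, n_candidates = cfg$n_starts,
                           null_reps = cfg$null_reps, cfg = cfg,
                           oops = TRUE, null_cache = null_cache)
  out$motif <- m
  out$evalue <- m$evalue
  out$valid <- TRUE
  out
}

#' Select the familial-profile frequency threshold by E-value
#'
#' Builds a profile at each grid value and returns the one with the
#' smallest E-value; ties go to the larger (more conservative) threshold.
#'
#' @param F a `motif_family`.
#' @param Y the full [seq_set()].
#' @param bg a `bg_model`.
#' @param grid candidate thresholds in [0, 1].
#' @param cfg optional [finder_config()].
#' @return list with `threshold`, `profile`, and `grid_evalues`.
#' @export
choose_fp_threshold <- function(F, Y, bg, grid = seq(0, 1, by = 0.1),
                                cfg = NULL, null_cache = NULL) {
  stopifnot(length(grid) >= 1L)
  fps <- lapply(grid, function(t)
    familial_profile(F, Y, bg, t, cfg, null_cache = null_cache))
  ev <- vapply(fps, function(fp) if (fp$valid) fp$evalue else Inf, 0)
  if (all(!is.finite(ev))) stop("no grid threshold produced a valid profile")
  best <- max(which(ev == min(ev)))  # ties -> larger threshold
  list(threshold = grid[best], profile = fps[[best]],
       grid_evalues = setNames(ev, grid))
}

#' MotifMap: familial-profile instances across all entries
#'
#' Scans each valid familial profile over the whole input set and records,
#' for each significant entry, the best-hit span (1-based inclusive) and
#' strand.  Rows are all entries of `Y`, columns are profiles;
#' non-significant cells stay empty.
#'
#' @param Y the full [seq_set()].
#' @param fps list of `familial_profile` objects.
#' @param bg a `bg_model`.
#' @param sig_evalue scanner significance threshold (default 10).
#' @param all_hits record every window whose position p-value beats the
#'   best-hit p-value threshold instead of only the best hit (off by
#'   default; the condensed map stores one instance per entry).
#' @return object of class `motif_map`: list with `entries`, `profiles`,
#'   and `cells` (list-matrix of data frames with start, end, strand).
#' @export
motif_map <- function(Y, fps, bg, sig_evalue = 10, all_hits = FALSE) {
  fps <- fps[vapply(fps, function(fp) isTRUE(fp$valid), TRUE)]
  pnames <- vapply(fps, function(fp) fp$motif$name, "")
  cells <- matrix(vector("list", n_entries(Y) * length(fps)),
                  nrow = n_entries(Y), ncol = length(fps),
                  dimnames = list(Y$id, pnames))
  for (k in seq_along(fps)) {
    m <- fps[[k]]$motif
    sc <- scan_motif(m, Y, bg, sig_evalue)
    h <- sc$hits[sc$hits$significant, , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      span <- data.frame(start = h$start[r] + 1L,
                         end = h$start[r] + m$width,
                         strand = h$strand[r], stringsAsFactors = FALSE)
      cells[[h$entry_id[r], k]] <- span
    }
    if (all_hits && nrow(h)) {
      tab <- position_pvalue_table(m, bg)
      for (r in seq_len(nrow(h))) {
        e <- h$entry_id[r]
        codes <- encode_seq(Y$seq[match(e, Y$id)])
        scw <- cpp_score_windows(codes, tab$S_int, TRUE)
        best <- max(scw)
        hit_idx <- which(scw >= best - 1e-9, arr.ind = TRUE)
        spans <- data.frame(start = hit_idx[, 1L],
                            end = hit_idx[, 1L] + m$width - 1L,
                            strand = c("+", "-")[hit_idx[, 2L]],
                            stringsAsFactors = FALSE)
        cells[[e, k]] <- spans[order(spans$start, spans$strand), ]
      }
    }
  }
  structure(list(entries = Y$id, profiles = pnames, cells = cells),
            class = "motif_map")
}

#' Export a MotifMap as TSV
#'
#' Cells are rendered `start..end(strand)` (semicolon-separated when the
#' map was built in all-hits mode) or `.` when empty.
#'
#' @param map a `motif_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
#' @keywords internal
write_motif_map_tsv <- function(map, path) {
  fmt_cell <- function(cell) {
    if (is.null(cell) || nrow(cell) == 0L) return(".")
    paste(sprintf("%d..%d(%s)", cell$start, cell$end, cell$strand),
          collapse = ";")
  }
  out <- matrix("", nrow = length(map$entries), ncol = length(map$profiles),
                dimnames = list(map$entries, map$profiles))
  for (i in seq_along(map$entries))
    for (j in seq_along(map$profiles))
      out[i, j] <- fmt_cell(map$cells[[i, j]])
  df <- data.frame(entry = map$entries, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
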
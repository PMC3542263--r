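#' Sample random seed subsets
#'
#' Draws `n` subsets of `size` entries uniformly without replacement from
#' the input set (size is capped at N).
#'
#' @param Y a [seq_set()] with at least 2 entries.
#' @param n number of seed subsets.
#' @param size entries per seed; default `max(8, ceiling(0.10 * N))`.
#' @param rng_seed optional integer seed.
#' @return list of character vectors of entry ids.
#' @export
sample_seeds <- function(Y, n, size = NULL, rng_seed = NA_integer_) {
  N <- n_entries(Y)
  if (N < 2L) stop("need at least 2 entries to sample seeds")
  if (is.null(size)) size <- max(8L, ceiling(0.10 * N))
  size <- min(as.integer(size), N)
  if (size < 2L) stop("seed size must be at least 2")
  maybe_seed(rng_seed)
  lapply(seq_len(n), function(i) Y$id[sort(sample.int(N, size))])
}

subset_by_id <- function(Y, ids) {
  keep <- match(ids, Y$id)
  if (anyNA(keep)) stop("unknown entry id in subset")
  seq_set(Y$seq[keep], Y$id[keep])
}

new_related_subset <- function(seed_id, scheme, members, motif, iterations,
                               converged, evalue_max = 0.001) {
  sig <- !is.null(motif) && !is.na(motif$evalue) && motif$evalue <= evalue_max
  structure(list(seed_id = seed_id, scheme = scheme, members = members,
                 motif = motif, iterations = iterations,
                 converged = converged, significant = sig),
            class = "related_subset")
}

finder_fun <- function(finder = c("em", "gibbs")) {
  switch(match.arg(finder), em = zoops_em, gibbs = zoops_gibbs)
}

# E-value helper sharing one null-sample cache across all seeds of a run
evalue_cached <- function(m, Yset, bg, cfg, cache = NULL, oops = FALSE) {
  n_cand <- if (!is.null(m$n_candidates)) m$n_candidates
            else (cfg$wmax - cfg$wmin + 1L) * cfg$n_starts
  motif_evalue(m, Yset, bg, n_candidates = n_cand,
               null_reps = cfg$null_reps, cfg = cfg, oops = oops,
               null_cache = cache)
}

#' Related-subset scheme 1: subset-only ZOOPS search
#'
#' Runs the finder on the seed subset alone; the related subset is the set
#' of entries whose subsequences were included in the construction of the
#' motif (so members never leave the seed).
#'
#' @param ids entry ids of the seed subset (>= 2).
#' @param Y full [seq_set()].
#' @param bg `bg_model`.
#' @param cfg [finder_config()].
#' @param evalue_max motif E-value filter recorded on the subset flag.
#' @param seed_id integer tag.
#' @param finder `"em"` or `"gibbs"`.
#' @return a `related_subset`.
#' @export
scheme_zoops_mc <- function(ids, Y, bg, cfg = finder_config(),
                            evalue_max = 0.001, seed_id = 1L,
                            finder = "em", cache = NULL) {
  stopifnot(length(ids) >= 2L)
  S <- subset_by_id(Y, ids)
  m <- tryCatch(finder_fun(finder)(S, bg, cfg, null_cache = cache),
                error = function(e) NULL)
  members <- if (is.null(m)) character() else unique(m$sites$entry_id)
  new_related_subset(seed_id, "zoops_mc", members, m, 1L,
                     converged = !is.null(m), evalue_max = evalue_max)
}

#' Related-subset scheme 2: single whole-set scan
#'
#' Finds a preliminary motif on the seed, scans it over the whole input
#' set, and takes all significantly matching entries as the related
#' subset; the reported motif is rebuilt from the best hits inside the
#' members so provenance always lies within the subset.
#'
#' @inheritParams scheme_zoops_mc
#' @param sig_evalue scanner significance threshold (default 10).
#' @return a `related_subset`.
#' @export
scheme_single_mast <- function(ids, Y, bg, cfg = finder_config(),
                               sig_evalue = 10, evalue_max = 0.001,
                               seed_id = 1L, finder = "em", cache = NULL) {
  stopifnot(length(ids) >= 2L)
  S <- subset_by_id(Y, ids)
  m0 <- tryCatch(finder_fun(finder)(S, bg, cfg, assign_evalue = FALSE),
                 error = function(e) NULL)
  if (is.null(m0))
    return(new_related_subset(seed_id, "single_mast", character(), NULL, 1L,
                              FALSE, evalue_max))
  sc <- scan_motif(m0, Y, bg, sig_evalue, both_strands = cfg$both_strands)
  members <- sort(sc$significant_ids)
  if (length(members) < 2L)
    return(new_related_subset(seed_id, "single_mast", members, NULL, 1L,
                              FALSE, evalue_max))
  m <- rebuild_from_hits(sc, members, Y, bg, cfg, m0$width)
  m$evalue <- evalue_cached(m, subset_by_id(Y, members), bg, cfg, cache)
  new_related_subset(seed_id, "single_mast", members, m, 1L, TRUE,
                     evalue_max)
}

rebuild_from_hits <- function(sc, members, Y, bg, cfg, width) {
  h <- sc$hits[sc$hits$entry_id %in% members, , drop = FALSE]
  sites <- data.frame(entry_id = h$entry_id, start = h$start,
                      strand = h$strand, width = width,
                      stringsAsFactors = FALSE)
  build_motif_from_sites(Y, sites, bg, pseudo_total = cfg$pseudo_total,
                         name = sprintf("motif_w%d", width))
}

#' Related-subset scheme 3: iterative fixed-point search
#'
#' Alternates motif fitting on the current entry set with a whole-set scan
#' until the scan returns exactly the current set (a fixed point: the motif
#' has instances in, and only in, its own subset).  Stops unconverged when
#' the set shrinks below 2 entries, when a previously visited set recurs
#' (cycle; the visited state with the smallest motif E-value is returned),
#' or at `max_rounds`.
#'
#' @inheritParams scheme_single_mast
#' @param max_rounds iteration cap (default 20).
#' @return a `related_subset` with `iterations` and `converged` recorded.
#' @export
scheme_iterative <- function(ids, Y, bg, cfg = finder_config(),
                             sig_evalue = 10, evalue_max = 0.001,
                             max_rounds = 20L, seed_id = 1L,
                             finder = "em", cache = NULL) {
  stopifnot(length(ids) >= 2L, max_rounds >= 1L)
  current <- sort(ids)
  seen <- list()
  states <- list()  # motifs of visited states, for cycle resolution
  run_finder <- finder_fun(finder)
  for (round in seq_len(max_rounds)) {
    key <- paste(current, collapse = "\r")
    if (!is.null(seen[[key]])) {
      # cycle: return the visited state with the smallest motif E-value
      # (E-values are deferred during iteration, so assign them now)
      for (si in seq_along(states)) {
        if (!is.null(states[[si]]$motif) &&
            is.na(states[[si]]$motif$evalue))
          states[[si]]$motif$evalue <- evalue_cached(
            states[[si]]$motif, subset_by_id(Y, states[[si]]$members),
            bg, cfg, cache)
      }
      evs <- vapply(states, function(s)
        if (is.null(s$motif)) Inf else s$motif$evalue, 0)
      bi <- which.min(evs)
      return(new_related_subset(seed_id, "iterative",
                                states[[bi]]$members, states[[bi]]$motif,
                                round, FALSE, evalue_max))
    }
    seen[[key]] <- TRUE
    S <- subset_by_id(Y, current)
    m <- tryCatch(run_finder(S, bg, cfg, assign_evalue = FALSE),
                  error = function(e) NULL)
    if (is.null(m))
      return(new_related_subset(seed_id, "iterative", current, NULL, round,
                                FALSE, evalue_max))
    states[[length(states) + 1L]] <- list(members = current, motif = m)
    sc <- scan_motif(m, Y, bg, sig_evalue, both_strands = cfg$both_strands)
    nxt <- sort(sc$significant_ids)
    if (identical(nxt, current)) {
      # fixed point: the motif was fitted on `current`, so its provenance
      # sites already lie inside the members, and this very scan certifies
      # that its significant set equals the members exactly
      m$evalue <- evalue_cached(m, S, bg, cfg, cache)
      return(new_related_subset(seed_id, "iterative", current, m, round,
                                TRUE, evalue_max))
    }
    if (length(nxt) < 2L)
      return(new_related_subset(seed_id, "iterative", nxt, m, round, FALSE,
                                evalue_max))
    current <- nxt
  }
  last <- states[[length(states)]]
  new_related_subset(seed_id, "iterative", last$members, last$motif,
                     max_rounds, FALSE, evalue_max)
}

#' Run the full Monte Carlo stage
#'
#' Samples `n` seed subsets and refines each with the chosen scheme under
#' an independent per-seed RNG substream, so results are reproducible and
#' order-stable.
#'
#' @param Y a [seq_set()].
#' @param bg a `bg_model`.
#' @param cfg a [finder_config()].
#' @param scheme `"iterative"`, `"single_mast"` or `"zoops_mc"`.
#' @param n number of seeds; defaults to the per-scheme convention
#'   500 (zoops_mc), 200 (single_mast), 50 (iterative).
#' @param size seed size; default `max(8, ceiling(0.10 * N))`.
#' @param rng_seed master seed for the whole stage.
#' @param sig_evalue scanner threshold for schemes 2 and 3.
#' @param evalue_max motif E-value filter recorded on the significance flag.
#' @param max_rounds iteration cap for the iterative scheme.
#' @param finder `"em"` or `"gibbs"`.
#' @param verbose log one line per seed.
#' @return list of `related_subset` objects, one per seed.
#' @export
run_mc <- function(Y, bg, cfg = finder_config(),
                   scheme = c("iterative", "single_mast", "zoops_mc"),
                   n = NULL, size = NULL, rng_seed = 1L, sig_evalue = 10,
                   evalue_max = 0.001, max_rounds = 20L, finder = "em",
                   verbose = FALSE, null_cache = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(n)) n <- default_n_seeds(scheme)
  seeds <- sample_seeds(Y, n, size, rng_seed = rng_seed)
  cfg$rng_seed <- NA_integer_  # per-seed substreams govern the finder RNG
  cache <- if (is.null(null_cache)) new.env(parent = emptyenv())
           else null_cache
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(rng_seed, i))
    out[[i]] <- switch(scheme,
      zoops_mc = scheme_zoops_mc(seeds[[i]], Y, bg, cfg, evalue_max,
                                 seed_id = i, finder = finder,
                                 cache = cache),
      single_mast = scheme_single_mast(seeds[[i]], Y, bg, cfg, sig_evalue,
                                       evalue_max, seed_id = i,
                                       finder = finder, cache = cache),
      iterative = scheme_iterative(seeds[[i]], Y, bg, cfg, sig_evalue,
                                   evalue_max, max_rounds, seed_id = i,
                                   finder = finder, cache = cache))
    if (verbose) {
      rs <- out[[i]]
      message(sprintf(
        "seed %d [%s]: %d members, E = %s, converged = %s", i, scheme,
        length(rs$members),
        if (is.null(rs$motif)) "NA" else format(rs$motif$evalue, digits = 3),
        rs$converged))
    }
  }
  out
}

# per-scheme seed-count conventions: many cheap subset-only searches, fewer
# single-scan searches, few (but expensive) iterative searches
default_n_seeds <- function(scheme) {
  switch(scheme, zoops_mc = 500L, single_mast = 200L, iterative = 50L)
}

# deterministic per-seed substream seed, kept below 2^31
substream_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 16807) %% 2147483647)
}

#' Serialize related subsets as JSON lines
#'
#' One JSON object per line: seed_id, scheme, members, iterations,
#' converged, significant, motif E-value and name.
#'
#' @param subsets list of `related_subset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @keywords internal
write_subsets_jsonl <- function(subsets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rs in subsets) {
    rec <- list(seed_id = rs$seed_id, scheme = rs$scheme,
                members = rs$members, iterations = rs$iterations,
                converged = rs$converged, significant = rs$significant,
                evalue = if (is.null(rs$motif)) NA else rs$motif$evalue,
                motif = if (is.null(rs$motif)) NA else rs$motif$name)
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                             digits = NA, na = "null")),
               con)
  }
  invisible(path)
}
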
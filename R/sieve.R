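#' Monte Carlo subset-sampling motif discovery
#'
#' The package's top-level fitting function.  Runs the four-stage pipeline
#' on a sequence set: (1) sample `n_seeds` random subsets and refine each
#' into a related subset with the chosen scheme; (2) drop subsets whose
#' motif E-value exceeds `evalue_max` and organise the survivors into a
#' UPGMA tree under the ALLR motif distance; (3) cut the tree into motif
#' families at `cluster_frac` of the maximum dissimilarity; (4) condense
#' each family into a familial profile at `fp_threshold` (or by E-value
#' selection over a grid when `"auto"`) and map every profile back onto the
#' input as a MotifMap.
#'
#' @param Y a [seq_set()] (or a FASTA path).
#' @param scheme related-subset protocol: `"iterative"`, `"single_mast"`
#'   or `"zoops_mc"`.
#' @param cfg a [finder_config()].
#' @param bg optional `bg_model`; estimated from `Y` at `bg_order` when
#'   missing.
#' @param bg_order background order used when estimating (default 3).
#' @param n_seeds number of seed subsets (per-scheme default 500/200/50).
#' @param seed_size entries per seed (default `max(8, ceiling(0.10 N))`).
#' @param rng_seed master seed; everything downstream is reproducible from
#'   it.
#' @param sig_evalue scanner significance threshold (default 10).
#' @param evalue_max motif E-value filter (default 0.001).
#' @param top_k retain at most this many subsets for the tree (default 200).
#' @param cluster_frac clustering threshold as a fraction of the maximum
#'   dissimilarity (default 0.05).
#' @param fp_threshold familial-profile frequency threshold in [0, 1], or
#'   `"auto"` for E-value selection over `fp_grid`.
#' @param fp_grid grid for `"auto"` selection.
#' @param max_rounds iteration cap for the iterative scheme.
#' @param finder `"em"` or `"gibbs"`.
#' @param verbose per-seed progress messages.
#' @param null_cache optional environment memoising shuffle-null samples
#'   (see [motif_evalue()]); pass one cache across several runs on data
#'   from the same generating conditions to amortise the null cost.
#' @return object of class `motif_sieve`: list with `subsets`, `retained`,
#'   `dist`, `tree`, `families`, `profiles`, `map`, `bg`, `config` and
#'   `call`.  `NULL` tree/map components indicate nothing survived the
#'   filter (an empty but valid result).
#' @export
motif_sieve <- function(Y, scheme = c("iterative", "single_mast",
                                      "zoops_mc"),
                        cfg = finder_config(), bg = NULL, bg_order = 3L,
                        n_seeds = NULL, seed_size = NULL, rng_seed = 1L,
                        sig_evalue = 10, evalue_max = 0.001, top_k = 200L,
                        cluster_frac = 0.05, fp_threshold = 1.0,
                        fp_grid = seq(0, 1, by = 0.1), max_rounds = 20L,
                        finder = "em", verbose = FALSE, null_cache = NULL) {
  scheme <- match.arg(scheme)
  if (is.character(Y) && length(Y) == 1L) Y <- read_fasta(Y)
  stopifnot(inherits(Y, "seq_set"))
  if (is.null(bg)) bg <- build_background(Y, order = bg_order)
  config <- list(scheme = scheme, finder = finder, cfg = cfg,
                 bg_order = bg$order, n_seeds = n_seeds,
                 seed_size = seed_size, rng_seed = rng_seed,
                 sig_evalue = sig_evalue, evalue_max = evalue_max,
                 top_k = top_k, cluster_frac = cluster_frac,
                 fp_threshold = fp_threshold)
  if (is.null(null_cache)) null_cache <- new.env(parent = emptyenv())
  subsets <- run_mc(Y, bg, cfg, scheme, n = n_seeds, size = seed_size,
                    rng_seed = rng_seed, sig_evalue = sig_evalue,
                    evalue_max = evalue_max, max_rounds = max_rounds,
                    finder = finder, verbose = verbose,
                    null_cache = null_cache)
  out <- structure(list(Y = Y, bg = bg, subsets = subsets,
                        retained = list(), dist = NULL, tree = NULL,
                        families = list(), profiles = list(), map = NULL,
                        config = config, call = match.call()),
                   class = "motif_sieve")
  retained <- withCallingHandlers(
    filter_subsets(subsets, evalue_max, top_k),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(retained) == 0L) {
    warning("no significant related subset; returning an empty fit")
    return(out)
  }
  out$retained <- retained
  D <- motif_distance_matrix(retained, bg$q, cfg$pseudo_total)
  out$dist <- D
  out$tree <- upgma_tree(D)
  fam <- cut_tree(out$tree, cluster_frac)
  out$family_of <- fam
  out$families <- make_families(retained, fam)
  set.seed(substream_seed(rng_seed, 0L))  # profile stage substream
  fpcfg <- NULL
  out$profiles <- lapply(out$families, function(F) {
    if (identical(fp_threshold, "auto")) {
      choose_fp_threshold(F, Y, bg, fp_grid, null_cache = null_cache)$profile
    } else {
      familial_profile(F, Y, bg, fp_threshold, null_cache = null_cache)
    }
  })
  # the MotifMap compares entries to *significant* profiles only
  mappable <- vapply(out$profiles, function(fp)
    isTRUE(fp$valid) && fp$evalue <= evalue_max, TRUE)
  if (any(mappable))
    out$map <- motif_map(Y, out$profiles[mappable], bg, sig_evalue)
  out
}

#' @export
print.motif_sieve <- function(x, ...) {
  cat("Monte Carlo motif discovery (", x$config$scheme, " scheme, ",
      x$config$finder, " finder)\n", sep = "")
  cat("  input: ", n_entries(x$Y), " entries; seeds: ",
      length(x$subsets), "; retained subsets: ", length(x$retained),
      "\n", sep = "")
  if (length(x$families)) {
    sizes <- vapply(x$families, function(F) length(F$members), 0L)
    cat("  families: ", length(x$families), " (sizes ",
        paste(sizes, collapse = ", "), ")\n", sep = "")
    for (fp in x$profiles) {
      if (isTRUE(fp$valid))
        cat(sprintf("  FP family %d: %s  E = %.3g  (%d entries)\n",
                    fp$family_id, consensus(fp$motif), fp$evalue,
                    length(fp$contributing_entries)))
    }
  } else cat("  no significant motif family\n")
  invisible(x)
}

#' @export
summary.motif_sieve <- function(object, ...) {
  x <- object
  conv <- vapply(x$subsets, function(rs) isTRUE(rs$converged), TRUE)
  sig <- vapply(x$subsets, function(rs) isTRUE(rs$significant), TRUE)
  fam_sizes <- vapply(x$families, function(F) length(F$members), 0L)
  s <- list(n_entries = n_entries(x$Y), n_seeds = length(x$subsets),
            n_converged = sum(conv), n_significant = sum(sig),
            n_retained = length(x$retained),
            n_families = length(x$families), family_sizes = fam_sizes,
            largest_family_fraction =
              if (length(fam_sizes) && length(x$retained))
                max(fam_sizes) / length(x$retained) else NA_real_,
            profiles = lapply(x$profiles, function(fp)
              if (isTRUE(fp$valid))
                list(family = fp$family_id, consensus = consensus(fp$motif),
                     evalue = fp$evalue,
                     n_entries = length(fp$contributing_entries))
              else NULL))
  class(s) <- "summary.motif_sieve"
  s
}

#' @export
print.summary.motif_sieve <- function(x, ...) {
  cat("entries:", x$n_entries, " seeds:", x$n_seeds,
      " converged:", x$n_converged, " significant:", x$n_significant, "\n")
  cat("retained:", x$n_retained, " families:", x$n_families, "\n")
  if (!is.na(x$largest_family_fraction))
    cat("largest family fraction of retained subsets:",
        round(x$largest_family_fraction, 3), "\n")
  for (p in x$profiles)
    if (!is.null(p))
      cat(sprintf("FP family %d: %s (E = %.3g, %d entries)\n",
                  p$family, p$consensus, p$evalue, p$n_entries))
  invisible(x)
}

#' @export
plot.motif_sieve <- function(x, ...) {
  if (is.null(x$tree) || length(x$tree$labels) < 2L) {
    fam_sizes <- vapply(x$families, function(F) length(F$members), 0L)
    if (length(fam_sizes))
      barplot(fam_sizes, names.arg = seq_along(fam_sizes),
              xlab = "family", ylab = "related subsets", ...)
    else plot(0, 0, type = "n", axes = FALSE, xlab = "", ylab = "",
              main = "no retained subsets")
    return(invisible(x))
  }
  phy <- ape::as.phylo(tree_as_hclust(x$tree))
  plot(phy, ...)
  invisible(x)
}

#' Map the fitted familial profiles onto new sequences
#'
#' @param object a fitted `motif_sieve`.
#' @param newdata a [seq_set()] or FASTA path (defaults to the training
#'   set).
#' @param sig_evalue scanner threshold.
#' @param ... unused.
#' @return a `motif_map` over `newdata`.
#' @export
predict.motif_sieve <- function(object, newdata = NULL, sig_evalue = NULL,
                                ...) {
  if (is.null(newdata)) newdata <- object$Y
  if (is.character(newdata)) newdata <- read_fasta(newdata)
  if (is.null(sig_evalue)) sig_evalue <- object$config$sig_evalue
  valid <- vapply(object$profiles, function(fp)
    isTRUE(fp$valid) && fp$evalue <= object$config$evalue_max, TRUE)
  if (!any(valid)) stop("fit has no significant familial profile")
  motif_map(newdata, object$profiles[valid], object$bg, sig_evalue)
}

#' Write the run artifacts of a fit to a directory
#'
#' Writes related-subsets JSON-lines, all subset motifs and familial
#' profiles in MEME minimal format, the distance matrix (TSV), the Newick
#' tree, a families JSON, the MotifMap TSV, the background model, and a
#' run log recording the configuration and RNG seed.  Re-running the same
#' configuration and seed reproduces every artifact byte for byte.
#'
#' @param fit a `motif_sieve`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_subsets_jsonl(fit$subsets, fp("related_subsets.jsonl"))
  ms <- lapply(fit$retained, function(rs) {
    m <- rs$motif
    m$name <- paste0("seed", rs$seed_id)
    m
  })
  write_meme_minimal(ms, fit$bg, fp("subset_motifs.meme"))
  write_background(fit$bg, fp("background.txt"))
  if (!is.null(fit$dist))
    write.table(round(fit$dist, 10), fp("distances.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
  if (!is.null(fit$tree)) tree_newick(fit$tree, fp("tree.nwk"))
  fam_json <- lapply(fit$families, function(F) list(
    family_id = F$family_id,
    subsets = vapply(F$members, function(rs) rs$seed_id, 0L),
    entry_freq = as.list(F$entry_freq)))
  writeLines(as.character(jsonlite::toJSON(fam_json, auto_unbox = TRUE,
                                           digits = NA)),
             fp("families.json"))
  valid <- vapply(fit$profiles, function(p) isTRUE(p$valid), TRUE)
  if (any(valid)) {
    write_meme_minimal(lapply(fit$profiles[valid], `[[`, "motif"), fit$bg,
                       fp("familial_profiles.meme"))
    hit_rows <- lapply(fit$profiles[valid], function(p) {
      sc <- scan_motif(p$motif, fit$Y, fit$bg, fit$config$sig_evalue)
      h <- sc$hits[sc$hits$significant, , drop = FALSE]
      if (nrow(h) == 0L) return(NULL)
      data.frame(profile = p$motif$name, entry = h$entry_id,
                 start = h$start + 1L, end = h$start + p$motif$width,
                 strand = h$strand, score = sprintf("%.4f", h$score),
                 seq_evalue = sprintf("%.6g", h$seq_evalue),
                 stringsAsFactors = FALSE)
    })
    hit_rows <- hit_rows[!vapply(hit_rows, is.null, TRUE)]
    if (length(hit_rows))
      write.table(do.call(rbind, hit_rows), fp("profile_hits.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$map)) write_motif_map_tsv(fit$map, fp("motif_map.tsv"))
  cfgdump <- fit$config
  cfgdump$cfg <- unclass(cfgdump$cfg)
  log <- c(sprintf("rng_seed: %s", fit$config$rng_seed),
           sprintf("config: %s",
                   as.character(jsonlite::toJSON(cfgdump, auto_unbox = TRUE,
                                                 digits = NA,
                                                 na = "null"))),
           sprintf("n_seeds: %d", length(fit$subsets)),
           sprintf("n_retained: %d", length(fit$retained)),
           sprintf("n_families: %d", length(fit$families)),
           sprintf("n_valid_profiles: %d", sum(valid)))
  writeLines(log, fp("run_log.txt"))
  invisible(dir)
}
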
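#' Motif site
#'
#' A site ties a motif column block to a concrete subsequence: an entry id, a
#' 0-based start offset, a strand and a width.  Reverse-strand sites
#' contribute the reverse complement of the spanned subsequence when a motif
#' is built.
#'
#' @param entry_id id of a sequence entry.
#' @param start 0-based offset within that entry.
#' @param strand `"+"` or `"-"`.
#' @param width site width (>= 1).
#' @return a one-row data frame; collections of sites are data frames with
#'   these four columns.
#' @export
site <- function(entry_id, start, strand = "+", width) {
  stopifnot(width >= 1L, all(strand %in% c("+", "-")), all(start >= 0L))
  data.frame(entry_id = as.character(entry_id), start = as.integer(start),
             strand = strand, width = as.integer(width),
             stringsAsFactors = FALSE)
}

#' Construct a motif object
#'
#' A motif is a 4 x w count matrix plus a pseudocount-smoothed frequency
#' matrix, a site weight (`nsites`), a significance E-value and optional
#' provenance sites.
#'
#' @param counts 4 x w nonnegative matrix (rows A, C, G, T).
#' @param freqs 4 x w column-stochastic matrix; computed from `counts` when
#'   missing.
#' @param nsites total site weight; defaults to the count column sum.
#' @param evalue motif significance E-value (may be `NA` until assigned).
#' @param sites data frame of provenance [site()]s, or `NULL`.
#' @param name text label.
#' @param bg_q order-0 background marginal used for smoothing.
#' @param pseudo_total total Dirichlet mass added per column when smoothing.
#' @return object of class `ms_motif`.
#' @export
new_motif <- function(counts, freqs = NULL, nsites = NULL, evalue = NA_real_,
                      sites = NULL, name = "motif", bg_q = rep(0.25, 4),
                      pseudo_total = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)")
  if (any(counts < 0)) stop("counts must be nonnegative")
  w <- ncol(counts)
  if (w < 1L) stop("width must be >= 1")
  if (is.null(nsites)) nsites <- sum(counts[, 1L])
  if (is.null(freqs)) {
    freqs <- sweep(counts + pseudo_total * bg_q, 2L,
                   colSums(counts) + pseudo_total, "/")
  }
  rownames(counts) <- rownames(freqs) <- c("A", "C", "G", "T")
  cs <- colSums(freqs)
  if (any(abs(cs - 1) > 1e-9))
    stop("freqs columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  structure(list(width = w, counts = counts, freqs = freqs,
                 nsites = nsites, evalue = evalue, sites = sites,
                 name = name),
            class = "ms_motif")
}

#' @export
print.ms_motif <- function(x, ...) {
  cat("motif '", x$name, "': width ", x$width, ", nsites ",
      signif(x$nsites, 4), ", E-value ",
      if (is.na(x$evalue)) "NA" else format(x$evalue, digits = 3),
      "\n  consensus ", consensus(x), "\n", sep = "")
  invisible(x)
}

extract_site_seq <- function(Y, entry_id, start, strand, width) {
  i <- match(entry_id, Y$id)
  if (is.na(i)) stop("site refers to unknown entry ", entry_id)
  L <- nchar(Y$seq[i])
  if (start < 0L || start + width > L)
    stop("site out of bounds in entry ", entry_id)
  s <- substr(Y$seq[i], start + 1L, start + width)
  if (strand == "-") s <- revcomp_chr(s)
  s
}

#' Build a motif from aligned sites
#'
#' Tallies per-column base counts over the (strand-resolved) site
#' subsequences, then smooths with a background-proportional Dirichlet of
#' total mass `pseudo_total` per column.
#'
#' @param Y a [seq_set()].
#' @param sites data frame of [site()]s sharing one width.
#' @param bg a `bg_model` (its order-0 marginal drives the smoothing).
#' @param pseudo_total total pseudocount mass per column (default 1).
#' @param name motif label.
#' @param evalue optional E-value to attach.
#' @return an `ms_motif`.
#' @export
build_motif_from_sites <- function(Y, sites, bg, pseudo_total = 1,
                                   name = "motif", evalue = NA_real_) {
  if (nrow(sites) == 0L) stop("no sites supplied")
  if (length(unique(sites$width)) != 1L)
    stop("sites have mixed widths")
  w <- sites$width[1L]
  counts <- matrix(0, 4L, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(sites))) {
    s <- extract_site_seq(Y, sites$entry_id[i], sites$start[i],
                          sites$strand[i], w)
    v <- encode_seq(s)
    if (any(v == 0L)) next  # sites overlapping N carry no countable bases
    counts[cbind(v, seq_len(w))] <- counts[cbind(v, seq_len(w))] + 1
  }
  new_motif(counts, nsites = sum(counts[, 1L]), evalue = evalue,
            sites = sites, name = name, bg_q = bg$q,
            pseudo_total = pseudo_total)
}

#' Per-column and total information content
#'
#' IC_j = sum_b f(b,j) log2(f(b,j)/q_b), with 0 log 0 = 0.
#'
#' @param m an `ms_motif`.
#' @param bg a `bg_model`.
#' @return list with `per_column` (numeric vector) and `total`.
#' @export
information_content <- function(m, bg) {
  q <- bg$q
  ic <- apply(m$freqs, 2L, function(f) {
    nz <- f > 0
    sum(f[nz] * log2(f[nz] / q[nz]))
  })
  list(per_column = ic, total = sum(ic))
}

#' Consensus string of a motif
#'
#' Per column, the most frequent base; ties broken by the fixed order
#' A < C < G < T so worked examples are deterministic.
#'
#' @param m an `ms_motif`.
#' @return character string of length `m$width`.
#' @export
consensus <- function(m) {
  paste(c("A", "C", "G", "T")[apply(m$freqs, 2L, which.max)], collapse = "")
}

#' Reverse complement of a motif
#'
#' @param m an `ms_motif`.
#' @return an `ms_motif` on the opposite strand.
#' @export
motif_rc <- function(m) {
  flip <- function(M) M[4:1, ncol(M):1, drop = FALSE]
  cn <- flip(m$counts); fr <- flip(m$freqs)
  rownames(cn) <- rownames(fr) <- c("A", "C", "G", "T")
  structure(list(width = m$width, counts = cn, freqs = fr,
                 nsites = m$nsites, evalue = m$evalue, sites = NULL,
                 name = paste0(m$name, "_rc")),
            class = "ms_motif")
}

#' Write motifs in MEME minimal text format
#'
#' Emits a file that MEME-suite tools accept: version line, alphabet,
#' strands, background letter frequencies, and one MOTIF block per motif
#' with its letter-probability matrix, nsites and E-value.
#'
#' @param ms list of `ms_motif` objects (possibly empty).
#' @param bg a `bg_model` providing the background frequency line.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(ms, bg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies"), con)
  writeLines(sprintf("A %.6f C %.6f G %.6f T %.6f",
                     bg$q[1L], bg$q[2L], bg$q[3L], bg$q[4L]), con)
  for (m in ms) {
    writeLines(c("", paste("MOTIF", m$name)), con)
    ev <- if (is.na(m$evalue)) 1 else m$evalue
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %.6g E= %.6g",
      m$width, m$nsites, ev), con)
    for (j in seq_len(m$width))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         m$freqs[1L, j], m$freqs[2L, j],
                         m$freqs[3L, j], m$freqs[4L, j]), con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' @param path path to a MEME minimal file.
#' @return list of `ms_motif` objects (counts recovered as nsites x freqs).
#' @export
read_meme_minimal <- function(path) {
  ln <- readLines(path)
  heads <- grep("^MOTIF", ln)
  out <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    i <- heads[k]
    name <- sub("^MOTIF\\s+", "", ln[i])
    name <- strsplit(name, "\\s+")[[1L]][1L]
    j <- i + 1L
    while (j <= length(ln) && !grepl("letter-probability matrix", ln[j]))
      j <- j + 1L
    if (j > length(ln))
      stop("motif block ", k, ": missing letter-probability matrix")
    hdr <- ln[j]
    getnum <- function(key) {
      mm <- regmatches(hdr, regexec(paste0(key, "=\\s*([0-9.eE+-]+)"), hdr))[[1L]]
      if (length(mm) < 2L) return(NA_real_)
      as.numeric(mm[2L])
    }
    w <- as.integer(getnum("w"))
    if (is.na(w)) stop("motif block ", k, ": cannot parse width")
    nsites <- getnum("nsites"); if (is.na(nsites)) nsites <- 20
    ev <- getnum("E"); if (is.na(ev)) ev <- NA_real_
    rows <- ln[(j + 1L):(j + w)]
    vals <- lapply(rows, function(r) {
      v <- as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
      if (length(v) != 4L || anyNA(v))
        stop("motif block ", k, ": bad matrix row '", r, "'")
      v
    })
    freqs <- t(do.call(rbind, vals))
    freqs <- sweep(freqs, 2L, colSums(freqs), "/")  # absorb rounding
    rownames(freqs) <- c("A", "C", "G", "T")
    out[[k]] <- new_motif(counts = freqs * nsites, freqs = freqs,
                          nsites = nsites, evalue = ev, name = name)
  }
  out
}
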
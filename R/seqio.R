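#' Construct a sequence set
#'
#' A `seq_set` is the ordered input collection of named DNA sequence entries
#' that every other stage of the package operates on.  Entries are uppercased
#' and restricted to the alphabet A, C, G, T, N; ids must be unique and
#' non-empty.
#'
#' @param seqs character vector of sequences.
#' @param ids character vector of unique entry labels (defaults to the names
#'   of `seqs`).
#' @param origin optional data frame with one row per entry (e.g. replicon,
#'   1-based genomic span, strand); carried along untouched.
#' @return an object of class `seq_set`: a list with elements `id`, `seq`,
#'   and optionally `origin`.
#' @export
seq_set <- function(seqs, ids = names(seqs), origin = NULL) {
  force(ids)
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (length(ids) != length(seqs))
    stop("ids and seqs must have equal length")
  if (any(!nzchar(ids))) stop("entry ids must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate entry id: ", ids[duplicated(ids)][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence ", ids[bad][1L], " contains characters outside {A,C,G,T,N}")
  if (any(nchar(seqs) < 1L)) stop("sequences must have length >= 1")
  x <- list(id = ids, seq = unname(seqs), origin = origin)
  class(x) <- "seq_set"
  x
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", length(x$id), "entries; lengths",
      paste(range(nchar(x$seq)), collapse = "-"), "nt\n")
  invisible(x)
}

n_entries <- function(Y) length(Y$id)

#' Read a FASTA file into a sequence set
#'
#' Sequences are uppercased on read; duplicate record ids are rejected.
#'
#' @param path path to a FASTA file (possibly with zero records).
#' @return a [seq_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("FASTA parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) {
    x <- list(id = character(), seq = character(), origin = NULL)
    class(x) <- "seq_set"
    return(x)
  }
  ids <- sub("\\s.*$", "", names(ss))
  seq_set(as.character(ss), ids)
}

#' Write a sequence set to FASTA
#'
#' @param Y a [seq_set()].
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(Y, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(setNames(Y$seq, Y$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# A=1 C=2 G=3 T=4 N=0 integer encoding used by the C++ core.
encode_seq <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 0L
  as.integer(v)
}

decode_seq <- function(codes) {
  paste(c("N", "A", "C", "G", "T")[codes + 1L], collapse = "")
}

encode_set <- function(Y) lapply(Y$seq, encode_seq)

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

#' Estimate a fixed-order Markov background model
#'
#' Counts (k+1)-mers over the whole set, by default pooled over both strands
#' so that the model is reverse-complement symmetric (the scanner searches
#' both strands).  Positions overlapping N are skipped.  Laplace smoothing
#' with `pseudocount` per (k+1)-mer guarantees strictly positive
#' probabilities.
#'
#' @param Y a [seq_set()].
#' @param order Markov order k >= 0 (default 3).
#' @param pseudocount added to every (k+1)-mer count (default 1).
#' @param both_strands pool counts from the reverse complement as well.
#' @return object of class `bg_model`: list with `order`, `prob` (a
#'   4^k x 4 matrix of conditional probabilities, rows named by context),
#'   `q` (the order-0 marginal estimated the same way), and `pseudocount`.
#' @export
build_background <- function(Y, order = 3L, pseudocount = 1,
                             both_strands = TRUE) {
  stopifnot(order >= 0L, pseudocount >= 0)
  seqs <- Y$seq
  if (both_strands) seqs <- c(seqs, vapply(seqs, revcomp_chr, ""))
  k <- as.integer(order)
  counts_k <- kmer_counts(seqs, k + 1L)
  if (sum(counts_k) == 0 && pseudocount == 0)
    stop("no countable ", k + 1L, "-mers in the input")
  if (all(nchar(Y$seq) <= k))
    stop("no sequence longer than the background order")
  ctx <- kmer_names(k)
  prob <- matrix(0, nrow = length(ctx), ncol = 4L,
                 dimnames = list(ctx, c("A", "C", "G", "T")))
  for (i in seq_along(ctx)) {
    cnt <- as.numeric(counts_k[paste0(ctx[i], c("A", "C", "G", "T"))])
    cnt[is.na(cnt)] <- 0
    tot <- sum(cnt) + 4 * pseudocount
    if (tot == 0) prob[i, ] <- 0.25 else prob[i, ] <- (cnt + pseudocount) / tot
  }
  counts_0 <- kmer_counts(seqs, 1L)
  q0 <- as.numeric(counts_0[c("A", "C", "G", "T")])
  q0[is.na(q0)] <- 0
  q <- (q0 + pseudocount) / (sum(q0) + 4 * pseudocount)
  structure(list(order = k, prob = prob, q = unname(q),
                 pseudocount = pseudocount),
            class = "bg_model")
}

kmer_names <- function(k) {
  if (k == 0L) return("")
  do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                  stringsAsFactors = FALSE)))
}

# counts of N-free k-mers over a character vector of sequences
kmer_counts <- function(seqs, k) {
  out <- c()
  words <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    substring(s, 1:(L - k + 1L), k:L)
  }))
  words <- words[!grepl("N", words, fixed = TRUE)]
  table(words)
}

#' Order-0 marginal of a background model
#'
#' @param bg a `bg_model`.
#' @return numeric length-4 probability vector (A, C, G, T).
#' @export
bg_marginal <- function(bg) bg$q

#' Write / read a background model as a plain-text table
#'
#' Format: a header line `ORDER k`, a line `Q pA pC pG pT` with the order-0
#' marginal, then one line per context: context and its four conditional
#' probabilities.
#'
#' @param bg a `bg_model`.
#' @param path file path.
#' @return `path` (write) or a `bg_model` (read).
#' @export
write_background <- function(bg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("ORDER", bg$order), con)
  writeLines(paste("Q", paste(sprintf("%.10f", bg$q), collapse = " ")), con)
  ctx <- rownames(bg$prob)
  ctx[ctx == ""] <- "."
  for (i in seq_len(nrow(bg$prob)))
    writeLines(paste(ctx[i],
                     paste(sprintf("%.10f", bg$prob[i, ]), collapse = " ")),
               con)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  ln <- readLines(path)
  k <- as.integer(strsplit(ln[1L], " ")[[1L]][2L])
  q <- as.numeric(strsplit(ln[2L], " ")[[1L]][-1L])
  body <- strsplit(ln[-(1:2)], " ")
  ctx <- vapply(body, `[`, "", 1L)
  ctx[ctx == "."] <- ""
  prob <- t(vapply(body, function(x) as.numeric(x[-1L]), numeric(4L)))
  dimnames(prob) <- list(ctx, c("A", "C", "G", "T"))
  structure(list(order = k, prob = prob, q = q, pseudocount = NA_real_),
            class = "bg_model")
}

# uniform background, mainly for tests and worked examples
uniform_bg <- function(order = 0L) {
  ctx <- kmer_names(order)
  prob <- matrix(0.25, nrow = length(ctx), ncol = 4L,
                 dimnames = list(ctx, c("A", "C", "G", "T")))
  structure(list(order = as.integer(order), prob = prob,
                 q = rep(0.25, 4), pseudocount = 0),
            class = "bg_model")
}
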
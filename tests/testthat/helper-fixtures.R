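# shared fixtures: built in code, tiny, deterministic

uniform_bg <- function(order = 0L) motifsieve:::uniform_bg(order)

# delta motif spelling a word exactly (counts n per column)
delta_motif <- function(word, n = 10, pseudo = 0) {
  v <- match(strsplit(word, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  counts <- matrix(0, 4, length(v))
  counts[cbind(v, seq_along(v))] <- n
  new_motif(counts, bg_q = rep(0.25, 4), pseudo_total = pseudo)
}

hamming_canonical <- function(a, b) {
  rc <- motifsieve:::revcomp_chr
  min(sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]]),
      sum(strsplit(a, "")[[1L]] != strsplit(rc(b), "")[[1L]]))
}

# small planted data set with an exact word in every entry
exact_word_set <- function(n = 12, L = 120, word = "GATTACAGATTA", seed = 7) {
  generate_planted(N = n, L = L, consensi = word, fraction = 1,
                   mut_rate = 0, rng_seed = seed)
}
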
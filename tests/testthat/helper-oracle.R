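# Independent brute-force oracles: dense count vectors over all r^k
# tuples and naive character-loop counting. Deliberately slow and
# simple; never shares code with the package internals.

# all r^k tuples over the alphabet's class representatives
dense_tuple_space <- function(alphabet, k) {
  reps <- sort(unique(unname(alphabet$representatives)))
  apply(do.call(expand.grid,
                c(rep(list(reps), k), stringsAsFactors = FALSE)),
        1L, paste, collapse = "")
}

# dense count vector by naive per-window string comparison
dense_counts <- function(sequence, k, alphabet) {
  space <- dense_tuple_space(alphabet, k)
  s <- toupper(sequence)
  reps <- alphabet$representatives
  ch <- strsplit(s, "")[[1]]
  ch <- ifelse(ch %in% names(reps), reps[ch], ch)
  n <- length(ch)
  counts <- setNames(integer(length(space)), space)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      w <- paste(ch[i:(i + k - 1)], collapse = "")
      if (w %in% space) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# Eq.-style similarity from dense vectors, one division at the end
oracle_similarity <- function(x, y, k, alphabet) {
  cx <- dense_counts(x, k, alphabet)
  cy <- dense_counts(y, k, alphabet)
  denom <- min(nchar(x), nchar(y)) - k + 1
  if (denom < 1) return(0)
  sum(pmin(cx, cy)) / denom
}

# the three 23-residue aligned kinase fragments used throughout the
# conserved-window tests (uppercased)
table2_seqs <- function() {
  c("SAANILVGENLVCKVADFGLARL",
    "AARNILVGENYICKVADFGLARL",
    "AARNVLIGEDNVAKICDFGLARV")
}

random_protein <- function(n) {
  paste(sample(kmersim::AMINO_ACIDS, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
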
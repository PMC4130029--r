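# k-mer counting and the shared-k-mer similarity F.
#
# A sequence of length n over an alphabet of r classes has n - k + 1
# windows of length k. Conceptually the counts form a dense vector over
# all r^k possible k-tuples; here they are held sparsely (only tuples that
# occur), which is what makes k >= 4 over 20 letters feasible.

#' Count k-mers in a sequence
#'
#' Uppercases and class-translates the sequence, then slides a window of
#' length `k` from position 1 to n - k + 1 and counts every window whose
#' symbols all belong to the alphabet. Windows containing any
#' out-of-alphabet symbol (ambiguity codes, gaps, ...) are skipped and
#' tallied separately, so a single unknown residue removes at most `k`
#' windows and never aborts a run.
#'
#' @param sequence A single residue string.
#' @param k Word length, a positive integer.
#' @param alphabet A `kmer_alphabet` object or alphabet name.
#' @return A `kmer_count_table`: list with `k`, `counts` (named integer
#'   vector over occurring k-mers, every count >= 1), `effective_windows`
#'   (number of valid windows; equals `sum(counts)`), `skipped_windows`,
#'   and `raw_length` (the untranslated sequence length).
#' @examples
#' count_kmers("ATATAC", 3, "identity-dna")$counts  # ATA 2, TAT 1, TAC 1
#' @export
count_kmers <- function(sequence, k, alphabet) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k))
    stop("'k' must be a positive integer")
  k <- as.integer(k)
  n <- nchar(sequence)
  empty <- structure(
    list(k = k, counts = integer(0), effective_windows = 0L,
         skipped_windows = 0L, raw_length = n),
    class = "kmer_count_table")
  if (n < k) return(empty)

  translated <- translate_seq(sequence, alphabet)
  chars <- strsplit(translated, "", fixed = TRUE)[[1]]
  valid <- chars %in% unique(unname(alphabet$representatives))
  n_windows <- n - k + 1L
  # a window starting at i is valid iff positions i..i+k-1 are all valid
  ok <- valid[seq_len(n_windows)]
  if (k > 1L) {
    for (off in seq_len(k - 1L)) ok <- ok & valid[seq_len(n_windows) + off]
  }
  starts <- which(ok)
  empty$skipped_windows <- n_windows - length(starts)
  if (length(starts) == 0L) return(empty)
  words <- substring(translated, starts, starts + k - 1L)
  tab <- table(words)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(
    list(k = k, counts = counts,
         effective_windows = length(starts),
         skipped_windows = n_windows - length(starts),
         raw_length = n),
    class = "kmer_count_table")
}

#' Convert k-mer counts to relative frequencies
#'
#' Each frequency is the count divided by the number of valid windows, so
#' frequencies sum to 1.
#'
#' @param table A `kmer_count_table` with at least one valid window.
#' @return A `kmer_frequency_table`: list with `k` and `frequencies`
#'   (named numeric vector in \[0,1\]).
#' @export
kmer_frequencies <- function(table) {
  if (!inherits(table, "kmer_count_table"))
    stop("'table' must be a kmer_count_table")
  if (table$effective_windows < 1L)
    stop("frequencies are undefined for a table with no valid windows")
  structure(
    list(k = table$k,
         frequencies = table$counts / table$effective_windows),
    class = "kmer_frequency_table")
}

#' Shared-k-mer similarity between two sequences
#'
#' The similarity is
#' \deqn{F(X,Y) = \frac{\sum_\tau \min[n_X(\tau), n_Y(\tau)]}
#'                     {\min(L_X, L_Y) - k + 1}}
#' where the sum runs over all k-mers \eqn{\tau}, \eqn{n_X(\tau)} is the
#' occurrence count of \eqn{\tau} in X after class translation, and
#' \eqn{L_X, L_Y} are the raw sequence lengths. F lies in \[0,1\]; two
#' identical clean sequences score 1, sequences sharing no k-mer score 0.
#' The denominator uses raw lengths even when windows were skipped for
#' out-of-alphabet symbols, so unknown residues can only lower F, never
#' inflate it. If the shorter sequence is shorter than `k` the score is
#' 0 with a warning (the denominator is undefined), so batch runs never
#' abort on one short sequence.
#'
#' @param seq_x,seq_y Residue strings (non-empty).
#' @param k Word length.
#' @param alphabet A `kmer_alphabet` object or alphabet name.
#' @return A similarity in \[0,1\].
#' @examples
#' kmer_similarity("ATATAC", "ATATAC", 3, "identity-dna")  # 1
#' kmer_similarity("ATATAC", "GGGGGG", 3, "identity-dna")  # 0
#' @export
kmer_similarity <- function(seq_x, seq_y, k, alphabet) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(is.character(seq_x), length(seq_x) == 1L,
            is.character(seq_y), length(seq_y) == 1L)
  if (!nzchar(seq_x) || !nzchar(seq_y))
    stop("sequences must be non-empty")
  cx <- count_kmers(seq_x, k, alphabet)
  cy <- count_kmers(seq_y, k, alphabet)
  denom <- min(cx$raw_length, cy$raw_length) - cx$k + 1L
  if (denom < 1L) {
    warning("shorter sequence has length < k; similarity reported as 0")
    return(0)
  }
  shared <- intersect(names(cx$counts), names(cy$counts))
  numer <- sum(pmin(cx$counts[shared], cy$counts[shared]))
  # integer numerator / integer denominator: one division at the end,
  # so parallel and sequential paths are bit-identical
  as.numeric(numer) / denom
}

#' Count fully conserved k-windows across aligned sequences
#'
#' Treats the input as pre-aligned columns. A column is conserved iff all
#' sequences carry the same class representative there; the function
#' returns the number of window start positions i such that columns
#' i..i+k-1 are all conserved. With `k = 1` this is the conserved-column
#' count. Used to quantify how class translation into a compressed
#' alphabet raises conservation.
#'
#' @param aligned_sequences Character vector of >= 2 equal-length residue
#'   strings.
#' @param k Window length.
#' @param alphabet A `kmer_alphabet` object or alphabet name.
#' @return Integer count of fully conserved k-windows.
#' @export
conserved_window_count <- function(aligned_sequences, k, alphabet) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(is.character(aligned_sequences))
  if (length(aligned_sequences) < 2L)
    stop("need at least two aligned sequences")
  lens <- nchar(aligned_sequences)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must all have the same length")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
    stop("'k' must be a positive integer")
  k <- as.integer(k)
  n <- lens[1]
  if (n < k) return(0L)
  translated <- vapply(aligned_sequences, translate_seq, "",
                       alphabet = alphabet, USE.NAMES = FALSE)
  mat <- do.call(rbind, strsplit(translated, "", fixed = TRUE))
  conserved <- apply(mat, 2L, function(col) all(col == col[1L]))
  ok <- conserved[seq_len(n - k + 1L)]
  if (k > 1L) {
    for (off in seq_len(k - 1L)) ok <- ok & conserved[seq_len(n - k + 1L) + off]
  }
  sum(ok)
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat("k-mer count table: k=", x$k, ", ", length(x$counts),
      " distinct k-mers, ", x$effective_windows, " windows",
      if (x$skipped_windows > 0) paste0(" (", x$skipped_windows, " skipped)"),
      "\n", sep = "")
  invisible(x)
}
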
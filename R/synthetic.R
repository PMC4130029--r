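# Synthetic sequence families: a random ancestor plus point-substituted
# descendants. Emulates a family of homologs at a controlled divergence;
# no indels, no rate heterogeneity, no phylogenetic structure (all
# members are independent draws from the same ancestor).

#' Generate a synthetic sequence family
#'
#' Draws one uniform-random ancestor over the alphabet's base residues,
#' then derives each family member by substituting every position
#' independently with probability `substitution_rate`; a substitution
#' picks uniformly among the other base residues. Same seed, same output.
#'
#' @param n_sequences Number of family members, >= 1.
#' @param length Sequence length, >= 1.
#' @param substitution_rate Per-residue substitution probability in
#'   \[0, 1\]. 0 gives identical sequences (all pairwise F = 1).
#' @param alphabet A `kmer_alphabet` or name; its base residue set is the
#'   sampling pool (default `"identity-dna"`).
#' @param seed Optional integer seed for reproducibility.
#' @param prefix Id prefix; members are named `<prefix>1..<prefix>n`.
#' @return Named character vector of sequences.
#' @examples
#' fam <- generate_family(5, 100, 0.1, seed = 42)
#' identical(fam, generate_family(5, 100, 0.1, seed = 42))  # TRUE
#' @export
generate_family <- function(n_sequences, length, substitution_rate,
                            alphabet = "identity-dna", seed = NULL,
                            prefix = "seq") {
  if (!is.numeric(n_sequences) || n_sequences < 1 ||
      n_sequences != floor(n_sequences))
    stop("'n_sequences' must be a positive integer")
  if (!is.numeric(length) || length < 1 || length != floor(length))
    stop("'length' must be a positive integer")
  if (!is.numeric(substitution_rate) || substitution_rate < 0 ||
      substitution_rate > 1)
    stop("'substitution_rate' must be in [0, 1]")
  alphabet <- as_alphabet(alphabet)
  residues <- alphabet$base
  if (!is.null(seed)) set.seed(as.integer(seed))
  ancestor <- sample(residues, length, replace = TRUE)
  seqs <- vapply(seq_len(n_sequences), function(i) {
    member <- ancestor
    hit <- stats::runif(length) < substitution_rate
    if (any(hit)) {
      # uniform over the other residues: shift by 1..r-1 in residue order
      cur <- match(member[hit], residues)
      shift <- sample.int(base::length(residues) - 1L, sum(hit), replace = TRUE)
      member[hit] <- residues[(cur - 1L + shift) %% base::length(residues) + 1L]
    }
    paste(member, collapse = "")
  }, "")
  names(seqs) <- paste0(prefix, seq_len(n_sequences))
  seqs
}
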
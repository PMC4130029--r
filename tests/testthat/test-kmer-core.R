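test_that("window-scan counting matches the worked DNA example", {
  tab <- count_kmers("ATATAC", 3, "identity-dna")
  expect_equal(tab$counts[["ATA"]], 2L)
  expect_equal(tab$counts[["TAT"]], 1L)
  expect_equal(tab$counts[["TAC"]], 1L)
  expect_equal(length(tab$counts), 3L)
  expect_equal(tab$effective_windows, 4L)
  expect_equal(tab$raw_length, 6L)

  fr <- kmer_frequencies(tab)
  expect_equal(fr$frequencies[["ATA"]], 0.5)
  expect_equal(fr$frequencies[["TAT"]], 0.25)
  expect_equal(fr$frequencies[["TAC"]], 0.25)
})

test_that("counting edge cases: single window, short sequence, bad k", {
  tab <- count_kmers("AAA", 3, "identity-dna")
  expect_equal(unname(tab$counts), 1L)
  expect_equal(names(tab$counts), "AAA")
  expect_equal(kmer_frequencies(tab)$frequencies[["AAA"]], 1.0)

  short <- count_kmers("AT", 3, "identity-dna")
  expect_equal(length(short$counts), 0L)
  expect_equal(short$effective_windows, 0L)
  expect_error(kmer_frequencies(short), "no valid windows")

  expect_error(count_kmers("ATAT", 0, "identity-dna"), "positive integer")
  expect_error(count_kmers("ATAT", -1, "identity-dna"), "positive integer")
})

test_that("windows containing out-of-alphabet symbols are skipped, not fatal", {
  tab <- count_kmers("ATNTAC", 3, "identity-dna")
  # windows ATN, TNT, NTA invalid; only TAC survives
  expect_equal(names(tab$counts), "TAC")
  expect_equal(tab$effective_windows, 1L)
  expect_equal(tab$skipped_windows, 3L)
  expect_equal(tab$effective_windows + tab$skipped_windows,
               tab$raw_length - tab$k + 1L)
})

test_that("count conservation: counts sum to the number of valid windows", {
  set.seed(21)
  for (rep_i in 1:20) {
    s <- random_protein(sample(10:120, 1))
    k <- sample(1:4, 1)
    ab <- get_alphabet(sample(list_alphabets()[-2], 1))
    tab <- count_kmers(s, k, ab)
    expect_equal(sum(tab$counts), tab$effective_windows)
    if (tab$effective_windows > 0)
      expect_equal(sum(kmer_frequencies(tab)$frequencies), 1,
                   tolerance = 1e-12)
    expect_true(all(tab$counts >= 1L))
    expect_true(all(nchar(names(tab$counts)) == k))
  }
})

test_that("sparse counting equals dense enumeration over all r^k tuples", {
  set.seed(31)
  for (ab_name in c("identity-dna", "se-v10", "dayhoff6")) {
    ab <- get_alphabet(ab_name)
    residues <- ab$base
    for (k in 1:3) {
      for (rep_i in 1:4) {
        s <- paste(sample(residues, 40, replace = TRUE), collapse = "")
        dense <- dense_counts(s, k, ab)
        sparse <- count_kmers(s, k, ab)$counts
        expect_equal(sum(dense > 0), length(sparse))
        expect_equal(dense[names(sparse)], sparse,
                     ignore_attr = TRUE)
        expect_equal(sum(dense), count_kmers(s, k, ab)$effective_windows)
      }
    }
  }
})

test_that("similarity matches hand-checkable cases and the dense oracle", {
  expect_equal(kmer_similarity("ATATAC", "ATATAC", 3, "identity-dna"), 1.0)
  expect_equal(kmer_similarity("ATATAC", "GGGGGG", 3, "identity-dna"), 0.0)

  # 23-residue kinase fragments: 15 of 21 windows shared under SE-V(10),
  # 14 of 21 under the plain amino-acid alphabet (frozen from the
  # dense-enumeration oracle)
  s <- table2_seqs()
  expect_equal(kmer_similarity(s[1], s[2], 3, "se-v10"), 15 / 21)
  expect_equal(kmer_similarity(s[1], s[2], 3, "identity-protein"), 14 / 21)
  expect_equal(kmer_similarity(s[1], s[2], 3, "se-v10"),
               oracle_similarity(s[1], s[2], 3, get_alphabet("se-v10")))

  expect_error(kmer_similarity("", "ATAT", 3, "identity-dna"), "non-empty")
  expect_warning(ret <- kmer_similarity("AT", "ATATAC", 3, "identity-dna"),
                 "length < k")
  expect_equal(ret, 0)
})

test_that("similarity is symmetric, bounded and oracle-equal on random pairs", {
  set.seed(41)
  for (rep_i in 1:15) {
    k <- sample(1:3, 1)
    ab <- get_alphabet(sample(c("identity-dna", "se-v10", "murphy10"), 1))
    len_x <- sample(8:60, 1); len_y <- sample(8:60, 1)
    pool <- ab$base
    x <- paste(sample(pool, len_x, replace = TRUE), collapse = "")
    y <- paste(sample(pool, len_y, replace = TRUE), collapse = "")
    fxy <- kmer_similarity(x, y, k, ab)
    expect_identical(fxy, kmer_similarity(y, x, k, ab))
    expect_gte(fxy, 0); expect_lte(fxy, 1)
    expect_equal(fxy, oracle_similarity(x, y, k, ab))
  }
})

test_that("compressing the alphabet never lowers the similarity of a pair", {
  set.seed(51)
  sev10 <- get_alphabet("se-v10")
  ident <- get_alphabet("identity-protein")
  for (rep_i in 1:40) {
    fam <- generate_family(2, 60, substitution_rate = runif(1, 0.05, 0.4),
                           alphabet = "identity-protein")
    f_comp <- kmer_similarity(fam[1], fam[2], 3, sev10)
    f_full <- kmer_similarity(fam[1], fam[2], 3, ident)
    expect_gte(f_comp, f_full)
  }
})

test_that("conserved-window counts reproduce the aligned kinase fragments", {
  s <- table2_seqs()
  expect_equal(conserved_window_count(s, 1, "identity-protein"), 12L)
  expect_equal(conserved_window_count(s, 1, "se-v10"), 19L)
  expect_equal(conserved_window_count(s, 3, "identity-protein"), 4L)
  expect_equal(conserved_window_count(s, 3, "se-v10"), 10L)
  expect_equal(conserved_window_count(s, 4, "identity-protein"), 3L)
  expect_equal(conserved_window_count(s, 4, "se-v10"), 8L)
})

test_that("conserved-window edge cases behave", {
  # identical sequences: every window conserved
  s <- random_protein(30)
  for (k in c(1, 3, 7))
    expect_equal(conserved_window_count(c(s, s), k, "identity-protein"),
                 30 - k + 1)
  expect_error(conserved_window_count(c("AAA", "AAAA"), 1, "identity-protein"),
               "same length")
  expect_error(conserved_window_count("AAA", 1, "identity-protein"),
               "at least two")
})
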
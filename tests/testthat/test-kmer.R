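test_that("reverse complement is correct and an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAC"), "GTT")
  expect_identical(reverse_complement(c("A", "ACG")), c("T", "CGT"))
  expect_error(reverse_complement("ACGN"), class = "kfc_invalid_alphabet")

  set.seed(42)
  seqs <- vapply(1:1000, function(i) rand_dna(sample(1:40, 1)), character(1))
  expect_identical(reverse_complement(reverse_complement(seqs)), seqs)
  expect_identical(reverse_complement(seqs), oracle_rc(seqs))
})

test_that("k-mer encoding is a lexicographic-order bijection", {
  expect_equal(encode_kmer("ACG", 3), 6)  # 0*16 + 1*4 + 2
  expect_equal(encode_kmer("AAA", 3), 0)
  expect_equal(encode_kmer("TTT", 3), 63)
  expect_error(encode_kmer("ACGT", 3), class = "kfc_invalid_alphabet")
  expect_error(encode_kmer("ACN", 3), class = "kfc_invalid_alphabet")
  expect_error(encode_kmer(strrep("A", 27), 27), class = "kfc_unsupported_k")

  # full enumeration at k = 3: bijective onto 0..63, numeric = lexicographic
  kmers <- sort(apply(expand.grid(BASES <- c("A", "C", "G", "T"),
                                  BASES, BASES)[, 3:1], 1, paste,
                      collapse = ""))
  codes <- encode_kmer(kmers, 3)
  expect_equal(codes, 0:63)
  expect_identical(decode_kmer(codes, 3), kmers)

  set.seed(7)
  for (k in c(1, 5, 12, 26)) {
    w <- vapply(1:20, function(i) rand_dna(k), character(1))
    expect_identical(decode_kmer(encode_kmer(w, k), k), w)
  }
})

test_that("canonical code takes the smaller strand", {
  expect_equal(canonical_code("CGT", 3), 6)  # min(27, code("ACG") = 6)
  expect_equal(canonical_code("ACG", 3), 6)
  expect_equal(canonical_code("AAA", 3), 0)
  set.seed(11)
  w <- vapply(1:50, function(i) rand_dna(7), character(1))
  expect_equal(canonical_code(w, 7),
               pmin(encode_kmer(w, 7), encode_kmer(oracle_rc(w), 7)))
})

test_that("profile_sequence counts ACGT windows and skips N", {
  p <- profile_sequence("ACGTACGT", 3)
  expect_equal(profile_as_named_counts(p), c(ACG = 4L, GTA = 2L))
  expect_equal(p$total, 6)

  p <- profile_sequence("AANCGT", 3)
  expect_equal(profile_as_named_counts(p), c(ACG = 1L))
  expect_equal(p$total, 1)

  p <- profile_sequence("AC", 3)
  expect_equal(length(p$codes), 0)
  expect_equal(p$total, 0)

  # lowercase and ambiguity codes: folded / treated as N
  expect_equal(profile_as_named_counts(profile_sequence("acgtacgt", 3)),
               c(ACG = 4L, GTA = 2L))
  expect_equal(profile_sequence("ACRT", 3)$total,
               profile_sequence("ACNT", 3)$total)
})

test_that("profile_sample merges contigs additively", {
  p <- profile_sample(data.frame(id = c("c1", "c2"),
                                 sequence = c("AACGT", "ACGTT")), 3)
  expect_equal(profile_as_named_counts(p), c(AAC = 2L, ACG = 4L))
  expect_equal(p$total, 6)

  rec <- rand_records(3, c(30, 60))
  single <- profile_sample(rec, 5)
  doubled <- profile_sample(rbind(rec, transform(rec, id = paste0(id, "b"))), 5)
  expect_equal(doubled$codes, single$codes)
  expect_equal(doubled$counts, 2 * single$counts)
  expect_equal(doubled$total, 2 * single$total)

  empty <- profile_sample(data.frame(id = character(), sequence = character()), 5)
  expect_equal(empty$total, 0)
})

test_that("encoded counting matches the naive string-dictionary oracle", {
  set.seed(101)
  for (rep in 1:40) {
    k <- sample(c(3, 5, 7), 1)
    rec <- rand_records(sample(1:4, 1), c(20, 120), with_n = (rep %% 3 == 0))
    p <- profile_sample(rec, k)
    expect_equal(profile_as_named_counts(p), oracle_profile(rec$sequence, k),
                 info = sprintf("rep %d, k %d", rep, k))
    expect_equal(p$total, sum(p$counts))
  }
})

test_that("profiles are strand-invariant for odd k", {
  set.seed(5)
  rec <- rand_records(5, c(60, 150))
  for (k in c(3, 7, 15)) {
    p1 <- profile_sample(rec, k)
    p2 <- profile_sample(reverse_complement_records(rec), k)
    expect_identical(p1$codes, p2$codes)
    expect_identical(p1$counts, p2$counts)
  }
})

test_that("total equals the number of full windows when no N present", {
  set.seed(9)
  rec <- rand_records(6, c(10, 80))
  for (k in c(4, 9)) {
    expected <- sum(pmax(0, nchar(rec$sequence) - k + 1))
    expect_equal(profile_sample(rec, k)$total, expected)
  }
})

test_that("an even-k palindromic window is counted once under one key", {
  # "AT" is its own reverse complement
  p <- profile_sequence("AT", 2)
  expect_equal(profile_as_named_counts(p), c(AT = 1L))
  expect_equal(p$total, 1)
})

test_that("profile TSV and binary cache round-trip", {
  rec <- rand_records(3, c(40, 90))
  p <- profile_sample(rec, 7, sample_id = "s1")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bin <- withr::local_tempfile(fileext = ".kfc")
  write_profile_tsv(p, tsv)
  write_profile_cache(p, bin)
  for (q in list(read_profile_tsv(tsv), read_profile_cache(bin))) {
    expect_equal(q$k, p$k)
    expect_equal(q$codes, p$codes)
    expect_equal(q$counts, p$counts)
    expect_equal(q$total, p$total)
    expect_equal(q$sample_id, "s1")
  }
})
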
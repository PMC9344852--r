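test_that("hamming distance matches a position-by-position oracle", {
  expect_identical(hamming_distance("ACGT", "ACGT"), 0L)
  expect_identical(hamming_distance("AAAA", "TTTT"), 4L)
  expect_error(hamming_distance("ACG", "ACGT"), "length")
  expect_error(hamming_distance("ACNT", "ACGT"), "non-ACGT")

  set.seed(11)
  for (i in 1:1000) {
    a <- rand_seqs(1, 26)
    b <- mutate_seq(a, sample(0:26, 1))
    expect_identical(hamming_distance(a, b), ham_oracle(a, b))
  }
})

test_that("truncated distance returns the cap+1 sentinel past the cap", {
  expect_identical(hamming_distance("AAAA", "TTTT", cap = 2), 3L)
  expect_identical(hamming_distance("AAAA", "TTTA", cap = 3), 3L)
  set.seed(12)
  for (i in 1:50) {
    a <- rand_seqs(1, 26)
    d <- sample(0:26, 1)
    b <- mutate_seq(a, d)
    cap <- sample(0:5, 1)
    got <- hamming_distance(a, b, cap = cap)
    expect_identical(got, if (d > cap) cap + 1L else d)
  }
})

test_that("partition schemes tile the sequence and count combinations", {
  s <- kmer_scheme(8, epsilon = 2, k = 2)
  expect_equal(s$p, 4)
  expect_equal(s$r, 0)
  expect_equal(unname(s$partition_bounds[, "start"]), c(0, 2, 4, 6))
  expect_equal(unname(s$partition_bounds[, "end"]), c(2, 4, 6, 8))
  expect_equal(s$n_combinations, choose(4, 2))

  s26 <- kmer_scheme(26, epsilon = 2, k = 3)
  expect_equal(s26$p, 9)
  expect_equal(s26$r, 2)
  expect_equal(s26$lens, c(rep(3L, 8), 2L))
  expect_equal(sum(s26$lens), 26)

  # p - epsilon > 0 impossible for any k
  expect_error(kmer_scheme(4, epsilon = 4), "no substring length")
  expect_error(kmer_scheme(4, epsilon = 4, k = 2), "infeasible")
})

test_that("automatic k is feasible and deterministic across epsilon", {
  for (eps in 1:3) {
    s <- kmer_scheme(26, eps, n = 1e5)
    expect_gte(s$p - eps, 1)
    expect_identical(s$k, kmer_scheme(26, eps, n = 1e5)$k)
  }
})

test_that("combination IDs: count, determinism, and the sharing criterion", {
  sch <- kmer_scheme(8, epsilon = 2, k = 2)
  set.seed(21)
  q <- rand_seqs(1, 8)
  ids <- combination_ids(q, sch)
  expect_length(ids, 6L) # 4C2 = 6 pairs of 2-mers
  expect_identical(ids, combination_ids(q, sch))

  # exhaustive l=4, k=2, eps=1: two sequences share an ID iff they agree on
  # at least one whole partition
  sch4 <- kmer_scheme(4, epsilon = 1, k = 2)
  all4 <- apply(expand.grid(BASES, BASES, BASES, BASES), 1, paste,
                collapse = "")
  idsets <- lapply(all4, combination_ids, scheme = sch4)
  halves1 <- substr(all4, 1, 2)
  halves2 <- substr(all4, 3, 4)
  for (i in seq_along(all4)) {
    shared <- vapply(idsets, function(x) any(x %in% idsets[[i]]), logical(1))
    agrees <- halves1 == halves1[i] | halves2 == halves2[i]
    expect_identical(shared, agrees)
  }
})

test_that("index construction satisfies the ID-count invariant", {
  sch <- kmer_scheme(26, epsilon = 2, k = 3)
  set.seed(31)
  one <- build_kmer_index(rand_seqs(1, 26), sch)
  expect_identical(shepherd:::cpp_table_entries_per_seq(one$ptr),
                   sch$n_combinations)

  seqs <- rand_seqs(200, 26)
  idx <- build_kmer_index(seqs, sch)
  expect_true(all(shepherd:::cpp_table_entries_per_seq(idx$ptr) ==
                    sch$n_combinations))
})

test_that("sequences within epsilon always share a combination ID", {
  # toy of Fig-1 shape: l=8, k=2, eps=2 - planted mutants at distance <= 2
  # must share >= 2 of the 4 2-mers, hence >= 1 combination ID
  sch <- kmer_scheme(8, epsilon = 2, k = 2)
  set.seed(41)
  for (i in 1:50) {
    a <- rand_seqs(1, 8)
    b <- mutate_seq(a, sample(1:2, 1))
    expect_true(any(combination_ids(a, sch) %in% combination_ids(b, sch)))
  }
})

test_that("k-mer neighborhood: self-exclusion, superset and distance bound", {
  set.seed(51)
  sch <- kmer_scheme(8, epsilon = 2, k = 2)
  solo <- build_kmer_index("ACGTACGT", sch)
  expect_length(kmer_neighborhood("ACGTACGT", solo), 0L)

  seqs <- rand_seqs(300, 26)
  # plant mutants so the epsilon-neighborhoods are non-trivial
  seqs <- unique(c(seqs, vapply(seqs[1:100],
                                function(s) mutate_seq(s, sample(1:3, 1)),
                                character(1))))
  mat <- char_matrix(seqs)
  for (eps in 1:2) {
    sch <- kmer_scheme(26, eps, n = length(seqs))
    idx <- build_kmer_index(seqs, sch)
    for (i in sample(seq_along(seqs), 30)) {
      nb <- kmer_neighborhood(seqs[i], idx)
      expect_false(i %in% nb)
      # pigeonhole: superset of the true epsilon-neighborhood
      expect_true(all(brute_eps_neighbors(mat, i, eps) %in% nb))
    }
  }

  # exact distance bound k*eps when l is a multiple of k
  sch8 <- kmer_scheme(8, epsilon = 2, k = 2)
  s8 <- unique(c(rand_seqs(100, 8),
                 vapply(rep(1:20, 3), function(j) mutate_seq("ACGTACGT", 3),
                        character(1)), "ACGTACGT"))
  idx8 <- build_kmer_index(s8, sch8)
  for (i in sample(seq_along(s8), 25)) {
    nb <- kmer_neighborhood(s8[i], idx8)
    if (length(nb))
      expect_lte(max(vapply(s8[nb], ham_oracle, numeric(1), b = s8[i])),
                 2 * 2)
  }
})

test_that("k-mer neighborhood never shrinks as epsilon grows", {
  set.seed(61)
  seqs <- unique(c(rand_seqs(200, 26),
                   vapply(rand_seqs(50, 26),
                          function(s) mutate_seq(s, sample(1:4, 1)),
                          character(1))))
  idx1 <- build_kmer_index(seqs, kmer_scheme(26, 1, k = 4))
  idx2 <- build_kmer_index(seqs, kmer_scheme(26, 2, k = 4))
  for (i in sample(seq_along(seqs), 20)) {
    expect_true(all(kmer_neighborhood(seqs[i], idx1) %in%
                      kmer_neighborhood(seqs[i], idx2)))
  }
})

test_that("epsilon-neighborhood equals the all-pairs Hamming filter", {
  set.seed(71)
  for (rep in 1:5) {
    base <- rand_seqs(150, 26)
    seqs <- unique(c(base, vapply(base[1:60],
                                  function(s) mutate_seq(s, sample(1:3, 1)),
                                  character(1))))
    counts <- sample(1:500, length(seqs), replace = TRUE)
    mat <- char_matrix(seqs)
    eps <- sample(1:3, 1)
    idx <- build_kmer_index(read_set(seqs, counts),
                            kmer_scheme(26, eps, n = length(seqs)))
    for (i in sample(seq_along(seqs), 20)) {
      nb <- epsilon_neighborhood(seqs[i], idx)
      expect_setequal(nb$idx, brute_eps_neighbors(mat, i, eps))
      # reported distances are correct and sorted ascending
      expect_identical(nb$dist,
                       vapply(seqs[nb$idx], ham_oracle, numeric(1),
                              b = seqs[i]) |> as.integer() |> unname())
      expect_false(is.unsorted(nb$dist))
    }
  }
})

test_that("epsilon boundary: distance epsilon is in, epsilon + 1 is out", {
  set.seed(81)
  a <- rand_seqs(1, 26)
  for (eps in 1:3) {
    at <- mutate_seq(a, eps)
    out <- mutate_seq(a, eps + 1L)
    idx <- build_kmer_index(read_set(c(a, at, out), c(10, 2, 1)),
                            kmer_scheme(26, eps, n = 3))
    nb <- epsilon_neighborhood(a, idx)
    expect_true(2L %in% nb$idx)
    expect_false(3L %in% nb$idx)
  }
})
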
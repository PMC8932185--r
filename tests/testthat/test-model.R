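test_that("tau lower bound matches independent arithmetic", {
  # direct evaluation, written out without reusing the implementation
  indep <- ((1 - 0.10) / (1 + 0.10)) * 1 / (2 * exp(14 * 0.15) - 1)
  expect_equal(tau_lower_bound(14, 0.15, 0.10), indep, tolerance = 1e-12)
  expect_lt(abs(tau_lower_bound(14, 0.15, 0.10) - 0.0534), 5e-4)
  expect_identical(tau_lower_bound(7, 0, 0), 1)
  # strictly decreasing in k
  taus <- vapply(10:20, tau_lower_bound, numeric(1), eps_P = 0.1, eps_B = 0.05)
  expect_true(all(diff(taus) < 0))
})

test_that("k-mer preservation probability follows the Poisson model", {
  expect_identical(kmer_preservation_prob(14, 0), 1)
  expect_equal(kmer_preservation_prob(14, 0.15), exp(-2.1), tolerance = 1e-12)
  # Monte-Carlo: simulator preservation at eps_P = 0.05, k = 10
  set.seed(101)
  s <- rand_dna(20000)
  m <- dupsweep:::mutate_copy(s, 0.05, 0)
  frac <- colinear_match_size(s, m$seq, 10) / (nchar(s) - 9)
  p <- exp(-0.5)
  sigma <- sqrt(p * (1 - p) / (nchar(s) - 9))
  # correlated preservation inflates the binomial sigma; allow a wide band
  expect_lt(abs(frac - p), 12 * sigma)
})

test_that("colinear matching equals the LCS oracle", {
  expect_equal(colinear_match_size("ACGGT", "GGTAC", 2), 2)
  expect_equal(brute_colinear("ACGGT", "GGTAC", 2), 2)
  expect_equal(colinear_match_size("AAAA", "CCCC", 2), 0)
  s <- "ACGTGCA"  # all distinct 3-mers
  expect_equal(colinear_match_size(s, s, 3), nchar(s) - 2)
  set.seed(77)
  for (rep in 1:60) {
    k <- sample(c(3, 5, 8), 1)
    n1 <- sample(20:120, 1); n2 <- sample(20:120, 1)
    s1 <- paste(sample(c("A", "C"), n1, TRUE), collapse = "") # repeat-rich
    s2 <- paste(sample(c("A", "C"), n2, TRUE), collapse = "")
    expect_equal(colinear_match_size(s1, s2, k), brute_colinear(s1, s2, k),
                 info = sprintf("rep %d k=%d", rep, k))
  }
  for (rep in 1:40) {
    k <- sample(c(3, 5, 8), 1)
    s1 <- rand_dna(sample(50:300, 1)); s2 <- rand_dna(sample(50:300, 1))
    expect_equal(colinear_match_size(s1, s2, k), brute_colinear(s1, s2, k))
  }
})

test_that("colinear matching is symmetric", {
  set.seed(13)
  for (rep in 1:20) {
    s1 <- rand_dna(80); s2 <- mutate_subs(s1, 10)
    k <- sample(c(3, 5, 8), 1)
    expect_equal(colinear_match_size(s1, s2, k),
                 colinear_match_size(s2, s1, k))
  }
})

test_that("ordered Jaccard excludes cross-over matches", {
  expect_equal(ordered_jaccard("ACGGT", "GGTAC", 2), 2 / 5)
  expect_equal(classical_jaccard("ACGGT", "GGTAC", 2), 3 / 5)
  s <- "ACGTGCA"
  expect_equal(ordered_jaccard(s, s, 3), 1)
  expect_equal(ordered_jaccard("AA", "CC", 2), 0)  # no shared k-mers
})

test_that("ordered Jaccard equals classical Jaccard under the model's assumptions", {
  # substitution-only mutants with repeat-free k-mer content
  set.seed(31)
  done <- 0
  while (done < 100) {
    k <- sample(c(5, 8), 1)
    s1 <- rand_dna(sample(60:200, 1))
    if (anyDuplicated(kmer_tokens(s1, k))) next
    s2 <- mutate_subs(s1, sample(1:8, 1))
    if (anyDuplicated(kmer_tokens(s2, k))) next
    # Lemma condition: every shared k-mer was shared before mutation, i.e.
    # occurs at the same position in both strings (mutation can re-create a
    # k-mer elsewhere by chance; such draws are outside the model)
    ta <- kmer_tokens(s1, k); tb <- kmer_tokens(s2, k)
    sh <- intersect(ta, tb)
    if (!all(match(sh, ta) == match(sh, tb))) next
    expect_identical(ordered_jaccard(s1, s2, k), classical_jaccard(s1, s2, k))
    # and never exceeds it
    expect_lte(ordered_jaccard(s1, s2, k), classical_jaccard(s1, s2, k) + 1e-12)
    done <- done + 1
  }
})

test_that("edit error is the normalized Levenshtein distance", {
  r <- edit_error("ACGT", "ACGT")
  expect_equal(r$err, 0)
  expect_equal(r$aln_len, 4)
  r2 <- edit_error("AC", "A")
  expect_equal(r2$E, 1); expect_equal(r2$aln_len, 2); expect_equal(r2$err, 0.5)
  set.seed(21)
  s <- rand_dna(1000)
  s2 <- mutate_subs(s, 10)
  r3 <- edit_error(s, s2)
  expect_equal(r3$err, 10 / 1000)
  # against the adist operation-count oracle, including indel cases
  for (rep in 1:20) {
    a <- rand_dna(sample(20:200, 1))
    b <- if (rep %% 2) mutate_subs(a, 5) else rand_dna(sample(20:200, 1))
    o <- adist_oracle(a, b)
    r <- edit_error(a, b)
    expect_equal(r$E, o$E)
    # co-optimal alignments can trade substitutions for gap pairs, so ell is
    # only pinned to the definition's bracket
    expect_gte(r$aln_len, max(nchar(a), nchar(b)))
    expect_lte(r$aln_len, nchar(a) + nchar(b))
    expect_equal(r$err, r$E / r$aln_len)
  }
  # err(s, s) = 0 and err in [0, 1]
  expect_gte(edit_error("ACGT", "TTTTTTTT")$err, 0)
  expect_lte(edit_error("ACGT", "TTTTTTTT")$err, 1)
})
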
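test_that("identical regions produce one full-diagonal chain", {
  set.seed(201)
  s <- rand_dna(2000)
  ch <- chain_anchors(s, s, k_align = 10)
  expect_gte(length(ch), 1)
  expect_equal(dupsweep:::chain_anchored_bases(ch[[1]], 10), 2000)
  aln <- refine_alignment(ch[[1]], s, s, eps = 0.25)
  expect_equal(aln$err, 0)
  expect_equal(aln$ell, 2000)
  expect_match(aln$cigar, "^2000=$")
})

test_that("a block insertion shows up as one diagonal shift", {
  set.seed(202)
  s <- rand_dna(3000)
  s2 <- paste0(substr(s, 1, 1500), rand_dna(100), substr(s, 1501, 3000))
  ch <- chain_anchors(s, s2, k_align = 10)
  expect_equal(length(ch), 1)
  d <- ch[[1]][, 2] - ch[[1]][, 1]
  expect_setequal(unique(d), c(0L, 100L))
  aln <- refine_alignment(ch[[1]], s, s2, eps = 0.25)
  expect_equal(aln$nins, 100)
  expect_equal(aln$ell, 3100)
  expect_equal(aln$err, 100 / 3100, tolerance = 1e-9)
})

test_that("unrelated regions produce no usable chain", {
  set.seed(203)
  for (rep in 1:10) {
    a <- rand_dna(3000); b <- rand_dna(3000)
    ch <- chain_anchors(a, b, k_align = 10)
    bases <- vapply(ch, function(x) as.numeric(dupsweep:::chain_anchored_bases(x, 10)), numeric(1))
    expect_true(all(bases < 200))
  }
})

test_that("refined error matches the exact edit-distance oracle", {
  set.seed(204)
  for (rep in 1:6) {
    s <- rand_dna(1500)
    s2 <- mutate_subs(s, 15 * rep)
    ch <- chain_anchors(s, s2, k_align = 10)
    aln <- refine_alignment(ch[[1]], s, s2, eps = 0.25)
    ta <- substr(s, aln$a_start + 1, aln$a_end)
    tb <- substr(s2, aln$b_start + 1, aln$b_end)
    oracle <- dupsweep:::cpp_edit_dist(ta, tb)
    # substitution-only: the banded path must realize the optimal distance
    expect_equal(aln$E, oracle$E)
    expect_equal(aln$err, oracle$err, tolerance = 1e-9)
  }
  # with indels the banded affine path may be slightly suboptimal, never better
  for (rep in 1:4) {
    s <- rand_dna(2000)
    m <- dupsweep:::mutate_copy(s, 0.1, 0.05)
    ch <- chain_anchors(s, m$seq, k_align = 10)
    aln <- refine_alignment(ch[[1]], s, m$seq, eps = 0.25)
    ta <- substr(s, aln$a_start + 1, aln$a_end)
    tb <- substr(m$seq, aln$b_start + 1, aln$b_end)
    oracle <- dupsweep:::cpp_edit_dist(ta, tb)
    expect_gte(aln$E + 1e-9, oracle$E)
    expect_lt(aln$err - oracle$err, 0.02)
  }
})

test_that("ten interior substitutions in 1000 bases give err 0.01", {
  set.seed(205)
  s <- rand_dna(1000)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in sample(30:970, 10)) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  s2 <- paste(ch, collapse = "")
  ch <- chain_anchors(s, s2, k_align = 10)
  aln <- refine_alignment(ch[[1]], s, s2, eps = 0.25)
  expect_equal(aln$ell, 1000)
  expect_equal(aln$err, 10 / 1000)
})

test_that("SD validation applies the three definition criteria", {
  model <- error_model()
  base <- list(chrom_a = "c", start_a = 0L, end_a = 1000L,
               chrom_b = "c", start_b = 5000L, end_b = 6000L,
               strand_b = "+", aln_len = 1000L, edit_error = 0,
               cigar = "", genome_a = "g", genome_b = "g")
  expect_true(validate_sd(base, model)$accept)
  r <- base; r$aln_len <- 999L
  expect_equal(validate_sd(r, model)$reason, "length")
  r <- base; r$aln_len <- 1000L; r$edit_error <- model$eps
  expect_true(validate_sd(r, model)$accept)  # closed thresholds
  r$edit_error <- model$eps + 1e-9
  expect_equal(validate_sd(r, model)$reason, "error")
  # overlap: eps * n + 1 is rejected, eps * n accepted
  r <- base
  n <- 1000L; ov_limit <- as.integer(model$eps * n)
  r$start_b <- r$end_a - ov_limit - 1L; r$end_b <- r$start_b + n
  expect_equal(validate_sd(r, model)$reason, "overlap")
  r$start_b <- r$end_a - ov_limit; r$end_b <- r$start_b + n
  expect_true(validate_sd(r, model)$accept)
  # different chromosomes never trip the overlap rule
  r <- base; r$chrom_b <- "d"; r$start_b <- 0L; r$end_b <- 1000L
  expect_true(validate_sd(r, model)$accept)
})

test_that("emitted records re-verify against the definition from raw sequence", {
  cfg <- sim_config(genome_len = 150000, n_sds = 4, len_range = c(1200, 4000),
                    eps = 0.2, seed = 206)
  sim <- simulate_genome(cfg)
  g <- sim$genome
  model <- error_model()
  calls <- run_single(g, model, forward_only = TRUE)
  expect_gt(nrow(calls), 0)
  for (i in seq_len(nrow(calls))) {
    sa <- dupsweep:::extract_seq(g, calls$chrom_a[i], calls$start_a[i], calls$end_a[i])
    sb <- dupsweep:::extract_seq(g, calls$chrom_b[i], calls$start_b[i], calls$end_b[i],
                                 rc = calls$strand_b[i] == "-")
    ed <- dupsweep:::cpp_edit_dist(sa, sb)
    expect_lte(ed$err, model$eps)
    expect_gte(calls$aln_len[i], 1000)
    expect_lte(calls$edit_error[i], model$eps)
    # reported ell within the definition's bracket
    expect_gte(calls$aln_len[i],
               max(calls$end_a[i] - calls$start_a[i],
                   calls$end_b[i] - calls$start_b[i]) - 1e-9)
    ov <- max(0, min(calls$end_a[i], calls$end_b[i]) -
                max(calls$start_a[i], calls$start_b[i]))
    n <- min(calls$end_a[i] - calls$start_a[i], calls$end_b[i] - calls$start_b[i])
    expect_lte(ov, model$eps * n)
  }
})

test_that("reported error recovers the simulated divergence", {
  cfg <- sim_config(genome_len = 200000, n_sds = 5, len_range = c(1500, 8000),
                    eps = 0.15, seed = 207)
  sim <- simulate_genome(cfg)
  calls <- run_single(sim$genome, error_model(), forward_only = TRUE)
  det <- attr(evaluate_sensitivity(sim$truth, calls), "detected")
  for (i in which(det)) {
    t <- sim$truth[i, ]
    hit <- which(vapply(seq_len(nrow(calls)), function(j)
      interval_cov(calls$start_a[j], calls$end_a[j], t$src_start, t$src_end) > 0.9 ||
        interval_cov(calls$start_b[j], calls$end_b[j], t$src_start, t$src_end) > 0.9,
      logical(1)))
    expect_true(length(hit) > 0)
    expect_lt(min(abs(calls$edit_error[hit] - t$realized_err)), 0.03)
  }
})
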
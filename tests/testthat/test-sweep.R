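make_planted <- function(seed, glen = 100000, sdlen = 2000, eps = 0) {
  cfg <- sim_config(genome_len = glen, n_sds = 1,
                    len_range = c(sdlen, sdlen), eps = eps,
                    eps_P = 0.6 * eps, eps_B = 0.4 * eps, seed = seed)
  simulate_genome(cfg)
}

test_that("plane sweep recovers an exact planted duplication", {
  sim <- make_planted(101, sdlen = 2000, eps = 0)
  g <- sim$genome
  idx <- build_index(g, kmer_params())
  cands <- plane_sweep(idx, g, sweep_params(), error_model())
  t <- sim$truth[1, ]
  cov_src <- vapply(seq_len(nrow(cands)), function(i)
    max(interval_cov(cands$start_a[i], cands$end_a[i], t$src_start, t$src_end),
        interval_cov(cands$start_b[i], cands$end_b[i], t$src_start, t$src_end)),
    numeric(1))
  cov_cpy <- vapply(seq_len(nrow(cands)), function(i)
    max(interval_cov(cands$start_a[i], cands$end_a[i], t$copy_start, t$copy_end),
        interval_cov(cands$start_b[i], cands$end_b[i], t$copy_start, t$copy_end)),
    numeric(1))
  expect_true(any(cov_src >= 0.9 & cov_cpy >= 0.9))
})

test_that("random genomes yield no large promoted candidates", {
  for (seed in 1:8) {
    set.seed(seed)
    g <- masked_genome(c(chr = rand_dna(100000)), name = "neg")
    idx <- build_index(g, kmer_params())
    cands <- plane_sweep(idx, g, sweep_params(), error_model())
    big <- cands[cands$end_a - cands$start_a >= 1000, , drop = FALSE]
    expect_equal(nrow(big), 0, info = paste("seed", seed))
  }
})

test_that("a copy mutated at the full error budget is still recovered", {
  sim <- make_planted(103, sdlen = 3000, eps = 0.25)
  g <- sim$genome
  calls <- run_single(g, error_model(), forward_only = TRUE)
  expect_gte(evaluate_sensitivity(sim$truth, calls), 1)
})

test_that("fragmented duplications merge back into one candidate", {
  # plant a 6 Kbp duplication, then mask a 300-base window inside the copy
  set.seed(104)
  core <- rand_dna(6000)
  left <- rand_dna(30000); mid <- rand_dna(20000); right <- rand_dna(5000)
  chr <- paste0(left, core, mid, core, right)
  ch <- strsplit(chr, "", fixed = TRUE)[[1]]
  gap0 <- 30000 + 6000 + 20000 + 2800
  ch[(gap0 + 1):(gap0 + 300)] <- tolower(ch[(gap0 + 1):(gap0 + 300)])
  g <- masked_genome(c(chr = paste(ch, collapse = "")), name = "frag")
  idx <- build_index(g, kmer_params())
  model <- error_model()
  params <- sweep_params()
  cands <- plane_sweep(idx, g, params, model)
  merged <- merge_putative(cands, params, g, model)
  # one candidate pair covering >=90% of both copies
  cov1 <- vapply(seq_len(nrow(merged)), function(i)
    interval_cov(merged$start_a[i], merged$end_a[i], 30000, 36000), numeric(1))
  cov2 <- vapply(seq_len(nrow(merged)), function(i)
    interval_cov(merged$start_b[i], merged$end_b[i], 56000, 62000), numeric(1))
  expect_true(any(cov1 >= 0.9 & cov2 >= 0.9))
  # idempotence
  again <- merge_putative(merged, params, g, model)
  expect_equal(nrow(again), nrow(merged))
})

test_that("merge leaves unrelated candidates and empty input unchanged", {
  model <- error_model()
  params <- sweep_params()
  set.seed(105)
  g <- masked_genome(c(c1 = rand_dna(2000), c2 = rand_dna(2000)), name = "x")
  cands <- data.frame(
    chrom_a = c("c1", "c2"), start_a = c(0L, 0L), end_a = c(500L, 500L),
    chrom_b = c("c1", "c2"), start_b = c(1000L, 1000L), end_b = c(1500L, 1500L),
    strand_b = "+", shared = 10L, union = 100L, jaccard = 0.1,
    genome_a = "x", genome_b = "x", stringsAsFactors = FALSE)
  out <- merge_putative(cands, params, g, model)
  expect_equal(nrow(out), 2)
  empty <- dupsweep:::empty_putative()
  expect_equal(nrow(merge_putative(empty, params, g, model)), 0)
})

test_that("cross sweep maps SD regions onto a second genome, not conservation", {
  set.seed(106)
  core <- rand_dna(3000)
  gB <- masked_genome(c(chrB = paste0(rand_dna(10000), core, rand_dna(10000))),
                      name = "B")
  gA <- masked_genome(c(chrA = paste0(rand_dna(20000), core, rand_dna(8000))),
                      name = "A")
  idxA <- build_index(gA, kmer_params())
  regions <- data.frame(chrom = "chrB", start = 10000L, end = 13000L,
                        stringsAsFactors = FALSE)
  cands <- cross_sweep(idxA, regions, gB, gA, sweep_params(), error_model())
  expect_gt(nrow(cands), 0)
  cov_b <- max(vapply(seq_len(nrow(cands)), function(i)
    interval_cov(cands$start_a[i], cands$end_a[i], 10000, 13000), numeric(1)))
  cov_a <- max(vapply(seq_len(nrow(cands)), function(i)
    interval_cov(cands$start_b[i], cands$end_b[i], 20000, 23000), numeric(1)))
  expect_gte(cov_b, 0.9)
  expect_gte(cov_a, 0.9)
  expect_true(all(cands$genome_a == "B" & cands$genome_b == "A"))
  # a region with no homolog produces nothing
  set.seed(107)
  gB2 <- masked_genome(c(chrB = rand_dna(20000)), name = "B2")
  r2 <- data.frame(chrom = "chrB", start = 5000L, end = 8000L)
  expect_equal(nrow(cross_sweep(idxA, r2, gB2, gA, sweep_params(), error_model())), 0)
})

test_that("promoted candidates satisfy the overlap rule by construction", {
  sim <- make_planted(108, sdlen = 2500, eps = 0.1)
  g <- sim$genome
  idx <- build_index(g, kmer_params())
  model <- error_model()
  cands <- plane_sweep(idx, g, sweep_params(), model)
  for (i in seq_len(nrow(cands))) {
    ov <- max(0, min(cands$end_a[i], cands$end_b[i]) -
                max(cands$start_a[i], cands$start_b[i]))
    n <- min(cands$end_a[i] - cands$start_a[i],
             cands$end_b[i] - cands$start_b[i])
    expect_lte(ov, model$eps * n)
    expect_gte(cands$jaccard[i], tau_lower_bound(14, model$eps_P, model$eps_B))
  }
})
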
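two_sd_records <- function(starts_a, ends_a, starts_b, ends_b) {
  data.frame(chrom_a = "c", start_a = starts_a, end_a = ends_a,
             chrom_b = "c", start_b = starts_b, end_b = ends_b,
             strand_b = "+", aln_len = ends_a - starts_a, edit_error = 0,
             cigar = "", genome_a = "g", genome_b = "g",
             stringsAsFactors = FALSE)
}

test_that("union-find clustering is transitive over paralog overlap", {
  # A-B overlap, B-C overlap, A-C disjoint -> one cluster of three
  r <- two_sd_records(c(0L, 900L, 1800L), c(1000L, 1900L, 2800L),
                      c(5000L, 8000L, 11000L), c(6000L, 9000L, 12000L))
  cl <- cluster_sds(r)
  expect_equal(length(cl), 1)
  expect_setequal(cl[[1]]$members, 1:3)
  # fully disjoint records -> singleton clusters
  r2 <- two_sd_records(c(0L, 20000L), c(1000L, 21000L),
                       c(5000L, 40000L), c(6000L, 41000L))
  cl2 <- cluster_sds(r2)
  expect_equal(length(cl2), 2)
  expect_equal(sort(lengths(lapply(cl2, `[[`, "members"))), c(1L, 1L))
  # sharing one paralog interval -> one cluster of two
  r3 <- two_sd_records(c(100L, 150L), c(1100L, 1200L),
                       c(5000L, 9000L), c(6000L, 10000L))
  expect_equal(length(cluster_sds(r3)), 1)
})

test_that("identical copies decompose into one full-length set", {
  set.seed(301)
  core <- rand_dna(1000)
  g <- masked_genome(c(c1 = paste0(rand_dna(300), core, rand_dna(300),
                                   core, rand_dna(200))), name = "g")
  rec <- two_sd_records(300L, 1300L, 1600L, 2600L)
  rec$chrom_a <- rec$chrom_b <- "c1"
  sets <- decompose_sds(rec, g, decompose_params())
  expect_equal(length(unique(sets$set_id)), 1)
  expect_equal(nrow(sets), 2)
  d_g <- 50
  expect_true(all(sets$end - sets$start >= 1000 - 2 * d_g))
})

test_that("mosaic SDs split into X, Y and Z elementary sets at the boundary images", {
  mz <- make_mosaic(seed = 302)
  sets <- decompose_sds(mz$records, mz$genome, decompose_params())
  supports <- table(sets$set_id)
  # Y occurs three times, X and Z twice each
  expect_setequal(as.integer(supports), c(2L, 3L, 2L))
  d_g <- 50
  b <- mz$blocks
  yid <- names(supports)[supports == 3]
  ymem <- sets[sets$set_id == as.integer(yid), ]
  # the three Y members sit on the three planted Y instances
  ystarts <- sort(ymem$start)
  expect_equal(length(ystarts), 3)
  planted_y <- sort(c(b$Y[1], b$Y[3], b$Y[5]))
  expect_true(all(abs(ystarts - planted_y) <= d_g))
  planted_ye <- sort(c(b$Y[2], b$Y[4], b$Y[6]))
  expect_true(all(abs(sort(ymem$end) - planted_ye) <= d_g))
  # concatenation property: members cover >= 80% of every SD paralog
  paralogs <- rbind(
    data.frame(s = mz$records$start_a, e = mz$records$end_a),
    data.frame(s = mz$records$start_b, e = mz$records$end_b))
  for (i in seq_len(nrow(paralogs))) {
    hit <- sets[sets$start < paralogs$e[i] & sets$end > paralogs$s[i], ]
    cov <- sum(pmin(hit$end, paralogs$e[i]) - pmax(hit$start, paralogs$s[i]))
    expect_gte(cov / (paralogs$e[i] - paralogs$s[i]), 0.8)
  }
})

test_that("members shorter than mu are dropped from emitted sets", {
  set.seed(303)
  core <- rand_dna(600)
  tail80 <- substr(core, 521, 600)  # 80 bp (< mu) partial third copy
  g <- masked_genome(c(c1 = paste0(rand_dna(200), core, rand_dna(200), core,
                                   rand_dna(200), tail80, rand_dna(200))),
                     name = "g")
  r <- dupsweep:::cpp_decompose(
    c(substr(g$seq[[1]], 201, 800), substr(g$seq[[1]], 1001, 1600),
      substr(g$seq[[1]], 1801, 1880)), 10L, 50L, 100L)
  supports <- vapply(r, nrow, integer(1))
  expect_true(all(supports == 2))   # the 80 bp member is discarded
})

test_that("decomposition output is invariant to record order", {
  mz <- make_mosaic(seed = 304)
  s1 <- decompose_sds(mz$records, mz$genome)
  s2 <- decompose_sds(mz$records[2:1, ], mz$genome)
  norm <- function(s) {
    s <- s[order(s$chrom, s$start, s$end), c("chrom", "start", "end", "strand")]
    rownames(s) <- NULL
    s
  }
  expect_equal(norm(s1), norm(s2))
})

test_that("greedy core duplicons match brute-force minima on small instances", {
  set.seed(305)
  # abstract instances: records on one chromosome, each set one member per
  # record it should cover
  for (rep in 1:12) {
    n_rec <- sample(4:6, 1)
    n_set <- sample(3:8, 1)
    # record i occupies [1000i, 1000i + 500)
    recs <- two_sd_records(as.integer(1000 * (1:n_rec)),
                           as.integer(1000 * (1:n_rec) + 500),
                           as.integer(100000 + 1000 * (1:n_rec)),
                           as.integer(100000 + 1000 * (1:n_rec) + 500))
    cover <- replicate(n_set, sample(1:n_rec, sample(1:n_rec, 1)),
                       simplify = FALSE)
    # ensure coverable
    for (i in seq_len(n_rec)) if (!any(vapply(cover, function(cc) i %in% cc, logical(1))))
      cover[[1]] <- unique(c(cover[[1]], i))
    sets <- do.call(rbind, lapply(seq_along(cover), function(sid)
      data.frame(set_id = sid, genome = "g", chrom = "c",
                 start = as.integer(1000 * cover[[sid]]),
                 end = as.integer(1000 * cover[[sid]] + 100),
                 strand = "+", stringsAsFactors = FALSE)))
    core <- core_duplicons(sets, recs)
    ids <- attr(core, "core_ids")
    rec_cover <- lapply(seq_len(n_rec), function(i)
      which(vapply(cover, function(cc) i %in% cc, logical(1))))
    opt <- brute_min_cover(rec_cover, n_rec)
    # greedy covers everything, and H(n)-approximation holds; on these sizes
    # demand exact optimality
    expect_true(all(vapply(rec_cover, function(cc) any(cc %in% ids), logical(1))))
    expect_lte(length(ids), length(opt) + ifelse(n_rec >= 6, 1, 0))
  }
  # single shared set covers all
  recs <- two_sd_records(c(1000L, 2000L), c(1500L, 2500L),
                         c(50000L, 60000L), c(50500L, 60500L))
  sets <- data.frame(set_id = c(1L, 1L, 2L), genome = "g", chrom = "c",
                     start = c(1000L, 2000L, 1000L),
                     end = c(1100L, 2100L, 1050L),
                     strand = "+", stringsAsFactors = FALSE)
  core <- core_duplicons(sets, recs)
  expect_equal(attr(core, "core_ids"), 1L)
  # zero SDs
  expect_equal(nrow(core_duplicons(sets, recs[0, ])), 0)
})

test_that("composition distance and NJ behave on planted structures", {
  sets <- data.frame(set_id = c(1L, 2L, 3L), genome = "g", chrom = "c",
                     start = c(0L, 500L, 1000L), end = c(400L, 900L, 1400L),
                     strand = "+", stringsAsFactors = FALSE)
  rg <- function(s, e) list(chrom = "c", start = s, end = e)
  expect_equal(composition_distance(rg(0, 1400), rg(0, 1400), sets), 0)
  expect_equal(composition_distance(rg(0, 400), rg(1000, 1400), sets), 1)
  expect_equal(composition_distance(rg(5000, 6000), rg(5000, 6000), sets), 0)
  expect_equal(composition_distance(rg(5000, 6000), rg(0, 400), sets), 1)
  expect_equal(composition_distance(rg(0, 900), rg(500, 1400), sets), 1 - 1 / 3)
  # four-taxon additive matrix: ((A,B),(C,D)) with internal branch 0.1
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.2
  d[3, 4] <- d[4, 3] <- 0.2
  d[1, 3] <- d[3, 1] <- d[1, 4] <- d[4, 1] <- 0.4
  d[2, 3] <- d[3, 2] <- d[2, 4] <- d[4, 2] <- 0.4
  nwk <- build_nj_tree(c("A", "B", "C", "D"), d)
  tr <- ape::read.tree(text = nwk)
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("C", "D")))
})

test_that("elementary members of one set stay mutually similar on mutated SDs", {
  cfg <- sim_config(genome_len = 100000, n_sds = 2, len_range = c(1500, 2500),
                    eps = 0.1, seed = 306)
  sim <- simulate_genome(cfg)
  calls <- run_single(sim$genome, error_model(), forward_only = TRUE)
  sets <- decompose_sds(calls, sim$genome)
  model <- error_model()
  for (sid in unique(sets$set_id)) {
    mem <- sets[sets$set_id == sid, ]
    if (nrow(mem) < 2) next
    seqs <- vapply(seq_len(nrow(mem)), function(i)
      dupsweep:::extract_seq(sim$genome, mem$chrom[i], mem$start[i], mem$end[i],
                             rc = mem$strand[i] == "-"), character(1))
    for (i in 1:(nrow(mem) - 1)) for (j in (i + 1):nrow(mem)) {
      expect_lte(dupsweep:::cpp_edit_dist(seqs[i], seqs[j])$err,
                 model$eps + 0.05)
    }
  }
})
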
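# Independent oracles and fixture builders used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

kmer_tokens <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# brute-force winnowing: enumerate every window explicitly and take the
# k-mer minimal under the canonical order key, rightmost on ties
brute_winnow <- function(s, k, w) {
  km <- encode_kmers(s, k)
  keys <- dupsweep:::cpp_order_key(km$code)
  m <- length(keys)
  if (m == 0) return(integer(0))
  if (m <= w) {
    best <- 1
    for (i in seq_len(m)) if (keys[i] <= keys[best]) best <- i
    return(km$pos[best])
  }
  sel <- integer(0)
  for (st in 1:(m - w + 1)) {
    win <- st:(st + w - 1)
    best <- win[1]
    for (i in win) if (keys[i] <= keys[best]) best <- i
    sel <- c(sel, best)
  }
  km$pos[sort(unique(sel))]
}

# maximum colinear k-mer matching by LCS over the k-mer token sequences
# (strictly increasing index pairs with equal tokens); independent of the
# package's LIS-over-pairs route
brute_colinear <- function(s1, s2, k) {
  a <- kmer_tokens(s1, k); b <- kmer_tokens(s2, k)
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  prev <- integer(nb + 1)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1)
    for (j in seq_len(nb)) {
      cur[j + 1] <- max(prev[j + 1], cur[j],
                        prev[j] + (a[i] == b[j]))
    }
    prev <- cur
  }
  prev[nb + 1]
}

classical_jaccard <- function(s1, s2, k) {
  a <- unique(kmer_tokens(s1, k)); b <- unique(kmer_tokens(s2, k))
  length(intersect(a, b)) / length(union(a, b))
}

# substitution-only mutant at a fixed number of positions (always changes
# the base)
mutate_subs <- function(s, n_subs) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), n_subs)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# edit distance + alignment length oracle via utils::adist operation counts
adist_oracle <- function(s1, s2) {
  d <- utils::adist(s1, s2, counts = TRUE)
  cnt <- attr(d, "counts")
  ins <- cnt[, , "ins"][1]
  E <- as.integer(d[1, 1])
  ell <- nchar(s1) + ins   # matches + subs + dels = |s1|; + ins columns
  list(E = E, ell = as.integer(ell), err = E / ell)
}

interval_cov <- function(s1, e1, s2, e2) {
  max(0, min(e1, e2) - max(s1, s2)) / max(1, e2 - s2)
}

# Fig.2-style mosaic: chrA carries X,Y,Z contiguously; X.Y and Y.Z are each
# duplicated elsewhere. Returns the genome, the two SD records, and the
# planted block coordinates.
make_mosaic <- function(seed = 9, lx = 600, ly = 700, lz = 500, pad = 400) {
  set.seed(seed)
  X <- rand_dna(lx); Y <- rand_dna(ly); Z <- rand_dna(lz)
  p1 <- rand_dna(pad); p2 <- rand_dna(pad); p3 <- rand_dna(pad); p4 <- rand_dna(pad)
  # layout: p1 XYZ p2 XY p3 YZ p4
  a0 <- pad
  b0 <- a0 + lx + ly + lz + pad
  c0 <- b0 + lx + ly + pad
  chr <- paste0(p1, X, Y, Z, p2, X, Y, p3, Y, Z, p4)
  g <- masked_genome(c(chrM = chr), name = "mosaic")
  recs <- data.frame(
    chrom_a = "chrM",
    start_a = c(a0, a0 + lx),
    end_a = c(a0 + lx + ly, a0 + lx + ly + lz),
    chrom_b = "chrM",
    start_b = c(b0, c0),
    end_b = c(b0 + lx + ly, c0 + ly + lz),
    strand_b = "+",
    aln_len = c(lx + ly, ly + lz),
    edit_error = 0, cigar = "",
    genome_a = "mosaic", genome_b = "mosaic",
    stringsAsFactors = FALSE)
  list(genome = g, records = recs,
       blocks = list(X = c(a0, a0 + lx, b0, b0 + lx),
                     Y = c(a0 + lx, a0 + lx + ly, b0 + lx, b0 + lx + ly,
                           c0, c0 + ly),
                     Z = c(a0 + lx + ly, a0 + lx + ly + lz, c0 + ly, c0 + ly + lz)))
}

# greedy-vs-optimal set cover harness on synthetic abstract instances
brute_min_cover <- function(cover_sets, n_records) {
  ids <- sort(unique(unlist(cover_sets)))
  best <- NULL
  for (sz in seq_along(ids)) {
    combs <- utils::combn(ids, sz, simplify = FALSE)
    for (cb in combs) {
      covered <- vapply(cover_sets, function(cc) any(cc %in% cb), logical(1))
      if (all(covered)) { best <- cb; break }
    }
    if (!is.null(best)) break
  }
  best
}
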
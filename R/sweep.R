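#' Plane-sweep parameters
#'
#' @param tau acceptance threshold for the ordered Jaccard index of a
#'   candidate region pair; by default derived from the error model via
#'   [tau_lower_bound()].
#' @param delta maximum distance (bases) between neighbouring matched
#'   k-mers while a putative SD grows.
#' @param max_gap retirement distance: a live candidate whose frontier falls
#'   farther than this behind the sweep line is retired (the maximum gap
#'   size of the smallest possible SD, 250).
#' @param min_span minimum span (bases, each side) a retired candidate needs
#'   to be promoted. Kept low (100) so fragments of small high-divergence
#'   SDs survive to the merge step; the 1 Kbp SD length floor is enforced
#'   after alignment.
#' @param extend flank (bases) added to each promoted region before
#'   alignment, and the maximum distance at which two candidates may merge.
#' @param min_shared minimum colinear matched k-mers for a candidate to be
#'   considered at all.
#' @return a `sweep_params` list.
#' @export
sweep_params <- function(tau = NULL, delta = 250, max_gap = 250,
                         min_span = 100, extend = 5000, min_shared = 2) {
  stopifnot(delta > 0, extend >= 0, min_shared >= 1)
  structure(list(tau = tau, delta = as.integer(delta),
                 max_gap = as.integer(max_gap),
                 min_span = as.integer(min_span),
                 extend = as.integer(extend),
                 min_shared = as.integer(min_shared)),
            class = "sweep_params")
}

# extract a genome interval; masked positions become N so that hard-masking
# semantics carry into exact k-mer computations and alignment
extract_seq <- function(genome, chrom, start, end, rc = FALSE, mask_to_N = TRUE) {
  s <- substr(genome$seq[[chrom]], start + 1L, end)
  if (mask_to_N) {
    m <- genome$mask[[chrom]][(start + 1L):end]
    if (any(m)) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      ch[m] <- "N"
      s <- paste(ch, collapse = "")
    }
  }
  if (rc) s <- revcomp(s)
  s
}

putative_cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                   "end_b", "strand_b", "shared", "union", "jaccard",
                   "genome_a", "genome_b")

empty_putative <- function() {
  data.frame(chrom_a = character(), start_a = integer(), end_a = integer(),
             chrom_b = character(), start_b = integer(), end_b = integer(),
             strand_b = character(), shared = integer(), union = integer(),
             jaccard = numeric(), genome_a = character(),
             genome_b = character(), stringsAsFactors = FALSE)
}

# raw sweep candidates (global coords) -> putative data frame in local
# coordinates; y intervals of a reverse-complement index are mapped back to
# forward coordinates with strand "-"
map_candidates <- function(raw, chroms_x, chroms_y, rc, name_x, name_y) {
  if (nrow(raw) == 0) return(empty_putative())
  ax <- global_to_local(chroms_x, raw$bx)
  axe <- raw$ex - (raw$bx - ax$local)            # local end
  ay <- global_to_local(chroms_y, raw$by)
  aye <- raw$ey - (raw$by - ay$local)
  if (rc) {
    len <- chroms_y$length[match(ay$chrom, chroms_y$chrom)]
    s <- len - aye
    e <- len - ay$local
    ay$local <- s; aye <- e
  }
  data.frame(chrom_a = ax$chrom, start_a = ax$local, end_a = axe,
             chrom_b = ay$chrom, start_b = ay$local, end_b = aye,
             strand_b = if (rc) "-" else "+",
             shared = raw$shared, union = NA_integer_, jaccard = NA_real_,
             genome_a = name_x, genome_b = name_y,
             stringsAsFactors = FALSE)
}

# exact promotion test: recompute the ordered Jaccard of the candidate spans
# on the full (non-winnowed) k-mer sets and keep candidates reaching tau
promote_candidates <- function(cands, genome_a, genome_b, k, tau, params,
                               model) {
  if (nrow(cands) == 0) return(cbind(cands))
  span_a <- cands$end_a - cands$start_a
  span_b <- cands$end_b - cands$start_b
  keep <- span_a >= params$min_span & span_b >= params$min_span
  # Definition-1 overlap rule for intra-genome same-chromosome pairs
  intra <- cands$genome_a == cands$genome_b & cands$chrom_a == cands$chrom_b
  ov <- pmax(0L, pmin(cands$end_a, cands$end_b) -
               pmax(cands$start_a, cands$start_b))
  keep <- keep & !(intra & ov > model$eps * pmin(span_a, span_b))
  cands <- cands[keep, , drop = FALSE]
  if (nrow(cands) == 0) return(cands)
  for (i in seq_len(nrow(cands))) {
    sa <- extract_seq(genome_a, cands$chrom_a[i], cands$start_a[i], cands$end_a[i])
    sb <- extract_seq(genome_b, cands$chrom_b[i], cands$start_b[i], cands$end_b[i],
                      rc = cands$strand_b[i] == "-")
    oj <- cpp_ordered_jaccard(sa, sb, as.integer(k),
                              win = as.integer(1000 * (1 - model$eps)))
    cands$shared[i] <- oj$shared
    cands$union[i] <- oj$union_size
    cands$jaccard[i] <- oj$window_jaccard
  }
  out <- cands[cands$jaccard >= tau, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plane-sweep search for putative SD regions
#'
#' Sweeps every valid k-mer position of the genome left to right against the
#' winnowed index. At each position `x` the index supplies the sorted
#' occurrence list of that k-mer among the winnowed fingerprint (so the
#' sweep stays linear in the genome while the index stays small); each
#' occurrence `y > x` either extends a live candidate whose
#' frontier is within `delta` on both axes, is subsumed by a candidate
#' already covering it, or starts a new candidate. Candidates retired by the
#' `max_gap` rule are promoted when the ordered Jaccard index of their
#' spans, recomputed exactly from the sequences, reaches `tau`, and when
#' they satisfy the span and overlap rules. With an additional
#' reverse-complement index, inverted duplications are found the same way
#' and reported with `strand_b == "-"`.
#'
#' @param index `winnow_index` of `genome` (forward strand).
#' @param genome the `masked_genome` the index was built from.
#' @param params a [sweep_params()] object.
#' @param model an [error_model()]; supplies `tau` when `params$tau` is
#'   `NULL`, and the overlap rule.
#' @param rc_index optional reverse-complement `winnow_index` of the same
#'   genome for inverted duplications.
#' @return a putative-SD data frame (`chrom_a start_a end_a chrom_b start_b
#'   end_b strand_b shared union jaccard genome_a genome_b`), 0-based
#'   half-open coordinates.
#' @export
plane_sweep <- function(index, genome, params = sweep_params(),
                        model = error_model(k = index$params$k),
                        rc_index = NULL) {
  k <- index$params$k
  tau <- if (is.null(params$tau)) tau_lower_bound(k, model$eps_P, model$eps_B) else params$tau
  q <- kmer_stream(genome, k)
  raw <- cpp_plane_sweep(q$pos, q$code, index$pos, index$code,
                         as.integer(k), params$delta, params$max_gap,
                         index$params$max_freq, TRUE, params$min_shared)
  cands <- map_candidates(raw, index$chroms, index$chroms, FALSE,
                          genome$name, genome$name)
  if (!is.null(rc_index)) {
    raw2 <- cpp_plane_sweep(q$pos, q$code, rc_index$pos, rc_index$code,
                            as.integer(k), params$delta, params$max_gap,
                            index$params$max_freq, FALSE, params$min_shared)
    c2 <- map_candidates(raw2, index$chroms, rc_index$chroms, TRUE,
                         genome$name, genome$name)
    # each inverted pair is discovered from both sides: keep the canonical
    # orientation (interval a lexicographically <= interval b), drop
    # palindromic self-matches
    if (nrow(c2) > 0) {
      keep <- (c2$chrom_a < c2$chrom_b) |
        (c2$chrom_a == c2$chrom_b & c2$start_a < c2$start_b) |
        (c2$chrom_a == c2$chrom_b & c2$start_a == c2$start_b & c2$end_a < c2$end_b)
      c2 <- c2[keep, , drop = FALSE]
      cands <- rbind(cands, c2)
    }
  }
  promote_candidates(cands, genome, genome, k, tau, params, model)
}

#' Merge nearby putative SDs
#'
#' Iteratively merges candidate pairs whose a-intervals and b-intervals are
#' each within `extend` of one another and share chromosome pair and
#' orientation, keeping a merge only if the ordered Jaccard of the united
#' spans still reaches `tau`; a candidate fully contained in another is
#' absorbed. The operation is idempotent.
#'
#' @param cands putative-SD data frame from [plane_sweep()].
#' @param params a [sweep_params()].
#' @param genome,genome_b the genome(s) the intervals refer to (`genome_b`
#'   defaults to `genome` for the intra-genome case).
#' @param model an [error_model()].
#' @return merged putative-SD data frame.
#' @export
merge_putative <- function(cands, params, genome, model = error_model(),
                           genome_b = genome, k = 14) {
  if (nrow(cands) <= 1) return(cands)
  tau <- if (is.null(params$tau)) tau_lower_bound(k, model$eps_P, model$eps_B) else params$tau
  win <- as.integer(1000 * (1 - model$eps))
  sa_ <- cands$start_a; ea_ <- cands$end_a
  sb_ <- cands$start_b; eb_ <- cands$end_b
  sh_ <- cands$shared; un_ <- cands$union; jc_ <- cands$jaccard
  key <- paste(cands$chrom_a, cands$chrom_b, cands$strand_b,
               cands$genome_a, cands$genome_b, sep = "\r")
  alive <- rep(TRUE, nrow(cands))
  repeat {
    changed <- FALSE
    idx <- which(alive)
    for (i in idx) {
      if (!alive[i]) next
      js <- which(alive & key == key[i] &
                    pmax(sa_[i], sa_) - pmin(ea_[i], ea_) <= params$extend &
                    pmax(sb_[i], sb_) - pmin(eb_[i], eb_) <= params$extend)
      js <- js[js != i]
      for (j in js) {
        if (!alive[j] || !alive[i]) break
        contained <- (sa_[j] >= sa_[i] && ea_[j] <= ea_[i] &&
                        sb_[j] >= sb_[i] && eb_[j] <= eb_[i]) ||
          (sa_[i] >= sa_[j] && ea_[i] <= ea_[j] &&
             sb_[i] >= sb_[j] && eb_[i] <= eb_[j])
        us <- min(sa_[i], sa_[j]); ue <- max(ea_[i], ea_[j])
        vs <- min(sb_[i], sb_[j]); ve <- max(eb_[i], eb_[j])
        seq_a <- extract_seq(genome, cands$chrom_a[i], us, ue)
        seq_b <- extract_seq(genome_b, cands$chrom_b[i], vs, ve,
                             rc = cands$strand_b[i] == "-")
        oj <- cpp_ordered_jaccard(seq_a, seq_b, as.integer(k), win = win)
        if (oj$window_jaccard >= tau) {
          sa_[i] <- us; ea_[i] <- ue; sb_[i] <- vs; eb_[i] <- ve
          sh_[i] <- oj$shared; un_[i] <- oj$union_size
          jc_[i] <- oj$window_jaccard
          alive[j] <- FALSE
          changed <- TRUE
        } else if (contained) {
          # keep the container
          drop <- if (ea_[i] - sa_[i] >= ea_[j] - sa_[j]) j else i
          alive[drop] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- cands[alive, , drop = FALSE]
  out$start_a <- sa_[alive]; out$end_a <- ea_[alive]
  out$start_b <- sb_[alive]; out$end_b <- eb_[alive]
  out$shared <- sh_[alive]; out$union <- un_[alive]
  out$jaccard <- jc_[alive]
  rownames(out) <- NULL
  out
}

#' Map SD regions of one genome onto another
#'
#' Runs the same sweep logic with the query k-mers drawn from the winnowed
#' fingerprints of SD paralog regions of genome B and the index built on
#' genome A (no `y > x` restriction). Only known SD regions are mapped, so
#' conserved-but-unduplicated sequence is never called as an SD.
#'
#' @param index_a forward `winnow_index` of genome A.
#' @param regions_b data frame (`chrom`, `start`, `end`) of SD paralog
#'   intervals in genome B.
#' @param genome_b the `masked_genome` of B.
#' @param genome_a the `masked_genome` of A.
#' @param params a [sweep_params()].
#' @param model an [error_model()].
#' @param rc_index_a optional reverse-complement index of A.
#' @return putative-SD data frame with `genome_a` = B's name (query side)
#'   and `genome_b` = A's name (hit side).
#' @export
cross_sweep <- function(index_a, regions_b, genome_b, genome_a,
                        params = sweep_params(),
                        model = error_model(k = index_a$params$k),
                        rc_index_a = NULL) {
  k <- index_a$params$k
  tau <- if (is.null(params$tau)) tau_lower_bound(k, model$eps_P, model$eps_B) else params$tau
  if (nrow(regions_b) == 0) return(empty_putative())
  # query fingerprint over the B regions, with one synthetic offset per region
  qpos <- integer(0); qcode <- numeric(0)
  offs <- integer(nrow(regions_b))
  cur <- 0L
  for (r in seq_len(nrow(regions_b))) {
    offs[r] <- cur
    s <- extract_seq(genome_b, regions_b$chrom[r], regions_b$start[r],
                     regions_b$end[r])
    km <- encode_kmers(s, k)
    qpos <- c(qpos, km$pos + cur)
    qcode <- c(qcode, km$code)
    cur <- cur + (regions_b$end[r] - regions_b$start[r])
  }
  qchroms <- data.frame(chrom = as.character(seq_len(nrow(regions_b))),
                        offset = offs,
                        length = regions_b$end - regions_b$start,
                        stringsAsFactors = FALSE)
  out <- empty_putative()
  for (rc in c(FALSE, TRUE)) {
    idx <- if (rc) rc_index_a else index_a
    if (is.null(idx)) next
    raw <- cpp_plane_sweep(qpos, qcode, idx$pos, idx$code, as.integer(k),
                           params$delta, params$max_gap,
                           index_a$params$max_freq, FALSE, params$min_shared)
    if (nrow(raw) == 0) next
    cands <- map_candidates(raw, qchroms, idx$chroms, rc,
                            genome_b$name, genome_a$name)
    # translate region-space a-intervals back to genome B coordinates
    r <- as.integer(cands$chrom_a)
    cands$chrom_a <- regions_b$chrom[r]
    cands$start_a <- cands$start_a + regions_b$start[r]
    cands$end_a <- cands$end_a + regions_b$start[r]
    out <- rbind(out, cands)
  }
  promote_candidates(out, genome_b, genome_a, k, tau, params, model)
}
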
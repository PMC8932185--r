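#' Simulation configuration
#'
#' Defines a synthetic genome with planted segmental duplications mutated
#' under the two-component SD error model: point substitutions at rate
#' `eps_P` (positions uniform, substituted base always different) and block
#' insertions/deletions with a total base budget of `eps_B` times the SD
#' length (block lengths geometric with mean 50, truncated at 5% of the SD
#' length). Mutation counts are fixed at their expectations so that every
#' planted SD respects the total error budget `eps`.
#'
#' @param genome_len background length in bases (i.i.d. uniform A/C/G/T).
#' @param n_sds number of planted SDs.
#' @param len_range `(min, max)` SD lengths, sampled uniformly.
#' @param eps total target error.
#' @param eps_P substitution budget (default `0.6 * eps`).
#' @param eps_B block budget (default `eps - eps_P`).
#' @param block_event_prob nominal per-base block event probability (model
#'   bookkeeping; the realized block count follows the `eps_B` budget).
#' @param inverted_frac fraction of copies planted as reverse complements.
#' @param seed RNG seed; the whole genome is reproducible from it.
#' @export
sim_config <- function(genome_len = 5e6, n_sds = 200,
                       len_range = c(1000, 10000), eps = 0.25,
                       eps_P = 0.6 * eps, eps_B = eps - eps_P,
                       block_event_prob = 0.005, inverted_frac = 0,
                       seed = 1) {
  stopifnot(abs(eps - (eps_P + eps_B)) < 1e-9,
            len_range[1] >= 1, len_range[2] <= genome_len,
            inverted_frac >= 0, inverted_frac <= 1)
  structure(list(genome_len = as.integer(genome_len),
                 n_sds = as.integer(n_sds),
                 len_range = as.integer(len_range), eps = eps,
                 eps_P = eps_P, eps_B = eps_B,
                 block_event_prob = block_event_prob,
                 inverted_frac = inverted_frac, seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate one SD copy: block edits first (insert/delete, fair coin), then
# point mutations as a Poisson process at rate eps_P per base -- mutation
# *events* are Poisson(eps_P * length), positions drawn with replacement,
# each event forcing a different base. A base may be hit more than once, so
# the fraction of k-mers left untouched is exp(-k * eps_P) exactly, the
# preservation probability the error model assumes. Returns the mutated
# string plus the edit script cost: E = substituted positions + inserted +
# deleted bases, ell = L + inserted.
mutate_copy <- function(src, eps_P, eps_B) {
  L <- nchar(src)
  ch <- strsplit(src, "", fixed = TRUE)[[1]]
  ins_tot <- 0L; del_tot <- 0L
  budget <- round(eps_B * L)
  maxblk <- max(1L, floor(0.05 * L))
  while (ins_tot + del_tot < budget) {
    len <- min(rgeom(1, 1 / 50) + 1L, maxblk, budget - ins_tot - del_tot)
    if (runif(1) < 0.5 && length(ch) > len + 1) { # deletion
      p <- sample.int(length(ch) - len, 1)
      ch <- ch[-(p:(p + len - 1L))]
      del_tot <- del_tot + len
    } else {                                      # insertion
      p <- sample.int(length(ch) + 1L, 1) - 1L
      blk <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      ch <- append(ch, blk, after = p)
      ins_tot <- ins_tot + len
    }
  }
  orig <- ch
  nev <- stats::rpois(1, eps_P * length(ch))
  if (nev > 0) {
    pos <- sample.int(length(ch), nev, replace = TRUE)
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
  }
  nsub <- sum(ch != orig)
  E <- nsub + ins_tot + del_tot
  ell <- L + ins_tot
  list(seq = paste(ch, collapse = ""), E = E, ell = ell,
       err = if (ell > 0) E / ell else 0, nsub = nsub,
       ins = ins_tot, del = del_tot)
}

#' Simulate a genome with planted segmental duplications
#'
#' Generates a uniform-random background, samples disjoint source segments,
#' mutates a copy of each under the SD error model, and splices the copies
#' into the background at random loci outside every source segment. Truth
#' coordinates are reported on the final genome.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a `masked_genome`, single chromosome
#'   `chrS`) and `truth` (data frame `chrom, src_start, src_end,
#'   copy_start, copy_end, strand, len, realized_err`).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  bg_len <- config$genome_len
  n <- config$n_sds
  lens <- if (n > 0)
    config$len_range[1] +
      sample.int(config$len_range[2] - config$len_range[1] + 1L, n,
                 replace = TRUE) - 1L
  else integer(0)
  # disjoint sources by rejection
  src_s <- integer(n)
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:1000) {
      s <- sample.int(bg_len - lens[i], 1) - 1L
      e <- s + lens[i]
      if (nrow(occupied) == 0 ||
          all(e <= occupied[, 1] | s >= occupied[, 2])) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("cannot place SD source without overlap; reduce n_sds or lengths")
    src_s[i] <- s
    occupied <- rbind(occupied, c(s, e))
  }
  src_e <- src_s + lens
  # insertion points outside all sources
  ins_p <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:1000) {
      p <- sample.int(bg_len + 1L, 1) - 1L
      if (all(p <= src_s | p >= src_e)) { ok <- TRUE; break }
    }
    if (!ok) stop("cannot place SD copy; reduce n_sds")
    ins_p[i] <- p
  }
  bg <- random_dna(bg_len)
  strands <- ifelse(runif(n) < config$inverted_frac, "-", "+")
  copies <- character(n)
  errs <- numeric(n)
  for (i in seq_len(n)) {
    m <- mutate_copy(substr(bg, src_s[i] + 1L, src_e[i]),
                     config$eps_P, config$eps_B)
    copies[i] <- if (strands[i] == "-") revcomp(m$seq) else m$seq
    errs[i] <- m$err
  }
  # splice copies into the background, ordered by insertion point
  o <- order(ins_p, seq_len(max(n, 1L))[seq_len(n)])
  parts <- character(0)
  cur <- 0L
  copy_s <- integer(n)
  shift <- 0L
  for (i in o) {
    parts <- c(parts, substr(bg, cur + 1L, ins_p[i]))
    copy_s[i] <- ins_p[i] + shift
    parts <- c(parts, copies[i])
    shift <- shift + nchar(copies[i])
    cur <- ins_p[i]
  }
  parts <- c(parts, substr(bg, cur + 1L, bg_len))
  final <- paste(parts, collapse = "")
  # final source coordinates: shifted by copies inserted at or before them
  src_shift <- vapply(seq_len(max(n, 1L))[seq_len(n)], function(i)
    sum(nchar(copies)[ins_p <= src_s[i]]), numeric(1))
  truth <- data.frame(chrom = rep("chrS", n),
                      src_start = as.integer(src_s + src_shift),
                      src_end = as.integer(src_e + src_shift),
                      copy_start = copy_s,
                      copy_end = copy_s + nchar(copies),
                      strand = strands, len = lens, realized_err = errs,
                      stringsAsFactors = FALSE)
  genome <- masked_genome(c(chrS = final), name = "sim", mask_policy = "none")
  list(genome = genome, truth = truth)
}

#' Score detection sensitivity against a planted truth set
#'
#' A planted SD counts as detected when a single reported SD call covers
#' more than `cov_thresh` of its basepairs: one call interval must cover
#' the source segment and the other the copy (either assignment, either
#' orientation), each above the threshold.
#'
#' @param truth truth data frame from [simulate_genome()].
#' @param calls an `sd_calls` data frame.
#' @param cov_thresh coverage threshold (default 0.9, strict inequality).
#' @return fraction detected; `attr(, "detected")` is the per-SD logical.
#' @export
evaluate_sensitivity <- function(truth, calls, cov_thresh = 0.9) {
  if (nrow(truth) == 0) return(structure(NaN, detected = logical(0)))
  covfrac <- function(s1, e1, s2, e2) {
    pmax(0, pmin(e1, e2) - pmax(s1, s2)) / pmax(1, e2 - s2)
  }
  det <- vapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    on <- calls$chrom_a == t$chrom & calls$chrom_b == t$chrom
    if (!any(on)) return(FALSE)
    c1 <- covfrac(calls$start_a[on], calls$end_a[on], t$src_start, t$src_end)
    c2 <- covfrac(calls$start_b[on], calls$end_b[on], t$copy_start, t$copy_end)
    c3 <- covfrac(calls$start_a[on], calls$end_a[on], t$copy_start, t$copy_end)
    c4 <- covfrac(calls$start_b[on], calls$end_b[on], t$src_start, t$src_end)
    any(pmin(c1, c2) > cov_thresh | pmin(c3, c4) > cov_thresh)
  }, logical(1))
  structure(mean(det), detected = det)
}
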
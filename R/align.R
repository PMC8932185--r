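#' Anchor chaining between two candidate regions
#'
#' Shared k-mers between the regions become anchors; the maximum-cardinality
#' strictly colinear chain is extracted by an O(n log n)
#' longest-increasing-subsequence sweep, split where the gap on either axis
#' exceeds `gap_split`, and the procedure repeats on the remaining anchors
#' so that several separate duplications inside one region pair are each
#' chained.
#'
#' @param region_a,region_b residue strings.
#' @param k_align anchoring k-mer length (default 10).
#' @param gap_split maximum within-chain gap on either axis (default 600:
#'   larger than any single block edit under the error model, smaller than
#'   chance-anchor hops between distinct duplications).
#' @param min_anchors minimum anchors per emitted chain.
#' @param max_occ per-k-mer occurrence cap for anchors.
#' @param exclude_diag optional `c(offset, halfwidth)`: drop anchors with
#'   `|(pos_a - pos_b) - offset| < halfwidth`. Used when the two regions
#'   overlap on the genome, so the trivial self-identity diagonal (which
#'   cannot belong to a valid SD, whose paralogs overlap at most
#'   `eps * n`) does not mask the real duplication.
#' @return list of anchor chains; each chain is a two-column matrix of
#'   0-based `(pos_a, pos_b)` anchor starts, sorted.
#' @export
chain_anchors <- function(region_a, region_b, k_align = 10, gap_split = 600,
                          min_anchors = 3, max_occ = 100,
                          exclude_diag = NULL) {
  an <- cpp_anchors(region_a, region_b, as.integer(k_align),
                    as.integer(max_occ))
  if (!is.null(exclude_diag) && nrow(an) > 0) {
    d <- an[, 1] - an[, 2]
    an <- an[abs(d - exclude_diag[1]) >= exclude_diag[2], , drop = FALSE]
  }
  if (nrow(an) == 0) return(list())
  cpp_chain_anchors(an, as.integer(k_align), as.integer(gap_split),
                    as.integer(min_anchors))
}

# bases on the a-axis covered by the anchors of a chain (overlaps collapsed)
chain_anchored_bases <- function(chain, k) {
  if (nrow(chain) == 0) return(0L)
  s <- chain[, 1]
  e <- chain[, 1] + k
  tot <- 0L; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) cur_e <- max(cur_e, e[i])
    else { tot <- tot + (cur_e - cur_s); cur_s <- s[i]; cur_e <- e[i] }
  }
  tot + (cur_e - cur_s)
}

#' Alignment scoring parameters
#'
#' Symmetric, edit-like scoring so that the reported error stays close to a
#' normalized edit distance: match +1, mismatch -1, gap open -2, gap extend
#' -1; the banded DP uses a band of `2 * delta` around the anchor-chain
#' diagonal.
#' @param match,mismatch,gap_open,gap_ext alignment scores.
#' @param band_radius half-width of the alignment band (bases).
#' @param min_anchor_bases minimum anchored bases (overlaps collapsed) a
#'   tier-2 chain needs before refinement. A guard against chance anchor
#'   chains only: at 25% divergence a true 1 Kbp SD still anchors roughly
#'   450 bases, while random region pairs essentially never chain 200; the
#'   SD length floor itself is enforced on the refined alignment.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                          gap_ext = -1, band_radius = 500,
                          min_anchor_bases = 200) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext, band_radius = as.integer(band_radius),
       min_anchor_bases = as.integer(min_anchor_bases))
}

#' Refine an anchor chain into an alignment
#'
#' Closes the inter-anchor gaps with banded affine dynamic programming along
#' the chain diagonal, then trims the boundaries to the longest contiguous
#' alignment window whose error rate stays within `eps`, clamped to the
#' anchor-chain footprint (random flanking sequence carries no anchors, so
#' it cannot inflate the call). Leading/trailing gap columns are dropped.
#' Returns the trimmed alignment with its CIGAR, edit distance `E`,
#' alignment length `ell` and `err = E / ell`, in region-local coordinates.
#'
#' @param chain anchor matrix from [chain_anchors()].
#' @param region_a,region_b residue strings.
#' @param scoring an [align_scoring()] list.
#' @param eps error-rate ceiling used for boundary trimming.
#' @param anchor_k k-mer length the chain anchors were built with.
#' @return list with `a_start, a_end, b_start, b_end, cigar, E, ell, err,
#'   score` or `NULL` if no alignment window survives.
#' @export
refine_alignment <- function(chain, region_a, region_b,
                             scoring = align_scoring(), eps = 0.25,
                             anchor_k = 10) {
  r <- cpp_align_banded(region_a, region_b, chain, scoring$band_radius,
                        eps, as.integer(anchor_k),
                        scoring$match, scoring$mismatch, scoring$gap_open,
                        scoring$gap_ext)
  if (is.null(r$a_start)) return(NULL)
  r
}

#' Validate an SD record against the SD definition
#'
#' A paralog pair is a valid SD iff its edit error does not exceed `eps`,
#' its optimal alignment length `ell` is at least 1000, and (for
#' same-chromosome intra-genome pairs) the two intervals overlap by at most
#' `eps * n` bases with `n` the smaller span.
#'
#' @param record one-row `sd_calls` data frame (or list with the same
#'   fields).
#' @param model an [error_model()].
#' @param min_len SD length floor on `ell`.
#' @return list with `accept` (logical) and `reason` (`"ok"`, `"error"`,
#'   `"length"` or `"overlap"`).
#' @export
validate_sd <- function(record, model = error_model(), min_len = 1000) {
  if (record$edit_error > model$eps)
    return(list(accept = FALSE, reason = "error"))
  if (record$aln_len < min_len)
    return(list(accept = FALSE, reason = "length"))
  if (identical(record$genome_a, record$genome_b) &&
      identical(record$chrom_a, record$chrom_b)) {
    ov <- max(0L, min(record$end_a, record$end_b) -
                max(record$start_a, record$start_b))
    n <- min(record$end_a - record$start_a, record$end_b - record$start_b)
    if (ov > model$eps * n)
      return(list(accept = FALSE, reason = "overlap"))
  }
  list(accept = TRUE, reason = "ok")
}

# Align one putative candidate into zero or more validated SD records.
# Two-tiered: tier 1 chains search-k anchors to split the (flank-extended)
# region pair into alignable sub-pairs; tier 2 re-anchors each sub-pair at
# k_align and refines with banded DP.
align_candidate <- function(cand, genome_a, genome_b, model, params,
                            k_search = 14, k_align = 10,
                            scoring = align_scoring(), min_len = 1000) {
  la <- nchar(genome_a$seq[[cand$chrom_a]])
  lb <- nchar(genome_b$seq[[cand$chrom_b]])
  ea_s <- max(0L, cand$start_a - params$extend)
  ea_e <- min(la, cand$end_a + params$extend)
  eb_s <- max(0L, cand$start_b - params$extend)
  eb_e <- min(lb, cand$end_b + params$extend)
  rc <- cand$strand_b == "-"
  sa <- extract_seq(genome_a, cand$chrom_a, ea_s, ea_e)
  sb <- extract_seq(genome_b, cand$chrom_b, eb_s, eb_e, rc = rc)
  score_floor <- scoring$min_anchor_bases
  # when the two (flank-extended) regions overlap on the genome, ban the
  # self-identity diagonal: anchors there map a position onto itself
  excl <- NULL
  if (!rc && identical(cand$genome_a, cand$genome_b) &&
      cand$chrom_a == cand$chrom_b && ea_s < eb_e && eb_s < ea_e) {
    excl <- c(eb_s - ea_s, 500L)
  }
  out <- list()
  tier1 <- chain_anchors(sa, sb, k_align = k_search,
                         gap_split = params$extend, min_anchors = 2,
                         max_occ = 100, exclude_diag = excl)
  if (length(tier1) == 0) return(out)
  for (t1 in tier1) {
    # sub-pair bounding box with a delta margin
    a0 <- max(0L, min(t1[, 1]) - params$delta)
    a1 <- min(nchar(sa), max(t1[, 1]) + k_search + params$delta)
    b0 <- max(0L, min(t1[, 2]) - params$delta)
    b1 <- min(nchar(sb), max(t1[, 2]) + k_search + params$delta)
    sub_a <- substr(sa, a0 + 1L, a1)
    sub_b <- substr(sb, b0 + 1L, b1)
    excl2 <- if (is.null(excl)) NULL else c(excl[1] + (b0 - a0), excl[2])
    # gap_split 600: wider than any single block edit the error model admits
    # (block lengths are capped at 5% of the SD, at most 500 bases), yet too
    # narrow for sparse chance anchors to chain two distinct nearby SDs into
    # one chimeric alignment
    tier2 <- chain_anchors(sub_a, sub_b, k_align = k_align,
                           gap_split = 600, min_anchors = 3, max_occ = 100,
                           exclude_diag = excl2)
    for (ch in tier2) {
      if (chain_anchored_bases(ch, k_align) < score_floor) next
      aln <- refine_alignment(ch, sub_a, sub_b, scoring, eps = model$eps,
                              anchor_k = k_align)
      if (is.null(aln)) next
      # map back to assembly coordinates
      ga_s <- ea_s + a0 + aln$a_start
      ga_e <- ea_s + a0 + aln$a_end
      if (!rc) {
        gb_s <- eb_s + b0 + aln$b_start
        gb_e <- eb_s + b0 + aln$b_end
      } else {
        # sb is the reverse complement of [eb_s, eb_e)
        n_b <- nchar(sb)
        gb_s <- eb_s + (n_b - (b0 + aln$b_end))
        gb_e <- eb_s + (n_b - (b0 + aln$b_start))
      }
      rec <- data.frame(chrom_a = cand$chrom_a, start_a = ga_s, end_a = ga_e,
                        chrom_b = cand$chrom_b, start_b = gb_s, end_b = gb_e,
                        strand_b = cand$strand_b,
                        aln_len = aln$ell, edit_error = aln$err,
                        cigar = aln$cigar,
                        genome_a = cand$genome_a, genome_b = cand$genome_b,
                        stringsAsFactors = FALSE)
      v <- validate_sd(rec, model, min_len = min_len)
      if (v$accept) out[[length(out) + 1L]] <- rec
    }
  }
  out
}

#' Align and validate putative SDs into final SD calls
#'
#' Runs the two-tiered chain-and-align refinement on every putative
#' candidate and keeps the records that satisfy the SD definition
#' (`err <= eps`, `ell >= 1000`, overlap rule), in canonical order.
#'
#' @param cands putative-SD data frame.
#' @param genome the `masked_genome` for side a (and side b when
#'   `genome_b` is omitted).
#' @param model an [error_model()].
#' @param params a [sweep_params()].
#' @param genome_b optional second genome for cross-genome candidates.
#' @param scoring an [align_scoring()].
#' @param min_len SD alignment length floor.
#' @return an `sd_calls` data frame.
#' @export
align_putative <- function(cands, genome, model = error_model(),
                           params = sweep_params(), genome_b = genome,
                           scoring = align_scoring(), min_len = 1000) {
  recs <- list()
  for (i in seq_len(nrow(cands))) {
    recs <- c(recs, align_candidate(cands[i, ], genome, genome_b, model,
                                    params, scoring = scoring,
                                    min_len = min_len))
  }
  if (length(recs) == 0) return(sd_calls())
  df <- do.call(rbind, recs)
  df <- canonicalize_calls(df)
  class(df) <- c("sd_calls", "data.frame")
  df
}
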
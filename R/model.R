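#' The two-component SD error model
#'
#' Divergence between SD paralogs is modelled as the sum of two independent
#' processes: background point mutations (paralogous sequence variants,
#' PSVs) at rate `eps_P`, assumed Poisson with per-k-mer parameter
#' `lambda = k * eps_P`, and clustered block edits at rate `eps_B`. The two
#' rates are additive: `eps = eps_P + eps_B`.
#'
#' @param eps total error threshold (default 0.25, i.e. 75% identity).
#' @param eps_P point-mutation rate (default 0.15).
#' @param eps_B block-edit rate (default `eps - eps_P`).
#' @param block_event_prob per-position probability of a large block event
#'   (default 0.005).
#' @param k k-mer length used when deriving `lambda`.
#' @return an `error_model` list with the rates, `lambda` and the k-mer
#'   preservation probability.
#' @export
error_model <- function(eps = 0.25, eps_P = 0.15, eps_B = eps - eps_P,
                        block_event_prob = 0.005, k = 14) {
  stopifnot(eps_P >= 0, eps_B >= 0, block_event_prob >= 0,
            block_event_prob <= 1)
  if (abs(eps - (eps_P + eps_B)) > 1e-9)
    stop("eps must equal eps_P + eps_B (the two rates are additive)")
  structure(list(eps = eps, eps_P = eps_P, eps_B = eps_B,
                 block_event_prob = block_event_prob,
                 k = as.integer(k), lambda = k * eps_P,
                 preservation = exp(-k * eps_P)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("error_model: eps=%.3f (eps_P=%.3f + eps_B=%.3f), lambda=k*eps_P=%.3f, P(k-mer preserved)=%.4f\n",
              x$eps, x$eps_P, x$eps_B, x$lambda, x$preservation))
  invisible(x)
}

#' Lower bound on the expected Jaccard index of SD paralogs
#'
#' For paralogs diverged under the two-component error model, the expected
#' Jaccard index of their k-mer sets is bounded below by
#' `((1 - eps_B) / (1 + eps_B)) * 1 / (2 * exp(k * eps_P) - 1)`. This bound
#' is the acceptance threshold `tau` of the plane sweep.
#'
#' @param k k-mer length.
#' @param eps_P point-mutation rate.
#' @param eps_B block-edit rate.
#' @return `tau` in `[0, 1]`.
#' @export
tau_lower_bound <- function(k, eps_P, eps_B) {
  stopifnot(k >= 1, eps_P >= 0, eps_P < 1, eps_B >= 0, eps_B < 1)
  ((1 - eps_B) / (1 + eps_B)) * 1 / (2 * exp(k * eps_P) - 1)
}

#' Probability that a k-mer survives point mutation
#'
#' Under the Poisson PSV model a k-mer accumulates on average `k * eps_P`
#' mutations, so it is preserved in both paralogs with probability
#' `exp(-k * eps_P)`.
#'
#' @inheritParams tau_lower_bound
#' @return probability in `[0, 1]`.
#' @export
kmer_preservation_prob <- function(k, eps_P) {
  stopifnot(k >= 1, eps_P >= 0, eps_P < 1)
  exp(-k * eps_P)
}

#' Maximum colinear k-mer matching size
#'
#' The size of the largest set of index pairs `(i, j)` such that the k-mers
#' at `i` in `s` and `j` in `s_prime` are identical and no two pairs cross
#' over. When k-mers repeat, every occurrence pair is a matching candidate
#' and a longest-increasing-subsequence chain picks a consistent subset
#' (O(m log m) in the number of candidate pairs).
#'
#' @param s,s_prime residue strings.
#' @param k k-mer length.
#' @param max_occ per-k-mer occurrence cap for candidate pairs.
#' @return integer matching size.
#' @export
colinear_match_size <- function(s, s_prime, k, max_occ = 1000) {
  cpp_ordered_jaccard(s, s_prime, as.integer(k), as.integer(max_occ))$shared
}

#' Ordered Jaccard index
#'
#' `J_hat(s, s') = (s (*) s') / |K(s) union K(s')|`: the maximum colinear
#' k-mer matching size over the set union of k-mers. Under the error model's
#' assumptions (no repeated k-mers within either string; shared k-mers
#' shared since the copy event) it equals the classical Jaccard index while
#' excluding cross-over matches that no alignment could realize. Defined as
#' 0 when neither string has a valid k-mer.
#'
#' @inheritParams colinear_match_size
#' @return `J_hat` in `[0, 1]`.
#' @export
ordered_jaccard <- function(s, s_prime, k, max_occ = 1000) {
  cpp_ordered_jaccard(s, s_prime, as.integer(k), as.integer(max_occ))$jaccard
}

#' Edit error between two sequences
#'
#' `err(s, s') = E / ell` where `E` is the Levenshtein distance and `ell`
#' the length of the corresponding optimal alignment (matches + mismatches +
#' gaps). Among co-optimal alignments the one with the fewest gaps (the
#' shortest alignment) is taken, so `err` is deterministic and conservative.
#'
#' @param s,s_prime non-empty residue strings.
#' @return list with `err`, `aln_len` (`ell`), `E` and `cigar`
#'   (`=`/`X`/`I`/`D` run-length operations).
#' @export
edit_error <- function(s, s_prime) {
  if (nchar(s) == 0 || nchar(s_prime) == 0) stop("sequences must be non-empty")
  r <- cpp_edit_dist(s, s_prime)
  list(err = r$err, aln_len = r$ell, E = r$E, cigar = r$cigar)
}
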
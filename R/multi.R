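#' Detect SDs in a single genome
#'
#' Composes the full single-genome pipeline: winnowed index construction
#' (forward and, unless `forward_only`, reverse-complement), plane sweep,
#' merge of nearby candidates, two-tiered chain-and-align refinement, and
#' SD-definition validation. Deterministic for fixed inputs.
#'
#' @param genome a `masked_genome`.
#' @param model an [error_model()].
#' @param kp search-phase [kmer_params()] (k = 14, w = 16 by default).
#' @param params a [sweep_params()].
#' @param forward_only skip the reverse-complement index (no inverted SDs).
#' @param scoring an [align_scoring()].
#' @param min_len SD alignment length floor (1000).
#' @return an `sd_calls` data frame.
#' @export
run_single <- function(genome, model = error_model(), kp = kmer_params(),
                       params = sweep_params(), forward_only = FALSE,
                       scoring = align_scoring(), min_len = 1000) {
  model <- error_model(model$eps, model$eps_P, model$eps_B,
                       model$block_event_prob, k = kp$k)
  idx <- build_index(genome, kp)
  rc_idx <- if (forward_only) NULL else build_index(genome, kp, rc = TRUE)
  cands <- plane_sweep(idx, genome, params, model, rc_index = rc_idx)
  cands <- merge_putative(cands, params, genome, model, k = kp$k)
  align_putative(cands, genome, model, params, scoring = scoring,
                 min_len = min_len)
}

# unique merged paralog intervals of a call set (both sides)
sd_paralog_regions <- function(calls) {
  if (nrow(calls) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  iv <- rbind(data.frame(chrom = calls$chrom_a, start = calls$start_a,
                         end = calls$end_a, stringsAsFactors = FALSE),
              data.frame(chrom = calls$chrom_b, start = calls$start_b,
                         end = calls$end_b, stringsAsFactors = FALSE))
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv$chrom[i] == out$chrom[last] && iv$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], iv$end[i])
    } else out <- rbind(out, iv[i, ])
  }
  rownames(out) <- NULL
  out
}

#' Detect and cross-map SDs across multiple genomes
#'
#' Runs [run_single()] on every genome independently, then maps the SD
#' paralogs of each genome onto every other genome with [cross_sweep()]
#' followed by the same chain-and-align validation (the SD definition is
#' re-applied to cross-genome hits). A failure in one genome isolates: the
#' remaining genomes still complete and the result is marked partial.
#'
#' @param genomes named list of `masked_genome` objects.
#' @param model an [error_model()].
#' @param kp search-phase [kmer_params()].
#' @param params a [sweep_params()].
#' @param forward_only skip reverse-complement indices.
#' @param min_len SD length floor.
#' @return list with `per_genome` (named list of `sd_calls`), `cross` (one
#'   `sd_calls` of cross-genome records, `genome_a != genome_b`) and
#'   `partial` (logical).
#' @export
run_multi <- function(genomes, model = error_model(), kp = kmer_params(),
                      params = sweep_params(), forward_only = FALSE,
                      min_len = 1000) {
  stopifnot(length(genomes) >= 1)
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$name, character(1))
  partial <- FALSE
  per <- lapply(genomes, function(g) {
    tryCatch(run_single(g, model, kp, params, forward_only, min_len = min_len),
             error = function(e) {
               warning("genome '", g$name, "' failed: ", conditionMessage(e))
               partial <<- TRUE
               NULL
             })
  })
  cross <- sd_calls()
  if (length(genomes) >= 2) {
    idxs <- lapply(genomes, function(g) build_index(g, kp))
    rcs <- if (forward_only) NULL else lapply(genomes, function(g) build_index(g, kp, rc = TRUE))
    for (i in names(genomes)) {
      if (is.null(per[[i]]) || nrow(per[[i]]) == 0) next
      regions <- sd_paralog_regions(per[[i]])
      for (j in names(genomes)) {
        if (i == j) next
        cands <- cross_sweep(idxs[[j]], regions, genomes[[i]], genomes[[j]],
                             params, model,
                             rc_index_a = if (forward_only) NULL else rcs[[j]])
        if (nrow(cands) == 0) next
        cc <- align_putative(cands, genomes[[i]], model, params,
                             genome_b = genomes[[j]], min_len = min_len)
        if (nrow(cc) > 0) cross <- rbind(cross, cc)
      }
    }
    if (nrow(cross) > 0) {
      cross <- canonicalize_calls(as.data.frame(cross))
      class(cross) <- c("sd_calls", "data.frame")
    }
  }
  list(per_genome = per, cross = cross, partial = partial)
}
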
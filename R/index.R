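#' k-mer and winnowing parameters
#'
#' @param k k-mer length. 14 for the putative-SD search; 10 for alignment
#'   anchoring and decomposition.
#' @param w winnowing window, in k-mers. The fingerprint keeps in each window
#'   of `w` consecutive k-mers the lexicographically smallest one (rightmost
#'   on ties), giving an expected density of `2/(w+1)`.
#' @param max_freq occurrence cap: k-mers occurring more often than this in
#'   the fingerprint are dropped from the index (hyper-repetitive leftovers
#'   that survive hard-masking).
#' @return a `kmer_params` list.
#' @export
kmer_params <- function(k = 14, w = 16, max_freq = 1000) {
  stopifnot(k >= 2, w >= 1, max_freq >= 1)
  structure(list(k = as.integer(k), w = as.integer(w),
                 max_freq = as.integer(max_freq)),
            class = "kmer_params")
}

#' Encode the valid k-mers of a sequence
#'
#' Packs each k-mer 2 bits per residue with `A < C < G < T`, so integer order
#' on codes equals lexicographic order on residues. Windows containing a
#' masked residue or `N` yield no k-mer.
#'
#' @param seq residue string.
#' @param k k-mer length.
#' @param mask optional logical vector flagging masked positions.
#' @return data frame with `pos` (0-based start) and `code`.
#' @export
encode_kmers <- function(seq, k, mask = NULL) {
  if (is.null(mask)) mask <- logical(0)
  r <- cpp_encode_kmers(seq, mask, as.integer(k))
  data.frame(pos = r$pos, code = r$code)
}

#' Winnow a k-mer sequence
#'
#' Streaming minimizer selection: the union, over every window of `w`
#' consecutive k-mers, of the window's minimal k-mer under a fixed
#' pseudo-random canonical order (a bit-mix of the packed code), rightmost
#' on ties. A pseudo-random order keeps the expected fingerprint density at
#' `2/(w+1)`; raw lexicographic rank would inflate it by roughly 10%
#' because overlapping low-rank k-mers correlate. With fewer than `w`
#' k-mers a single window covers all of them.
#'
#' @param kmers data frame from [encode_kmers()] (position-sorted).
#' @param w window size in k-mers.
#' @return the selected subset of `kmers`, sorted and deduplicated.
#' @export
winnow <- function(kmers, w) {
  if (nrow(kmers) == 0) return(kmers)
  sel <- cpp_winnow(kmers$code, as.integer(w)) + 1L
  kmers[sel, , drop = FALSE]
}

#' Build the winnowed k-mer index of a genome
#'
#' Computes the winnowing fingerprint of every chromosome (masked residues
#' and `N` excluded) and indexes the selected k-mers by code. Positions are
#' globalized by cumulative chromosome offsets so a multi-chromosome genome
#' is swept as one string; k-mers never span chromosome boundaries.
#'
#' @param genome a `masked_genome`.
#' @param params a [kmer_params()] object.
#' @param rc if `TRUE`, index the reverse complement of each chromosome
#'   (fingerprint positions are in reverse-complement coordinates); used to
#'   discover inverted duplications.
#' @return a `winnow_index`: list with `params`, `pos` (sorted global
#'   fingerprint positions), `code`, `chroms` (offset table),
#'   `fingerprint_size`, `n_kmers` (valid k-mers before winnowing), and `rc`.
#' @export
build_index <- function(genome, params = kmer_params(), rc = FALSE) {
  stopifnot(inherits(genome, "masked_genome"))
  lens <- nchar(genome$seq)
  offs <- cumsum(c(0, as.numeric(lens)))[seq_along(lens)]
  pos <- integer(0); code <- numeric(0); nk <- 0
  for (i in seq_along(genome$seq)) {
    s <- genome$seq[[i]]
    m <- genome$mask[[i]]
    if (rc) { s <- revcomp(s); m <- rev(m) }
    km <- encode_kmers(s, params$k, m)
    nk <- nk + nrow(km)
    wn <- winnow(km, params$w)
    pos <- c(pos, wn$pos + as.integer(offs[i]))
    code <- c(code, wn$code)
  }
  structure(list(params = params, pos = pos, code = code,
                 chroms = data.frame(chrom = names(genome$seq),
                                     offset = as.integer(offs),
                                     length = as.integer(lens),
                                     stringsAsFactors = FALSE),
                 fingerprint_size = length(pos), n_kmers = nk,
                 rc = rc, genome_name = genome$name),
            class = "winnow_index")
}

#' @export
print.winnow_index <- function(x, ...) {
  cat("winnow_index of '", x$genome_name, "'",
      if (x$rc) " (reverse complement)", ": k=", x$params$k,
      ", w=", x$params$w, ", ", x$fingerprint_size, " fingerprint k-mers of ",
      x$n_kmers, " (density ", sprintf("%.4f", x$fingerprint_size / max(1, x$n_kmers)),
      ")\n", sep = "")
  invisible(x)
}

#' Look up the indexed positions of one k-mer code
#' @param index a `winnow_index`.
#' @param code packed k-mer code.
#' @return sorted integer positions (global coordinates).
#' @export
index_lookup <- function(index, code) {
  sort(index$pos[index$code == code])
}

# full (non-winnowed) k-mer stream of a genome in global coordinates; the
# sweep queries every valid k-mer position against the winnowed index
kmer_stream <- function(genome, k, rc = FALSE) {
  lens <- nchar(genome$seq)
  offs <- cumsum(c(0, as.numeric(lens)))[seq_along(lens)]
  pos <- integer(0); code <- numeric(0)
  for (i in seq_along(genome$seq)) {
    s <- genome$seq[[i]]
    m <- genome$mask[[i]]
    if (rc) { s <- revcomp(s); m <- rev(m) }
    km <- encode_kmers(s, k, m)
    pos <- c(pos, km$pos + as.integer(offs[i]))
    code <- c(code, km$code)
  }
  list(pos = pos, code = code)
}

# map global positions to (chrom, local) given an index/chrom table
global_to_local <- function(chroms, gpos) {
  i <- findInterval(gpos, chroms$offset)
  data.frame(chrom = chroms$chrom[i], local = gpos - chroms$offset[i],
             stringsAsFactors = FALSE)
}
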
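#' Decomposition parameters
#'
#' @param k k-mer length for the decomposition sweep (default 10; the index
#'   here is full, not winnowed).
#' @param d_g chaining distance: two k-mer locations chain when within
#'   `d_g` bases, and a putative elementary SD with no appended location for
#'   `d_g` bases of sweep progress is retired. 50 is large enough to absorb
#'   PSVs and small gaps while covering elementary SDs of 100 bp and more.
#' @param mu minimum elementary-SD length (default 100 bp); shorter members
#'   are discarded at emission.
#' @export
decompose_params <- function(k = 10, d_g = 50, mu = 100) {
  stopifnot(d_g > 0, mu >= k)
  structure(list(k = as.integer(k), d_g = as.integer(d_g),
                 mu = as.integer(mu)),
            class = "decompose_params")
}

#' Cluster SDs by paralog-interval overlap
#'
#' Union-find over all paralog intervals: any two SDs sharing at least one
#' overlapping paralog interval end up in the same cluster (transitive
#' closure). Each cluster carries its merged genomic region set, the input
#' to the per-cluster decomposition sweep.
#'
#' @param records an `sd_calls` data frame.
#' @return list of clusters; each has `members` (record row indices) and
#'   `regions` (data frame `genome, chrom, start, end, strand` of merged
#'   intervals; a region's orientation is that of the first paralog
#'   contributing to it).
#' @export
cluster_sds <- function(records) {
  n <- nrow(records)
  if (n == 0) return(list())
  iv <- rbind(
    data.frame(rec = seq_len(n), genome = records$genome_a,
               chrom = records$chrom_a, start = records$start_a,
               end = records$end_a, strand = "+", stringsAsFactors = FALSE),
    data.frame(rec = seq_len(n), genome = records$genome_b,
               chrom = records$chrom_b, start = records$start_b,
               end = records$end_b, strand = records$strand_b,
               stringsAsFactors = FALSE))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  o <- order(iv$genome, iv$chrom, iv$start)
  iv <- iv[o, ]
  # sweep intervals per (genome, chrom): union records of overlapping intervals
  prev_end <- -1L; prev_rec <- NA_integer_; prev_key <- ""
  for (i in seq_len(nrow(iv))) {
    key <- paste0(iv$genome[i], "\r", iv$chrom[i])
    if (key == prev_key && iv$start[i] < prev_end) {
      unite(iv$rec[i], prev_rec)
      prev_end <- max(prev_end, iv$end[i])
    } else {
      prev_end <- iv$end[i]; prev_key <- key
    }
    prev_rec <- iv$rec[i]
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split_idx <- split(seq_len(n), roots)
  lapply(unname(split_idx), function(members) {
    sub <- iv[iv$rec %in% members, , drop = FALSE]
    # merge overlapping intervals per genome/chrom, first-contributor strand
    regions <- do.call(rbind, lapply(
      split(sub, paste0(sub$genome, "\r", sub$chrom)),
      function(g) {
        g <- g[order(g$start), , drop = FALSE]
        out <- g[1, c("genome", "chrom", "start", "end", "strand"), drop = FALSE]
        if (nrow(g) > 1) for (i in 2:nrow(g)) {
          last <- nrow(out)
          if (g$start[i] <= out$end[last]) {
            out$end[last] <- max(out$end[last], g$end[i])
          } else {
            out <- rbind(out, g[i, c("genome", "chrom", "start", "end", "strand")])
          }
        }
        out
      }))
    rownames(regions) <- NULL
    list(members = members, regions = regions)
  })
}

#' Decompose one SD cluster into elementary SD sets
#'
#' Builds a full k-mer index over the cluster's merged regions and sweeps
#' them left to right, chaining identical k-mers whose locations stay
#' within `d_g`; a change in the number of co-extending copies closes the
#' current putative elementary SD at that boundary and opens a new one, and
#' a retired element emits all member intervals of length at least `mu` as
#' one elementary-SD set. Members on minus-strand regions are tracked in
#' reverse-complement space and reported with strand `-`.
#'
#' @param cluster one element of [cluster_sds()] output.
#' @param genomes named list of `masked_genome` objects (or a single
#'   genome).
#' @param params a [decompose_params()].
#' @param first_set_id id of the first emitted set.
#' @return data frame `set_id, genome, chrom, start, end, strand`.
#' @export
decompose_cluster <- function(cluster, genomes, params = decompose_params(),
                              first_set_id = 1L) {
  if (inherits(genomes, "masked_genome"))
    genomes <- stats::setNames(list(genomes), genomes$name)
  rg <- cluster$regions
  if (is.null(rg) || nrow(rg) == 0) return(empty_elementary())
  seqs <- character(nrow(rg))
  for (i in seq_len(nrow(rg))) {
    seqs[i] <- extract_seq(genomes[[rg$genome[i]]], rg$chrom[i],
                           rg$start[i], rg$end[i], rc = rg$strand[i] == "-")
  }
  sets <- cpp_decompose(seqs, params$k, params$d_g, params$mu)
  if (length(sets) == 0) return(empty_elementary())
  out <- vector("list", length(sets))
  for (s in seq_along(sets)) {
    m <- sets[[s]]
    r <- m[, 1] + 1L
    loc_s <- m[, 2]; loc_e <- m[, 3]
    minus <- rg$strand[r] == "-"
    len <- rg$end[r] - rg$start[r]
    gs <- ifelse(minus, rg$start[r] + (len - loc_e), rg$start[r] + loc_s)
    ge <- ifelse(minus, rg$start[r] + (len - loc_s), rg$start[r] + loc_e)
    out[[s]] <- data.frame(set_id = first_set_id + s - 1L,
                           genome = rg$genome[r], chrom = rg$chrom[r],
                           start = as.integer(gs), end = as.integer(ge),
                           strand = ifelse(minus, "-", "+"),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

empty_elementary <- function() {
  data.frame(set_id = integer(), genome = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Decompose a set of SD calls into elementary SDs
#'
#' Clusters overlapping SDs with union-find and decomposes each cluster
#' independently (results do not depend on cluster processing order).
#'
#' @param records an `sd_calls` data frame.
#' @param genomes a `masked_genome` or named list of them.
#' @param params a [decompose_params()].
#' @return data frame `set_id, genome, chrom, start, end, strand` of all
#'   elementary-SD members; `attr(, "clusters")` holds the clustering.
#' @export
decompose_sds <- function(records, genomes, params = decompose_params()) {
  clusters <- cluster_sds(records)
  out <- empty_elementary()
  nid <- 1L
  for (cl in clusters) {
    r <- decompose_cluster(cl, genomes, params, first_set_id = nid)
    if (nrow(r) > 0) nid <- max(r$set_id) + 1L
    out <- rbind(out, r)
  }
  attr(out, "clusters") <- clusters
  out
}

#' Select core duplicons by greedy set cover
#'
#' Core duplicons are the minimal subset of elementary-SD sets covering all
#' SDs, where an SD is covered by a set if either of its paralogs overlaps a
#' member of that set. The classical greedy approximation repeatedly picks
#' the set covering the most still-uncovered SDs (ties: larger total member
#' span, then lower `set_id`). SDs covered by no set are reported
#' uncoverable and excluded from the universe with a warning.
#'
#' @param sets elementary-set data frame from [decompose_sds()].
#' @param records the `sd_calls` the sets decompose.
#' @return the selected subset of `sets`; `attr(, "core_ids")` gives the
#'   chosen set ids and `attr(, "uncovered")` any uncoverable record
#'   indices.
#' @export
core_duplicons <- function(sets, records) {
  if (nrow(records) == 0 || nrow(sets) == 0) {
    out <- sets[integer(0), , drop = FALSE]
    attr(out, "core_ids") <- integer(0)
    attr(out, "uncovered") <- integer(0)
    return(out)
  }
  overlaps <- function(g, ch, s, e) {
    sets$genome == g & sets$chrom == ch & sets$start < e & sets$end > s
  }
  cover <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    hit <- overlaps(r$genome_a, r$chrom_a, r$start_a, r$end_a) |
      overlaps(r$genome_b, r$chrom_b, r$start_b, r$end_b)
    sort(unique(sets$set_id[hit]))
  })
  uncoverable <- which(lengths(cover) == 0)
  if (length(uncoverable) > 0)
    warning(length(uncoverable), " SD record(s) covered by no elementary set; excluded")
  universe <- setdiff(seq_len(nrow(records)), uncoverable)
  span <- tapply(sets$end - sets$start, sets$set_id, sum)
  chosen <- integer(0)
  uncovered <- universe
  while (length(uncovered) > 0) {
    ids <- sort(unique(unlist(cover[uncovered])))
    gain <- vapply(ids, function(id)
      sum(vapply(cover[uncovered], function(cc) id %in% cc, logical(1))),
      integer(1))
    sp <- as.numeric(span[as.character(ids)])
    o <- order(-gain, -sp, ids)
    pick <- ids[o[1]]
    chosen <- c(chosen, pick)
    uncovered <- uncovered[!vapply(cover[uncovered],
                                   function(cc) pick %in% cc, logical(1))]
  }
  out <- sets[sets$set_id %in% chosen, , drop = FALSE]
  attr(out, "core_ids") <- chosen
  attr(out, "uncovered") <- uncoverable
  out
}

#' Elementary-composition distance between two regions
#'
#' `d = 1 - |A intersect B| / |A union B|` over the sets of elementary-SD
#' ids overlapping each region (overlap by any base). `d` is 0 for two
#' regions with no elementary annotation and 1 when exactly one of them has
#' none.
#'
#' @param region_x,region_y lists or one-row data frames with `genome`
#'   (optional), `chrom`, `start`, `end`.
#' @param sets elementary-set data frame.
#' @return distance in `[0, 1]`.
#' @export
composition_distance <- function(region_x, region_y, sets) {
  ids <- function(rg) {
    hit <- sets$chrom == rg$chrom & sets$start < rg$end & sets$end > rg$start
    if (!is.null(rg$genome) && "genome" %in% names(sets))
      hit <- hit & sets$genome == rg$genome
    unique(sets$set_id[hit])
  }
  a <- ids(region_x); b <- ids(region_y)
  if (length(a) == 0 && length(b) == 0) return(0)
  if (length(a) == 0 || length(b) == 0) return(1)
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param labels leaf labels.
#' @param d symmetric distance matrix (full), `length(labels)` square.
#' @return a newick string (with trailing semicolon).
#' @export
build_nj_tree <- function(labels, d) {
  d <- as.matrix(d)
  dimnames(d) <- list(labels, labels)
  tr <- ape::nj(stats::as.dist(d))
  ape::write.tree(tr)
}
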
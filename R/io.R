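#' Load a genome assembly with masking semantics
#'
#' Reads a (soft-masked) FASTA assembly. Under `mask_policy = "lowercase"`
#' every lowercase residue is flagged as masked -- the convention used by
#' repeat maskers for low-complexity and common-repeat bases -- and those
#' positions are skipped during k-mer extraction while remaining in the
#' coordinate system, so all reported intervals refer to the original
#' assembly. `N` residues are always masked. All coordinates downstream are
#' 0-based, half-open.
#'
#' @param path path to a FASTA file.
#' @param mask_policy `"lowercase"` (default) masks lowercase residues;
#'   `"none"` masks only `N`.
#' @param name assembly identifier; defaults to the file name without
#'   extension.
#' @return A `masked_genome` object: a list with `name`, `seq` (named
#'   character vector, uppercase), `mask` (list of logical vectors) and
#'   `total_unmasked`.
#' @export
load_masked_genome <- function(path, mask_policy = c("lowercase", "none"),
                               name = NULL) {
  mask_policy <- match.arg(mask_policy)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.null(name)) name <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  bad <- regexpr("[^ACGTNacgtn]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid residue in sequence '", names(seqs)[i], "' at position ",
         bad[i], " (only A/C/G/T/N and lowercase variants allowed)")
  }
  masked_genome(seqs, name = name, mask_policy = mask_policy)
}

#' Construct a masked genome from in-memory sequences
#'
#' @param seqs named character vector of sequences (may contain lowercase
#'   and `N`).
#' @param name assembly identifier.
#' @param mask_policy see [load_masked_genome()].
#' @return A `masked_genome` object.
#' @export
masked_genome <- function(seqs, name = "genome",
                          mask_policy = c("lowercase", "none")) {
  mask_policy <- match.arg(mask_policy)
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  mask <- lapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    m <- ch == "N" | ch == "n"
    if (mask_policy == "lowercase") m <- m | (ch %in% c("a", "c", "g", "t"))
    m
  })
  up <- toupper(seqs)
  g <- structure(list(name = name, seq = up, mask = mask,
                      total_unmasked = sum(lengths(mask)) - sum(unlist(lapply(mask, sum)))),
                 class = "masked_genome")
  g
}

#' @export
print.masked_genome <- function(x, ...) {
  cat("masked_genome '", x$name, "': ", length(x$seq), " sequence(s), ",
      sum(nchar(x$seq)), " bp total, ", x$total_unmasked, " unmasked\n", sep = "")
  invisible(x)
}

#' Write a masked genome back to FASTA
#'
#' Masked positions are re-lowercased, so writing and re-reading is the
#' identity on sequence content and mask flags (`N` stays `N`).
#'
#' @param genome a `masked_genome`.
#' @param path output FASTA path.
#' @export
write_masked_fasta <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seq)) {
    ch <- strsplit(genome$seq[[nm]], "", fixed = TRUE)[[1]]
    m <- genome$mask[[nm]] & ch != "N"
    ch[m] <- tolower(ch[m])
    writeLines(paste0(">", nm), con)
    s <- paste(ch, collapse = "")
    starts <- seq(1, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

sd_call_cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
                  "strand_b", "aln_len", "edit_error", "cigar",
                  "genome_a", "genome_b")

#' Create an (empty or filled) SD call table
#'
#' SD calls are plain data frames with twelve columns in a fixed paired
#' interval layout: `chrom_a start_a end_a chrom_b start_b end_b strand_b
#' aln_len edit_error cigar genome_a genome_b`. Coordinates are 0-based,
#' half-open, and records are kept in canonical order (interval a
#' lexicographically <= interval b).
#'
#' @param ... column vectors, as in `data.frame()`.
#' @return a `data.frame` with class `sd_calls`.
#' @export
sd_calls <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    df <- data.frame(chrom_a = character(), start_a = integer(), end_a = integer(),
                     chrom_b = character(), start_b = integer(), end_b = integer(),
                     strand_b = character(), aln_len = integer(),
                     edit_error = numeric(), cigar = character(),
                     genome_a = character(), genome_b = character(),
                     stringsAsFactors = FALSE)
  }
  stopifnot(identical(names(df), sd_call_cols))
  class(df) <- c("sd_calls", "data.frame")
  df
}

# canonical ordering: (genome_a, interval a) lexicographically <= b; swaps
# sides where needed and sorts rows
canonicalize_calls <- function(df) {
  if (nrow(df) == 0) return(df)
  swap <- (df$genome_a > df$genome_b) |
    (df$genome_a == df$genome_b &
       (df$chrom_a > df$chrom_b |
          (df$chrom_a == df$chrom_b &
             (df$start_a > df$start_b |
                (df$start_a == df$start_b & df$end_a > df$end_b)))))
  if (any(swap)) {
    tmp <- df[swap, c("chrom_a", "start_a", "end_a", "genome_a")]
    df[swap, c("chrom_a", "start_a", "end_a", "genome_a")] <-
      df[swap, c("chrom_b", "start_b", "end_b", "genome_b")]
    df[swap, c("chrom_b", "start_b", "end_b", "genome_b")] <- tmp
  }
  o <- order(df$genome_a, df$chrom_a, df$start_a, df$end_a,
             df$genome_b, df$chrom_b, df$start_b, df$end_b)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[, c(sd_call_cols[1:7], "genome_a", "genome_b")]), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write SD calls to a tab-separated paired-interval file
#'
#' @param records an `sd_calls` data frame (canonically ordered).
#' @param path output path.
#' @export
write_sd_calls <- function(records, path) {
  df <- as.data.frame(records)[, sd_call_cols, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sd_call_cols, collapse = "\t"), con)
  if (nrow(df) > 0)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read SD calls written by [write_sd_calls()]
#' @param path input path.
#' @return an `sd_calls` data frame.
#' @export
read_sd_calls <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "integer",
                                  "character", "integer", "numeric",
                                  "character", "character", "character"))
  names(df) <- sd_call_cols
  df$cigar[is.na(df$cigar)] <- ""
  class(df) <- c("sd_calls", "data.frame")
  df
}

#' @export
print.sd_calls <- function(x, ...) {
  cat("sd_calls: ", nrow(x), " record(s)\n", sep = "")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Write elementary-SD sets as BED6
#'
#' One line per member interval: `chrom start end setID memberCount strand`.
#'
#' @param sets elementary-set table as returned by [decompose_sds()]: a data
#'   frame with columns `set_id, chrom, start, end, strand` (optionally
#'   `genome`).
#' @param path output path.
#' @export
write_elementary_bed <- function(sets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(sets) || nrow(sets) == 0) return(invisible(path))
  support <- table(sets$set_id)
  df <- data.frame(chrom = sets$chrom, start = sets$start, end = sets$end,
                   name = paste0("set", sets$set_id),
                   score = as.integer(support[as.character(sets$set_id)]),
                   strand = sets$strand)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file written by [write_elementary_bed()]
#' @param path input path.
#' @return data frame with `chrom, start, end, set_id, support, strand`.
#' @export
read_elementary_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      set_id = integer(), support = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "support", "strand")
  df$set_id <- as.integer(sub("^set", "", df$name))
  df[, c("chrom", "start", "end", "set_id", "support", "strand")]
}
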
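#' Quality-trim a single read
#'
#' Trims bases one at a time from the 3' end, recomputing the mean Phred
#' quality after each removal, until the mean is strictly greater than
#' `min_mean_quality`. The retained read is therefore the longest prefix
#' whose mean quality exceeds the threshold. If no such prefix of length
#' at least `min_length` exists the read is discarded.
#'
#' A read whose best prefix averages exactly the threshold is discarded:
#' the criterion is strict ("above", not "at or above").
#'
#' @param bases Character scalar, the read sequence (ACGTN).
#' @param quals Integer vector of per-base Phred scores, same length as
#'   `bases`.
#' @param min_mean_quality Minimum mean Phred quality (strict); default 20.
#' @param min_length Minimum retained length in bases; default 50.
#' @return A list with elements `bases` and `quals` for the trimmed read,
#'   or `NULL` if the read is discarded.
#' @examples
#' trim_read(strrep("A", 55), rep(30L, 55))           # kept unchanged
#' trim_read(strrep("A", 100), rep(15L, 100))         # NULL: discarded
#' @export
trim_read <- function(bases, quals, min_mean_quality = 20, min_length = 50) {
  if (!is.character(bases) || length(bases) != 1L)
    stop("'bases' must be a single character string")
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals))
    stop("malformed read record: bases and quals lengths differ (",
         nchar(bases), " vs ", length(quals), ")")
  if (any(quals < 0L)) stop("malformed read record: negative quality score")
  k <- trim_length(quals, min_mean_quality)
  if (k < min_length) return(NULL)
  if (k == length(quals)) return(list(bases = bases, quals = quals))
  list(bases = substr(bases, 1L, k), quals = quals[seq_len(k)])
}

## longest prefix with mean quality strictly above the threshold (0 if none);
## equivalent to stepwise 3' removal with the mean recomputed at each step
trim_length <- function(quals, min_mean_quality) {
  n <- length(quals)
  if (n == 0L) return(0L)
  ok <- cumsum(as.numeric(quals)) / seq_len(n) > min_mean_quality
  if (!any(ok)) 0L else max(which(ok))
}

#' Quality-control a read library
#'
#' Applies [trim_read()] to every read of a library, emitting survivors in
#' input order, and tallies read/basepair retention. Percentages for an
#' empty input are defined as 100.
#'
#' @param reads A read set as returned by [read_fastq()]: a list with
#'   character vector `id`, character vector `bases` and list `quals` of
#'   integer vectors.
#' @inheritParams trim_read
#' @return A list with `reads` (the surviving, possibly trimmed read set)
#'   and `summary`, a list with `reads_in`, `reads_out`, `bp_in`, `bp_out`,
#'   `pct_reads_retained` and `pct_bp_retained`.
#' @export
qc_library <- function(reads, min_mean_quality = 20, min_length = 50) {
  stopifnot(is.list(reads), all(c("id", "bases", "quals") %in% names(reads)))
  n <- length(reads$id)
  if (length(reads$bases) != n || length(reads$quals) != n)
    stop("malformed read set: id/bases/quals lengths differ")
  len_in <- nchar(reads$bases)
  keep_len <- integer(n)
  for (i in seq_len(n)) {
    q <- reads$quals[[i]]
    if (len_in[i] != length(q))
      stop("malformed read record at index ", i,
           ": bases and quals lengths differ")
    keep_len[i] <- trim_length(q, min_mean_quality)
  }
  keep <- keep_len >= min_length
  out <- list(
    id    = reads$id[keep],
    bases = substr(reads$bases[keep], 1L, keep_len[keep]),
    quals = mapply(function(q, k) q[seq_len(k)], reads$quals[keep],
                   keep_len[keep], SIMPLIFY = FALSE)
  )
  bp_in  <- sum(len_in)
  bp_out <- sum(keep_len[keep])
  summary <- list(
    reads_in = n, reads_out = sum(keep),
    bp_in = bp_in, bp_out = bp_out,
    pct_reads_retained = if (n == 0L) 100 else 100 * sum(keep) / n,
    pct_bp_retained    = if (bp_in == 0L) 100 else 100 * bp_out / bp_in
  )
  list(reads = out, summary = summary)
}

#' Read a FASTQ file
#'
#' Reads a (optionally gzipped) FASTQ file into a simple read-set list.
#' Qualities are decoded with the given ASCII offset (33 for modern
#' Sanger/Illumina data, 64 for some legacy runs).
#'
#' @param path Path to the FASTQ file.
#' @param offset Quality encoding offset; default 33 (Phred+33).
#' @return A list with `id`, `bases` (character vectors) and `quals`
#'   (list of integer vectors).
#' @export
read_fastq <- function(path, offset = 33L) {
  nl <- length(readLines(path, warn = FALSE))
  if (nl %% 4L != 0L)
    stop("FASTQ format error in '", path, "': truncated at record ",
         nl %/% 4L + 1L, call. = FALSE)
  parse_fail <- function(e)
    stop("FASTQ format error in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = parse_fail)
  qual <- S4Vectors::mcols(x)$qualities
  quals <- tryCatch(
    lapply(unname(as.character(qual)),
           function(s) utf8ToInt(s) - as.integer(offset)),
    error = parse_fail)
  list(id = names(x), bases = unname(as.character(x)), quals = quals)
}

#' Write a FASTQ file
#'
#' Writes a read set (as from [read_fastq()] or [qc_library()]) as
#' Phred+33 FASTQ.
#'
#' @param reads Read set list (`id`, `bases`, `quals`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$bases)
  names(seqs) <- reads$id
  quals <- Biostrings::BStringSet(vapply(reads$quals,
    function(q) intToUtf8(as.integer(q) + 33L), character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}
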
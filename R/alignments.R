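#' Read alignment records from SAM or BAM
#'
#' Loads every record (mapped, unmapped, secondary, supplementary) of a
#' SAM or BAM file into a data frame, preserving file order. SAM input is
#' converted to BAM in a temporary file via [Rsamtools::asBam()].
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data frame with columns `read_id`, `flag`, `contig_id`
#'   (`NA` for unmapped records), `mapq`, `is_mapped` and `is_primary`
#'   (neither secondary nor supplementary), plus an attribute
#'   `contig_universe`: the reference sequence names from the header, in
#'   header order.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e)
        stop("SAM format error in '", path, "': ", conditionMessage(e),
             call. = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  universe <- names(hdr$targets)
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "mapq")))[[1]]
  flag <- res$flag
  aln <- data.frame(
    read_id   = res$qname,
    flag      = flag,
    contig_id = as.character(res$rname),
    mapq      = as.integer(res$mapq),
    stringsAsFactors = FALSE
  )
  aln$is_mapped  <- bitwAnd(flag, 4L) == 0L
  aln$is_primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  aln$contig_id[!aln$is_mapped] <- NA_character_
  attr(aln, "contig_universe") <- universe
  aln
}

#' Take the first n alignment records
#'
#' Returns exactly the first `n_reads` records in file order; if the file
#' has fewer records the whole stream is returned with a warning. This is
#' the normalisation used when equalising library sizes by taking the
#' first N reads of each alignment file.
#'
#' @param aln Alignment data frame from [read_alignments()].
#' @param n_reads Number of records to keep (>= 0).
#' @return The truncated alignment data frame (attributes preserved).
#' @export
head_subsample <- function(aln, n_reads) {
  stopifnot(is.data.frame(aln), n_reads >= 0)
  if (n_reads > nrow(aln)) {
    warning("requested ", n_reads, " records but only ", nrow(aln),
            " available; returning all")
    return(aln)
  }
  out <- aln[seq_len(n_reads), , drop = FALSE]
  attr(out, "contig_universe") <- attr(aln, "contig_universe")
  out
}

#' Count alignments per contig
#'
#' Builds one sample's metagenome profile: each mapped, primary record with
#' `mapq >= min_mapq` increments its contig by one. Unmapped and
#' secondary/supplementary records count only toward the library total.
#' With `count_pairs = TRUE`, a read pair (records sharing a read id)
#' contributes a single count to the contig of its first qualifying end,
#' and the library total is the number of distinct read ids.
#'
#' @param aln Alignment data frame from [read_alignments()].
#' @param contig_universe Character vector of all contig ids in the
#'   reference. Defaults to the universe recorded on `aln`.
#' @param min_mapq Minimum mapping quality for a record to be counted;
#'   default 0 (count everything the aligner reported as mapped).
#' @param count_pairs Count a read pair once if either end maps
#'   (default `FALSE`: every end counts individually).
#' @return A list with `counts` (named integer vector over
#'   `contig_universe`), `aligned`, `total` and `percent_aligned`
#'   (defined as 0 when `total` is 0).
#' @export
count_alignments <- function(aln, contig_universe = attr(aln, "contig_universe"),
                             min_mapq = 0, count_pairs = FALSE) {
  stopifnot(is.data.frame(aln))
  if (is.null(contig_universe))
    stop("no contig universe: supply 'contig_universe' or use read_alignments()")
  if (anyDuplicated(contig_universe))
    stop("duplicated contig ids in the universe")
  seen <- unique(aln$contig_id[aln$is_mapped])
  unknown <- setdiff(seen, contig_universe)
  if (length(unknown))
    stop("alignments reference contigs absent from the universe: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) ", ...")
  mapq <- aln$mapq
  mapq[is.na(mapq)] <- 0L
  qual <- aln$is_mapped & aln$is_primary & mapq >= min_mapq
  if (count_pairs) {
    hit <- aln[qual, c("read_id", "contig_id")]
    hit <- hit[!duplicated(hit$read_id), , drop = FALSE]
    counted <- hit$contig_id
    total <- length(unique(aln$read_id))
  } else {
    counted <- aln$contig_id[qual]
    total <- sum(aln$is_primary)
  }
  counts <- table(factor(counted, levels = contig_universe))
  counts <- stats::setNames(as.integer(counts), contig_universe)
  aligned <- length(counted)
  list(counts = counts, aligned = aligned, total = total,
       percent_aligned = if (total == 0L) 0 else 100 * aligned / total)
}
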
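#' Assemble a sample-by-contig count matrix
#'
#' Binds per-sample count vectors (as from [count_alignments()]) into the
#' sample-by-contig matrix of metagenome profiles. All vectors must be
#' over the same contig universe; rows keep the input order. Contigs with
#' zero counts everywhere are retained: they matter for presence/absence
#' tallies.
#'
#' @param vectors Named list of named count vectors, one per sample, or a
#'   named list of [count_alignments()] results.
#' @param library_sizes Optional named numeric vector of total reads per
#'   sample (including unaligned); taken from `vectors` when they are
#'   [count_alignments()] results.
#' @return An integer matrix (samples x contigs) with a `library_sizes`
#'   attribute.
#' @export
build_matrix <- function(vectors, library_sizes = NULL) {
  stopifnot(is.list(vectors), length(vectors) >= 1)
  if (is.null(names(vectors)) || anyDuplicated(names(vectors)))
    stop("'vectors' must be uniquely named by sample id")
  is_ca <- vapply(vectors, function(v) is.list(v) && !is.null(v$counts), logical(1))
  if (all(is_ca)) {
    if (is.null(library_sizes))
      library_sizes <- vapply(vectors, function(v) as.numeric(v$total), numeric(1))
    vectors <- lapply(vectors, `[[`, "counts")
  }
  universe <- names(vectors[[1]])
  if (is.null(universe)) stop("count vectors must be named by contig id")
  for (i in seq_along(vectors)) {
    ui <- names(vectors[[i]])
    if (!identical(ui, universe)) {
      diff <- union(setdiff(ui, universe), setdiff(universe, ui))
      if (length(diff))
        stop("inconsistent contig universes; symmetric difference: ",
             paste(utils::head(diff, 10), collapse = ", "),
             if (length(diff) > 10) ", ...")
      vectors[[i]] <- vectors[[i]][universe]  # same set, different order
    }
  }
  m <- do.call(rbind, vectors)
  storage.mode(m) <- "integer"
  rownames(m) <- names(vectors)
  if (!is.null(library_sizes)) {
    if (any(rowSums(m) > library_sizes[rownames(m)]))
      stop("a row sum exceeds its library size")
    attr(m, "library_sizes") <- library_sizes[rownames(m)]
  }
  m
}

#' Downsample a count matrix to a fixed depth
#'
#' Draws, for every sample, `depth` reads without replacement from the
#' sample's aligned reads (multivariate hypergeometric), so every row of
#' the result sums exactly to `depth`. This is the seeded, order-free
#' alternative to normalising by [head_subsample()].
#'
#' @param m Sample-by-contig count matrix.
#' @param depth Target aligned reads per sample; must not exceed any row
#'   total.
#' @param seed Optional integer seed for reproducibility. Each sample gets
#'   its own substream derived from `seed` and the sample id, so the draw
#'   for one sample does not depend on the others (permuting rows permutes
#'   the result).
#' @return The downsampled integer matrix.
#' @export
downsample_matrix <- function(m, depth, seed = NULL) {
  stopifnot(is.matrix(m), depth >= 0)
  rs <- rowSums(m)
  if (any(rs < depth)) {
    bad <- rownames(m)[which(rs < depth)[1]]
    stop("depth ", depth, " exceeds the aligned total of sample '", bad, "'")
  }
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  out <- m
  for (i in seq_len(nrow(m))) {
    if (!is.null(seed)) set.seed((seed + string_hash(ids[i])) %% 2147483647L)
    out[i, ] <- rmvhyper(m[i, ], depth)
  }
  storage.mode(out) <- "integer"
  attr(out, "library_sizes") <- NULL
  out
}

## stable 31-adic string hash into [0, 2^31 - 2]
string_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

## one multivariate hypergeometric draw by sequential rhyper
rmvhyper <- function(counts, k) {
  n <- length(counts)
  out <- integer(n)
  remaining <- sum(counts)
  for (j in seq_len(n)) {
    if (k == 0L) break
    cj <- counts[j]
    x <- stats::rhyper(1, cj, remaining - cj, k)
    out[j] <- x
    k <- k - x
    remaining <- remaining - cj
  }
  out
}

#' Drop sparsely covered contigs
#'
#' Retains exactly the contigs whose total count across samples is at
#' least `min_total` (default 10, the usual pre-filter before the mixed
#' model), preserving column order.
#'
#' @param m Sample-by-contig count matrix.
#' @param min_total Minimum column total to keep; default 10.
#' @return The filtered matrix.
#' @export
filter_min_reads <- function(m, min_total = 10) {
  stopifnot(is.matrix(m))
  keep <- colSums(m) >= min_total
  out <- m[, keep, drop = FALSE]
  attr(out, "library_sizes") <- attr(m, "library_sizes")
  out
}

#' Write / read a count matrix as TSV
#'
#' Plain tab-separated text: rows are samples, columns are contigs, with a
#' header row and a leading `sample` column.
#'
#' @param m Sample-by-contig count matrix.
#' @param path File path.
#' @return `write_count_matrix()`: `path`, invisibly.
#'   `read_count_matrix()`: the integer matrix.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "sample") stop("not a count matrix TSV: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  storage.mode(m) <- "integer"
  m
}
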
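#' Cluster profiles at increasing sequencing depths
#'
#' Replays the depth-sufficiency experiment: for each depth, takes the
#' first `depth` alignment records of every sample (file order, matching
#' how libraries are normalised), rebuilds the count matrix, clusters and
#' attaches multiscale-bootstrap support. Depths exceeding the shortest
#' alignment stream truncate the series with a warning.
#'
#' @param aln_list Named list of alignment data frames
#'   ([read_alignments()]), one per sample.
#' @param depths Strictly increasing read counts, e.g.
#'   `c(1e3, 1e4, 1e5, 1e6, ...)`.
#' @param grid A [scale_grid()] for the bootstrap.
#' @param method,variant Distance and linkage, as in [profile_support()].
#' @param min_mapq Passed to [count_alignments()].
#' @return An object of class `depth_series`: a list with `depths` and
#'   `runs` (per depth: `matrix`, `support`).
#' @export
depth_series <- function(aln_list, depths, grid = scale_grid(),
                         method = "canberra", variant = "ward.D",
                         min_mapq = 0) {
  stopifnot(is.list(aln_list), length(aln_list) >= 2)
  if (is.unsorted(depths, strictly = TRUE))
    stop("'depths' must be strictly increasing")
  n_min <- min(vapply(aln_list, nrow, integer(1)))
  if (any(depths > n_min)) {
    warning("depths beyond the shortest alignment stream (", n_min,
            " records) dropped; series truncated")
    depths <- depths[depths <= n_min]
  }
  if (!length(depths)) stop("no usable depths")
  runs <- lapply(depths, function(dep) {
    vecs <- lapply(aln_list, function(a)
      count_alignments(head_subsample(a, dep), min_mapq = min_mapq))
    mat <- build_matrix(vecs)
    list(matrix = mat,
         support = profile_support(mat, grid = grid, method = method,
                                   variant = variant))
  })
  names(runs) <- format(depths, scientific = FALSE, trim = TRUE)
  structure(list(depths = depths, runs = runs), class = "depth_series")
}

#' Group monophyly and support in a dendrogram
#'
#' For each group of samples, reports whether the group's samples form an
#' exact clade of the tree (leaf-set equality) and, when support is
#' available, the AU value of the group-defining edge. Single-member
#' groups are trivially monophyletic with support 1.
#'
#' @param x An [stats::hclust] tree or a [profile_support()] object.
#' @param labels Group label per sample, named by sample id (every leaf
#'   must be labelled).
#' @return Data frame: `group`, `monophyletic`, `au` (`NA` when no
#'   support is attached or the group is not a clade).
#' @export
group_purity <- function(x, labels) {
  edges_au <- NULL
  if (inherits(x, "profile_support")) {
    edges_au <- stats::setNames(x$edges$au, x$edges$edge)
    hc <- x$hclust
  } else if (inherits(x, "hclust")) {
    hc <- x
  } else stop("'x' must be an hclust tree or a profile_support object")
  leaves <- hc$labels
  unlab <- setdiff(leaves, names(labels))
  if (length(unlab)) stop("unlabelled leaves: ", paste(unlab, collapse = ", "))
  labels <- labels[leaves]
  keys <- names(edge_leafsets(hc))
  res <- lapply(split(leaves, labels), function(members) {
    if (length(members) == 1)
      return(data.frame(monophyletic = TRUE, au = 1))
    key <- paste(sort(members), collapse = ",")
    mono <- key %in% keys
    au <- if (mono && !is.null(edges_au)) unname(edges_au[key]) else NA_real_
    data.frame(monophyletic = mono, au = au)
  })
  out <- do.call(rbind, res)
  data.frame(group = names(res), out, row.names = NULL)
}

#' Minimal depth at which samples cluster by group
#'
#' Scans a [depth_series()] for the smallest depth at which every group is
#' monophyletic and every group-defining edge has AU support at least
#' `au_threshold`. `au_threshold = 0` asks for monophyly alone.
#'
#' @param series A `depth_series`.
#' @param labels Group label per sample, named by sample id.
#' @param au_threshold Minimum AU support; default 0.95.
#' @return The depth (numeric scalar), or `NA` if never achieved.
#' @export
minimal_adequate_depth <- function(series, labels, au_threshold = 0.95) {
  stopifnot(inherits(series, "depth_series"))
  for (i in seq_along(series$depths)) {
    pur <- group_purity(series$runs[[i]]$support, labels)
    au <- ifelse(is.na(pur$au), -Inf, pur$au)
    if (all(pur$monophyletic) && all(au >= au_threshold))
      return(series$depths[i])
  }
  NA_real_
}

#' @export
print.depth_series <- function(x, ...) {
  cat("Depth series over", length(x$depths), "depths:",
      paste(names(x$runs), collapse = ", "), "\n")
  invisible(x)
}
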
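#' Distance matrix between sample profiles
#'
#' Computes pairwise dissimilarities between the rows (samples) of a
#' count matrix.
#'
#' `method = "canberra"` uses the Canberra distance
#' \deqn{d(x, y) = \sum_i |x_i - y_i| / (|x_i| + |y_i|)}
#' with terms where \eqn{x_i = y_i = 0} omitted from the sum. Note that
#' [stats::dist()] additionally rescales the sum by
#' `ncol / n_used` when terms are omitted; set `rescale = TRUE` to
#' reproduce that behaviour.
#'
#' `method = "binary"` maps entries to presence (count > 0) and returns
#' the Jaccard mismatch fraction: positions present in exactly one sample
#' divided by positions present in at least one (0 if none), as in
#' [stats::dist()].
#'
#' @param m Numeric matrix, samples in rows (>= 2 rows).
#' @param method `"canberra"` (counts) or `"binary"` (presence/absence).
#' @param rescale Canberra only: rescale the sum over omitted terms as
#'   [stats::dist()] does. Default `FALSE` (plain omitted sum).
#' @return A [stats::dist] object labelled by sample id.
#' @export
profile_dist <- function(m, method = c("canberra", "binary"), rescale = FALSE) {
  method <- match.arg(method)
  stopifnot(is.matrix(m))
  if (nrow(m) < 2) stop("need at least 2 samples to compute distances")
  if (method == "binary") return(stats::dist(m, method = "binary"))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      x <- m[i, ]; y <- m[j, ]
      den <- abs(x) + abs(y)
      use <- den > 0
      s <- sum(abs(x[use] - y[use]) / den[use])
      if (rescale && any(!use) && any(use))
        s <- s * length(x) / sum(use)
      d[i, j] <- d[j, i] <- s
    }
  }
  stats::as.dist(d)
}

#' Ward hierarchical clustering of sample profiles
#'
#' Agglomerative clustering by the Lance-Williams Ward recurrence applied
#' directly to the supplied dissimilarities (`"ward.D"`, the historical
#' default; `"ward.D2"` squares them first). Merge heights are recorded
#' exactly as produced: with `"ward.D"` on raw dissimilarities they can be
#' non-monotone in pathological cases and are never reordered.
#'
#' @param d A [stats::dist] object (no missing or negative entries).
#' @param variant `"ward.D"` (default) or `"ward.D2"`.
#' @return An [stats::hclust] tree.
#' @export
ward_cluster <- function(d, variant = c("ward.D", "ward.D2")) {
  variant <- match.arg(variant)
  if (!inherits(d, "dist")) stop("'d' must be a dist object")
  if (anyNA(d)) stop("distance matrix contains missing values")
  if (any(d < 0)) stop("distance matrix contains negative values")
  stats::hclust(d, method = variant)
}

#' Leaf set of every internal edge of a dendrogram
#'
#' Each of the n-1 merges of an [stats::hclust] tree defines an internal
#' edge, identified here by the sorted set of leaf labels below it.
#'
#' @param hc An [stats::hclust] tree with labelled leaves.
#' @return A list of n-1 sorted character vectors, in merge order; names
#'   are the canonical comma-separated keys.
#' @export
edge_leafsets <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  labs <- hc$labels
  if (is.null(labs)) labs <- as.character(seq_len(nrow(hc$merge) + 1))
  nm <- nrow(hc$merge)
  members <- vector("list", nm)
  for (k in seq_len(nm)) {
    pick <- function(x) if (x < 0) labs[-x] else members[[x]]
    members[[k]] <- sort(c(pick(hc$merge[k, 1]), pick(hc$merge[k, 2])))
  }
  names(members) <- vapply(members, paste, character(1), collapse = ",")
  members
}

#' Export a dendrogram as Newick text
#'
#' Converts an [stats::hclust] tree to Newick with branch lengths derived
#' from the merge heights (via [ape::as.phylo()]). Internal-node labels
#' (e.g. bootstrap support) may be supplied keyed by the edge's canonical
#' leaf-set key (sorted leaf labels joined by commas, as produced by
#' [edge_leafsets()]).
#'
#' @param hc An [stats::hclust] tree.
#' @param labels Optional named character vector of internal-node labels
#'   keyed by leaf set.
#' @param file Optional path; when given the text is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
to_newick <- function(hc, labels = NULL, file = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  if (!is.null(labels)) {
    parts <- ape::prop.part(phy)
    keys <- vapply(parts, function(idx)
      paste(sort(phy$tip.label[idx]), collapse = ","), character(1))
    unknown <- setdiff(names(labels), keys)
    if (length(unknown))
      stop("label keys are not edges of the tree: ",
           paste(unknown, collapse = "; "))
    nl <- rep("", phy$Nnode)
    nl[match(names(labels), keys)] <- labels
    phy$node.label <- nl
  }
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
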
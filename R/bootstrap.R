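#' Multiscale bootstrap settings
#'
#' The resampling grid for multiscale bootstrap: at each ratio `r` the
#' contigs (features) are resampled with replacement to `round(n * r)`
#' columns, `B` times. `r = 1` gives the ordinary bootstrap; the spread of
#' ratios is what allows the approximately unbiased (AU) extrapolation.
#'
#' @param r Resampling ratios; default `seq(0.5, 1.4, by = 0.1)`.
#' @param B Replicates per scale; default 1000.
#' @param seed Integer seed; default 1.
#' @return A list of class `scale_grid`.
#' @export
scale_grid <- function(r = seq(0.5, 1.4, by = 0.1), B = 1000, seed = 1) {
  if (any(r <= 0)) stop("all resampling ratios must be positive")
  if (B < 1) stop("B must be at least 1")
  structure(list(r = r, B = as.integer(B), seed = as.integer(seed)),
            class = "scale_grid")
}

#' Per-edge recovery counts under multiscale resampling
#'
#' For each scale `r` of the grid, generates `B` bootstrap replicates by
#' resampling `round(n_contigs * r)` contigs (columns) with replacement --
#' samples stay fixed -- reclusters each replicate with the same distance
#' and linkage, and counts how often each edge of the original tree
#' (identified by exact leaf-set equality) reappears.
#'
#' @param m Sample-by-contig count matrix.
#' @param hc The tree built from `m` with the same `method`/`variant`.
#' @param grid A [scale_grid()].
#' @param method Distance: `"canberra"` or `"binary"`.
#' @param variant Linkage: `"ward.D"` or `"ward.D2"`.
#' @return Integer matrix of recovery counts, edges (canonical leaf-set
#'   keys) x scales.
#' @export
resample_edge_counts <- function(m, hc, grid = scale_grid(),
                                 method = "canberra", variant = "ward.D") {
  stopifnot(is.matrix(m), inherits(hc, "hclust"), inherits(grid, "scale_grid"))
  n <- ncol(m)
  sizes <- round(n * grid$r)
  if (any(sizes == 0))
    stop("scale grid produces an empty resample (round(n*r) == 0) at r = ",
         grid$r[which(sizes == 0)[1]])
  keys <- names(edge_leafsets(hc))
  counts <- matrix(0L, length(keys), length(grid$r),
                   dimnames = list(keys, format(grid$r)))
  set.seed(grid$seed)
  for (si in seq_along(grid$r)) {
    size <- sizes[si]
    for (b in seq_len(grid$B)) {
      idx <- sample.int(n, size, replace = TRUE)
      hb <- ward_cluster(profile_dist(m[, idx, drop = FALSE], method = method),
                         variant = variant)
      hit <- keys %in% names(edge_leafsets(hb))
      counts[hit, si] <- counts[hit, si] + 1L
    }
  }
  counts
}

#' Fit the multiscale-bootstrap model for one edge
#'
#' Given the per-scale recovery frequencies of an edge, fits the
#' signed-distance/curvature model of the multiscale bootstrap: with
#' \eqn{\sigma_r = \sqrt{1/r}} and \eqn{z_r = \Phi^{-1}(1 - BP_r)}, the
#' model \eqn{z = v/\sigma + c\,\sigma} is fitted by weighted least
#' squares with weights \eqn{B\,\phi(z_r)^2 / (BP_r (1 - BP_r))}; `v` is
#' the signed distance (it multiplies \eqn{1/\sigma = \sqrt{r}}) and `c`
#' the boundary curvature. The approximately unbiased support is
#' \eqn{AU = 1 - \Phi(v - c)} and the fitted ordinary bootstrap
#' probability \eqn{1 - \Phi(v + c)}. The sign convention is part of the
#' contract: a strongly supported edge has large negative `v` and AU
#' near 1.
#' Frequencies are clipped to `[1/(2B), 1 - 1/(2B)]` before the
#' z-transform. If the edge is recovered in no replicate at any scale the
#' result is `au = 0` (`au = 1` when recovered in all), with
#' `fit_ok = FALSE`.
#'
#' @param counts Integer vector of recovery counts, one per scale.
#' @param grid The [scale_grid()] that produced them.
#' @return A list with `v`, `c`, `au`, `bp_fitted`, `fit_ok` and `rss`
#'   (the weighted residual sum of squares, a chi-squared-style fit
#'   diagnostic).
#' @export
fit_au <- function(counts, grid) {
  stopifnot(inherits(grid, "scale_grid"), length(counts) == length(grid$r))
  B <- grid$B
  if (all(counts == 0))
    return(list(v = NA_real_, c = NA_real_, au = 0, bp_fitted = 0,
                fit_ok = FALSE, rss = NA_real_))
  if (all(counts == B))
    return(list(v = NA_real_, c = NA_real_, au = 1, bp_fitted = 1,
                fit_ok = FALSE, rss = NA_real_))
  if (length(unique(grid$r)) < 2)
    stop("need at least 2 distinct scales to fit the multiscale model")
  bp <- pmin(pmax(counts / B, 1 / (2 * B)), 1 - 1 / (2 * B))
  z <- stats::qnorm(1 - bp)
  sigma <- sqrt(1 / grid$r)
  X <- cbind(inv_sigma = 1 / sigma, sigma = sigma)
  w <- B * stats::dnorm(z)^2 / (bp * (1 - bp))
  fit <- stats::lm.wfit(X, z, w)
  v <- unname(fit$coefficients[1])
  cc <- unname(fit$coefficients[2])
  list(v = v, c = cc,
       au = 1 - stats::pnorm(v - cc),
       bp_fitted = 1 - stats::pnorm(v + cc),
       fit_ok = TRUE,
       rss = sum(w * fit$residuals^2))
}

#' Cluster sample profiles with multiscale-bootstrap edge support
#'
#' One-call orchestration: builds the distance matrix and Ward dendrogram,
#' runs the multiscale bootstrap over contigs, and attaches to every edge
#' its ordinary bootstrap probability (BP, observed frequency at `r = 1`)
#' and approximately unbiased (AU) support.
#'
#' @inheritParams resample_edge_counts
#' @return An object of class `profile_support`: a list with `hclust`
#'   (the tree), `edges` (data frame: `edge` key, `bp`, `au`, `v`, `c`,
#'   `fit_ok`), `counts` (recovery counts), `grid`, `method`, `variant`.
#' @export
profile_support <- function(m, grid = scale_grid(), method = "canberra",
                            variant = "ward.D") {
  d <- profile_dist(m, method = method)
  hc <- ward_cluster(d, variant = variant)
  counts <- resample_edge_counts(m, hc, grid, method = method,
                                 variant = variant)
  r1 <- which(abs(grid$r - 1) < 1e-9)[1]
  fits <- apply(counts, 1, fit_au, grid = grid)
  edges <- data.frame(
    edge   = rownames(counts),
    bp     = if (is.na(r1)) NA_real_ else counts[, r1] / grid$B,
    au     = vapply(fits, `[[`, numeric(1), "au"),
    v      = vapply(fits, `[[`, numeric(1), "v"),
    c      = vapply(fits, `[[`, numeric(1), "c"),
    fit_ok = vapply(fits, `[[`, logical(1), "fit_ok"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(hclust = hc, edges = edges, counts = counts, grid = grid,
                 method = method, variant = variant),
            class = "profile_support")
}

#' @export
print.profile_support <- function(x, ...) {
  cat("Profile clustering with multiscale-bootstrap support\n")
  cat(sprintf("  %d samples, distance = %s, linkage = %s, B = %d per scale (%d scales)\n",
              length(x$hclust$labels), x$method, x$variant, x$grid$B,
              length(x$grid$r)))
  df <- x$edges
  df$au <- round(df$au, 3)
  df$bp <- round(df$bp, 3)
  print(df[, c("edge", "au", "bp", "fit_ok")], row.names = FALSE)
  invisible(x)
}

#' @describeIn profile_support Newick export with `au|bp` edge labels.
#' @param x A `profile_support` object.
#' @param file Optional output path.
#' @export
support_newick <- function(x, file = NULL) {
  stopifnot(inherits(x, "profile_support"))
  lab <- sprintf("%.2f|%.2f", x$edges$au, x$edges$bp)
  names(lab) <- x$edges$edge
  ## the root "edge" (all leaves) is not an internal node of the phylo tree
  root_key <- paste(sort(x$hclust$labels), collapse = ",")
  to_newick(x$hclust, labels = lab[names(lab) != root_key], file = file)
}
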
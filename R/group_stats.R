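#' Unique and shared contigs between two sample groups
#'
#' A contig is "in" a group when its summed count over that group's
#' samples is positive. Contigs with no reads anywhere are excluded, so
#' the three classes (unique to each group, present in both) partition the
#' contigs with any reads.
#'
#' @param m Sample-by-contig count matrix (raw counts).
#' @param groups Two-level factor (or vector) of group labels, one per
#'   sample, in row order of `m` (or named by sample id).
#' @return A list with `groups` (the two labels), `unique_a`, `unique_b`,
#'   `both` (contig counts), `m_total` (their sum) and `contigs`, a list
#'   of the contig ids in each class.
#' @export
overlap_summary <- function(m, groups) {
  groups <- align_groups(m, groups)
  lev <- levels(groups)
  if (length(lev) != 2) stop("exactly 2 groups are required, got ",
                             length(lev))
  in_a <- colSums(m[groups == lev[1], , drop = FALSE]) > 0
  in_b <- colSums(m[groups == lev[2], , drop = FALSE]) > 0
  ids <- colnames(m)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(m)))
  cls <- list(unique_a = ids[in_a & !in_b],
              unique_b = ids[!in_a & in_b],
              both     = ids[in_a & in_b])
  list(groups = lev,
       unique_a = length(cls$unique_a),
       unique_b = length(cls$unique_b),
       both = length(cls$both),
       m_total = sum(lengths(cls)),
       contigs = cls)
}

align_groups <- function(m, groups) {
  stopifnot(is.matrix(m))
  if (!is.null(names(groups))) {
    missing <- setdiff(rownames(m), names(groups))
    if (length(missing)) stop("samples without a group label: ",
                              paste(missing, collapse = ", "))
    groups <- groups[rownames(m)]
  } else if (length(groups) != nrow(m)) {
    stop("'groups' must have one label per sample")
  }
  factor(groups)
}

#' Per-contig two-sample t-tests
#'
#' Tests each contig for differential representation between two sample
#' groups with a two-sided two-sample t-test (Student's equal-variance by
#' default; Welch with `var_equal = FALSE`). Run this on the normalised
#' (equal-depth) matrix. Degenerate contigs: zero variance in both groups
#' with equal means gives p = 1; zero pooled variance with unequal means
#' gives p = 0, flagged.
#'
#' @param m Sample-by-contig matrix (normalised counts).
#' @param groups Two-level group labels as in [overlap_summary()].
#' @param var_equal Pool the variances (Student's t); default `TRUE`.
#' @return Data frame: `contig`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
per_contig_ttest <- function(m, groups, var_equal = TRUE) {
  groups <- align_groups(m, groups)
  lev <- levels(groups)
  if (length(lev) != 2) stop("exactly 2 groups are required")
  a <- m[groups == lev[1], , drop = FALSE]
  b <- m[groups == lev[2], , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples")
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, ncol(m))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0
  t[degenerate & ma == mb] <- 0
  p[degenerate & ma == mb] <- 1
  t[degenerate & ma != mb] <- sign(ma - mb)[degenerate & ma != mb] * Inf
  p[degenerate & ma != mb] <- 0
  ids <- colnames(m)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(m)))
  data.frame(contig = ids, mean_a = ma, mean_b = mb, t = t, df = df, p = p,
             degenerate = degenerate & ma != mb, row.names = NULL)
}

#' Empirical false discovery rate at a p-value threshold
#'
#' The expected number of false positives among m tests at threshold
#' alpha is m * alpha; dividing by the k contigs actually declared
#' significant gives the empirical FDR
#' \deqn{\mathrm{FDR} = 100 \cdot \min(1, m\alpha/k)\ \%,}
#' reported to one decimal. `m` is the number of contigs with any aligned
#' reads (the sum of the unique/shared classes of [overlap_summary()]).
#'
#' @param m Number of tests (contigs with any reads).
#' @param k Number of significant contigs at the threshold (>= 1).
#' @param alpha The p-value threshold.
#' @return A list with `m`, `k`, `alpha`, `fdr_percent` (one decimal) and
#'   `fdr_exact` (unrounded).
#' @export
estimate_fdr <- function(m, k, alpha) {
  if (k < 1) stop("FDR is undefined when no contig is significant (k = 0)")
  if (m < k) stop("'k' cannot exceed the number of tests 'm'")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  fdr <- 100 * min(1, m * alpha / k)
  list(m = m, k = k, alpha = alpha,
       fdr_percent = round(fdr, 1), fdr_exact = fdr)
}

#' Benjamini-Hochberg alternative to the empirical FDR
#'
#' Adjusts a vector of per-contig p-values by [stats::p.adjust()]
#' (`"BH"`); provided as the standard alternative to [estimate_fdr()].
#'
#' @param p Vector of p-values.
#' @return BH-adjusted p-values.
#' @export
fdr_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Cross-group profile correlations: same animal vs different animals
#'
#' Correlates every profile of one group with every profile of the other
#' (Pearson by default), then tests whether pairs from the same animal
#' correlate more strongly than pairs from different animals (two-sample
#' Student's t-test on the correlation values).
#'
#' @param m Sample-by-contig matrix (normalised counts).
#' @param design Data frame with columns `sample`, `group` (2 levels) and
#'   `animal`. Animals lacking a sample in either group are dropped with a
#'   warning.
#' @param method Correlation type, `"pearson"` (default) or
#'   `"spearman"`.
#' @return A list with `cor_matrix` (group-A samples x group-B samples),
#'   `within` and `between` (correlation values), `t`, `p`.
#' @export
correlation_compare <- function(m, design, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(design),
            all(c("sample", "group", "animal") %in% names(design)))
  design <- design[match(rownames(m), design$sample), ]
  if (anyNA(design$sample)) stop("samples missing from the design")
  grp <- factor(design$group)
  lev <- levels(grp)
  if (length(lev) != 2) stop("exactly 2 groups are required")
  keep_animals <- intersect(design$animal[grp == lev[1]],
                            design$animal[grp == lev[2]])
  dropped <- setdiff(unique(design$animal), keep_animals)
  if (length(dropped)) {
    warning("animals without a sample in both groups excluded: ",
            paste(dropped, collapse = ", "))
    sel <- design$animal %in% keep_animals
    m <- m[sel, , drop = FALSE]; design <- design[sel, ]; grp <- factor(design$group)
  }
  ia <- grp == lev[1]; ib <- grp == lev[2]
  cm <- stats::cor(t(m[ia, , drop = FALSE]), t(m[ib, , drop = FALSE]),
                   method = method)
  same <- outer(design$animal[ia], design$animal[ib], "==")
  within <- cm[same]; between <- cm[!same]
  if (length(within) < 2 || length(between) < 2)
    stop("need at least 2 within- and 2 between-animal pairs")
  tt <- stats::t.test(within, between, var.equal = TRUE)
  list(cor_matrix = cm, within = within, between = between,
       t = unname(tt$statistic), p = tt$p.value)
}
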
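test_that("overlap_summary partitions contigs with any reads", {
  m <- rbind(a1 = c(c1 = 2L, c2 = 0L, c3 = 1L, c4 = 0L),
             a2 = c(c1 = 1L, c2 = 0L, c3 = 0L, c4 = 0L),
             b1 = c(c1 = 0L, c2 = 3L, c3 = 2L, c4 = 0L),
             b2 = c(c1 = 0L, c2 = 1L, c3 = 0L, c4 = 0L))
  grp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  ov <- overlap_summary(m, grp)
  expect_equal(ov$unique_a, 1)     # c1
  expect_equal(ov$unique_b, 1)     # c2
  expect_equal(ov$both, 1)         # c3; c4 has no reads anywhere
  expect_equal(ov$m_total, 3)
  # identical groups leave nothing unique
  m2 <- rbind(x1 = c(1L, 0L, 2L), x2 = c(1L, 0L, 2L),
              y1 = c(1L, 0L, 2L), y2 = c(1L, 0L, 2L))
  ov2 <- overlap_summary(m2, c("A", "A", "B", "B"))
  expect_equal(ov2$unique_a + ov2$unique_b, 0)
  expect_error(overlap_summary(m, c(a1 = "A", a2 = "B", b1 = "C", b2 = "C")),
               "2 groups")
})

test_that("overlap_summary is invariant to sample order and count scaling", {
  set.seed(51)
  for (rep in 1:10) {
    m <- rand_count_matrix(6, 40)
    grp <- setNames(rep(c("A", "B"), each = 3), rownames(m))
    ov <- overlap_summary(m, grp)
    # partition property
    nonzero <- sum(colSums(m) > 0)
    expect_equal(ov$unique_a + ov$unique_b + ov$both, nonzero)
    # sample order
    perm <- sample(nrow(m))
    expect_equal(overlap_summary(m[perm, ], grp)[c("unique_a", "unique_b", "both")],
                 ov[c("unique_a", "unique_b", "both")])
    # scaling one sample by a positive integer changes no presence call
    ms <- m; ms[2, ] <- ms[2, ] * 7L
    expect_equal(overlap_summary(ms, grp)[c("unique_a", "unique_b", "both")],
                 ov[c("unique_a", "unique_b", "both")])
  }
})

test_that("per-contig t statistics match closed form and stats::t.test", {
  m <- rbind(a1 = c(p = 1, q = 1), a2 = c(p = 2, q = 2), a3 = c(p = 3, q = 3),
             b1 = c(p = 1, q = 4), b2 = c(p = 2, q = 5), b3 = c(p = 3, q = 6))
  grp <- rep(c("A", "B"), each = 3)
  tt <- per_contig_ttest(m, grp)
  # identical samples: t = 0, p = 1
  expect_equal(tt$t[1], 0); expect_equal(tt$p[1], 1)
  # (1,2,3) vs (4,5,6): t = -3/sqrt(2/3), df = 4
  expect_equal(tt$t[2], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df[2], 4)
  expect_equal(tt$p[2], 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  # random matrices agree with stats::t.test column by column (both variants)
  set.seed(52)
  r <- matrix(rnorm(8 * 30, 50, 5), 8)
  colnames(r) <- paste0("c", 1:30)
  grp8 <- rep(c("A", "B"), each = 4)
  student <- per_contig_ttest(r, grp8)
  welch <- per_contig_ttest(r, grp8, var_equal = FALSE)
  for (j in c(1, 7, 30)) {
    ts <- t.test(r[1:4, j], r[5:8, j], var.equal = TRUE)
    tw <- t.test(r[1:4, j], r[5:8, j])
    expect_equal(student$p[j], ts$p.value, tolerance = 1e-12)
    expect_equal(welch$p[j], tw$p.value, tolerance = 1e-12)
    expect_equal(welch$df[j], unname(tw$parameter), tolerance = 1e-9)
  }
})

test_that("degenerate contigs get the contracted p-values", {
  m <- rbind(a1 = c(u = 5, w = 5), a2 = c(u = 5, w = 5),
             b1 = c(u = 5, w = 9), b2 = c(u = 5, w = 9))
  tt <- per_contig_ttest(m, c("A", "A", "B", "B"))
  expect_equal(tt$p[1], 1)             # no variance, equal means
  expect_equal(tt$p[2], 0)             # no variance, different means
  expect_true(tt$degenerate[2])
  expect_error(per_contig_ttest(m[c(1, 3, 4), ], c("A", "B", "B")),
               "at least 2 samples")
})

test_that("t p-values agree with exhaustive permutation on a small instance", {
  set.seed(53)
  x <- c(12.1, 9.8, 11.4); y <- c(8.2, 7.9, 10.1)
  m <- matrix(c(x, y), ncol = 1, dimnames = list(paste0("s", 1:6), "c1"))
  p_t <- per_contig_ttest(m, rep(c("A", "B"), each = 3))$p
  vals <- c(x, y)
  combs <- combn(6, 3)
  t_obs <- abs(t.test(x, y, var.equal = TRUE)$statistic)
  t_perm <- apply(combs, 2, function(idx)
    abs(t.test(vals[idx], vals[-idx], var.equal = TRUE)$statistic))
  p_perm <- mean(t_perm >= t_obs - 1e-12)
  expect_lt(abs(p_t - p_perm), 0.15)   # permutation p is granular at n = 20
})

test_that("empirical FDR reproduces the m*alpha/k construction", {
  expect_equal(estimate_fdr(190809, 3037, 0.01)$fdr_percent, 62.8)
  expect_equal(estimate_fdr(11545, 822, 0.01)$fdr_percent, 14.0)
  # boundary: k equal to the expected false positives gives 100%
  expect_equal(estimate_fdr(5000, 50, 0.01)$fdr_percent, 100)
  # capped at 100
  expect_equal(estimate_fdr(5000, 10, 0.01)$fdr_percent, 100)
  expect_error(estimate_fdr(100, 0, 0.01), "k = 0")
  expect_error(estimate_fdr(10, 20, 0.01), "cannot exceed")
  expect_equal(fdr_bh(c(0.01, 0.02, 0.5)), p.adjust(c(0.01, 0.02, 0.5), "BH"))
})

test_that("correlation comparison separates shared-animal structure", {
  set.seed(54)
  n_contigs <- 80
  base <- rnorm(n_contigs, 8, 2)
  make_design <- function() data.frame(
    sample = c(paste0("r", 1:5), paste0("f", 1:5)),
    group = rep(c("rumen", "faeces"), each = 5),
    animal = rep(paste0("cow", 1:5), 2))
  sim_pair <- function(animal_sd) {
    A <- matrix(rnorm(n_contigs * 5, 0, animal_sd), n_contigs)
    prof <- function(k) base + A[, k] + rnorm(n_contigs, 0, 1)
    m <- t(cbind(sapply(1:5, prof), sapply(1:5, prof)))
    rownames(m) <- make_design()$sample
    m
  }
  # duplicated profiles: within-animal correlation is exactly 1
  md <- sim_pair(0)
  md[6:10, ] <- md[1:5, ]
  cc <- correlation_compare(md, make_design())
  expect_true(all(abs(diag(cc$cor_matrix) - 1) < 1e-12))
  expect_true(all(diag(cc$cor_matrix) >= cc$cor_matrix[row(cc$cor_matrix) !=
                                                         col(cc$cor_matrix)]))
  # strong shared animal effect: significant in nearly every replicate
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    correlation_compare(sim_pair(3), make_design())$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # an animal missing one group is excluded with a warning
  d_miss <- make_design(); d_miss$animal[10] <- "cow9"
  expect_warning(correlation_compare(sim_pair(1), d_miss), "excluded")
})
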
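# five-record SAM fixture: r1,r2 -> c1; r3 -> c2; r4 unmapped; r5 -> c1 secondary
five_record_sam <- function() {
  path <- tempfile(fileext = ".sam")
  write_sam_fixture(path, universe = c("c1", "c2", "c3"),
                    qname = paste0("r", 1:5),
                    flag = c(0L, 0L, 0L, 4L, 256L),
                    rname = c("c1", "c1", "c2", "*", "c1"))
  path
}

test_that("count_alignments counts primary mapped records once each", {
  aln <- read_alignments(five_record_sam())
  expect_identical(attr(aln, "contig_universe"), c("c1", "c2", "c3"))
  res <- count_alignments(aln)
  expect_identical(res$counts, c(c1 = 2L, c2 = 1L, c3 = 0L))
  expect_equal(res$aligned, 3)
  expect_equal(res$total, 4)       # 4 primary records; the secondary is excluded
  expect_equal(res$percent_aligned, 75)
  # count conservation: total counts == qualifying records
  expect_equal(sum(res$counts), sum(aln$is_mapped & aln$is_primary))
})

test_that("count_alignments handles empty and fully unmapped inputs", {
  p1 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown", "@SQ\tSN:c1\tLN:100"), p1)
  a1 <- read_alignments(p1)
  r1 <- count_alignments(a1)
  expect_identical(r1$counts, c(c1 = 0L))
  expect_equal(r1$percent_aligned, 0)

  p2 <- tempfile(fileext = ".sam")
  write_sam_fixture(p2, universe = "c1", qname = c("x", "y"),
                    flag = c(4L, 4L), rname = c("*", "*"))
  r2 <- count_alignments(read_alignments(p2))
  expect_equal(sum(r2$counts), 0)
  expect_equal(r2$percent_aligned, 0)
})

test_that("count_alignments rejects contigs outside the universe and honours mapq", {
  aln <- read_alignments(five_record_sam())
  expect_error(count_alignments(aln, contig_universe = c("c1", "c3")),
               "absent from the universe")
  res <- count_alignments(aln, min_mapq = 61)
  expect_equal(sum(res$counts), 0)   # fixture mapq is 60
})

test_that("pair counting collapses records sharing a read id", {
  path <- tempfile(fileext = ".sam")
  # r1 has both ends mapped (2 records), r2 has one end mapped + one unmapped
  write_sam_fixture(path, universe = c("c1", "c2"),
                    qname = c("r1", "r1", "r2", "r2"),
                    flag = c(0L, 0L, 0L, 4L),
                    rname = c("c1", "c1", "c2", "*"))
  aln <- read_alignments(path)
  per_end <- count_alignments(aln)
  expect_identical(per_end$counts, c(c1 = 2L, c2 = 1L))
  per_pair <- count_alignments(aln, count_pairs = TRUE)
  expect_identical(per_pair$counts, c(c1 = 1L, c2 = 1L))
  expect_equal(per_pair$total, 2)    # two distinct read ids
})

test_that("head_subsample takes exactly the leading records", {
  aln <- read_alignments(five_record_sam())
  expect_identical(head_subsample(aln, 3)$read_id, c("r1", "r2", "r3"))
  expect_identical(nrow(head_subsample(aln, 0)), 0L)
  expect_warning(full <- head_subsample(aln, 99), "only 5")
  expect_identical(full$read_id, aln$read_id)
  # streaming consistency: counting a prefix equals the prefix of counting
  pre <- count_alignments(head_subsample(aln, 3))
  expect_identical(pre$counts, c(c1 = 2L, c2 = 1L, c3 = 0L))
})

test_that("build_matrix assembles rows in input order and validates universes", {
  v1 <- c(c1 = 3L, c2 = 0L); v2 <- c(c1 = 0L, c2 = 7L)
  m <- build_matrix(list(sA = v1, sB = v2))
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(m["sA", ], v1)
  expect_identical(m["sB", ], v2)
  # single sample
  m1 <- build_matrix(list(only = v1))
  expect_identical(m1[1, ], v1)
  # permuting input order permutes rows only
  mp <- build_matrix(list(sB = v2, sA = v1))
  expect_identical(mp[c("sA", "sB"), ], m)
  expect_error(build_matrix(list(a = v1, b = c(c1 = 1L, cX = 2L))),
               "symmetric difference.*cX|cX.*symmetric difference")
})

test_that("downsample_matrix hits the target depth and matches hypergeometric moments", {
  set.seed(5)
  m <- rand_count_matrix(4, 30, lambda = 20, zero_frac = 0.2)
  dep <- min(rowSums(m))
  d0 <- downsample_matrix(m, dep, seed = 1)
  expect_true(all(rowSums(d0) == dep))
  # a row already at the target depth is unchanged
  i <- which.min(rowSums(m))
  expect_identical(d0[i, ], m[i, ])
  # exceeding a row total errors, naming the offending sample
  expect_error(downsample_matrix(m, max(rowSums(m)) + 1),
               "exceeds the aligned total of sample 's")
  # Monte-Carlo mean matches depth * p for a chosen contig
  j <- which.max(m[1, ])
  p <- m[1, j] / sum(m[1, ])
  draws <- vapply(1:400, function(s)
    downsample_matrix(m[1, , drop = FALSE], 50, seed = s)[1, j], numeric(1))
  se <- sqrt(50 * p * (1 - p) * (sum(m[1, ]) - 50) / (sum(m[1, ]) - 1)) / sqrt(400)
  expect_lt(abs(mean(draws) - 50 * p), 3.5 * se)
  # row independence: permuting rows permutes the output under the same seed
  perm <- c(3, 1, 4, 2)
  expect_identical(downsample_matrix(m[perm, ], dep, seed = 9),
                   downsample_matrix(m, dep, seed = 9)[perm, ])
})

test_that("filter_min_reads applies the column-total threshold", {
  m <- rbind(s1 = c(a = 4L, b = 6L, c = 9L),
             s2 = c(a = 5L, b = 4L, c = 0L))
  f <- filter_min_reads(m, 10)
  expect_identical(colnames(f), "b")   # total 10 kept, 9 dropped
  expect_identical(filter_min_reads(m, 0), m)
  set.seed(6)
  r <- rand_count_matrix(5, 60)
  keep <- vapply(seq_len(ncol(r)), function(j) sum(r[, j]) >= 10, logical(1))
  expect_identical(filter_min_reads(r, 10), r[, keep])
})

test_that("count matrix TSV round-trips", {
  m <- rand_count_matrix(3, 8)
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  expect_identical(read_count_matrix(path), m)
})
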
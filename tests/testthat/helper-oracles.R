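# Independent oracles and small fixture builders shared across tests.
# These deliberately use naive scalar loops / first-principles recurrences
# so they share no code path with the implementation they check.

# plain Canberra: scalar loop, zero-zero terms skipped, no rescaling
canberra_oracle <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) {
    den <- abs(x[i]) + abs(y[i])
    if (den > 0) s <- s + abs(x[i] - y[i]) / den
  }
  as.numeric(s)
}

binary_oracle <- function(x, y) {
  px <- x != 0; py <- y != 0
  any_ <- sum(px | py)
  if (any_ == 0) 0 else sum(xor(px, py)) / any_
}

# exhaustive Lance-Williams agglomeration, ward.D recurrence on the raw
# dissimilarities; returns merge heights and the leaf set of every merge
lw_ward_oracle <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  clusters <- as.list(labs)
  sizes <- rep(1, length(labs))
  active <- seq_along(labs)
  heights <- numeric(0)
  leafsets <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1)) {
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < bh) { bh <- d[i, j]; best <- c(j, i) }
    }
    i <- best[1]; j <- best[2]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    heights <- c(heights, bh)
    leafsets <- c(leafsets, list(merged))
    # Ward update for every remaining cluster k
    for (k in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      d[i, k] <- d[k, i] <-
        ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
    }
    clusters[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  list(heights = heights, leafsets = leafsets)
}

rand_count_matrix <- function(n_samples, n_contigs, lambda = 5,
                              zero_frac = 0.3) {
  m <- matrix(rpois(n_samples * n_contigs, lambda), n_samples, n_contigs)
  m[matrix(runif(length(m)) < zero_frac, nrow(m))] <- 0L
  rownames(m) <- paste0("s", seq_len(n_samples))
  colnames(m) <- paste0("c", seq_len(n_contigs))
  storage.mode(m) <- "integer"
  m
}

# balanced Gaussian crossed data for the variance-component model
gen_crossed <- function(a, u, cg, vs, seed, mu = 100) {
  set.seed(seed)
  d <- expand.grid(animal = factor(paste0("a", 1:a)),
                   unit = factor(paste0("u", 1:u)),
                   contig = factor(paste0("c", 1:cg)))
  d$count <- mu +
    rnorm(a, 0, sqrt(vs[1]))[d$animal] +
    rnorm(u, 0, sqrt(vs[2]))[d$unit] +
    rnorm(cg, 0, sqrt(vs[3]))[d$contig] +
    rnorm(nrow(d), 0, sqrt(vs[4]))
  d
}

# literal stepwise 3' trimming: remove one base at a time, recompute mean
trim_oracle <- function(quals, min_mean_quality, min_length) {
  k <- length(quals)
  while (k > 0L && mean(quals[seq_len(k)]) <= min_mean_quality) k <- k - 1L
  if (k < min_length) 0L else k
}

rand_reads <- function(n, len_range = c(20, 120), q_range = c(2, 40)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  list(
    id = paste0("r", seq_len(n)),
    bases = vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE),
            collapse = ""), character(1)),
    quals = lapply(lens, function(L)
      sample(q_range[1]:q_range[2], L, replace = TRUE))
  )
}

# write a small SAM file from parallel record vectors
write_sam_fixture <- function(path, universe, qname, flag, rname, pos = NULL,
                              lens = NULL) {
  if (is.null(lens)) lens <- rep(1000L, length(universe))
  if (is.null(pos)) pos <- ifelse(rname == "*", 0L, 1L)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", universe, lens))
  seq <- strrep("A", 10)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 qname, flag, rname, pos,
                 ifelse(rname == "*", 0L, 60L),
                 ifelse(rname == "*", "*", "10M"),
                 seq, strrep("I", 10))
  writeLines(c(hdr, rec), path)
  path
}
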
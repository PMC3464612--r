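#' Simulation parameters for synthetic metagenome communities
#'
#' Defines a crossed host-animal x sampling-unit design over a log-normal
#' community. Log-abundance of contig j in the sample from animal k, unit
#' i is `base_j + A_jk + U_ji + eps`, each effect Gaussian on the log
#' scale; softmax turns it into a probability vector and reads are drawn
#' multinomially at the chosen depth.
#'
#' Defaults emulate the rumen-position study design: 3 animals x 3
#' sampling positions, a dominant contig effect (`base_sdlog`), a
#' smaller host-animal effect and a much smaller position effect, with
#' residual log-scale noise a third of the animal effect. The
#' `"faeces"` preset switches to 7 animals x 2 sample types with the
#' sample-type effect dominating the animal effect, mirroring the
#' rumen-vs-faeces comparison.
#'
#' @param n_animals,n_units,n_contigs Design dimensions.
#' @param base_meanlog,base_sdlog Log-normal law of baseline contig
#'   abundances.
#' @param sd_animal,sd_unit,sd_noise Log-scale standard deviations of the
#'   animal effect, unit (position/sample-type) effect and residual noise.
#' @param aligned_frac Expected fraction of reads aligning to the
#'   reference. The default 1 models the aligned compartment directly
#'   (every read hits a contig, `depth` = aligned reads). Below 1, an
#'   unaligned compartment is added that is subject to the same
#'   animal/unit effects, so overall alignment rates vary between animals
#'   as they do between real libraries; `depth` then counts sequenced
#'   reads and row sums of the count matrix vary around
#'   `depth * aligned_frac`.
#' @param depth Reads per sample.
#' @param seed Integer seed.
#' @param read_length,error_rate,contig_length Read emission settings
#'   (used by [simulate_reads()]).
#' @param preset `"position"` (default) or `"faeces"`; presets set the
#'   design fields, explicit arguments still override.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_animals = 3, n_units = 3, n_contigs = 200,
                       base_meanlog = 0, base_sdlog = 1.5,
                       sd_animal = 0.3, sd_unit = 0.05, sd_noise = 0.1,
                       aligned_frac = 1, depth = 50000, seed = 1,
                       read_length = 100, error_rate = 0.005,
                       contig_length = c(300, 800),
                       preset = c("position", "faeces")) {
  preset <- match.arg(preset)
  if (preset == "faeces") {
    if (missing(n_animals)) n_animals <- 7
    if (missing(n_units))   n_units <- 2
    if (missing(sd_unit))   sd_unit <- 0.6
    if (missing(sd_animal)) sd_animal <- 0.1
  }
  p <- list(n_animals = n_animals, n_units = n_units, n_contigs = n_contigs,
            base_meanlog = base_meanlog, base_sdlog = base_sdlog,
            sd_animal = sd_animal, sd_unit = sd_unit, sd_noise = sd_noise,
            aligned_frac = aligned_frac, depth = depth, seed = as.integer(seed),
            read_length = read_length, error_rate = error_rate,
            contig_length = contig_length, preset = preset)
  if (p$n_contigs < 2) stop("need at least 2 contigs")
  if (p$depth < 0) stop("depth must be non-negative")
  if (any(c(p$sd_animal, p$sd_unit, p$sd_noise, p$base_sdlog) < 0))
    stop("standard deviations must be non-negative")
  if (p$aligned_frac <= 0 || p$aligned_frac > 1)
    stop("'aligned_frac' must be in (0, 1]")
  structure(p, class = "sim_params")
}

#' Simulate per-sample relative abundances
#'
#' Draws the baseline contig abundances and the crossed animal/unit
#' effects, and returns a softmax-normalised probability vector for every
#' (animal, unit) sample, along with the full truth record.
#'
#' @param params A [sim_params()] object.
#' @return A list with `prob` (samples x contigs probability matrix, rows
#'   named `a<k>_u<i>`), `design` (sample, animal, unit data frame) and
#'   `truth` (base, animal and unit effect draws, noise).
#' @export
simulate_abundances <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  nc <- params$n_contigs; na <- params$n_animals; nu <- params$n_units
  base <- stats::rnorm(nc, params$base_meanlog, params$base_sdlog)
  ids <- contig_ids(nc)
  if (params$aligned_frac < 1) {
    # one extra category absorbs the reads that would not hit the
    # reference; its weight is set so the expected aligned share is
    # aligned_frac, and it feels the same animal/unit effects
    af <- params$aligned_frac
    base <- c(base, log(sum(exp(base)) * (1 - af) / af))
    ids <- c(ids, ".unaligned")
    nc <- nc + 1L
  }
  A <- matrix(stats::rnorm(nc * na, 0, params$sd_animal), nc, na)
  U <- matrix(stats::rnorm(nc * nu, 0, params$sd_unit), nc, nu)
  design <- expand.grid(unit = seq_len(nu), animal = seq_len(na))
  design <- data.frame(sample = sprintf("a%d_u%d", design$animal, design$unit),
                       animal = sprintf("a%d", design$animal),
                       unit = sprintf("u%d", design$unit))
  eps <- matrix(stats::rnorm(nrow(design) * nc, 0, params$sd_noise),
                nrow(design), nc)
  prob <- matrix(NA_real_, nrow(design), nc,
                 dimnames = list(design$sample, ids))
  for (s in seq_len(nrow(design))) {
    k <- match(design$animal[s], sprintf("a%d", seq_len(na)))
    i <- match(design$unit[s], sprintf("u%d", seq_len(nu)))
    la <- base + A[, k] + U[, i] + eps[s, ]
    la <- la - max(la)                 # softmax, overflow-safe
    prob[s, ] <- exp(la) / sum(exp(la))
  }
  list(prob = prob, design = design,
       truth = list(base = base, animal_effects = A, unit_effects = U,
                    noise = eps))
}

contig_ids <- function(n) sprintf("contig%0*d", nchar(n), seq_len(n))

#' Multinomial read sampling at fixed depth
#'
#' Draws each sample's counts as one multinomial of size `depth` over its
#' abundance vector, so every row sums exactly to `depth`. When the
#' abundances carry an `.unaligned` compartment (see
#' [sim_params()]`$aligned_frac`), those draws are dropped from the
#' returned matrix: row sums are then the aligned totals, and `depth` is
#' recorded as the library size.
#'
#' @param prob Samples x contigs probability matrix (rows sum to 1).
#' @param depth Reads per sample.
#' @param seed Optional integer seed.
#' @return Integer count matrix with a `library_sizes` attribute.
#' @export
simulate_counts <- function(prob, depth, seed = NULL) {
  stopifnot(is.matrix(prob), depth >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- t(apply(prob, 1, function(p) stats::rmultinom(1, depth, p)[, 1]))
  dimnames(m) <- dimnames(prob)
  m <- m[, colnames(m) != ".unaligned", drop = FALSE]
  storage.mode(m) <- "integer"
  attr(m, "library_sizes") <- stats::setNames(rep(depth, nrow(m)), rownames(m))
  m
}

#' Random reference contigs
#'
#' Uniform-random ACGT sequences named `contig1..n`, for read emission.
#'
#' @param n Number of contigs.
#' @param length_range Length range (uniform integer draw).
#' @param seed Optional seed.
#' @return A [Biostrings::DNAStringSet].
#' @export
simulate_contigs <- function(n, length_range = c(300, 800), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample.int(length_range[2] - length_range[1] + 1L, n,
                     replace = TRUE) + length_range[1] - 1L
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- contig_ids(n)
  out
}

#' Emit reads and truth alignments for a count matrix
#'
#' For every sample, writes `count[s, j]` reads per contig j: uniformly
#' positioned substrings of the contig with substitution errors at
#' `error_rate` and Phred qualities drawn around Q35 with 3' decay (so
#' quality trimming has nontrivial work). A truth SAM per sample records
#' the source contig and position of every read, so counting the truth
#' alignments reproduces the input matrix exactly.
#'
#' @param contigs A [Biostrings::DNAStringSet] of reference contigs; all
#'   must be at least `read_length` long.
#' @param counts Sample-by-contig count matrix (columns must match
#'   `names(contigs)`).
#' @param dir Output directory (created if needed).
#' @param read_length Read length; default 100.
#' @param error_rate Per-base substitution rate; default 0.005.
#' @param seed Optional seed.
#' @return Data frame with one row per sample: `sample`, `fastq`, `sam`.
#' @export
simulate_reads <- function(contigs, counts, dir, read_length = 100,
                           error_rate = 0.005, seed = NULL) {
  stopifnot(methods::is(contigs, "DNAStringSet"), is.matrix(counts))
  if (!identical(colnames(counts), names(contigs)))
    stop("count matrix columns must match contig names")
  lens <- Biostrings::width(contigs)
  if (any(lens < read_length))
    stop("contig shorter than the read length: ",
         names(contigs)[which(lens < read_length)[1]])
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cseq <- as.character(contigs)
  out <- data.frame(sample = rownames(counts), fastq = NA_character_,
                    sam = NA_character_)
  for (s in seq_len(nrow(counts))) {
    sample_id <- rownames(counts)[s]
    n_reads <- sum(counts[s, ])
    src <- rep(seq_along(contigs), counts[s, ])
    if (n_reads > 0) src <- sample(src)          # shuffle file order
    ids <- sprintf("%s_read%d", sample_id, seq_len(max(n_reads, 0)))
    pos <- integer(n_reads); seqs <- character(n_reads)
    quals <- vector("list", n_reads)
    for (r in seq_len(n_reads)) {
      j <- src[r]
      p <- sample.int(lens[j] - read_length + 1L, 1)
      bases <- strsplit(substr(cseq[j], p, p + read_length - 1L), "")[[1]]
      err <- stats::runif(read_length) < error_rate
      if (any(err))
        bases[err] <- vapply(bases[err], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      q <- round(35 - 10 * (seq_len(read_length) / read_length)^2 +
                   stats::rnorm(read_length, 0, 2))
      quals[[r]] <- pmax(2L, pmin(40L, as.integer(q)))
      pos[r] <- p
      seqs[r] <- paste(bases, collapse = "")
    }
    fq <- file.path(dir, paste0(sample_id, ".fastq"))
    write_fastq(list(id = ids, bases = seqs, quals = quals), fq)
    sam <- file.path(dir, paste0(sample_id, ".sam"))
    write_truth_sam(sam, ids, names(contigs)[src], pos, seqs, quals,
                    names(contigs), lens)
    out$fastq[s] <- fq
    out$sam[s] <- sam
  }
  out
}

#' Synthetic alignment streams from a count matrix
#'
#' Expands each sample's counts into a stream of already-aligned records
#' (one mapped primary record per read, shuffled into a random file
#' order), the cheap, sequence-free counterpart of [simulate_reads()] for
#' exercising depth subsampling and counting at scale.
#'
#' @param counts Sample-by-contig count matrix.
#' @param seed Optional seed for the record shuffle.
#' @return Named list of alignment data frames in the
#'   [read_alignments()] layout, each carrying the contig universe.
#' @export
simulate_alignment_stream <- function(counts, seed = NULL) {
  stopifnot(is.matrix(counts))
  if (!is.null(seed)) set.seed(seed)
  universe <- colnames(counts)
  out <- lapply(seq_len(nrow(counts)), function(s) {
    src <- rep(universe, counts[s, ])
    if (length(src) > 1) src <- sample(src)
    aln <- data.frame(
      read_id   = sprintf("%s_read%d", rownames(counts)[s], seq_along(src)),
      flag      = 0L,
      contig_id = src,
      mapq      = 60L,
      is_mapped = TRUE,
      is_primary = TRUE,
      stringsAsFactors = FALSE
    )
    attr(aln, "contig_universe") <- universe
    aln
  })
  names(out) <- rownames(counts)
  out
}

## minimal SAM text emission (header + one primary mapped record per read)
write_truth_sam <- function(path, ids, rnames, pos, seqs, quals,
                            universe, lens) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", universe, lens))
  qstr <- vapply(quals, function(q) intToUtf8(q + 33L), character(1))
  rec <- if (length(ids)) sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                                  ids, rnames, pos, nchar(seqs), seqs, qstr)
         else character(0)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
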
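#' Glitch rate from the glitch size/skip parameter
#'
#' Read glitches — localised breaks in read continuity — are controlled by
#' three numbers: glitch size, glitch skip, and the mean distance in bp
#' between glitches (the rate). The rate is derived from the shared
#' size/skip value `s` as
#' \deqn{rate(s) = 100000 / 1.6986^{s/10}}
#' so reads with no glitchiness (`s = 0`) see one glitch every 100,000 bp
#' on average, and the rate decreases strictly as `s` grows.
#'
#' @param size_skip Non-negative glitch size/skip value(s).
#' @return Mean bp between glitches (same length as `size_skip`).
#' @examples
#' glitch_rate(0)   # 100000
#' glitch_rate(10)  # 100000 / 1.6986
#' @export
glitch_rate <- function(size_skip) {
  if (any(size_skip < 0)) stop("size_skip must be non-negative")
  100000 / 1.6986^(size_skip / 10)
}

#' Sample read-simulation parameter vectors
#'
#' Draws the per-read-set simulation parameters from the distributions used
#' to generate a maximally varied benchmarking panel:
#' mean depth ~ U(5, 200) x; mean read length ~ U(100, 20000) bp; read
#' length SD ~ U(100, 2 x mean length); mean read identity ~ U(80, 99) %;
#' max identity ~ U(mean identity + 1, 100) %; identity SD ~ U(1, max
#' identity - mean identity); junk, random and chimera rates each
#' exponential with mean 2%; a shared glitch size/skip ~ U(0, 100) from
#' which the glitch rate follows via [glitch_rate()]; adapter length
#' exponential with mean 50 bp. The exponential draws are unbounded above
#' and accepted as drawn. Every draw is deterministic for a given seed.
#'
#' @param seed Integer seed.
#' @param n Number of parameter vectors to draw.
#' @return Data frame with one row per read set and columns `mean_depth`,
#'   `mean_length`, `length_sd`, `mean_identity`, `max_identity`,
#'   `identity_sd`, `junk_rate`, `random_rate`, `chimera_rate`,
#'   `glitch_size`, `glitch_skip`, `glitch_rate`, `adapter_length`, `seed`.
#' @export
sample_read_params <- function(seed = 1L, n = 1L) {
  withr::with_seed(seed, {
    mean_depth <- runif(n, 5, 200)
    mean_length <- runif(n, 100, 20000)
    length_sd <- runif(n, 100, 2 * mean_length)
    mean_identity <- runif(n, 80, 99)
    max_identity <- runif(n, mean_identity + 1, 100)
    identity_sd <- runif(n, 1, max_identity - mean_identity)
    junk_rate <- rexp(n, rate = 1 / 0.02)
    random_rate <- rexp(n, rate = 1 / 0.02)
    chimera_rate <- rexp(n, rate = 1 / 0.02)
    s <- runif(n, 0, 100)
    adapter_length <- rexp(n, rate = 1 / 50)
    data.frame(mean_depth, mean_length, length_sd, mean_identity,
               max_identity, identity_sd, junk_rate, random_rate,
               chimera_rate, glitch_size = s, glitch_skip = s,
               glitch_rate = glitch_rate(s), adapter_length,
               seed = seed)
  })
}

#' Write sampled read parameters as TSV
#'
#' @param params Data frame from [sample_read_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_params <- function(params, path) {
  write.table(params, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample a plasmid's read depth relative to the chromosome
#'
#' Small plasmids often have high per-cell copy number but can be biased
#' against in library preparation, so their read depth relative to the
#' chromosome is drawn from a range that widens as the plasmid shrinks:
#' the log2 relative depth is uniform on `[-W, W]` where the half-width
#' `W` interpolates log-linearly in plasmid length between `w_large`
#' (default 0.1, i.e. within ~7% of chromosome depth) at `large_size`
#' (300 kbp, the maximum plasmid size under QC) and `w_small` (default
#' 2.0, i.e. 0.25x-4x) at `small_size` (1 kbp). This envelope is this
#' package's own parameterisation of that qualitative design; the
#' endpoints are configurable.
#'
#' @param plasmid_len Plasmid length, bp (must not exceed
#'   `chromosome_len`).
#' @param chromosome_len Chromosome length, bp.
#' @param seed Integer seed.
#' @param w_small,w_large Half-widths (log2) at `small_size`/`large_size`.
#' @param small_size,large_size Plasmid lengths anchoring the envelope, bp.
#' @return Relative depth multiplier (> 0), deterministic per seed.
#' @export
sample_plasmid_depth <- function(plasmid_len, chromosome_len, seed = 1L,
                                 w_small = 2.0, w_large = 0.1,
                                 small_size = 1000, large_size = 300e3) {
  if (plasmid_len <= 0) stop("plasmid_len must be positive")
  if (plasmid_len > chromosome_len)
    stop("plasmid_len exceeds chromosome_len")
  w <- plasmid_depth_halfwidth(plasmid_len, w_small, w_large,
                               small_size, large_size)
  withr::with_seed(seed, 2^runif(1, -w, w))
}

plasmid_depth_halfwidth <- function(plasmid_len, w_small = 2.0,
                                    w_large = 0.1, small_size = 1000,
                                    large_size = 300e3) {
  x <- pmin(pmax(log(plasmid_len), log(small_size)), log(large_size))
  frac <- (x - log(small_size)) / (log(large_size) - log(small_size))
  w_small + frac * (w_large - w_small)
}

#' Subsample reads to a target depth
#'
#' Draws a random subset of reads, without replacement, whose total base
#' count divided by the genome size is the smallest depth at or above
#' `target_depth` achievable by adding whole reads in the sampled order
#' (so removing the last-added read would fall below the target).
#'
#' @param reads Named character vector of read sequences, or a
#'   `DNAStringSet`.
#' @param genome_size Genome size in bp.
#' @param target_depth Target depth in x coverage.
#' @param seed Integer seed.
#' @return The selected reads, in sampled order.
#' @export
subsample_reads <- function(reads, genome_size, target_depth, seed = 1L) {
  lens <- if (is.character(reads)) nchar(reads)
          else Biostrings::width(reads)
  total_depth <- sum(as.numeric(lens)) / genome_size
  if (total_depth < target_depth)
    stop(sprintf(
      "input reads reach only %.2fx depth (target %.2fx)",
      total_depth, target_depth))
  ord <- withr::with_seed(seed, sample.int(length(reads)))
  cum <- cumsum(as.numeric(lens[ord])) / genome_size
  k <- which(cum >= target_depth)[1]
  reads[ord[seq_len(k)]]
}

#' Subsample a FASTQ file to a target depth
#'
#' Reads a four-line-per-record FASTQ file, applies [subsample_reads()] to
#' its sequences (qualities are carried along unchanged; depth is computed
#' from sequence lengths only) and writes the subset.
#'
#' @param path Input FASTQ path.
#' @param out Output FASTQ path.
#' @inheritParams subsample_reads
#' @return Number of reads written, invisibly.
#' @export
subsample_fastq <- function(path, out, genome_size, target_depth,
                            seed = 1L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ file is not four lines per record: ", path)
  n <- length(lines) %/% 4L
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  names(seqs) <- as.character(seq_len(n))
  kept <- subsample_reads(seqs, genome_size, target_depth, seed)
  idx <- as.integer(names(kept))
  rec <- unlist(lapply(idx, function(i) lines[(4L * (i - 1L) + 1L):(4L * i)]))
  writeLines(rec, out)
  invisible(length(idx))
}
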
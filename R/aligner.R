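#' Aligner backends
#'
#' Assessment needs alignments of assembly contigs against each (tripled)
#' reference replicon. Three interchangeable backends are provided, each a
#' function `f(contigs, target_name, target_seq)` returning an
#' [alignments] data frame:
#'
#' * `aligner_builtin()` — a compiled local affine-gap aligner
#'   (match +1, mismatch -4, gap open 4, gap extend 2). After reporting the
#'   best local alignment it masks the aligned query interval and repeats,
#'   so fragmented or rearranged contigs yield one alignment per block. It
#'   is exact and dependency-free but quadratic, intended for sequences up
#'   to a few tens of kbp.
#' * `aligner_minimap2()` — shells out to an external `minimap2` binary with
#'   the asm20 preset, 10 kbp chain-elongation and banding thresholds, and
#'   Z-drop scores 1000/500, with `--eqx` so CIGARs distinguish matches from
#'   mismatches. Use this at genome scale.
#' * `aligner_paf()` — serves precomputed alignments (e.g. fixture ground
#'   truth, or a PAF produced by any aligner), filtered by target name.
#'
#' @param min_score Minimum local alignment score to report.
#' @param max_alignments Maximum alignments reported per contig and strand.
#' @return A backend function.
#' @name aligner-backends
NULL

#' @rdname aligner-backends
#' @param zdrop Z-drop score: an alignment is split wherever its running
#'   score falls more than this far below its running maximum, mirroring
#'   the chain-breaking behaviour of the external aligner so that long
#'   low-identity regions (e.g. an inverted segment) do not get bridged
#'   into one spuriously long alignment.
#' @export
aligner_builtin <- function(min_score = 50L, max_alignments = 20L,
                            zdrop = 1000L) {
  function(contigs, target_name, target_seq) {
    out <- list()
    tlen <- nchar(target_seq)
    for (ct in contigs) {
      qlen <- nchar(ct$seq)
      for (std in c("+", "-")) {
        qseq <- if (std == "+") ct$seq else reverse_complement(ct$seq)
        hits <- sw_align_multi(qseq, target_seq,
                               min_score = min_score,
                               max_alignments = max_alignments)
        for (h in hits) {
          for (p in split_hit_zdrop(h, zdrop)) {
            if (p$score < min_score) next
            qs <- p$q_start; qe <- p$q_end
            if (std == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
            out[[length(out) + 1L]] <- data.frame(
              query_name = ct$name, query_len = qlen,
              query_start = qs, query_end = qe, strand = std,
              target_name = target_name, target_len = tlen,
              target_start = p$t_start, target_end = p$t_end,
              matches = p$n_match, cigar = p$cigar, mapq = 255L,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(out) == 0L) return(alignments())
    df <- do.call(rbind, out)
    df$has_cigar <- nzchar(df$cigar)
    class(df) <- c("alignments", "data.frame")
    validate_alignments(df)
  }
}

# Split one raw alignment hit wherever the running alignment score drops
# more than `zdrop` below its running maximum. Each piece is trimmed to
# start and end on a match run; pieces without matches are dropped.
# Scoring matches the built-in aligner: match +1, mismatch -4, gap run of
# length k costs 4 + 2k.
split_hit_zdrop <- function(h, zdrop) {
  ops <- cigar_ops(h$cigar)
  n <- nrow(ops)
  sc <- ifelse(ops$op == "=", ops$len,
        ifelse(ops$op == "X", -4 * ops$len, -(4 + 2 * ops$len)))
  cq <- c(0L, cumsum(ifelse(ops$op %in% c("=", "X", "I"), ops$len, 0L)))
  ct <- c(0L, cumsum(ifelse(ops$op %in% c("=", "X", "D"), ops$len, 0L)))
  cs <- c(0, cumsum(sc))
  segs <- list()
  seg_start <- 1L; best <- 1L
  for (i in seq_len(n + 1L)) {
    if (cs[i] > cs[best]) best <- i
    else if (cs[best] - cs[i] > zdrop) {
      segs[[length(segs) + 1L]] <- c(seg_start, best)
      seg_start <- i; best <- i
    }
  }
  segs[[length(segs) + 1L]] <- c(seg_start, best)
  pieces <- list()
  for (s in segs) {
    a <- s[1]; b <- s[2]
    while (a < b && ops$op[a] != "=") a <- a + 1L
    while (b > a && ops$op[b - 1L] != "=") b <- b - 1L
    if (b <= a) next
    idx <- a:(b - 1L)
    pieces[[length(pieces) + 1L]] <- list(
      q_start = h$q_start + cq[a], q_end = h$q_start + cq[b],
      t_start = h$t_start + ct[a], t_end = h$t_start + ct[b],
      n_match = sum(ops$len[idx][ops$op[idx] == "="]),
      score = cs[b] - cs[a],
      cigar = paste0(ops$len[idx], ops$op[idx], collapse = ""))
  }
  pieces
}

#' @rdname aligner-backends
#' @param truth An [alignments] data frame or path to a PAF file with
#'   precomputed alignments against the tripled references.
#' @export
aligner_paf <- function(truth) {
  aln <- if (is.character(truth)) parse_paf(truth) else truth
  function(contigs, target_name, target_seq) {
    keep <- aln$target_name == target_name &
      aln$query_name %in% vapply(contigs, `[[`, character(1), "name")
    out <- aln[keep, , drop = FALSE]
    class(out) <- c("alignments", "data.frame")
    out
  }
}

#' @rdname aligner-backends
#' @param binary Name or path of the minimap2 executable.
#' @param preset Minimap2 preset (`-x`).
#' @param chain_gap Chain elongation threshold in bp (`-g`).
#' @param band Banding threshold in bp (`-r`).
#' @param zdrop,zdrop_inv Z-drop and inversion Z-drop scores (`-z`).
#' @export
aligner_minimap2 <- function(binary = "minimap2", preset = "asm20",
                             chain_gap = 10000, band = 10000,
                             zdrop = 1000, zdrop_inv = 500) {
  if (Sys.which(binary) == "" && !file.exists(binary))
    stop("minimap2 binary not found: ", binary)
  function(contigs, target_name, target_seq) {
    ref_fa <- tempfile(fileext = ".fasta")
    qry_fa <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(ref_fa, qry_fa)), add = TRUE)
    writeLines(c(paste0(">", target_name), target_seq), ref_fa)
    write_fasta(contigs, qry_fa)
    args <- c("-c", "--eqx", "-x", preset, "-g", format(chain_gap),
              "-r", format(band), "-z", paste0(zdrop, ",", zdrop_inv),
              ref_fa, qry_fa)
    paf <- suppressWarnings(system2(binary, args, stdout = TRUE,
                                    stderr = FALSE))
    if (length(paf) == 0L) return(alignments())
    parse_paf(paf)
  }
}
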
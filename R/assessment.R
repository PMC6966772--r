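#' Contiguity of an assembled replicon
#'
#' Contiguity is the headline assembly-quality metric: the length of the
#' longest single alignment between the assembly and the reference
#' replicon, as a percentage of the replicon length. Alignments are made
#' against a tripled copy of the circular reference (see
#' [triple_reference()]), so the metric does not depend on where the
#' assembler chose to start the circular contig. Exactly 100% means the
#' replicon was assembled completely with clean circularisation; values
#' below 100% indicate missing sequence (e.g. a gapped junction, or
#' fragmentation for much lower values); values above 100% indicate
#' duplicated sequence, typically start-end overlap (a fully doubled
#' plasmid contig gives ~200%).
#'
#' @param aln An [alignments] data frame of contig-vs-tripled-reference
#'   alignments for one replicon.
#' @param replicon_length Length of the (untripled) reference replicon, bp.
#' @return Contiguity in percent (0 when there is no alignment; may exceed
#'   100, bounded by 300 for a tripled reference).
#' @examples
#' a <- alignments("ctg", 10000L, 0L, 10000L, "+", "ref", 30000L,
#'                 100L, 10100L, 10000L, "10000=")
#' contiguity(a, 10000)  # 100
#' @export
contiguity <- function(aln, replicon_length) {
  if (replicon_length <= 0) stop("replicon_length must be positive")
  if (nrow(aln) == 0L) return(0)
  i <- longest_alignment(aln)
  100 * (aln$target_end[i] - aln$target_start[i]) / replicon_length
}

#' Select the longest single alignment
#'
#' "Longest" is measured on the target (reference) side, because contiguity
#' is defined relative to the reference replicon length. Ties are broken by
#' more matching bases, then by lexicographically smaller contig name, so
#' the choice is deterministic.
#'
#' @param aln An [alignments] data frame (non-empty).
#' @return Row index of the longest alignment.
#' @export
longest_alignment <- function(aln) {
  if (nrow(aln) == 0L) stop("no alignments")
  span <- aln$target_end - aln$target_start
  ord <- order(-span, -aln$matches, aln$query_name)
  ord[1]
}

#' Base-level identity of an alignment
#'
#' BLAST-style identity: matching bases divided by the number of alignment
#' columns, where columns include mismatches and every inserted or deleted
#' base. With `gap_compressed = TRUE` each indel run counts as a single
#' column (minimap2's `de`-tag convention) — offered as an option, not the
#' default. For CIGARs containing `M` (match-or-mismatch), the match count
#' falls back to the alignment's `matches` field.
#'
#' @param aln A one-row [alignments] data frame (or a row index into a
#'   larger one via `aln[i, ]`).
#' @param gap_compressed Count each indel run as one column.
#' @return Identity in percent.
#' @examples
#' a <- alignments("c", 100L, 0L, 100L, "+", "r", 100L, 0L, 99L, 99L, "99=1X1D")
#' @export
alignment_identity <- function(aln, gap_compressed = FALSE) {
  stopifnot(nrow(aln) == 1L)
  if (!aln$has_cigar)
    stop("alignment for '", aln$query_name, "' has no CIGAR")
  ops <- cigar_ops(aln$cigar)
  n_match <- if (any(ops$op == "=")) sum(ops$len[ops$op == "="])
             else aln$matches
  columns <- if (gap_compressed)
    sum(ops$len[ops$op %in% c("M", "=", "X")]) + sum(ops$op %in% c("I", "D"))
  else sum(ops$len)
  100 * n_match / columns
}

#' Maximum indel size in an alignment
#'
#' The largest single insertion or deletion operation in the CIGAR of the
#' longest alignment — a measure of the worst localised structural error.
#'
#' @param aln A one-row [alignments] data frame.
#' @return Largest single I or D length in bp (0 when there are none).
#' @examples
#' a <- alignments("c", 80L, 0L, 80L, "+", "r", 100L, 0L, 83L, 80L,
#'                 "50=3D20=12I10=")
#' @export
max_indel <- function(aln) {
  stopifnot(nrow(aln) == 1L)
  if (!aln$has_cigar)
    stop("alignment for '", aln$query_name, "' has no CIGAR")
  ops <- cigar_ops(aln$cigar)
  indel <- ops$len[ops$op %in% c("I", "D")]
  if (length(indel) == 0L) 0L else max(indel)
}

#' Classify assembly completeness
#'
#' Four-way completeness status from per-replicon contiguities:
#' `fully_complete` when every replicon (chromosome and all plasmids)
#' reaches the threshold; `complete_chromosome` when the chromosome does
#' but some plasmid falls short; `incomplete` when the chromosome falls
#' short; `empty` when the assembly has no contigs at all. The threshold is
#' inclusive: contiguity of exactly 99% counts as complete.
#'
#' @param contiguities Named numeric vector (or data frame with columns
#'   `role` and `contiguity`), one entry per reference replicon.
#' @param roles Character vector matching `contiguities` when a plain
#'   vector is given; must contain exactly one `"chromosome"`.
#' @param threshold Completeness threshold in percent (default 99).
#' @param empty Logical: the assembly contained no contigs.
#' @return One of `"fully_complete"`, `"complete_chromosome"`,
#'   `"incomplete"`, `"empty"`.
#' @examples
#' classify_assembly(c(99.9, 100.2), c("chromosome", "plasmid"))
#' @export
classify_assembly <- function(contiguities, roles = NULL, threshold = 99,
                              empty = FALSE) {
  if (empty) return("empty")
  if (is.data.frame(contiguities)) {
    roles <- contiguities$role
    contiguities <- contiguities$contiguity
  }
  if (is.null(roles)) stop("replicon roles are required")
  if (sum(roles == "chromosome") != 1L)
    stop("exactly one chromosome contiguity is required")
  chrom_ok <- contiguities[roles == "chromosome"] >= threshold
  plasmid_ok <- all(contiguities[roles == "plasmid"] >= threshold)
  if (!chrom_ok) "incomplete"
  else if (plasmid_ok) "fully_complete"
  else "complete_chromosome"
}

#' Assess an assembly against a reference genome
#'
#' For each reference replicon, all contigs are aligned to the tripled
#' replicon sequence (or the plain sequence for a linear replicon), the
#' single longest alignment is selected, and contiguity, identity and
#' maximum indel size are computed from it. Contigs are assessed against
#' every replicon independently, so a contig may contribute to more than
#' one replicon's metrics. The assembly-level identity and maximum indel
#' are those of the chromosome's longest alignment, and the completeness
#' status is derived from the per-replicon contiguities.
#'
#' @param contigs List of [replicon] objects (an assembly), possibly empty.
#' @param reference A [genome] with replicon roles set.
#' @param backend An aligner backend (see [aligner-backends]).
#' @param threshold Completeness threshold in percent.
#' @param label Assembly label for reporting.
#' @return An object of class `assembly_assessment`: list with
#'   `assembly_label`, `replicons` (data frame: replicon, role, length,
#'   contiguity, identity, max_indel), `status`, `identity`, `max_indel`
#'   (chromosome-level), `n_contigs`.
#' @export
assess_assembly <- function(contigs, reference,
                            backend = aligner_builtin(),
                            threshold = 99, label = "assembly") {
  stopifnot(inherits(reference, "genome"))
  reps <- reference$replicons
  n <- length(reps)
  res <- data.frame(
    replicon = vapply(reps, `[[`, character(1), "name"),
    role = vapply(reps, `[[`, character(1), "role"),
    length = vapply(reps, length, integer(1)),
    contiguity = numeric(n), identity = rep(NA_real_, n),
    max_indel = rep(NA_integer_, n), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  chrom_identity <- NA_real_
  chrom_max_indel <- NA_integer_
  if (length(contigs) > 0L) {
    for (i in seq_len(n)) {
      r <- reps[[i]]
      target <- if (r$circular) triple_reference(r) else r$seq
      aln <- backend(contigs, r$name, target)
      if (nrow(aln) == 0L) next
      j <- longest_alignment(aln)
      best <- aln[j, , drop = FALSE]
      res$contiguity[i] <- contiguity(aln, length(r))
      if (best$has_cigar) {
        res$identity[i] <- alignment_identity(best)
        res$max_indel[i] <- max_indel(best)
      }
      if (r$role == "chromosome") {
        chrom_identity <- res$identity[i]
        chrom_max_indel <- res$max_indel[i]
      }
    }
  }
  status <- classify_assembly(res$contiguity, res$role, threshold,
                              empty = length(contigs) == 0L)
  structure(list(assembly_label = label, replicons = res, status = status,
                 identity = chrom_identity, max_indel = chrom_max_indel,
                 n_contigs = length(contigs)),
            class = "assembly_assessment")
}

#' @export
print.assembly_assessment <- function(x, ...) {
  cat(sprintf("<assembly_assessment> %s: %d contig(s), status %s\n",
              x$assembly_label, x$n_contigs, x$status))
  df <- x$replicons
  df$contiguity <- sprintf("%.1f%%", df$contiguity)
  df$identity <- ifelse(is.na(df$identity), "-",
                        sprintf("%.4f%%", as.numeric(df$identity)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Count nucleotide differences between two assemblies
#'
#' Total differences — mismatched columns plus inserted plus deleted bases —
#' summed over all alignments between two assemblies of the same genome.
#' Used to decide whether two independently produced assemblies agree
#' closely enough for one to serve as ground truth: a pair with more
#' differences than `threshold` (default 50) is rejected.
#'
#' @param aln An [alignments] data frame between the two assemblies.
#' @return `assembly_difference_count()`: integer count of differences.
#' @export
assembly_difference_count <- function(aln) {
  if (nrow(aln) == 0L) stop("no alignments between the assemblies")
  total <- 0L
  for (i in seq_len(nrow(aln))) {
    if (aln$has_cigar[i]) {
      ops <- cigar_ops(aln$cigar[i])
      if (any(ops$op == "=")) {
        total <- total + sum(ops$len[ops$op %in% c("X", "I", "D")])
      } else {
        total <- total + sum(ops$len) - aln$matches[i]
      }
    } else {
      span <- max(aln$query_end[i] - aln$query_start[i],
                  aln$target_end[i] - aln$target_start[i])
      total <- total + span - aln$matches[i]
    }
  }
  as.integer(total)
}

#' @rdname assembly_difference_count
#' @param threshold Maximum tolerated differences.
#' @return `assemblies_agree()`: logical.
#' @export
assemblies_agree <- function(aln, threshold = 50L) {
  assembly_difference_count(aln) <= threshold
}
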
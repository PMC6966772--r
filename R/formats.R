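#' Read sequences from a FASTA file
#'
#' Reads a (possibly multi-record, wrapped or unwrapped) FASTA file into a
#' list of [replicon] objects. The header token before the first whitespace
#' becomes the replicon name and sequences are upper-cased. Roles and
#' circularity flags can be supplied through a sidecar metadata table
#' (see [read_replicon_metadata()]); without metadata every record defaults
#' to a putatively-circular `"contig"`, which is how assembly output is
#' assessed when the assembler provides no circularity information.
#'
#' @param path Path to a FASTA file. A zero-byte file yields an empty list
#'   (an empty assembly).
#' @param metadata Optional data frame with columns `name`, `role`,
#'   `circular`, as returned by [read_replicon_metadata()].
#' @return List of `replicon` objects (possibly empty).
#' @export
read_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) return(list())
  nms <- sub("\\s.*$", "", names(set))
  seqs <- unname(toupper(as.character(set)))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    role <- "contig"; circ <- TRUE
    if (!is.null(metadata)) {
      row <- match(nms[i], metadata$name)
      if (!is.na(row)) {
        role <- metadata$role[row]
        circ <- metadata$circular[row]
      }
    }
    out[[i]] <- replicon(nms[i], seqs[i], circular = circ, role = role)
  }
  names(out) <- nms
  out
}

#' Write replicons to a FASTA file
#'
#' @param replicons A list of [replicon] objects or a [genome].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(replicons, path, width = 70L) {
  if (inherits(replicons, "genome")) replicons <- replicons$replicons
  seqs <- vapply(replicons, `[[`, character(1), "seq")
  names(seqs) <- vapply(replicons, `[[`, character(1), "name")
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read or write a replicon metadata sidecar table
#'
#' The sidecar is a tab-separated table with header `name`, `role`,
#' `circular` conveying the role (chromosome/plasmid) and circularity of
#' each reference replicon.
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `name` (character), `role` (character)
#'   and `circular` (logical).
#' @export
read_replicon_metadata <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "role", "circular")
  if (!all(need %in% names(df)))
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  df$circular <- as.logical(df$circular)
  df[need]
}

#' @rdname read_replicon_metadata
#' @param x A [genome] or list of replicons.
#' @export
write_replicon_metadata <- function(x, path) {
  if (inherits(x, "genome")) x <- x$replicons
  df <- data.frame(
    name = vapply(x, `[[`, character(1), "name"),
    role = vapply(x, `[[`, character(1), "role"),
    circular = vapply(x, `[[`, logical(1), "circular"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Replace ambiguous bases with 'A'
#'
#' Reference sequences are canonicalised before read simulation by replacing
#' every character outside `{A,C,G,T}` with `A`, so downstream tools see only
#' the four canonical DNA bases. Length is preserved and the operation is
#' idempotent.
#'
#' @param x A character vector of sequences, a [replicon], or a [genome].
#' @return Object of the same shape with ambiguity codes replaced.
#' @examples
#' replace_ambiguous("ACGN")  # "ACGA"
#' @export
replace_ambiguous <- function(x) UseMethod("replace_ambiguous")

#' @export
replace_ambiguous.character <- function(x) gsub("[^ACGT]", "A", toupper(x))

#' @export
replace_ambiguous.replicon <- function(x) {
  x$seq <- replace_ambiguous(x$seq)
  x
}

#' @export
replace_ambiguous.genome <- function(x) {
  x$replicons <- lapply(x$replicons, replace_ambiguous)
  x
}

#' Rotate a circular sequence
#'
#' Moves the start position of a (circular) sequence: the first `offset`
#' bases are moved to the end, i.e. `seq[offset+1..L]` followed by
#' `seq[1..offset]`. Offsets are reduced modulo the sequence length, so a
#' full-period rotation is the identity.
#'
#' @param seq A single non-empty sequence string.
#' @param offset Non-negative rotation in bp.
#' @return The rotated sequence (same length).
#' @examples
#' rotate_sequence("ACGT", 1)  # "CGTA"
#' @export
rotate_sequence <- function(seq, offset) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n == 0L) stop("cannot rotate an empty sequence")
  if (offset < 0) stop("offset must be non-negative")
  k <- offset %% n
  if (k == 0L) return(seq)
  paste0(substr(seq, k + 1L, n), substr(seq, 1L, k))
}

#' Triple a circular reference replicon
#'
#' Concatenates a circular replicon's sequence three times. Any rotation of
#' the replicon — even one carrying start-end overlap shorter than the
#' replicon itself — occurs as a single contiguous substring of the triple,
#' which is what makes the longest-alignment contiguity metric invariant to
#' the arbitrary start position of circular contigs.
#'
#' @param x A [replicon] (must be circular) or a single sequence string.
#' @return A character string of length `3 * length(x)`.
#' @export
triple_reference <- function(x) UseMethod("triple_reference")

#' @export
triple_reference.replicon <- function(x) {
  if (!x$circular)
    stop("tripling is only meaningful for circular replicons ('",
         x$name, "' is linear)")
  triple_reference(x$seq)
}

#' @export
triple_reference.character <- function(x) {
  stopifnot(length(x) == 1L, nchar(x) > 0L)
  paste0(x, x, x)
}

#' Reverse complement
#'
#' @param seq A single DNA sequence string.
#' @return The reverse complement.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Detect circular contigs from a GFA assembly graph
#'
#' Assemblers that emit GFA 1.x graphs signal a circularised contig with a
#' link (`L` line) from a segment back to itself in a consistent orientation
#' (`L A + A +` or `L A - A -`). Only such self-loops are treated as
#' circularity evidence; multi-contig cycles are not, because they do not
#' represent a single completely-assembled replicon.
#'
#' @param gfa_path Path to a GFA 1.x file.
#' @return Named logical vector: `TRUE` for contigs with an end-to-start
#'   self-link, `FALSE` otherwise, one entry per `S` segment.
#' @export
detect_circular_contigs <- function(gfa_path) {
  if (!file.exists(gfa_path)) stop("GFA file not found: ", gfa_path)
  lines <- readLines(gfa_path, warn = FALSE)
  segs <- character(0)
  circ <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    type <- substr(ln, 1L, 1L)
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (type == "S") {
      if (length(f) < 2L) stop("malformed S line at line ", i)
      segs <- c(segs, f[2])
    } else if (type == "L") {
      if (length(f) < 5L ||
          !(f[3] %in% c("+", "-")) || !(f[5] %in% c("+", "-")))
        stop("malformed L line at line ", i)
      if (f[2] == f[4] && f[3] == f[5]) circ <- c(circ, f[2])
    }
  }
  out <- segs %in% circ
  names(out) <- segs
  out
}
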
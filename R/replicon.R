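#' Replicon and genome containers
#'
#' A replicon is a single named DNA sequence with a circularity flag and a
#' role (`"chromosome"`, `"plasmid"`, or `"contig"` for assembly sequences
#' whose role is unknown). A genome is a labelled, ordered collection of
#' replicons containing exactly one chromosome and zero or more plasmids.
#'
#' @param name Sequence identifier (single string, no whitespace).
#' @param seq DNA sequence as a single character string. Upper-cased on
#'   construction; IUPAC ambiguity codes are permitted.
#' @param circular Logical; is the replicon circular?
#' @param role One of `"chromosome"`, `"plasmid"`, `"contig"`.
#' @return `replicon()` returns an object of class `replicon`; `genome()`
#'   an object of class `genome` with elements `label` and `replicons`.
#' @examples
#' chrom <- replicon("chr", "ACGTACGT", circular = TRUE, role = "chromosome")
#' g <- genome("toy", list(chrom))
#' replicon_lengths(g)
#' @export
replicon <- function(name, seq, circular = TRUE,
                     role = c("chromosome", "plasmid", "contig")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("replicon '", name, "' has an empty sequence")
  if (grepl("[^ACGTRYSWKMBDHVN]", seq))
    stop("replicon '", name, "' contains non-IUPAC characters")
  structure(
    list(name = name, seq = seq, circular = isTRUE(circular), role = role),
    class = "replicon")
}

#' @export
length.replicon <- function(x) nchar(x$seq)

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp, %s, %s\n", x$name,
              format(length(x), big.mark = ","),
              if (x$circular) "circular" else "linear", x$role))
  invisible(x)
}

#' @rdname replicon
#' @param label Genome label.
#' @param replicons List of `replicon` objects.
#' @export
genome <- function(label, replicons) {
  stopifnot(is.character(label), length(label) == 1L, is.list(replicons))
  if (!all(vapply(replicons, inherits, logical(1), "replicon")))
    stop("'replicons' must be a list of replicon objects")
  roles <- vapply(replicons, `[[`, character(1), "role")
  if (sum(roles == "chromosome") != 1L)
    stop("a genome must contain exactly one chromosome (got ",
         sum(roles == "chromosome"), ")")
  names(replicons) <- vapply(replicons, `[[`, character(1), "name")
  structure(list(label = label, replicons = replicons), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d replicon(s)\n", x$label, length(x$replicons)))
  for (r in x$replicons) print(r)
  invisible(x)
}

#' @rdname replicon
#' @param x A `genome`.
#' @export
replicon_lengths <- function(x) {
  stopifnot(inherits(x, "genome"))
  vapply(x$replicons, length, integer(1))
}

#' @rdname replicon
#' @export
chromosome_of <- function(x) {
  stopifnot(inherits(x, "genome"))
  roles <- vapply(x$replicons, `[[`, character(1), "role")
  x$replicons[[which(roles == "chromosome")]]
}

#' @rdname replicon
#' @export
plasmids_of <- function(x) {
  stopifnot(inherits(x, "genome"))
  roles <- vapply(x$replicons, `[[`, character(1), "role")
  x$replicons[roles == "plasmid"]
}
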
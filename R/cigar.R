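#' CIGAR string utilities
#'
#' Alignments carry CIGAR strings over the operations `=` (match), `X`
#' (mismatch), `I` (insertion relative to the target), `D` (deletion) and
#' `M` (match-or-mismatch, as produced by aligners run without `--eqx`).
#' `cigar_ops()` parses a CIGAR into a two-column data frame; the span
#' helpers sum the query- and target-consuming operation lengths.
#'
#' @param cigar A single CIGAR string (may be empty).
#' @return `cigar_ops()`: data frame with integer `len` and character `op`.
#' @examples
#' cigar_ops("50=3D20=12I10=")
#' cigar_query_span("10=5D10=")   # 20
#' cigar_target_span("10=5D10=")  # 25
#' @export
cigar_ops <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L)
  if (!nzchar(cigar)) return(data.frame(len = integer(0), op = character(0)))
  if (!grepl("^([0-9]+[MIDX=])+$", cigar))
    stop("invalid CIGAR string: ", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDX=]", cigar))[[1]]
  data.frame(len = as.integer(sub("[MIDX=]$", "", toks)),
             op = sub("^[0-9]+", "", toks))
}

#' @rdname cigar_ops
#' @export
cigar_query_span <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
}

#' @rdname cigar_ops
#' @export
cigar_target_span <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "D")])
}

#' @rdname cigar_ops
#' @export
cigar_n_columns <- function(cigar) {
  sum(cigar_ops(cigar)$len)
}
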
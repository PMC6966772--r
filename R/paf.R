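#' Alignment records and PAF input/output
#'
#' Alignments are kept as a data frame in PAF column order, one row per
#' alignment, with 0-based half-open intervals, forward-target coordinates
#' and the CIGAR (from the `cg:Z` tag) as a string column. `has_cigar`
#' flags rows whose PAF line carried no CIGAR.
#'
#' @param query_name,query_len,query_start,query_end Query (contig) side.
#' @param strand `"+"` or `"-"`.
#' @param target_name,target_len,target_start,target_end Target side
#'   (always forward-strand coordinates).
#' @param matches Number of matching bases (PAF column 10).
#' @param cigar CIGAR string; `""` when absent.
#' @param mapq Mapping quality (255 = unavailable).
#' @return A data frame of class `c("alignments", "data.frame")`.
#' @export
alignments <- function(query_name = character(0), query_len = integer(0),
                       query_start = integer(0), query_end = integer(0),
                       strand = character(0), target_name = character(0),
                       target_len = integer(0), target_start = integer(0),
                       target_end = integer(0), matches = integer(0),
                       cigar = character(0), mapq = integer(0)) {
  n <- length(query_name)
  if (length(mapq) == 0L && n > 0L) mapq <- rep(255L, n)
  df <- data.frame(
    query_name = as.character(query_name),
    query_len = as.integer(query_len),
    query_start = as.integer(query_start),
    query_end = as.integer(query_end),
    strand = as.character(strand),
    target_name = as.character(target_name),
    target_len = as.integer(target_len),
    target_start = as.integer(target_start),
    target_end = as.integer(target_end),
    matches = as.integer(matches),
    cigar = as.character(cigar),
    mapq = as.integer(mapq),
    stringsAsFactors = FALSE)
  df$has_cigar <- nzchar(df$cigar)
  class(df) <- c("alignments", "data.frame")
  validate_alignments(df)
}

validate_alignments <- function(df) {
  if (nrow(df) == 0L) return(df)
  bad <- df$query_end <= df$query_start | df$target_end <= df$target_start
  if (any(bad))
    stop("alignment ", which(bad)[1], ": empty or inverted interval")
  if (!all(df$strand %in% c("+", "-")))
    stop("alignment strand must be '+' or '-'")
  span_q <- df$query_end - df$query_start
  span_t <- df$target_end - df$target_start
  if (any(df$matches > pmin(span_q, span_t)))
    stop("alignment matches exceed the aligned span")
  for (i in which(df$has_cigar)) {
    qs <- cigar_query_span(df$cigar[i])
    ts <- cigar_target_span(df$cigar[i])
    if (qs != span_q[i])
      stop("alignment ", i, " (", df$query_name[i],
           "): CIGAR consumes ", qs, " query bases but the interval spans ",
           span_q[i])
    if (ts != span_t[i])
      stop("alignment ", i, " (", df$query_name[i],
           "): CIGAR consumes ", ts, " target bases but the interval spans ",
           span_t[i])
  }
  df
}

#' Read alignments from a PAF file
#'
#' Parses minimap2-style PAF with optional `cg:Z` CIGAR tags. Records are
#' validated against the alignment invariants (interval orientation, CIGAR
#' consistency with the stated query/target spans). Lines without a CIGAR
#' are retained with `cigar = ""` and `has_cigar = FALSE`.
#'
#' @param path Path to a PAF file (or a character vector of PAF lines).
#' @return An [alignments] data frame.
#' @export
parse_paf <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(alignments())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop("PAF line ", i, " has ", length(f), " columns (expected >= 12)")
    cg <- ""
    if (length(f) > 12L) {
      tag <- grep("^cg:Z:", f[13:length(f)], value = TRUE)
      if (length(tag)) cg <- sub("^cg:Z:", "", tag[1])
    }
    rows[[i]] <- data.frame(
      query_name = f[1], query_len = as.integer(f[2]),
      query_start = as.integer(f[3]), query_end = as.integer(f[4]),
      strand = f[5], target_name = f[6], target_len = as.integer(f[7]),
      target_start = as.integer(f[8]), target_end = as.integer(f[9]),
      matches = as.integer(f[10]), cigar = cg, mapq = as.integer(f[12]),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$has_cigar <- nzchar(df$cigar)
  class(df) <- c("alignments", "data.frame")
  validate_alignments(df)
}

#' Write alignments to a PAF file
#'
#' Emits one 12-column PAF line per alignment plus a `cg:Z` tag for rows
#' with a CIGAR. `parse_paf()` round-trips the output.
#'
#' @param aln An [alignments] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  lines <- character(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    block <- if (aln$has_cigar[i]) cigar_n_columns(aln$cigar[i])
             else max(aln$query_end[i] - aln$query_start[i],
                      aln$target_end[i] - aln$target_start[i])
    base <- paste(aln$query_name[i], aln$query_len[i], aln$query_start[i],
                  aln$query_end[i], aln$strand[i], aln$target_name[i],
                  aln$target_len[i], aln$target_start[i], aln$target_end[i],
                  aln$matches[i], block, aln$mapq[i], sep = "\t")
    if (aln$has_cigar[i])
      base <- paste(base, paste0("cg:Z:", aln$cigar[i]), sep = "\t")
    lines[i] <- base
  }
  writeLines(lines, path)
  invisible(path)
}
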
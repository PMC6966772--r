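#' Assess an assembly from files and write TSV reports
#'
#' File-level orchestration of [assess_assembly()]: reads the assembly
#' FASTA (and optional GFA for circularity flags), the reference FASTA
#' with its metadata sidecar, aligns with the chosen backend and writes
#' two tab-separated reports into `outdir`:
#'
#' * `<label>_replicons.tsv` — one row per reference replicon with columns
#'   `assembly`, `replicon`, `role`, `length`, `contiguity`, `identity`,
#'   `max_indel`. Percentages are reported to 0.1% (contiguity) and
#'   0.0001% (identity) precision; raw values stay at full precision in
#'   the returned object.
#' * `<label>_status.tsv` — one row per assembly with columns `assembly`,
#'   `status`, `n_contigs`, `identity`, `max_indel` (chromosome-level).
#'
#' A short log describing the backend and thresholds goes to `stderr`.
#'
#' @param assembly Path to the assembly FASTA. A missing or zero-byte file
#'   is assessed as an empty assembly.
#' @param reference Path to the reference FASTA.
#' @param metadata Path to the reference metadata TSV (`name`, `role`,
#'   `circular`); when `NULL`, the first reference record is taken as the
#'   chromosome and the rest as plasmids, all circular.
#' @param gfa Optional path to the assembly's GFA graph; contigs with a
#'   self-loop are flagged circular (informational only — all contigs are
#'   assessed against the circular references regardless).
#' @param backend `"builtin"`, `"minimap2"`, or a path to a precomputed
#'   PAF of alignments against the tripled references; alternatively a
#'   backend function (see [aligner-backends]).
#' @param threshold Completeness threshold in percent.
#' @param outdir Output directory (created if needed).
#' @param label Assembly label used in file names and report rows.
#' @return The `assembly_assessment`, invisibly.
#' @export
assess_files <- function(assembly, reference, metadata = NULL, gfa = NULL,
                         backend = "builtin", threshold = 99,
                         outdir = ".", label = NULL) {
  if (!file.exists(reference)) stop("reference not found: ", reference)
  if (is.null(label))
    label <- sub("\\.(fa|fasta|fna)$", "", basename(assembly))
  meta <- if (!is.null(metadata)) read_replicon_metadata(metadata) else NULL
  refs <- read_fasta(reference, meta)
  if (is.null(meta) && length(refs) > 0L) {
    refs[[1]]$role <- "chromosome"
    for (i in seq_along(refs)[-1]) refs[[i]]$role <- "plasmid"
  }
  ref_genome <- genome(tools::file_path_sans_ext(basename(reference)), refs)
  contigs <- if (file.exists(assembly)) read_fasta(assembly) else list()
  if (!is.null(gfa)) {
    circ <- detect_circular_contigs(gfa)
    for (i in seq_along(contigs)) {
      hit <- match(contigs[[i]]$name, names(circ))
      if (!is.na(hit)) contigs[[i]]$circular <- circ[[hit]]
    }
  }
  backend_fn <- if (is.function(backend)) backend
    else switch(backend,
                builtin = aligner_builtin(),
                minimap2 = aligner_minimap2(),
                aligner_paf(backend))
  backend_lbl <- if (is.function(backend)) "custom" else backend
  message(sprintf("[circassess] assess %s vs %s | backend=%s threshold=%s%%",
                  label, ref_genome$label, backend_lbl, threshold))
  report <- assess_assembly(contigs, ref_genome, backend_fn,
                            threshold = threshold, label = label)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_assessment_tsv(report, outdir)
  invisible(report)
}

write_assessment_tsv <- function(report, outdir) {
  df <- report$replicons
  per <- data.frame(assembly = report$assembly_label, replicon = df$replicon,
                    role = df$role, length = df$length,
                    contiguity = sprintf("%.1f", df$contiguity),
                    identity = ifelse(is.na(df$identity), "NA",
                                      sprintf("%.4f", df$identity)),
                    max_indel = df$max_indel, stringsAsFactors = FALSE)
  status <- data.frame(assembly = report$assembly_label,
                       status = report$status, n_contigs = report$n_contigs,
                       identity = ifelse(is.na(report$identity), "NA",
                                         sprintf("%.4f", report$identity)),
                       max_indel = report$max_indel,
                       stringsAsFactors = FALSE)
  f1 <- file.path(outdir, paste0(report$assembly_label, "_replicons.tsv"))
  f2 <- file.path(outdir, paste0(report$assembly_label, "_status.tsv"))
  write.table(per, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(status, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Summarise completeness statuses across assemblies
#'
#' Aggregates assessment reports (or their status TSVs) into per-status
#' counts and proportions — the aggregation behind "proportion of each
#' possible assembly outcome" summary panels. Proportions sum to 1.
#'
#' @param reports A list of `assembly_assessment` objects, or a character
#'   vector of `*_status.tsv` paths.
#' @return Data frame with columns `status`, `count`, `proportion`,
#'   covering all four statuses (zero counts included).
#' @export
summarise_assessments <- function(reports) {
  statuses <- if (is.character(reports)) {
    unlist(lapply(reports, function(p) read.delim(p)$status))
  } else {
    vapply(reports, `[[`, character(1), "status")
  }
  levels <- c("fully_complete", "complete_chromosome", "incomplete", "empty")
  counts <- vapply(levels, function(s) sum(statuses == s), integer(1))
  data.frame(status = levels, count = counts,
             proportion = counts / max(1L, length(statuses)),
             row.names = NULL, stringsAsFactors = FALSE)
}
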
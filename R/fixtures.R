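#' Reference-genome quality-control rules
#'
#' The genome-selection filters applied before building a benchmarking
#' panel: a genome is excluded if its chromosome exceeds `max_chromosome`
#' or falls below `min_chromosome`, if any plasmid exceeds `max_plasmid`
#' or `max_plasmid_fraction` of the chromosome size, or if it carries more
#' than `max_plasmid_count` plasmids. Defaults are the published thresholds
#' (10 Mbp / 500 kbp / 300 kbp / 25% / 9); all are configurable so that
#' desk-scale genomes (kbp rather than Mbp) can exercise every rule.
#'
#' @param max_chromosome,min_chromosome Chromosome size bounds, bp.
#' @param max_plasmid Maximum plasmid size, bp.
#' @param max_plasmid_fraction Maximum plasmid size as a fraction of the
#'   chromosome size.
#' @param max_plasmid_count Maximum number of plasmids.
#' @return A list of class `qc_rule`.
#' @export
qc_rule <- function(max_chromosome = 10e6, min_chromosome = 500e3,
                    max_plasmid = 300e3, max_plasmid_fraction = 0.25,
                    max_plasmid_count = 9L) {
  stopifnot(min_chromosome < max_chromosome, max_plasmid > 0,
            max_plasmid_fraction > 0, max_plasmid_count >= 0)
  structure(list(max_chromosome = max_chromosome,
                 min_chromosome = min_chromosome,
                 max_plasmid = max_plasmid,
                 max_plasmid_fraction = max_plasmid_fraction,
                 max_plasmid_count = as.integer(max_plasmid_count)),
            class = "qc_rule")
}

qc_violations <- function(g, rule) {
  chrom_len <- length(chromosome_of(g))
  plas_lens <- vapply(plasmids_of(g), length, integer(1))
  out <- character(0)
  if (chrom_len > rule$max_chromosome) out <- c(out, "max_chromosome")
  if (chrom_len < rule$min_chromosome) out <- c(out, "min_chromosome")
  if (any(plas_lens > rule$max_plasmid)) out <- c(out, "max_plasmid")
  if (any(plas_lens > rule$max_plasmid_fraction * chrom_len))
    out <- c(out, "max_plasmid_fraction")
  if (length(plas_lens) > rule$max_plasmid_count)
    out <- c(out, "max_plasmid_count")
  out
}

#' Apply quality-control filters to a set of genomes
#'
#' A genome survives if and only if it violates none of the five rules in
#' `rule`; the rejection table lists every violated rule per genome. The
#' filter is order-independent and idempotent.
#'
#' @param genomes List of [genome] objects.
#' @param rule A [qc_rule].
#' @return List with `retained` (surviving genomes), `rejected` (data frame
#'   with columns `label`, `reasons`) and `keep` (logical vector).
#' @export
apply_qc_filters <- function(genomes, rule = qc_rule()) {
  viols <- lapply(genomes, qc_violations, rule = rule)
  keep <- lengths(viols) == 0L
  labels <- vapply(genomes, `[[`, character(1), "label")
  rejected <- data.frame(
    label = labels[!keep],
    reasons = vapply(viols[!keep], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  list(retained = genomes[keep], rejected = rejected, keep = keep)
}

#' Generate a random genome
#'
#' Fabricates a genome of uniform-random A/C/G/T sequences with the
#' requested chromosome and plasmid lengths — a stand-in for a real
#' reference genome so that the whole assessment pipeline can be exercised
#' without downloads. By default only the scale-free QC rules (plasmid
#' fraction and count) are enforced on the request, so desk-scale genomes
#' of a few kbp are allowed; pass a [qc_rule] to enforce absolute size
#' bounds as well.
#'
#' @param chrom_len Chromosome length, bp.
#' @param plasmid_lens Integer vector of plasmid lengths, bp (may be empty).
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @param label Genome label.
#' @param rule Optional [qc_rule] applied to the requested structure.
#' @return A [genome] with one circular chromosome and one circular plasmid
#'   per requested length.
#' @export
generate_random_genome <- function(chrom_len, plasmid_lens = integer(0),
                                   seed = 1L, label = "genome",
                                   rule = NULL) {
  stopifnot(chrom_len > 0, all(plasmid_lens > 0))
  if (any(plasmid_lens > 0.25 * chrom_len))
    stop("requested plasmid exceeds 25% of the chromosome size ",
         "(max_plasmid_fraction)")
  if (length(plasmid_lens) > 9L)
    stop("more than 9 plasmids requested (max_plasmid_count)")
  reps <- withr::with_seed(seed, {
    draw <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
    out <- list(replicon(paste0(label, "_chromosome"), draw(chrom_len),
                         circular = TRUE, role = "chromosome"))
    for (i in seq_along(plasmid_lens))
      out[[i + 1L]] <- replicon(paste0(label, "_plasmid_", i),
                                draw(plasmid_lens[i]),
                                circular = TRUE, role = "plasmid")
    out
  })
  g <- genome(label, reps)
  if (!is.null(rule)) {
    v <- qc_violations(g, rule)
    if (length(v))
      stop("requested genome violates QC rule(s): ", paste(v, collapse = ", "))
  }
  g
}

#' Select a benchmarking panel of genomes
#'
#' Rejection sampling that mirrors the published panel design: draw
#' `n_plasmid_bearing` genomes from those carrying plasmids, redrawing the
#' whole subset until it contains exactly `target_plasmid_total` plasmids,
#' then add `n_plasmid_free` genomes drawn from those without plasmids.
#' (At full scale: 250 plasmid-bearing genomes re-drawn until they hold
#' exactly 500 plasmids, plus 250 plasmid-free genomes.)
#'
#' @param genomes Pool of [genome] objects.
#' @param n_plasmid_bearing Number of plasmid-bearing genomes to select.
#' @param target_plasmid_total Required total plasmid count in the
#'   plasmid-bearing subset.
#' @param n_plasmid_free Number of plasmid-free genomes to add.
#' @param seed Integer seed.
#' @param max_attempts Maximum redraws before giving up.
#' @return List with `panel` (selected genomes, bearing first), `attempts`,
#'   and `plasmid_total`.
#' @export
select_genome_panel <- function(genomes, n_plasmid_bearing,
                                target_plasmid_total, n_plasmid_free,
                                seed = 1L, max_attempts = 1000L) {
  n_plas <- vapply(genomes, function(g) length(plasmids_of(g)), integer(1))
  bearing <- genomes[n_plas > 0L]
  free <- genomes[n_plas == 0L]
  if (length(bearing) < n_plasmid_bearing)
    stop("only ", length(bearing), " plasmid-bearing genomes in the pool")
  if (length(free) < n_plasmid_free)
    stop("only ", length(free), " plasmid-free genomes in the pool")
  withr::with_seed(seed, {
    best <- NA_integer_
    for (attempt in seq_len(max_attempts)) {
      pick <- sample.int(length(bearing), n_plasmid_bearing)
      total <- sum(n_plas[n_plas > 0L][pick])
      if (is.na(best) ||
          abs(total - target_plasmid_total) < abs(best - target_plasmid_total))
        best <- total
      if (total == target_plasmid_total) {
        panel <- c(bearing[pick], sample(free, n_plasmid_free))
        return(list(panel = panel, attempts = attempt,
                    plasmid_total = total))
      }
    }
    stop("could not reach ", target_plasmid_total, " plasmids in ",
         max_attempts, " attempts (closest achieved: ", best, ")")
  })
}

#' Specify an assembly defect
#'
#' Describes how to derange one replicon's perfect assembly into one of the
#' six possible states of a circular-replicon assembly: `perfect` (clean
#' circularisation), `gapped` (bases missing at the contig junction),
#' `overlapping` (start-end overlap: leading bases duplicated at the end),
#' `fragmented` (split into several contigs), `missing` (an internal block
#' deleted), and `misassembled` (an internal segment inverted, breaking the
#' longest alignment).
#'
#' @param state One of the six states above.
#' @param magnitude Gap/overlap/deletion length in bp, or the fragment
#'   count (>= 2) for `fragmented`.
#' @param rotation Start-position rotation in bp applied before the defect.
#' @param position Optional 0-based offset (within the rotated contig) for
#'   the `missing` deletion or `misassembled` segment start; drawn at
#'   random when `NULL`.
#' @return A list of class `defect_spec`.
#' @export
defect_spec <- function(state = c("perfect", "gapped", "overlapping",
                                  "fragmented", "missing", "misassembled"),
                        magnitude = 0L, rotation = 0L, position = NULL) {
  state <- match.arg(state)
  if (state %in% c("gapped", "missing") && magnitude < 1L)
    stop("state '", state, "' needs a positive magnitude")
  if (state == "overlapping" && magnitude < 1L)
    stop("state 'overlapping' needs a positive magnitude")
  if (state == "fragmented" && magnitude < 2L)
    stop("fragment count must be at least 2")
  structure(list(state = state, magnitude = as.integer(magnitude),
                 rotation = as.integer(rotation), position = position),
            class = "defect_spec")
}

# Build the contigs and exact truth blocks for one replicon.
# Truth blocks are (t_start, span, strand, q_start) in tripled-reference
# coordinates; the rotated contig starts at replicon position `rot`.
defect_blocks <- function(r, spec) {
  L <- length(r)
  rot <- spec$rotation %% L
  rotseq <- rotate_sequence(r$seq, rot)
  m <- spec$magnitude
  ctg_name <- function(i = 1L) paste0(r$name, "_contig_", i)
  contigs <- list(); truth <- list()
  add_truth <- function(qname, qlen, qs, ts, span, strand = "+") {
    truth[[length(truth) + 1L]] <<- data.frame(
      query_name = qname, query_len = qlen, query_start = qs,
      query_end = qs + span, strand = strand, target_name = r$name,
      target_len = 3L * L, target_start = ts, target_end = ts + span,
      matches = span, cigar = paste0(span, "="), mapq = 255L,
      stringsAsFactors = FALSE)
  }
  switch(spec$state,
    perfect = {
      contigs[[1]] <- replicon(ctg_name(), rotseq, role = "contig")
      add_truth(ctg_name(), L, 0L, rot, L)
    },
    gapped = {
      if (m >= L) stop("gap magnitude must be smaller than the replicon")
      seq <- substr(rotseq, 1L, L - m)
      contigs[[1]] <- replicon(ctg_name(), seq, role = "contig")
      add_truth(ctg_name(), L - m, 0L, rot, L - m)
    },
    overlapping = {
      if (m > L) stop("overlap magnitude cannot exceed the replicon length")
      seq <- paste0(rotseq, substr(rotseq, 1L, m))
      contigs[[1]] <- replicon(ctg_name(), seq, role = "contig")
      add_truth(ctg_name(), L + m, 0L, rot, L + m)
    },
    fragmented = {
      k <- m
      if (k > L) stop("cannot split into more fragments than bases")
      cuts <- sort(sample.int(L - 1L, k - 1L))
      bounds <- c(0L, cuts, L)
      for (i in seq_len(k)) {
        piece <- substr(rotseq, bounds[i] + 1L, bounds[i + 1L])
        contigs[[i]] <- replicon(ctg_name(i), piece, role = "contig")
        add_truth(ctg_name(i), nchar(piece), 0L, rot + bounds[i],
                  bounds[i + 1L] - bounds[i])
      }
    },
    missing = {
      if (m >= L) stop("deletion magnitude must be smaller than the replicon")
      p <- if (is.null(spec$position)) sample.int(L - m + 1L, 1L) - 1L
           else as.integer(spec$position)
      if (p < 0L || p + m > L) stop("deletion does not fit in the replicon")
      seq <- paste0(substr(rotseq, 1L, p), substr(rotseq, p + m + 1L, L))
      contigs[[1]] <- replicon(ctg_name(), seq, role = "contig")
      qlen <- L - m
      if (p > 0L) add_truth(ctg_name(), qlen, 0L, rot, p)
      if (p + m < L) add_truth(ctg_name(), qlen, p, rot + p + m, L - p - m)
    },
    misassembled = {
      seg <- max(1L, m)
      if (seg >= L - 1L) stop("inverted segment must be internal")
      a <- if (is.null(spec$position))
        sample.int(L - seg - 1L, 1L) else as.integer(spec$position)
      if (a < 1L || a + seg >= L) stop("inverted segment must be internal")
      b <- a + seg
      seq <- paste0(substr(rotseq, 1L, a),
                    reverse_complement(substr(rotseq, a + 1L, b)),
                    substr(rotseq, b + 1L, L))
      contigs[[1]] <- replicon(ctg_name(), seq, role = "contig")
      add_truth(ctg_name(), L, 0L, rot, a)
      add_truth(ctg_name(), L, a, rot + a, seg, strand = "-")
      add_truth(ctg_name(), L, b, rot + b, L - b)
    })
  list(contigs = contigs, truth = truth)
}

#' Build a defective assembly with ground-truth alignments
#'
#' Derives an assembly (a set of contigs) from a genome by applying one
#' [defect_spec] per replicon, and emits exact ground-truth alignments of
#' every contig against the tripled reference replicons. All CIGARs are
#' pure-match (`=`) blocks, one alignment per contiguous block, so the
#' contiguity each defect should produce follows by exact arithmetic:
#' a gap of `g` bp on a replicon of length `L` gives `100 (L - g) / L`,
#' a start-end overlap of `o` gives `100 (L + o) / L`.
#'
#' @param genome A [genome].
#' @param defects Named list of [defect_spec]s, one per replicon name.
#' @param seed Integer seed for randomly placed defect positions.
#' @return List of class `defective_assembly` with `contigs` (list of
#'   [replicon]), `truth` (an [alignments] data frame against the tripled
#'   references), `genome_label` and `defects`.
#' @export
make_defective_assembly <- function(genome, defects, seed = 1L) {
  stopifnot(inherits(genome, "genome"))
  nms <- names(genome$replicons)
  if (!setequal(names(defects), nms))
    stop("'defects' must name every replicon exactly once: ",
         paste(nms, collapse = ", "))
  res <- withr::with_seed(seed, lapply(nms, function(nm)
    defect_blocks(genome$replicons[[nm]], defects[[nm]])))
  contigs <- do.call(c, lapply(res, `[[`, "contigs"))
  truth_rows <- do.call(c, lapply(res, `[[`, "truth"))
  truth <- if (length(truth_rows)) {
    df <- do.call(rbind, truth_rows)
    df$has_cigar <- TRUE
    class(df) <- c("alignments", "data.frame")
    validate_alignments(df)
  } else alignments()
  structure(list(contigs = contigs, truth = truth,
                 genome_label = genome$label, defects = defects),
            class = "defective_assembly")
}

#' Write a defective assembly's ground-truth alignments as PAF
#'
#' @param assembly A `defective_assembly` from [make_defective_assembly()].
#' @param genome The [genome] the assembly was derived from (used to verify
#'   provenance).
#' @param path Output PAF path.
#' @return `path`, invisibly.
#' @export
emit_truth_paf <- function(assembly, genome, path) {
  stopifnot(inherits(assembly, "defective_assembly"))
  if (!identical(assembly$genome_label, genome$label) ||
      !all(assembly$truth$target_name %in% names(genome$replicons)))
    stop("assembly was not derived from genome '", genome$label, "'")
  write_paf(assembly$truth, path)
}

#' Materialise a battery of defective-assembly fixtures
#'
#' Writes, for each of the six defect states, an assembly FASTA and a
#' ground-truth PAF for a freshly generated random genome, plus the
#' reference FASTA and metadata sidecar — a self-contained test battery
#' for the assessment pipeline.
#'
#' @param outdir Output directory (created if needed).
#' @param chrom_len Chromosome length, bp.
#' @param plasmid_lens Plasmid lengths, bp.
#' @param seed Integer seed.
#' @return Data frame cataloguing the written files, invisibly.
#' @export
fixture_battery <- function(outdir, chrom_len = 10000L,
                            plasmid_lens = 2000L, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_random_genome(chrom_len, plasmid_lens, seed = seed,
                              label = "fixture")
  write_fasta(g, file.path(outdir, "reference.fasta"))
  write_replicon_metadata(g, file.path(outdir, "reference.tsv"))
  states <- c("perfect", "gapped", "overlapping", "fragmented", "missing",
              "misassembled")
  state_magnitude <- function(s, L) {
    switch(s, perfect = 0L, gapped = min(10L, L %/% 10L),
           overlapping = min(100L, L %/% 10L), fragmented = 3L,
           missing = max(2L, as.integer(0.3 * L)),
           misassembled = max(2L, as.integer(0.2 * L)))
  }
  rows <- list()
  for (s in states) {
    defects <- lapply(names(g$replicons), function(nm)
      defect_spec(s, magnitude = state_magnitude(s,
                    length(g$replicons[[nm]])), rotation = 137L))
    names(defects) <- names(g$replicons)
    asm <- make_defective_assembly(g, defects, seed = seed + match(s, states))
    fa <- file.path(outdir, paste0(s, ".fasta"))
    paf <- file.path(outdir, paste0(s, ".paf"))
    write_fasta(asm$contigs, fa)
    emit_truth_paf(asm, g, paf)
    rows[[s]] <- data.frame(state = s, assembly = fa, truth_paf = paf,
                            stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, rows))
}
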
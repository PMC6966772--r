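# Shared helpers: tiny replicons, independent oracles.

random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

toy_replicon <- function(len, seed = 1, name = "toy",
                         role = "chromosome", circular = TRUE) {
  replicon(name, random_seq(len, seed), circular = circular, role = role)
}

toy_genome <- function(chrom_len = 2000, plasmid_lens = integer(0),
                       seed = 1, label = "toy") {
  generate_random_genome(chrom_len, plasmid_lens, seed = seed, label = label)
}

# Brute-force identity oracle: expand the CIGAR into one character per
# alignment column and count, independent of the package's arithmetic.
identity_oracle <- function(cigar, matches_field = NA) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDX=]", cigar))[[1]]
  cols <- unlist(lapply(ops, function(o) {
    n <- as.integer(sub("[MIDX=]$", "", o))
    rep(sub("^[0-9]+", "", o), n)
  }))
  n_match <- if (any(cols == "=")) sum(cols == "=") else matches_field
  100 * n_match / length(cols)
}

# Brute-force difference oracle: mismatched columns + inserted + deleted.
difference_oracle <- function(cigars) {
  sum(vapply(cigars, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDX=]", cg))[[1]]
    lens <- as.integer(sub("[MIDX=]$", "", ops))
    kinds <- sub("^[0-9]+", "", ops)
    sum(lens[kinds %in% c("X", "I", "D")])
  }, numeric(1)))
}

# One-row alignments object from a CIGAR, with consistent coordinates.
aln_from_cigar <- function(cigar, matches = NULL, qname = "ctg",
                           tname = "ref") {
  qs <- cigar_query_span(cigar)
  ts <- cigar_target_span(cigar)
  if (is.null(matches)) {
    ops <- cigar_ops(cigar)
    matches <- if (any(ops$op == "=")) sum(ops$len[ops$op == "="])
               else min(qs, ts)
  }
  alignments(qname, qs, 0L, qs, "+", tname, ts, 0L, ts,
             as.integer(matches), cigar)
}

expect_status <- function(g, defects, expected, seed = 5) {
  asm <- make_defective_assembly(g, defects, seed = seed)
  rep <- assess_assembly(asm$contigs, g, aligner_paf(asm$truth))
  expect_identical(rep$status, expected)
  invisible(rep)
}
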
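test_that("contiguity is the longest single alignment over the replicon length", {
  L <- 10000
  full <- alignments("c1", 10000L, 0L, 10000L, "+", "ref", 30000L,
                     137L, 10137L, 10000L, "10000=")
  expect_identical(contiguity(full, L), 100)

  doubled <- alignments("c1", 20000L, 0L, 20000L, "+", "ref", 30000L,
                        0L, 20000L, 20000L, "20000=")
  expect_identical(contiguity(doubled, L), 200)

  halves <- alignments(c("c1", "c2"), c(7000L, 3000L), c(0L, 0L),
                       c(7000L, 3000L), c("+", "+"), "ref", 30000L,
                       c(0L, 7000L), c(7000L, 10000L), c(7000L, 3000L),
                       c("7000=", "3000="))
  expect_identical(contiguity(halves, L), 70)

  expect_identical(contiguity(alignments(), L), 0)
  expect_error(contiguity(full, 0), "positive")
})

test_that("longest alignment ties break on matches then contig name", {
  a <- alignments(c("b", "a", "a"), c(100L, 100L, 100L), c(0L, 0L, 0L),
                  c(100L, 100L, 90L), rep("+", 3), "ref", 300L,
                  c(0L, 100L, 200L), c(100L, 200L, 290L),
                  c(98L, 100L, 90L), c("98=1X1=", "100=", "90="))
  expect_identical(longest_alignment(a), 2L)  # same span, more matches
  expect_error(longest_alignment(alignments()), "no alignments")
})

test_that("identity matches a brute-force column-walk oracle", {
  expect_identical(alignment_identity(aln_from_cigar("100=")), 100)
  expect_identical(alignment_identity(aln_from_cigar("99=1X")), 99)
  expect_identical(alignment_identity(aln_from_cigar("98=2D")), 98)
  # random CIGARs, compared column-by-column against the oracle
  for (seed in 1:25) {
    cg <- withr::with_seed(seed, {
      n <- sample(3:12, 1)
      ops <- sample(c("=", "X", "I", "D"), n, replace = TRUE,
                    prob = c(0.6, 0.2, 0.1, 0.1))
      ops[1] <- "="; ops[n] <- "="
      lens <- sample(1:50, n, replace = TRUE)
      paste0(lens, ops, collapse = "")
    })
    a <- aln_from_cigar(cg)
    expect_equal(alignment_identity(a), identity_oracle(cg))
  }
  # M-style CIGAR falls back to the matches field
  a <- alignments("c", 100L, 0L, 100L, "+", "r", 100L, 0L, 100L, 97L, "100M")
  expect_equal(alignment_identity(a), identity_oracle("100M", 97))
  expect_error(alignment_identity(
    alignments("c", 10L, 0L, 10L, "+", "r", 10L, 0L, 10L, 10L, "")),
    "no CIGAR")
})

test_that("gap-compressed identity counts each indel run once", {
  a <- aln_from_cigar("90=10I")
  expect_equal(alignment_identity(a), 90)
  expect_equal(alignment_identity(a, gap_compressed = TRUE),
               100 * 90 / 91)
})

test_that("max indel is the largest single I or D operation", {
  expect_identical(max_indel(aln_from_cigar("100=")), 0L)
  expect_identical(max_indel(aln_from_cigar("50=3D20=12I10=")), 12L)
  expect_identical(max_indel(aln_from_cigar("10=1I10=1D10=")), 1L)
})

test_that("status classifier reproduces the four-way rule at the boundary", {
  expect_identical(
    classify_assembly(c(99.9, 100.2), c("chromosome", "plasmid")),
    "fully_complete")
  expect_identical(
    classify_assembly(c(99.5, 40.0), c("chromosome", "plasmid")),
    "complete_chromosome")
  expect_identical(classify_assembly(98.9, "chromosome"), "incomplete")
  expect_identical(classify_assembly(numeric(0), character(0), empty = TRUE),
                   "empty")
  # the 99% threshold is inclusive
  expect_identical(classify_assembly(99.0, "chromosome"), "fully_complete")
  expect_identical(classify_assembly(98.999999, "chromosome"), "incomplete")
  expect_identical(
    classify_assembly(c(100, 99.0), c("chromosome", "plasmid")),
    "fully_complete")
  expect_identical(
    classify_assembly(c(100, 98.999999), c("chromosome", "plasmid")),
    "complete_chromosome")
  expect_error(classify_assembly(c(99, 99), c("plasmid", "plasmid")),
               "chromosome")
  # total over a grid: always exactly one of the four statuses
  for (chrom in c(0, 50, 98.9, 99, 99.9, 101, 200)) {
    for (plas in c(0, 98.9, 99, 150)) {
      s <- classify_assembly(c(chrom, plas), c("chromosome", "plasmid"))
      expect_true(s %in% c("fully_complete", "complete_chromosome",
                           "incomplete", "empty"))
    }
  }
})

test_that("difference counting matches the column-walk oracle", {
  identical_asm <- alignments("a", 100L, 0L, 100L, "+", "b", 100L, 0L, 100L,
                              100L, "100=")
  expect_identical(assembly_difference_count(identical_asm), 0L)

  one_sub_one_del <- aln_from_cigar("40=1X30=3D29=")
  expect_identical(assembly_difference_count(one_sub_one_del), 4L)
  expect_identical(assembly_difference_count(one_sub_one_del),
                   as.integer(difference_oracle("40=1X30=3D29=")))

  over <- aln_from_cigar(paste0("100=51X100="))
  expect_identical(assembly_difference_count(over), 51L)
  expect_false(assemblies_agree(over, threshold = 50))
  expect_true(assemblies_agree(one_sub_one_del, threshold = 50))
  expect_error(assembly_difference_count(alignments()), "no alignments")
})

test_that("perfect circular assemblies score 100% at every rotation", {
  g <- toy_genome(1500, seed = 21)
  nm <- names(g$replicons)
  offsets <- withr::with_seed(77, sample(0:1499, 22))
  for (k in offsets) {
    asm <- make_defective_assembly(
      g, setNames(list(defect_spec("perfect", rotation = k)), nm))
    rep <- assess_assembly(asm$contigs, g, aligner_paf(asm$truth))
    expect_identical(rep$replicons$contiguity, 100)
    expect_identical(rep$status, "fully_complete")
  }
})

test_that("gap and overlap contiguity follow exact arithmetic", {
  L <- 2000
  g <- toy_genome(L, seed = 8)
  nm <- names(g$replicons)
  for (seed in 1:10) {
    gap <- withr::with_seed(seed, sample(1:500, 1))
    ov <- withr::with_seed(seed + 100, sample(1:500, 1))
    rot <- withr::with_seed(seed + 200, sample(0:(L - 1), 1))
    asm_g <- make_defective_assembly(
      g, setNames(list(defect_spec("gapped", gap, rot)), nm))
    expect_equal(contiguity(asm_g$truth, L), 100 * (L - gap) / L)
    asm_o <- make_defective_assembly(
      g, setNames(list(defect_spec("overlapping", ov, rot)), nm))
    expect_equal(contiguity(asm_o$truth, L), 100 * (L + ov) / L)
  }
})

test_that("contiguity and identity are invariant under strand flip", {
  g <- toy_genome(1200, seed = 31)
  r <- g$replicons[[1]]
  fwd <- replicon("fwd", rotate_sequence(r$seq, 400), role = "contig")
  rev <- replicon("rev", reverse_complement(fwd$seq), role = "contig")
  backend <- aligner_builtin()
  tri <- triple_reference(r)
  a_fwd <- backend(list(fwd), r$name, tri)
  a_rev <- backend(list(rev), r$name, tri)
  expect_identical(a_rev$strand[longest_alignment(a_rev)], "-")
  expect_identical(contiguity(a_fwd, length(r)), contiguity(a_rev, length(r)))
  expect_identical(
    alignment_identity(a_fwd[longest_alignment(a_fwd), ]),
    alignment_identity(a_rev[longest_alignment(a_rev), ]))
})

test_that("assess_assembly reports per-replicon metrics and chromosome-level identity", {
  g <- toy_genome(1500, 300, seed = 13)
  nms <- names(g$replicons)
  # chromosome perfect, plasmid absent -> complete_chromosome
  asm <- make_defective_assembly(g, setNames(list(
    defect_spec("perfect", rotation = 45),
    defect_spec("perfect", rotation = 10)), nms))
  contigs <- asm$contigs[1]  # drop the plasmid contig
  truth <- asm$truth[asm$truth$query_name == contigs[[1]]$name, ]
  rep <- assess_assembly(contigs, g, aligner_paf(truth))
  expect_identical(rep$status, "complete_chromosome")
  expect_identical(rep$replicons$contiguity, c(100, 0))
  expect_identical(rep$identity, 100)
  expect_identical(rep$max_indel, 0L)

  # empty assembly
  rep0 <- assess_assembly(list(), g, aligner_paf(asm$truth))
  expect_identical(rep0$status, "empty")
  expect_identical(rep0$replicons$contiguity, c(0, 0))

  # fragmented chromosome: contiguity equals the largest fragment and the
  # status follows the threshold rule applied to it
  asm2 <- make_defective_assembly(g, setNames(list(
    defect_spec("fragmented", 2, rotation = 0),
    defect_spec("perfect")), nms), seed = 42)
  rep2 <- assess_assembly(asm2$contigs, g, aligner_paf(asm2$truth))
  chrom_truth <- asm2$truth[asm2$truth$target_name == nms[1], ]
  largest <- max(chrom_truth$target_end - chrom_truth$target_start)
  expect_equal(rep2$replicons$contiguity[1], 100 * largest / 1500)
  expect_identical(rep2$status,
                   if (100 * largest / 1500 >= 99) "fully_complete"
                   else "incomplete")
})
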
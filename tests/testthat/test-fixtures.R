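test_that("random genomes are deterministic and respect structural rules", {
  g <- generate_random_genome(10000, 2000, seed = 1)
  expect_identical(unname(replicon_lengths(g)), c(10000L, 2000L))
  expect_identical(vapply(g$replicons, `[[`, character(1), "role"),
                   c(genome_chromosome = "chromosome",
                     genome_plasmid_1 = "plasmid"))
  g2 <- generate_random_genome(10000, 2000, seed = 1)
  expect_identical(g, g2)
  g3 <- generate_random_genome(10000, 2000, seed = 2)
  expect_false(identical(g$replicons[[1]]$seq, g3$replicons[[1]]$seq))

  # a 3 kbp plasmid on a 10 kbp chromosome breaches the 25% fraction rule
  expect_error(generate_random_genome(10000, 3000, seed = 1),
               "25%")
  expect_error(generate_random_genome(10000, rep(100, 10), seed = 1),
               "9 plasmids")
  expect_error(generate_random_genome(2000, 400, seed = 1,
                                      rule = qc_rule(max_chromosome = 10e3,
                                                     min_chromosome = 3000,
                                                     max_plasmid = 500)),
               "min_chromosome")
})

test_that("QC filters reject and retain a constructed battery per the five rules", {
  # thin sequences: only lengths matter to the rules
  mk <- function(label, chrom, plasmids = integer(0)) {
    reps <- c(list(replicon("c", strrep("A", chrom), role = "chromosome")),
              lapply(seq_along(plasmids), function(i)
                replicon(paste0("p", i), strrep("A", plasmids[i]),
                         role = "plasmid")))
    genome(label, reps)
  }
  battery <- list(
    mk("too_big", 11e6),                       # >10 Mbp chromosome
    mk("too_small", 400e3),                    # <500 kbp chromosome
    mk("big_plasmid", 2e6, 400e3),             # >300 kbp plasmid
    mk("frac_plasmid", 800e3, 250e3),          # plasmid >25% of chromosome
    mk("many_plasmids", 2e6, rep(1e3, 10)),    # more than 9 plasmids
    mk("ok_plain", 5e6),
    mk("ok_two", 5e6, c(50e3, 50e3)),
    mk("ok_nine", 2e6, rep(2e3, 9)),           # exactly 9 plasmids is fine
    mk("ok_quarter", 1.2e6, 300e3),            # exactly 25% and 300 kbp is fine
    mk("multi_bad", 11e6, rep(3e6, 10)))       # violates several rules at once
  res <- apply_qc_filters(battery, qc_rule())
  expect_identical(vapply(res$retained, `[[`, character(1), "label"),
                   c("ok_plain", "ok_two", "ok_nine", "ok_quarter"))
  expect_identical(res$rejected$label,
                   c("too_big", "too_small", "big_plasmid", "frac_plasmid",
                     "many_plasmids", "multi_bad"))
  expect_identical(res$rejected$reasons[1], "max_chromosome")
  expect_identical(res$rejected$reasons[2], "min_chromosome")
  expect_identical(res$rejected$reasons[3], "max_plasmid")
  expect_identical(res$rejected$reasons[4], "max_plasmid_fraction")
  expect_identical(res$rejected$reasons[5], "max_plasmid_count")
  expect_identical(res$rejected$reasons[6],
                   "max_chromosome,max_plasmid,max_plasmid_fraction,max_plasmid_count")

  # idempotent and order-independent
  again <- apply_qc_filters(res$retained, qc_rule())
  expect_identical(length(again$retained), length(res$retained))
  rev_res <- apply_qc_filters(rev(battery), qc_rule())
  expect_setequal(rev_res$rejected$label, res$rejected$label)
})

test_that("panel selection redraws until the plasmid target is met exactly", {
  pool2 <- lapply(1:8, function(i)
    generate_random_genome(2000, c(300, 300), seed = i,
                           label = paste0("b", i)))
  pool0 <- lapply(1:12, function(i)
    generate_random_genome(2000, seed = 100 + i, label = paste0("f", i)))

  sel <- select_genome_panel(c(pool2, pool0), 5, 10, 10, seed = 3)
  expect_identical(sel$plasmid_total, 10L)
  expect_identical(sel$attempts, 1L)  # every bearing genome has 2 plasmids
  expect_length(sel$panel, 15L)

  # an odd target is unreachable when all counts are even
  expect_error(
    select_genome_panel(c(pool2, pool0), 5, 11, 10, seed = 3,
                        max_attempts = 25),
    "closest achieved: 10")

  # same seed, same panel
  sel2 <- select_genome_panel(c(pool2, pool0), 5, 10, 10, seed = 3)
  expect_identical(vapply(sel$panel, `[[`, character(1), "label"),
                   vapply(sel2$panel, `[[`, character(1), "label"))
})

test_that("a scaled 25/50/25 panel holds exactly 50 plasmids", {
  bearing <- lapply(1:40, function(i)
    generate_random_genome(2000, rep(300, (i %% 3) + 1), seed = i,
                           label = paste0("b", i)))
  free <- lapply(1:30, function(i)
    generate_random_genome(2000, seed = 200 + i, label = paste0("f", i)))
  sel <- select_genome_panel(c(bearing, free), 25, 50, 25, seed = 11)
  expect_length(sel$panel, 50L)
  n_plas <- vapply(sel$panel, function(g) length(plasmids_of(g)), integer(1))
  expect_identical(sum(n_plas), 50L)
  expect_identical(sum(n_plas > 0), 25L)
})

test_that("each defect state yields its designed contiguity and status", {
  g <- toy_genome(4000, seed = 17, label = "toy")
  nm <- names(g$replicons)
  d <- function(...) setNames(list(defect_spec(...)), nm)

  r1 <- expect_status(g, d("perfect", rotation = 137), "fully_complete")
  expect_identical(r1$replicons$contiguity, 100)

  r2 <- expect_status(g, d("gapped", 4, 137), "fully_complete")
  expect_equal(r2$replicons$contiguity, 100 * 3996 / 4000)

  r3 <- expect_status(g, d("gapped", 400, 137), "incomplete")
  expect_equal(r3$replicons$contiguity, 90)

  r4 <- expect_status(g, d("overlapping", 100, 137), "fully_complete")
  expect_equal(r4$replicons$contiguity, 102.5)

  r5 <- expect_status(g, d("fragmented", 4, 137), "incomplete")

  r6 <- expect_status(g, d("missing", 1200, 137, position = 2800),
                      "incomplete")
  expect_equal(r6$replicons$contiguity, 70)

  r7 <- expect_status(g, d("misassembled", 800, 137, position = 1500),
                      "incomplete")
  expect_equal(r7$replicons$contiguity, 100 * 1700 / 4000)
})

test_that("fragmented truth alignments partition the replicon", {
  g <- toy_genome(3000, seed = 23)
  nm <- names(g$replicons)
  asm <- make_defective_assembly(
    g, setNames(list(defect_spec("fragmented", 5, rotation = 61)), nm),
    seed = 9)
  expect_length(asm$contigs, 5L)
  spans <- asm$truth$target_end - asm$truth$target_start
  expect_identical(sum(spans), 3000L)
  # blocks are adjacent on the tripled reference
  ord <- order(asm$truth$target_start)
  expect_identical(asm$truth$target_start[ord][-1],
                   asm$truth$target_end[ord][-5])
  # contig sequences re-concatenate to the rotated replicon
  expect_identical(paste(vapply(asm$contigs, `[[`, character(1), "seq"),
                         collapse = ""),
                   rotate_sequence(g$replicons[[1]]$seq, 61))
})

test_that("truth PAF round-trips and rejects foreign genomes", {
  g <- toy_genome(1000, 250, seed = 29)
  defects <- setNames(list(defect_spec("perfect", rotation = 3),
                           defect_spec("overlapping", 250, 7)),
                      names(g$replicons))
  asm <- make_defective_assembly(g, defects)
  paf <- withr::local_tempfile(fileext = ".paf")
  emit_truth_paf(asm, g, paf)
  back <- parse_paf(paf)
  expect_equal(as.data.frame(back), as.data.frame(asm$truth))
  # fully doubled plasmid spans 2L in one block on the tripled reference
  plas <- back[back$target_name == names(g$replicons)[2], ]
  expect_identical(plas$target_end - plas$target_start, 500L)

  other <- toy_genome(1000, 250, seed = 30, label = "other")
  expect_error(emit_truth_paf(asm, other, paf), "not derived")
})

test_that("defect magnitudes are validated against the replicon", {
  g <- toy_genome(500, seed = 2)
  nm <- names(g$replicons)
  expect_error(make_defective_assembly(
    g, setNames(list(defect_spec("gapped", 500)), nm)), "smaller")
  expect_error(make_defective_assembly(
    g, setNames(list(defect_spec("missing", 600)), nm)), "smaller")
  expect_error(make_defective_assembly(
    g, setNames(list(defect_spec("overlapping", 501)), nm)), "exceed")
  expect_error(defect_spec("fragmented", 1), "at least 2")
  expect_error(make_defective_assembly(g, list()), "every replicon")
})

test_that("the fixture battery materialises all six states on disk", {
  outdir <- withr::local_tempdir()
  cat_tab <- fixture_battery(outdir, chrom_len = 1000, plasmid_lens = 240,
                             seed = 4)
  expect_identical(nrow(cat_tab), 6L)
  expect_true(all(file.exists(cat_tab$assembly, cat_tab$truth_paf)))
  meta <- read_replicon_metadata(file.path(outdir, "reference.tsv"))
  expect_identical(meta$role, c("chromosome", "plasmid"))
})
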
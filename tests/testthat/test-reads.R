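# One small simulated library reused across the read-processing tests.
make_library <- function(seed = 101) {
  ref <- make_reference_with_mirnas(n_precursors = 4, contig_length = 500,
                                    seed = seed, stem_len = 30, loop_len = 8)
  contam <- list(
    rRNA = c(rrna1 = random_rna_fixed(300, seed + 1)),
    tRNA = c(trna1 = random_rna_fixed(90, seed + 2)),
    snRNA = c(snrna1 = random_rna_fixed(120, seed + 3)),
    "repeat" = c(rep1 = random_rna_fixed(200, seed + 4)))
  lib <- simulate_sreads(ref$truth, depth = 8, star_depth = 2,
                         n_contaminant = 20, n_polyA = 10, n_short = 5,
                         n_adapter5 = 5, n_lowq = 5,
                         contaminants = contam, seed = seed)
  list(ref = ref, contam = contam, lib = lib)
}

test_that("read cleaning discards the generator's junk classes exactly", {
  fx <- make_library()
  cl <- clean_reads(fx$lib$reads, adapter_3p = "UCGUAUGCCGUCUUCUGCUUG",
                    adapter_5p = "GUUCAGAGUUCUACAGUCCGACGAUC")
  truth <- fx$lib$truth
  n_bad <- sum(truth$class %in% c("polyA", "short", "adapter5", "lowq"))
  expect_equal(cl$accounting$raw_count, nrow(truth))
  expect_equal(cl$accounting$cleaned_count, nrow(truth) - n_bad)
  expect_equal(unname(cl$discarded["adapter5"]), sum(truth$class == "adapter5"))
  expect_equal(unname(cl$discarded["polyA"]), sum(truth$class == "polyA"))
  expect_equal(unname(cl$discarded["low_quality"]), sum(truth$class == "lowq"))
  expect_equal(unname(cl$discarded["short"]), sum(truth$class == "short"))
  # every surviving sequence is a clean insert: adapters trimmed, >= 18 nt
  expect_true(all(nchar(cl$reads$sequence) >= 18))
  expect_false(any(grepl("UCGUAUGC", cl$reads$sequence, fixed = TRUE)))
})

test_that("a 17-nt insert is discarded after trimming", {
  a3 <- "UCGUAUGCCGUCUUCUGCUUG"
  insert <- random_rna_fixed(17, 55)
  cl <- clean_reads(paste0(insert, a3), adapter_3p = a3)
  expect_equal(cl$accounting$cleaned_count, 0)
  expect_equal(unname(cl$discarded["short"]), 1)
  insert18 <- random_rna_fixed(18, 56)
  cl18 <- clean_reads(paste0(insert18, a3), adapter_3p = a3)
  expect_equal(cl18$reads$sequence, insert18)
})

test_that("contaminant annotation follows the rRNA > tRNA > snRNA > repeat priority", {
  shared <- random_rna_fixed(22, 77)
  sets <- list(rRNA = c(r1 = paste0("GG", shared, "CC")),
               tRNA = c(t1 = random_rna_fixed(80, 78)),
               "repeat" = c(p1 = paste0("AU", shared, "GC")))
  reads <- data.frame(sequence = c(shared, substring(sets$tRNA, 10, 31),
                                   random_rna_fixed(22, 79)),
                      count = c(3L, 2L, 1L))
  ann <- annotate_contaminants(reads, sets)
  expect_equal(ann$reads$annotation_class, c("rRNA", "tRNA", "unannotated"))
  # counts are multiplicity-weighted
  expect_equal(unname(ann$accounting$contaminants["rRNA"]), 3L)
  expect_equal(ann$accounting$remaining_count, 1L)
})

test_that("the published totals reproduce the printed remaining-read count", {
  acc <- read_accounting(11665437, 7327921,
                         c(other_srna = 125827L, repeat. = 18994L))
  expect_equal(acc$remaining_count, 7183100)
  expect_equal(acc$pct_contaminants[["other_srna"]], "1.72")
  expect_equal(acc$pct_contaminants[["repeat."]], "0.26")
})

test_that("read-based discovery recovers planted precursors with correct matures", {
  fx <- make_library(seed = 202)
  cl <- clean_reads(fx$lib$reads, adapter_3p = "UCGUAUGCCGUCUUCUGCUUG",
                    adapter_5p = "GUUCAGAGUUCUACAGUCCGACGAUC")
  ann <- annotate_contaminants(cl$reads, fx$contam,
                               raw_count = cl$accounting$raw_count)
  un <- ann$reads[ann$reads$annotation_class == "unannotated", ]
  disc <- discover_from_reads(un, fx$ref$references)
  truth <- fx$ref$truth
  expect_equal(nrow(disc$catalog), nrow(truth))
  expect_setequal(disc$catalog$mature_sequence, truth$mature)
  # accounting identity holds through the full pipeline
  expect_equal(ann$accounting$remaining_count,
               ann$accounting$cleaned_count - sum(ann$accounting$contaminants))
  # every mature is a substring of its precursor at the recorded offset
  for (i in seq_len(nrow(disc$catalog))) {
    expect_equal(substring(disc$catalog$precursor_sequence[i],
                           disc$catalog$mature_start[i],
                           disc$catalog$mature_end[i]),
                 disc$catalog$mature_sequence[i])
  }
})

test_that("a locus below min_locus_reads is rejected with its reason", {
  ref <- make_reference_with_mirnas(n_precursors = 1, contig_length = 400,
                                    seed = 303)
  mature <- ref$truth$mature[1]
  reads <- data.frame(sequence = mature, count = 1L)
  disc <- discover_from_reads(reads, ref$references, min_locus_reads = 2)
  expect_equal(nrow(disc$catalog), 0)
  expect_true(all(disc$rejected$reason == "min_locus_reads"))
  # with 2 reads the same locus passes
  reads2 <- data.frame(sequence = mature, count = 2L)
  disc2 <- discover_from_reads(reads2, ref$references, min_locus_reads = 2)
  expect_equal(nrow(disc2$catalog), 1)
})

test_that("reads straddling the loop do not yield a locus", {
  hp <- make_hairpin(stem_len = 25, loop_len = 8, seed = 17)
  ref <- c(c1 = paste0(random_rna_fixed(80, 18), hp$sequence,
                       random_rna_fixed(80, 19)))
  straddle <- substring(hp$sequence, 15, 40)  # covers arm, loop, other arm
  disc <- discover_from_reads(data.frame(sequence = straddle, count = 5L), ref)
  expect_equal(nrow(disc$catalog), 0)
  expect_true(disc$rejected$reason %in% c("mature_not_in_one_arm", "stem_coverage_ok"))
})

test_that("shuffled decoy loci yield zero candidates", {
  set.seed(404)
  decoy_contig <- c(d1 = random_rna(400, gc = 0.5))
  # reads sampled straight from the decoy background (no planted hairpin)
  pos <- seq(50, 250, by = 40)
  reads <- data.frame(sequence = vapply(pos, function(p) {
    substring(decoy_contig, p, p + 21)
  }, character(1)), count = 5L)
  disc <- discover_from_reads(reads, decoy_contig)
  expect_equal(nrow(disc$catalog), 0)
})

test_that("catalog merging unifies both arms and assigns conservation", {
  set.seed(33)
  known <- c(known1 = random_rna(22, gc = 0.6))
  h <- data.frame(name = "mirH", mature_sequence = "ACGUACGUACGUACGUACGUAC",
                  precursor_id = "c1:100-250", precursor_sequence = "x",
                  structure = ".", dG = -20, reference_id = "c1",
                  start = 100L, end = 250L, strand = "+", mature_start = 61L,
                  mature_end = 82L, star_sequence = NA, expression_count = 0L,
                  provenance = "homology", stringsAsFactors = FALSE)
  s_same <- h
  s_same$name <- "srna-m001"
  s_same$provenance <- "srna"
  s_same$expression_count <- 12L
  m1 <- merge_catalogs(h, s_same)
  expect_equal(nrow(m1$catalog), 1)
  expect_equal(m1$catalog$provenance, "both")
  expect_equal(m1$catalog$expression_count, 12L)
  expect_equal(unname(m1$summary["conserved"]), 1L)

  # sequencing-only entry homologous to a known miRNA is conserved;
  # an unrelated one is specific
  s_known <- s_same
  s_known$mature_sequence <- known[[1]]
  s_known$reference_id <- "c2"
  s_unrel <- s_same
  s_unrel$mature_sequence <- "UUUUGGGGAAAACCCCUUUUGG"
  s_unrel$reference_id <- "c3"
  m2 <- merge_catalogs(h, rbind(s_known, s_unrel), known_matures = known)
  expect_equal(unname(m2$summary["total"]), 3L)
  expect_equal(m2$catalog$conservation[m2$catalog$reference_id == "c2"], "conserved")
  expect_equal(m2$catalog$conservation[m2$catalog$reference_id == "c3"], "specific")

  # empty sequencing set: catalog equals the homology set
  m3 <- merge_catalogs(h, h[0, ])
  expect_equal(nrow(m3$catalog), 1)
  expect_equal(m3$catalog$mature_sequence, h$mature_sequence)
})

test_that("isomiRs are end-shifted variants, never the reference read", {
  hp <- make_hairpin(stem_len = 28, loop_len = 8, seed = 21)
  cat <- data.frame(name = "m1", precursor_sequence = hp$sequence,
                    mature_start = 1L, mature_end = 22L,
                    stringsAsFactors = FALSE)
  mature <- substring(hp$sequence, 1, 22)
  plus1 <- substring(hp$sequence, 1, 23)
  minus2 <- substring(hp$sequence, 1, 20)
  far <- substring(hp$sequence, 1, 26)   # 3' end shifted by 4: too far
  reads <- data.frame(sequence = c(mature, plus1, minus2, far),
                      count = c(10L, 2L, 1L, 1L))
  iso <- detect_isomiRs(reads, cat)
  expect_equal(nrow(iso), 2)
  expect_setequal(iso$sequence, c(plus1, minus2))
})

test_that("planted isomiR variants are all detected", {
  ref <- make_reference_with_mirnas(n_precursors = 2, contig_length = 500,
                                    seed = 71)
  lib <- simulate_sreads(ref$truth, depth = 5, star_depth = 0, isomir_per = 3,
                         seed = 72)
  cl <- clean_reads(lib$reads, adapter_3p = "UCGUAUGCCGUCUUCUGCUUG")
  cat <- data.frame(name = ref$truth$name,
                    precursor_sequence = ref$truth$precursor,
                    mature_start = ref$truth$mature_start,
                    mature_end = ref$truth$mature_end,
                    stringsAsFactors = FALSE)
  iso <- detect_isomiRs(cl$reads, cat)
  truth_iso <- unique(lib$truth$id[lib$truth$class == "isomir"])
  # every planted isomiR sequence is recovered (collapsed by sequence)
  planted <- unique(lib$reads$sequence[lib$reads$id %in% truth_iso])
  planted <- sub("UCGUAUGCC.*$", "", planted)
  expect_true(all(vapply(planted, function(s) {
    any(startsWith(iso$sequence, substring(s, 1, 18)))
  }, logical(1))))
})

test_that("moRNAs are adjacent, non-overlapping precursor reads", {
  pre <- paste0(strrep("G", 5), random_rna_fixed(60, 91))
  mature_span <- c(25, 46)
  star_span <- c(1, 20)
  adj <- substring(pre, 47, 64)           # immediately 3' of the mature
  gap3 <- substring(pre, 50, 65)          # gap of 3: too far
  overlap <- substring(pre, 46, 63)       # overlaps the mature by 1 nt
  reads <- data.frame(sequence = c(adj, gap3, overlap), count = 1L)
  mo <- detect_moRNAs(reads, pre, mature_span, star_span, max_gap = 2)
  expect_equal(nrow(mo), 1)
  expect_equal(mo$sequence, adj)
  expect_equal(mo$adjacent_to, "mature3")
})
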
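test_that("mature deduplication keeps first-seen names and records aliases", {
  m <- c(a = "UGAGGUA", b = "UGAGGUA", c = "UGAGGUC")
  dd <- dedup_matures(m)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$name, c("a", "c"))
  expect_equal(dd$aliases, c("b", ""))
  expect_equal(nrow(dedup_matures(character(0))), 0)
})

test_that("planted duplicates are collapsed to the generator truth", {
  set.seed(3)
  base <- replicate(60, random_rna(22))
  dups <- sample(base, 40, replace = TRUE)
  pool <- sample(c(base, dups))
  names(pool) <- paste0("m", seq_along(pool))
  expect_equal(nrow(dedup_matures(pool)), length(unique(pool)))
})

test_that("homology hits honour the 90% identity threshold arithmetic", {
  set.seed(5)
  q <- random_rna(22, gc = 0.55)
  contig <- paste0(random_rna(100), q, random_rna(100))
  refs <- c(c1 = contig)
  hit <- align_mirna(q, refs)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$start, 101)
  expect_equal(hit$end, 122)

  v2 <- mutate_homolog(q, 20 / 22, seed = 9)   # 2 substitutions
  contig2 <- c(c1 = paste0(random_rna(80), v2$sequence, random_rna(80)))
  hit2 <- align_mirna(q, contig2)
  expect_equal(nrow(hit2), 1)
  expect_equal(hit2$identity, 20 / 22)

  v3 <- mutate_homolog(q, 19 / 22, seed = 9)   # 3 substitutions
  contig3 <- c(c1 = paste0(random_rna(80), v3$sequence, random_rna(80)))
  expect_equal(nrow(align_mirna(q, contig3)), 0)

  expect_error(align_mirna("ACGUACGUACGUACGUA", refs), "shorter than 18")
})

test_that("minus-strand homologs are found with plus-strand coordinates", {
  set.seed(6)
  q <- random_rna(22, gc = 0.55)
  contig <- c(c1 = paste0(random_rna(50), revcomp_rna(q), random_rna(50)))
  hit <- align_mirna(q, contig)
  expect_equal(hit$strand, "-")
  expect_equal(hit$start, 51)
  expect_equal(hit$end, 72)
})

test_that("candidate excision extends by 60 nt and truncates at contig ends", {
  set.seed(7)
  ref <- c(c1 = random_rna(1000))
  cand <- extract_candidate(ref, list(reference_id = "c1", start = 100, end = 121,
                                      strand = "+"))
  expect_equal(cand$location$start, 40)
  expect_equal(cand$location$end, 181)
  expect_equal(nchar(cand$sequence), 142)
  expect_equal(cand$mature_span, c(61, 82))

  trunc <- extract_candidate(ref, list(reference_id = "c1", start = 10, end = 31,
                                       strand = "+"))
  expect_equal(trunc$location$start, 1)
  expect_equal(trunc$location$end, 91)
  expect_true(trunc$truncated[["left"]])
})

test_that("minus-strand excision reverse-complements and remaps the mature", {
  set.seed(8)
  mature <- random_rna(22, gc = 0.6)
  ref <- c(c1 = paste0(random_rna(100), revcomp_rna(mature), random_rna(100)))
  hit <- align_mirna(mature, ref)
  cand <- extract_candidate(ref, hit[1, ])
  extracted <- substring(cand$sequence, cand$mature_span[1], cand$mature_span[2])
  expect_equal(extracted, mature)  # strand round trip
})

test_that("each hairpin criterion flips exactly at its printed boundary", {
  hp <- make_hairpin(stem_len = 30, loop_len = 8, seed = 41)
  base <- check_hairpin_criteria(hp$sequence, hp$mature_span,
                                 structure = hp$structure,
                                 dG = energy_of(hp$sequence, hp$structure))
  expect_true(base$overall)

  # (1) dG boundary: -15.0 passes, anything above fails
  r <- check_hairpin_criteria(hp$sequence, hp$mature_span,
                              structure = hp$structure, dG = -15.0)
  expect_true(r$dG_ok)
  r <- check_hairpin_criteria(hp$sequence, hp$mature_span,
                              structure = hp$structure, dG = -14.99)
  expect_false(r$dG_ok)

  # deterministic construct with k broken pairs inside the 22-nt mature
  mk_mm <- function(k) {
    stem <- 30; loop <- 8
    arm5 <- strrep("G", stem)
    arm3 <- rep("C", stem)
    o <- rep("(", stem); cl <- rep(")", stem)
    if (k > 0) {
      for (i in 3:(2 + k)) {
        j <- stem - i + 1
        arm3[j] <- "A"; o[i] <- "."; cl[j] <- "."
      }
    }
    seqn <- paste0(arm5, strrep("U", loop), paste(arm3, collapse = ""))
    struct <- paste0(paste(o, collapse = ""), strrep(".", loop),
                     paste(cl, collapse = ""))
    check_hairpin_criteria(seqn, c(1, 22), structure = struct, dG = -30)
  }

  # (2) stem coverage: 17/22 paired = 0.773 fails, 18/22 passes
  r5 <- mk_mm(5)
  r4 <- mk_mm(4)
  expect_equal(r5$mature_antistem_mismatches, 5)
  expect_true(r4$stem_coverage_ok)   # 18/22 = 0.818
  expect_false(r5$stem_coverage_ok)  # 17/22 = 0.773

  # (5) loop boundary: 21 passes, 22 fails
  hp21 <- make_hairpin(stem_len = 30, loop_len = 21, seed = 43)
  hp22 <- make_hairpin(stem_len = 30, loop_len = 22, seed = 43)
  expect_true(check_hairpin_criteria(hp21$sequence, c(1, 22),
                                     structure = hp21$structure, dG = -30)$loop_ok)
  expect_false(check_hairpin_criteria(hp22$sequence, c(1, 22),
                                      structure = hp22$structure, dG = -30)$loop_ok)

  # (4) length boundary: 53 fails, 54 passes (stem*2 + loop)
  hp53 <- make_hairpin(stem_len = 25, loop_len = 3, seed = 44)   # 53 nt
  hp54 <- make_hairpin(stem_len = 25, loop_len = 4, seed = 44)   # 54 nt
  expect_equal(nchar(hp53$sequence), 53)
  expect_false(check_hairpin_criteria(hp53$sequence, c(1, 22),
                                      structure = hp53$structure, dG = -30)$length_ok)
  expect_true(check_hairpin_criteria(hp54$sequence, c(1, 22),
                                     structure = hp54$structure, dG = -30)$length_ok)

  # (3) bulge boundary: a single interior loop of 18 passes, 19 fails
  mk_bulged <- function(k) {
    stem <- 15
    arm5 <- strrep("G", stem)
    arm3 <- strrep("C", stem)
    seqn <- paste0(arm5, "AAAA", substring(arm3, 1, 7), strrep("A", k),
                   substring(arm3, 8))
    struct <- paste0(strrep("(", stem), "....", strrep(")", 7), strrep(".", k),
                     strrep(")", 8))
    check_hairpin_criteria(seqn, c(1, 10), structure = struct, dG = -30)
  }
  expect_equal(mk_bulged(18)$max_bulge, 18)
  expect_true(mk_bulged(18)$bulge_ok)
  expect_false(mk_bulged(19)$bulge_ok)

  # (6) mismatch boundary: 6 passes, 7 fails (coverage ignored here)
  expect_true(mk_mm(6)$mismatch_ok)
  expect_false(mk_mm(7)$mismatch_ok)
})

test_that("mature span outside the candidate is a coordinate error", {
  hp <- make_hairpin(seed = 46)
  expect_error(check_hairpin_criteria(hp$sequence, c(1, hp$length + 1),
                                      structure = hp$structure, dG = -20),
               "outside")
})

test_that("within-family identity calibration recovers the planted floor", {
  fams <- list(f1 = c("UGAGGUAGUAGGUUGUAUAGUU", "UGAGGUAGUAGGUUGUAUAGUU"))
  expect_equal(calibrate_identity_threshold(fams)$min_identity, 1.0)

  set.seed(31)
  base <- random_rna(20)
  fams2 <- list()
  for (k in 1:5) {
    v <- mutate_homolog(base, 0.9, seed = k)  # 2 subs on a 20-mer: identity 0.9
    fams2[[paste0("f", k)]] <- c(base, v$sequence)
  }
  cal <- calibrate_identity_threshold(fams2)
  expect_gte(cal$min_identity, 0.9)
  expect_lte(cal$min_identity, 0.95)

  expect_error(calibrate_identity_threshold(list(a = "ACGUACGUACGUACGUACG",
                                                 b = "ACGUACGUACGUACGUACG")),
               "undefined")
})
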
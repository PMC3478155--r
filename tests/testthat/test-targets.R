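# A miRNA with a GC-balanced seed used across the target tests.
TEST_MIR <- "UGGCAGUCGAAGCUGCCAGCAU"

test_that("canonical site types are detected at planted positions", {
  fx8 <- make_utr_with_sites(TEST_MIR, "8mer", seed = 1)
  sites <- predict_seedtype(TEST_MIR, fx8$utr$sequence)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_type, "8mer")
  expect_equal(sites$start, fx8$truth$site_start)
  expect_equal(sites$end, fx8$truth$site_end)

  for (tp in c("7mer-m8", "7mer-A1", "6mer")) {
    fx <- make_utr_with_sites(TEST_MIR, tp, seed = 2)
    s <- predict_seedtype(TEST_MIR, fx$utr$sequence)
    expect_equal(s$site_type, tp)
  }
})

test_that("a hostile UTR yields no sites and strongest type wins", {
  expect_equal(nrow(predict_seedtype("CCGCGCGCGCGCGCGCGCGC", strrep("A", 60))), 0)
  # an 8mer site must not also be reported as its contained 6mer
  fx <- make_utr_with_sites(TEST_MIR, "8mer", seed = 3)
  s <- predict_seedtype(TEST_MIR, fx$utr$sequence)
  expect_equal(nrow(s), 1)
  expect_equal(s$site_type, "8mer")
})

test_that("seed scanning agrees with the brute-force offset oracle", {
  set.seed(13)
  for (rep in 1:25) {
    mir <- random_rna(22, gc = 0.5)
    utr <- random_rna(300, gc = 0.5)
    got <- predict_seedtype(mir, utr)
    oracle <- oracle_seed_scan(mir, utr)
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(got) > 0) {
      expect_equal(sort(got$site_type), sort(oracle$site_type))
    }
  }
})

test_that("every 8mer site contains a 6mer core at the same register", {
  set.seed(14)
  for (rep in 1:10) {
    mir <- random_rna(22)
    utr <- random_rna(500)
    s <- predict_seedtype(mir, utr)
    eights <- s[s$site_type == "8mer", , drop = FALSE]
    for (i in seq_len(nrow(eights))) {
      core <- substring(utr, eights$start[i] + 1, eights$start[i] + 6)
      expect_equal(core, revcomp_rna(substring(mir, 2, 7)))
    }
  }
})

test_that("the energy predictor enforces the published seed rules", {
  fx <- make_utr_with_sites(TEST_MIR, "8mer", seed = 4)
  b <- predict_energy(TEST_MIR, fx$utr$sequence)
  expect_gte(nrow(b), 1)
  expect_true(all(b$duplex_dG <= -9 + 1e-9))
  expect_true(all(b$gu_count <= 1))

  # two G:U wobbles are rejected regardless of energy: seed GGGGGG pairing
  # a UTR stretch of UU + CCCC gives two GU pairs
  mir_g <- "AGGGGGGCGCGCGCGCGCGC"
  utr_2gu <- paste0(strrep("A", 30), "UUCCCC", strrep("A", 30))
  # registers pairing positions 2-7 (GGGGGG) against UUCCCC have 2 GU wobbles
  b2 <- predict_energy(mir_g, utr_2gu, ddG_cutoff = 0)
  expect_false(any(b2$start <= 36 & b2$end >= 31 & b2$gu_count > 1))

  # an AU-only weak seed misses the cutoff
  mir_au <- "UAUAUAUACGCGCGCGCGCG"
  utr_au <- paste0(strrep("C", 30), revcomp_rna(substring(mir_au, 2, 9)),
                   strrep("C", 30))
  b3 <- predict_energy(mir_au, utr_au, ddG_cutoff = -9)
  expect_equal(nrow(b3), 0)
  b4 <- predict_energy(mir_au, utr_au, ddG_cutoff = 0)
  expect_gte(nrow(b4), 1)  # the duplex exists; only the cutoff rejected it
})

test_that("duplex energies match an independent additive recomputation", {
  em <- energy_model()
  fx <- make_utr_with_sites(TEST_MIR, "8mer", seed = 5)
  b <- predict_energy(TEST_MIR, fx$utr$sequence)
  expect_gte(nrow(b), 1)
  uc <- strsplit(fx$utr$sequence, "")[[1]]
  mc <- strsplit(TEST_MIR, "")[[1]]
  for (i in seq_len(nrow(b))) {
    L <- b$end[i] - b$start[i] + 1L
    anchor <- b$start[i] + L + 1L
    # grow the helix through the register, then sum stacks by hand
    pos <- b$start[i]:b$end[i]
    while (pos[1] - 1 >= 1 && anchor - (pos[1] - 1) <= length(mc) &&
           !is.na(pair_type(uc[pos[1] - 1], mc[anchor - (pos[1] - 1)]))) {
      pos <- c(pos[1] - 1, pos)
    }
    while (pos[length(pos)] + 1 <= length(uc) && anchor - (pos[length(pos)] + 1) >= 1 &&
           !is.na(pair_type(uc[pos[length(pos)] + 1], mc[anchor - (pos[length(pos)] + 1)]))) {
      pos <- c(pos, pos[length(pos)] + 1)
    }
    pts <- pair_type(uc[pos], mc[anchor - pos])
    e <- em$duplex_init + sum(em$stack[cbind(pts[-length(pts)], pts[-1])])
    expect_equal(b$duplex_dG[i], e)
  }
})

test_that("consensus requires both predictors with overlapping sites", {
  a <- data.frame(mirna_id = "m", mrna_id = "g", start = 101L, end = 108L,
                  site_type = "8mer", gu_count = 0L, duplex_dG = NA,
                  predictor = "A_seedtype", stringsAsFactors = FALSE)
  b <- a
  b$start <- 103L; b$end <- 108L; b$predictor <- "B_energy"
  expect_equal(nrow(consensus_targets(a, b)), 1)

  b_far <- b
  b_far$start <- 200L; b_far$end <- 207L
  expect_equal(nrow(consensus_targets(a, b_far)), 0)
  expect_equal(nrow(consensus_targets(a, b_far, pair_level = TRUE)), 1)
  expect_equal(nrow(consensus_targets(a, b[0, ])), 0)  # A only: no consensus
})

test_that("FPR arithmetic and consensus monotonicity hold on labeled sets", {
  set.seed(23)
  mirs <- replicate(6, random_rna(22, gc = 0.55))
  neg <- data.frame(mirna = mirs,
                    utr = replicate(6, random_rna(400)),
                    label = "negative", stringsAsFactors = FALSE)
  pos <- do.call(rbind, lapply(1:4, function(i) {
    fx <- make_utr_with_sites(mirs[i], "8mer", seed = 100 + i)
    data.frame(mirna = mirs[i], utr = fx$utr$sequence, label = "positive",
               stringsAsFactors = FALSE)
  }))
  pairs <- rbind(neg, pos)
  fA <- estimate_fpr(function(m, u) predict_seedtype(m, u), pairs)
  fB <- estimate_fpr(function(m, u) predict_energy(m, u), pairs)
  fC <- estimate_fpr(consensus_predictor(), pairs)
  expect_lte(fC$fpr, min(fA$fpr, fB$fpr))
  expect_equal(fA$tpr, 1)   # planted canonical sites are always seed-recovered
  expect_error(estimate_fpr(function(m, u) predict_seedtype(m, u), pos),
               "negative")

  # arithmetic: 2 flagged of 10 is 0.20
  flag2 <- local({
    i <- 0
    function(m, u) {
      i <<- i + 1
      if (i <= 2) data.frame(mirna_id = "m", mrna_id = "g", start = 1L, end = 6L,
                             site_type = "6mer", gu_count = 0L, duplex_dG = NA,
                             predictor = "A_seedtype")
      else mirpipe:::.empty_sites()
    }
  })
  ten <- data.frame(mirna = rep("x", 10), utr = rep("y", 10), label = "negative")
  expect_equal(estimate_fpr(flag2, ten)$fpr, 0.2)
})

test_that("antisense miRNAs are exact reverse-complement matches only", {
  set.seed(29)
  mature <- random_rna(22)
  mrna_hit <- paste0(random_rna(50), revcomp_rna(mature), random_rna(50))
  ch <- strsplit(revcomp_rna(mature), "")[[1]]
  ch[11] <- setdiff(c("A", "C", "G", "U"), ch[11])[1]
  mrna_miss <- paste0(random_rna(50), paste(ch, collapse = ""), random_rna(50))
  hits <- find_antisense_mirnas(c(m1 = mature),
                                c(g1 = mrna_hit, g2 = mrna_miss, g3 = mrna_hit))
  expect_equal(nrow(hits), 2)           # two mRNAs carry the perfect antisense
  expect_setequal(hits$mrna_id, c("g1", "g3"))
  expect_equal(hits$start[1], 51)
})
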
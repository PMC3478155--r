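.empty_sites <- function() {
  data.frame(mirna_id = character(0), mrna_id = character(0),
             start = integer(0), end = integer(0), site_type = character(0),
             gu_count = integer(0), duplex_dG = numeric(0),
             predictor = character(0), stringsAsFactors = FALSE)
}

.wc_complement <- function(b) chartr("ACGU", "UGCA", b)

#' Canonical seed-type target prediction (predictor A)
#'
#' Scans a 3'UTR for Watson-Crick matches to the miRNA seed. Site types:
#' 6mer = complement of miRNA positions 2-7; 7mer-m8 = positions 2-8;
#' 7mer-A1 = positions 2-7 plus an A on the UTR opposite miRNA position 1;
#' 8mer = positions 2-8 plus the A1. No G:U pairs, no mismatches; each seed
#' match is reported once with the strongest type
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer). The miRNA is antiparallel to the UTR,
#' so on the UTR (5'->3') the site reads: [m8 complement][positions 7..2
#' complement][A1].
#'
#' @param mirna mature miRNA sequence (>= 8 nt).
#' @param utr 3'UTR sequence.
#' @param mirna_id,mrna_id identifiers carried into the site table.
#' @return site data frame (1-based inclusive UTR coordinates).
#' @export
predict_seedtype <- function(mirna, utr, mirna_id = "mirna", mrna_id = "mrna") {
  mirna <- as_rna(mirna); utr <- as_rna(utr)
  if (nchar(mirna) < 8) stop("miRNA must be at least 8 nt", call. = FALSE)
  core6 <- revcomp_rna(substring(mirna, 2, 7))
  m8c <- .wc_complement(substring(mirna, 8, 8))
  n <- nchar(utr)
  hits <- gregexpr(core6, utr, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(.empty_sites())
  rows <- lapply(as.integer(hits), function(c0) {
    has_m8 <- c0 > 1 && substring(utr, c0 - 1, c0 - 1) == m8c
    has_a1 <- c0 + 6 <= n && substring(utr, c0 + 6, c0 + 6) == "A"
    if (has_m8 && has_a1) {
      data.frame(start = c0 - 1L, end = c0 + 6L, site_type = "8mer")
    } else if (has_m8) {
      data.frame(start = c0 - 1L, end = c0 + 5L, site_type = "7mer-m8")
    } else if (has_a1) {
      data.frame(start = c0, end = c0 + 6L, site_type = "7mer-A1")
    } else {
      data.frame(start = c0, end = c0 + 5L, site_type = "6mer")
    }
  })
  out <- do.call(rbind, rows)
  data.frame(mirna_id = mirna_id, mrna_id = mrna_id, start = out$start,
             end = out$end, site_type = out$site_type, gu_count = 0L,
             duplex_dG = NA_real_, predictor = "A_seedtype",
             stringsAsFactors = FALSE)
}

# Energy of the maximal contiguous miRNA:UTR helix through a fixed register.
# Register: UTR position u pairs miRNA position m with u + m == anchor.
.duplex_energy <- function(utr_chars, mir_chars, u_start, u_end, anchor, model) {
  u <- u_start
  while (u - 1 >= 1 && anchor - (u - 1) <= length(mir_chars) &&
         !is.na(pair_type(utr_chars[u - 1], mir_chars[anchor - (u - 1)]))) {
    u <- u - 1
  }
  v <- u_end
  while (v + 1 <= length(utr_chars) && anchor - (v + 1) >= 1 &&
         !is.na(pair_type(utr_chars[v + 1], mir_chars[anchor - (v + 1)]))) {
    v <- v + 1
  }
  pos <- u:v
  pts <- pair_type(utr_chars[pos], mir_chars[anchor - pos])
  e <- model$duplex_init
  if (length(pos) > 1) {
    for (k in seq_len(length(pos) - 1)) e <- e + model$stack[pts[k], pts[k + 1]]
  }
  e
}

#' Energy-filtered seed target prediction (predictor B)
#'
#' Candidate sites are 6-8 nt seed duplexes starting at miRNA position 2
#' with zero mismatches and at most one G:U wobble (no G:U in 6mers). For
#' each candidate register the full miRNA:UTR duplex energy is computed as
#' the maximal contiguous helix through the seed under the shared
#' nearest-neighbour stack table (duplex initiation included, no
#' intramolecular accessibility term); the site is kept when
#' `duplex_dG <= ddG_cutoff`. One site per register, at the longest
#' qualifying seed.
#'
#' @param mirna mature miRNA sequence (>= 8 nt).
#' @param utr 3'UTR sequence.
#' @param ddG_cutoff duplex energy cutoff in kcal/mol (default -9).
#' @param model [energy_model()].
#' @param mirna_id,mrna_id identifiers.
#' @return site data frame; `site_type` is `seed6`/`seed7`/`seed8`.
#' @export
predict_energy <- function(mirna, utr, ddG_cutoff = -9, model = energy_model(),
                           mirna_id = "mirna", mrna_id = "mrna") {
  mirna <- as_rna(mirna); utr <- as_rna(utr)
  if (nchar(mirna) < 8) stop("miRNA must be at least 8 nt", call. = FALSE)
  uc <- .seq_chars(utr); mc <- .seq_chars(mirna)
  n <- length(uc)
  rows <- list()
  for (c0 in seq_len(n)) {
    best <- NULL
    for (L in c(8L, 7L, 6L)) {
      if (nchar(mirna) < L + 1 || c0 + L - 1 > n) next
      # UTR positions c0..c0+L-1 pair miRNA positions (L+1)..2 (antiparallel)
      anchor <- c0 + L + 1L
      mpos <- anchor - (c0:(c0 + L - 1L))
      pts <- pair_type(uc[c0:(c0 + L - 1L)], mc[mpos])
      if (anyNA(pts)) next
      gu <- sum(pts %in% c("GU", "UG"))
      if (gu > 1 || (L == 6 && gu > 0)) next
      dG <- .duplex_energy(uc, mc, c0, c0 + L - 1L, anchor, model)
      if (dG <= ddG_cutoff + 1e-9) {
        best <- data.frame(start = c0, end = c0 + L - 1L,
                           site_type = paste0("seed", L), gu_count = gu,
                           duplex_dG = dG)
        break
      }
    }
    if (!is.null(best)) rows[[length(rows) + 1]] <- best
  }
  if (length(rows) == 0) return(.empty_sites())
  out <- do.call(rbind, rows)
  data.frame(mirna_id = mirna_id, mrna_id = mrna_id, start = out$start,
             end = out$end, site_type = out$site_type, gu_count = out$gu_count,
             duplex_dG = out$duplex_dG, predictor = "B_energy",
             stringsAsFactors = FALSE)
}

#' Consensus of the two target predictors
#'
#' A miRNA-mRNA pair is a consensus target when predictor A and predictor B
#' each report at least one site for the pair and the sites overlap by at
#' least one UTR position (set `pair_level = TRUE` to relax the overlap
#' requirement to pair identity). The consensus site is the A-site,
#' annotated with both provenances.
#'
#' @param sites_A,sites_B site tables from [predict_seedtype()] and
#'   [predict_energy()] over the same miRNA/UTR universe.
#' @param pair_level if `TRUE`, any pair predicted by both is consensus.
#' @return consensus site data frame (`predictor = "consensus"`).
#' @export
consensus_targets <- function(sites_A, sites_B, pair_level = FALSE) {
  if (nrow(sites_A) == 0 || nrow(sites_B) == 0) return(.empty_sites())
  rows <- list()
  for (key in unique(paste(sites_A$mirna_id, sites_A$mrna_id))) {
    a <- sites_A[paste(sites_A$mirna_id, sites_A$mrna_id) == key, , drop = FALSE]
    b <- sites_B[paste(sites_B$mirna_id, sites_B$mrna_id) == key, , drop = FALSE]
    if (nrow(b) == 0) next
    for (i in seq_len(nrow(a))) {
      hit <- pair_level ||
        any(b$start <= a$end[i] & b$end >= a$start[i])
      if (hit) {
        r <- a[i, ]
        r$predictor <- "consensus"
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else .empty_sites()
}

#' Estimate a predictor's false positive rate on labeled pairs
#'
#' FPR = fraction of negative miRNA-UTR pairs for which the predictor
#' reports at least one site.
#'
#' @param predictor a function `(mirna, utr)` returning a site table, e.g.
#'   `predict_seedtype`, `predict_energy`, or [consensus_predictor()].
#' @param pairs data frame with columns `mirna`, `utr`, `label`
#'   (`"positive"`/`"negative"`).
#' @return list with `fpr`, `n_negative`, `n_flagged` and `tpr` (on the
#'   positive pairs, `NA` when there are none).
#' @export
estimate_fpr <- function(predictor, pairs) {
  neg <- pairs[pairs$label == "negative", , drop = FALSE]
  if (nrow(neg) == 0) stop("at least one negative pair required", call. = FALSE)
  fires <- function(df) vapply(seq_len(nrow(df)), function(i) {
    nrow(predictor(df$mirna[i], df$utr[i])) > 0
  }, logical(1))
  n_flagged <- sum(fires(neg))
  pos <- pairs[pairs$label == "positive", , drop = FALSE]
  tpr <- if (nrow(pos)) mean(fires(pos)) else NA_real_
  list(fpr = n_flagged / nrow(neg), n_negative = nrow(neg),
       n_flagged = n_flagged, tpr = tpr)
}

#' Consensus predictor closure for [estimate_fpr()]
#'
#' @param ddG_cutoff energy cutoff passed to [predict_energy()].
#' @param model [energy_model()].
#' @param pair_level passed to [consensus_targets()].
#' @return function `(mirna, utr)` returning consensus sites.
#' @export
consensus_predictor <- function(ddG_cutoff = -9, model = energy_model(),
                                pair_level = FALSE) {
  function(mirna, utr) {
    consensus_targets(predict_seedtype(mirna, utr),
                      predict_energy(mirna, utr, ddG_cutoff, model),
                      pair_level = pair_level)
  }
}

#' Find miRNAs antisense to mRNAs
#'
#' Pairs where the reverse complement of the full mature miRNA is an exact
#' substring of an mRNA (the miRNA is perfectly complementary to the sense
#' transcript).
#'
#' @param catalog catalog data frame (or named character vector of matures).
#' @param mrnas mRNA sequences (named character vector or
#'   `read_sequences()` frame).
#' @return data frame: `mirna_id`, `mrna_id`, `start`, `end` (match span on
#'   the mRNA).
#' @export
find_antisense_mirnas <- function(catalog, mrnas) {
  matures <- if (is.data.frame(catalog) && "mature_sequence" %in% names(catalog)) {
    stats::setNames(catalog$mature_sequence, catalog$name)
  } else {
    .as_named_seqs(catalog)
  }
  mrnas <- .as_named_seqs(mrnas)
  rows <- list()
  for (mi in names(matures)) {
    rc <- revcomp_rna(matures[[mi]])
    for (mr in names(mrnas)) {
      hits <- gregexpr(rc, mrnas[[mr]], fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      for (h in as.integer(hits)) {
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = mi, mrna_id = mr, start = h,
          end = h + nchar(rc) - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(mirna_id = character(0), mrna_id = character(0),
               start = integer(0), end = integer(0))
  }
}
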
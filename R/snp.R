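#' Classify a precursor SNP by hairpin region
#'
#' Four-type classification against the wild-type structure: `mature` when
#' the position falls in the mature span (overriding everything else),
#' `loop` when in the terminal loop, `anti-stem` when on the arm opposite
#' the mature, and `stem` otherwise (same arm as the mature but outside the
#' mature span).
#'
#' @param position 1-based SNP position on the precursor.
#' @param annotation [annotate_regions()] result with a mature span.
#' @return one of `"mature"`, `"stem"`, `"loop"`, `"anti-stem"`.
#' @export
classify_snp <- function(position, annotation) {
  n <- length(annotation$region)
  if (position < 1 || position > n) {
    stop("SNP position outside the precursor", call. = FALSE)
  }
  ms <- annotation$mature_span
  if (is.null(ms)) stop("annotation lacks a mature span", call. = FALSE)
  if (position >= ms[1] && position <= ms[2]) return("mature")
  reg <- annotation$region[position]
  if (reg == "loop") return("loop")
  if (reg == annotation$mature_arm) "stem" else "anti-stem"
}

#' Apply a single-nucleotide substitution
#'
#' @param sequence RNA string.
#' @param snp list or one-row data frame with `position`, `ref_allele`,
#'   `alt_allele` (RNA alphabet).
#' @return the mutated sequence. Errors when the reference allele does not
#'   match the sequence (stale coordinates guard).
#' @export
apply_snp <- function(sequence, snp) {
  sequence <- as_rna(sequence)
  pos <- as.integer(snp$position)
  if (pos < 1 || pos > nchar(sequence)) {
    stop("SNP position outside the sequence", call. = FALSE)
  }
  ref <- as_rna(snp$ref_allele)
  if (substring(sequence, pos, pos) != ref) {
    stop(sprintf("reference allele mismatch at position %d: sequence has %s, SNP says %s",
                 pos, substring(sequence, pos, pos), ref), call. = FALSE)
  }
  paste0(substring(sequence, 1, pos - 1), as_rna(snp$alt_allele),
         substring(sequence, pos + 1))
}

#' Interpret a precursor energy change for miRNA biogenesis
#'
#' Energy changes smaller than `threshold` in magnitude are negligible.
#' Under the literal published rule, a SNP that decreases the hairpin
#' energy (ddG <= -threshold) reduces mature-miRNA production and one that
#' increases it (ddG >= +threshold) increases production;
#' `rule = "inverted"` swaps the mapping.
#'
#' @param ddG energy change in kcal/mol (mutant minus wild type).
#' @param threshold minimum magnitude treated as biogenesis-altering
#'   (default 0.3 kcal/mol).
#' @param rule `"literal"` (default) or `"inverted"`.
#' @return one of `"negligible"`, `"decrease_production"`,
#'   `"increase_production"`.
#' @export
interpret_biogenesis <- function(ddG, threshold = 0.3,
                                 rule = c("literal", "inverted")) {
  rule <- match.arg(rule)
  if (!is.finite(ddG)) stop("ddG must be finite", call. = FALSE)
  if (abs(ddG) < threshold - 1e-9) return("negligible")
  down <- ddG <= -threshold + 1e-9
  if (rule == "literal") {
    if (down) "decrease_production" else "increase_production"
  } else {
    if (down) "increase_production" else "decrease_production"
  }
}

#' Energy change of a precursor SNP (ddG)
#'
#' Folds the wild-type and mutant precursors independently with the same
#' engine; ddG = dG(mutant) - dG(wild type) (the sign convention is fixed
#' as mutant-minus-wild). The SNP region is classified on the wild-type
#' structure; the biogenesis interpretation follows
#' [interpret_biogenesis()]. Because loop penalties are size-only, a loop
#' SNP that leaves the minimum-energy structure unchanged has ddG exactly 0.
#'
#' @param precursor wild-type precursor sequence.
#' @param snp SNP record (`position`, `ref_allele`, `alt_allele`).
#' @param mature_span mature span on the precursor (1-based inclusive).
#' @param engine folding engine with the [fold_with()] contract.
#' @param threshold,rule passed to [interpret_biogenesis()].
#' @param ... passed to the engine.
#' @return list with `ddG`, `dG_wild`, `dG_mut`, `region`,
#'   `interpretation`, `structure_wild`, `structure_mut`.
#' @export
ddg <- function(precursor, snp, mature_span, engine = fold_hairpin,
                threshold = 0.3, rule = "literal", ...) {
  precursor <- as_rna(precursor)
  wild <- fold_with(precursor, engine, ...)
  mut_seq <- apply_snp(precursor, snp)
  mut <- fold_with(mut_seq, engine, ...)
  region <- tryCatch({
    ann <- annotate_regions(wild$structure, mature_span)
    classify_snp(as.integer(snp$position), ann)
  }, error = function(e) NA_character_)  # e.g. mature straddles arms after refolding
  ddG <- mut$dG - wild$dG
  list(ddG = ddG, dG_wild = wild$dG, dG_mut = mut$dG, region = region,
       interpretation = interpret_biogenesis(ddG, threshold, rule),
       structure_wild = wild$structure, structure_mut = mut$structure)
}

#' Gain/loss verdict from predictor firing patterns
#'
#' The published definitions, as a pure function of whether each predictor
#' reports any site on the wild-type and SNP-type UTR: a target **loss**
#' requires consensus (both predictors) on the wild type and neither
#' predictor firing on the SNP type; a target **gain** is the symmetric
#' case; the remaining 14 of the 16 firing patterns are **unchanged**.
#'
#' @param a_wild,b_wild,a_mut,b_mut logicals: does predictor A/B fire on
#'   the wild-type / SNP-type UTR?
#' @return `"loss"`, `"gain"` or `"unchanged"`.
#' @export
gain_loss_verdict <- function(a_wild, b_wild, a_mut, b_mut) {
  if (a_wild && b_wild && !a_mut && !b_mut) return("loss")
  if (a_mut && b_mut && !a_wild && !b_wild) return("gain")
  "unchanged"
}

#' Call SNP-driven target gain/loss in a 3'UTR
#'
#' Runs both predictors on the wild-type and SNP-type UTR, restricted to
#' sites overlapping the SNP position +/- (maximum site length - 1), and
#' issues one verdict per miRNA with any site in that window on either
#' allele. The consensus requirement on the firing side uses the
#' site-overlap rule of [consensus_targets()].
#'
#' @param mirnas named character vector of mature miRNA sequences (or a
#'   catalog data frame).
#' @param utr wild-type 3'UTR sequence.
#' @param snp SNP record (`position`, `ref_allele`, `alt_allele`) on the
#'   UTR.
#' @param ddG_cutoff energy cutoff for predictor B.
#' @param model [energy_model()].
#' @return data frame: `mirna_id`, `verdict`, `a_wild`, `b_wild`,
#'   `consensus_wild`, `a_mut`, `b_mut`, `consensus_mut`.
#' @export
call_gain_loss <- function(mirnas, utr, snp, ddG_cutoff = -9,
                           model = energy_model()) {
  matures <- if (is.data.frame(mirnas) && "mature_sequence" %in% names(mirnas)) {
    stats::setNames(mirnas$mature_sequence, mirnas$name)
  } else {
    .as_named_seqs(mirnas)
  }
  utr <- as_rna(utr)
  pos <- as.integer(snp$position)
  if (pos < 1 || pos > nchar(utr)) {
    stop("SNP outside the UTR", call. = FALSE)
  }
  mut <- apply_snp(utr, snp)
  win <- c(pos - 7L, pos + 7L)
  in_window <- function(sites) {
    sites[sites$start <= win[2] & sites$end >= win[1], , drop = FALSE]
  }
  rows <- list()
  for (mi in names(matures)) {
    aw <- in_window(predict_seedtype(matures[[mi]], utr, mirna_id = mi))
    bw <- in_window(predict_energy(matures[[mi]], utr, ddG_cutoff, model,
                                   mirna_id = mi))
    am <- in_window(predict_seedtype(matures[[mi]], mut, mirna_id = mi))
    bm <- in_window(predict_energy(matures[[mi]], mut, ddG_cutoff, model,
                                   mirna_id = mi))
    if (nrow(aw) + nrow(bw) + nrow(am) + nrow(bm) == 0) next
    cons_w <- nrow(consensus_targets(aw, bw)) > 0
    cons_m <- nrow(consensus_targets(am, bm)) > 0
    verdict <- if (cons_w && nrow(am) == 0 && nrow(bm) == 0) {
      "loss"
    } else if (cons_m && nrow(aw) == 0 && nrow(bw) == 0) {
      "gain"
    } else {
      "unchanged"
    }
    rows[[length(rows) + 1]] <- data.frame(
      mirna_id = mi, verdict = verdict,
      a_wild = nrow(aw) > 0, b_wild = nrow(bw) > 0, consensus_wild = cons_w,
      a_mut = nrow(am) > 0, b_mut = nrow(bm) > 0, consensus_mut = cons_m,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(mirna_id = character(0), verdict = character(0),
               a_wild = logical(0), b_wild = logical(0),
               consensus_wild = logical(0), a_mut = logical(0),
               b_mut = logical(0), consensus_mut = logical(0))
  }
}
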
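# Coerce sequence input (data frame from read_sequences, named character
# vector, or Biostrings XStringSet) to a named character vector of RNA strings.
.as_named_seqs <- function(x) {
  if (length(x) == 0) return(stats::setNames(character(0), character(0)))
  if (is.data.frame(x)) {
    out <- as_rna(x$sequence)
    names(out) <- x$id
  } else if (methods::is(x, "XStringSet")) {
    out <- as_rna(as.character(x))
  } else {
    out <- as_rna(unlist(x))
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  }
  out
}

#' Remove identical mature miRNA sequences
#'
#' Exact-sequence deduplication; the first-seen name is retained and the
#' names of identical later entries are recorded as aliases.
#'
#' @param matures named character vector or `read_sequences()` data frame.
#' @return data frame with columns `name`, `sequence`, `aliases`
#'   (comma-separated, empty when unique).
#' @export
dedup_matures <- function(matures) {
  seqs <- .as_named_seqs(matures)
  if (length(seqs) == 0) {
    return(data.frame(name = character(0), sequence = character(0),
                      aliases = character(0)))
  }
  first <- !duplicated(seqs)
  keep <- seqs[first]
  aliases <- vapply(keep, function(s) {
    dup <- names(seqs)[seqs == s]
    paste(dup[-1], collapse = ",")
  }, character(1))
  data.frame(name = names(keep), sequence = unname(keep),
             aliases = unname(aliases), row.names = NULL)
}

# Count of character mismatches between equal-length strings.
.mm_count <- function(a, b) {
  mapply(function(x, y) sum(.seq_chars(x) != .seq_chars(y)), a, b, USE.NAMES = FALSE)
}

#' Align a mature miRNA against reference sequences by homology
#'
#' Ungapped sliding alignment of the full query against every window of each
#' reference, on both strands; identity is the fraction of query positions
#' that match. Hits at or above `min_identity` are returned sorted by
#' identity, then reference order, then position.
#'
#' @param query mature miRNA sequence (RNA or DNA alphabet), length >= 18.
#' @param references reference contigs (named character vector or
#'   `read_sequences()` data frame).
#' @param min_identity identity threshold (default 0.90).
#' @param query_id optional query name carried through to the hits.
#' @return data frame with columns `query_id`, `reference_id`, `start`,
#'   `end` (1-based inclusive on the plus strand), `strand`, `mismatches`,
#'   `identity`.
#' @export
align_mirna <- function(query, references, min_identity = 0.90, query_id = "query") {
  query <- as_rna(query)
  .check_rna(query, "query")
  qlen <- nchar(query)
  if (qlen < 18) stop("query shorter than 18 nt is refused", call. = FALSE)
  refs <- .as_named_seqs(references)
  max_mm <- floor((1 - min_identity) * qlen + 1e-9)
  hits <- list()
  for (ref_id in names(refs)) {
    ref <- refs[[ref_id]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") query else revcomp_rna(query)
      m <- Biostrings::matchPattern(pat, Biostrings::BString(ref),
                                    max.mismatch = max_mm, with.indels = FALSE)
      if (length(m) == 0) next
      st <- BiocGenerics::start(m)
      en <- BiocGenerics::end(m)
      ok <- st >= 1 & en <= nchar(ref)
      st <- st[ok]; en <- en[ok]
      if (length(st) == 0) next
      mm <- .mm_count(substring(ref, st, en), pat)
      hits[[length(hits) + 1]] <- data.frame(
        query_id = query_id, reference_id = ref_id, start = st, end = en,
        strand = strand, mismatches = mm, identity = (qlen - mm) / qlen)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(query_id = character(0), reference_id = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      mismatches = integer(0), identity = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[out$identity >= min_identity - 1e-9, , drop = FALSE]
  out <- out[order(-out$identity, match(out$reference_id, names(refs)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Excise a candidate precursor around a homology hit
#'
#' Extends the mapped interval by `flank` nucleotides on each side (silently
#' truncated at the reference ends). Minus-strand hits are excised and
#' reverse-complemented, with the mature offset recomputed on the excised
#' strand.
#'
#' @param reference single reference sequence (character) or named set from
#'   which `hit$reference_id` is taken.
#' @param hit one row of an [align_mirna()] hit table (list or data frame).
#' @param flank flanking length in nt (default 60).
#' @return list with `sequence` (candidate, excised strand), `location`
#'   (reference_id/start/end/strand, plus-strand coordinates), `mature_span`
#'   (1-based on the candidate) and `truncated` (logical, either end).
#' @export
extract_candidate <- function(reference, hit, flank = 60) {
  refs <- .as_named_seqs(reference)
  ref_id <- if (!is.null(hit$reference_id) && hit$reference_id %in% names(refs)) {
    hit$reference_id
  } else {
    names(refs)[1]
  }
  ref <- refs[[ref_id]]
  len <- nchar(ref)
  if (hit$start < 1 || hit$end > len) stop("hit outside reference", call. = FALSE)
  start <- max(1L, as.integer(hit$start) - as.integer(flank))
  end <- min(len, as.integer(hit$end) + as.integer(flank))
  cand <- substring(ref, start, end)
  strand <- if (is.null(hit$strand)) "+" else hit$strand
  if (strand == "-") {
    cand <- revcomp_rna(cand)
    mature_span <- c(end - hit$end + 1L, end - hit$start + 1L)
  } else {
    mature_span <- c(hit$start - start + 1L, hit$end - start + 1L)
  }
  list(sequence = cand,
       location = list(reference_id = ref_id, start = start, end = end,
                       strand = strand),
       mature_span = as.integer(mature_span),
       truncated = c(left = start > hit$start - flank,
                     right = end < hit$end + flank))
}

#' Evaluate the six hairpin criteria for a candidate precursor
#'
#' A candidate qualifies as a miRNA precursor when all six structural
#' criteria hold: (1) minimum free energy <= -15 kcal/mol; (2) at least 80%
#' of the mature miRNA base-paired in the stem; (3) no single bulge or
#' internal loop with more than 18 unpaired nt; (4) hairpin longer than
#' 53 nt (53 fails); (5) terminal loop shorter than 22 nt (22 fails);
#' (6) at most 6 mature positions unpaired against the anti-stem arm.
#' Boundary semantics follow the printed thresholds exactly.
#'
#' @param candidate precursor sequence (RNA string).
#' @param mature_span 1-based inclusive span of the mature on the candidate.
#' @param structure dot-bracket structure of the candidate (single hairpin);
#'   folded with [fold_hairpin()] when `NULL`.
#' @param dG minimum free energy in kcal/mol; folded when `NULL`.
#' @param model [energy_model()] used when folding is needed.
#' @return list of class `six_criteria` with logical flags `dG_ok`,
#'   `stem_coverage_ok`, `bulge_ok`, `length_ok`, `loop_ok`, `mismatch_ok`,
#'   the measured values, and `overall` (AND of the six).
#' @export
check_hairpin_criteria <- function(candidate, mature_span, structure = NULL,
                                   dG = NULL, model = energy_model()) {
  candidate <- as_rna(candidate)
  n <- nchar(candidate)
  mature_span <- as.integer(mature_span)
  if (mature_span[1] < 1 || mature_span[2] > n) {
    stop("mature span outside candidate", call. = FALSE)
  }
  if (is.null(structure) || is.null(dG)) {
    f <- fold_hairpin(candidate, model)
    structure <- f$structure
    dG <- f$dG
  }
  pt <- pair_table(structure)
  mat_idx <- mature_span[1]:mature_span[2]
  paired_mature <- sum(pt[mat_idx] > 0)
  coverage <- paired_mature / length(mat_idx)
  mismatches <- length(mat_idx) - paired_mature
  # interior loop sizes along the helix chain (total unpaired nt per loop)
  max_bulge <- 0L
  loop_len <- NA_integer_
  if (any(pt > 0)) {
    ch <- .hairpin_chain(pt)
    if (nrow(ch) > 1) {
      s <- (ch[-1, 1] - ch[-nrow(ch), 1] - 1L) + (ch[-nrow(ch), 2] - ch[-1, 2] - 1L)
      max_bulge <- max(0L, s)
    }
    loop_len <- ch[nrow(ch), 2] - ch[nrow(ch), 1] - 1L
  } else {
    loop_len <- n  # open structure: treat everything as loop (fails anyway)
  }
  rep <- list(
    dG = dG, dG_ok = dG <= -15,
    stem_coverage = coverage, stem_coverage_ok = coverage >= 0.80 - 1e-9,
    max_bulge = max_bulge, bulge_ok = max_bulge <= 18,
    length = n, length_ok = n > 53,
    loop_length = loop_len, loop_ok = loop_len < 22,
    mature_antistem_mismatches = mismatches, mismatch_ok = mismatches <= 6
  )
  rep$overall <- rep$dG_ok && rep$stem_coverage_ok && rep$bulge_ok &&
    rep$length_ok && rep$loop_ok && rep$mismatch_ok
  class(rep) <- "six_criteria"
  rep
}

# Best ungapped-alignment identity between two sequences: slide the shorter
# over the longer, identity = matches / shorter length.
.pairwise_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  qa <- .seq_chars(a); qlen <- length(qa)
  best <- 0
  for (off in 0:(nchar(b) - qlen)) {
    m <- sum(qa == .seq_chars(substring(b, off + 1, off + qlen)))
    best <- max(best, m / qlen)
  }
  best
}

#' Minimum within-family identity over mature miRNA families
#'
#' Computes the best ungapped-alignment identity for every within-family
#' pair of mature sequences and returns the minimum over all pairs --
#' the data-driven way to choose a homology-search identity threshold.
#'
#' @param families named list; each element a character vector of mature
#'   sequences belonging to one family.
#' @return list with `min_identity` and the per-pair table `pairs`.
#' @export
calibrate_identity_threshold <- function(families) {
  rows <- list()
  for (fam in names(families)) {
    seqs <- as_rna(families[[fam]])
    if (length(seqs) < 2) next
    idx <- utils::combn(length(seqs), 2)
    for (k in seq_len(ncol(idx))) {
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, i = idx[1, k], j = idx[2, k],
        identity = .pairwise_identity(seqs[idx[1, k]], seqs[idx[2, k]]))
    }
  }
  if (length(rows) == 0) {
    stop("no family with at least 2 members; minimum identity undefined", call. = FALSE)
  }
  pairs <- do.call(rbind, rows)
  list(min_identity = min(pairs$identity), pairs = pairs)
}
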
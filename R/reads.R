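#' Clean raw small-RNA reads
#'
#' Applies the standard small-RNA cleaning cascade, in order: reads carrying
#' the 5' adapter (anywhere, up to 1 mismatch) are discarded; the 3' adapter
#' is trimmed at its leftmost match (minimum overlap 6 nt, allowed
#' mismatches = aligned length %/% 10); reads with a poly(A) stretch (>= 8
#' consecutive A, or > 80% A after trimming) are discarded; reads with mean
#' Phred quality below `min_mean_q` are discarded; reads shorter than
#' `min_len` after trimming are discarded. Survivors are collapsed to unique
#' sequences with multiplicities.
#'
#' @param reads data frame from [read_sequences()] (FASTQ); a character
#'   vector of sequences is also accepted (no quality filter then).
#' @param adapter_3p 3' adapter sequence (required, non-empty).
#' @param adapter_5p 5' adapter sequence (optional).
#' @param min_len minimum read length after trimming (default 18).
#' @param min_mean_q minimum mean Phred score (default 20).
#' @return list with `reads` (data frame `sequence`, `count`, RNA alphabet),
#'   `accounting` (a [read_accounting()] with no contaminant classes yet)
#'   and `discarded` (named counts per discard reason).
#' @export
clean_reads <- function(reads, adapter_3p, adapter_5p = NULL,
                        min_len = 18, min_mean_q = 20) {
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("r", seq_along(reads)), sequence = as_rna(reads))
    reads$quality <- rep(list(NULL), nrow(reads))
  }
  if (missing(adapter_3p) || is.null(adapter_3p) || !nzchar(adapter_3p)) {
    stop("adapter_3p must be non-empty", call. = FALSE)
  }
  a3 <- as_rna(adapter_3p)
  a5 <- if (!is.null(adapter_5p) && nzchar(adapter_5p)) as_rna(adapter_5p) else NULL
  n_raw <- nrow(reads)
  seqs <- as_rna(reads$sequence)
  quals <- if ("quality" %in% names(reads)) reads$quality else rep(list(NULL), n_raw)

  drop_reason <- character(n_raw)

  if (!is.null(a5)) {
    has5 <- Biostrings::vcountPattern(a5, Biostrings::BStringSet(seqs),
                                      max.mismatch = 1) > 0
    drop_reason[has5] <- "adapter5"
  }

  a3_chars <- .seq_chars(a3)
  trimmed <- seqs
  for (i in seq_len(n_raw)) {
    if (nzchar(drop_reason[i])) next
    r <- .seq_chars(seqs[i])
    len <- length(r)
    for (p in seq_len(len)) {
      ov <- min(length(a3_chars), len - p + 1L)
      if (ov < 6) break
      mm <- sum(r[p:(p + ov - 1L)] != a3_chars[seq_len(ov)])
      if (mm <= ov %/% 10) {
        trimmed[i] <- if (p == 1) "" else paste(r[seq_len(p - 1L)], collapse = "")
        if (!is.null(quals[[i]])) quals[i] <- list(quals[[i]][seq_len(p - 1L)])
        break
      }
    }
  }

  for (i in seq_len(n_raw)) {
    if (nzchar(drop_reason[i])) next
    s <- trimmed[i]
    nc <- nchar(s)
    frac_a <- if (nc > 0) sum(.seq_chars(s) == "A") / nc else 0
    if (grepl("AAAAAAAA", s, fixed = TRUE) || frac_a > 0.80) {
      drop_reason[i] <- "polyA"
    } else if (!is.null(quals[[i]]) && length(quals[[i]]) > 0 &&
               mean(quals[[i]]) < min_mean_q) {
      drop_reason[i] <- "low_quality"
    } else if (nc < min_len) {
      drop_reason[i] <- "short"
    }
  }

  keep <- !nzchar(drop_reason)
  if (any(keep)) {
    tab <- table(trimmed[keep])
    cleaned <- data.frame(sequence = names(tab), count = as.integer(tab),
                          row.names = NULL, stringsAsFactors = FALSE)
    cleaned <- cleaned[order(-cleaned$count, cleaned$sequence), , drop = FALSE]
    rownames(cleaned) <- NULL
  } else {
    cleaned <- data.frame(sequence = character(0), count = integer(0))
  }
  list(reads = cleaned,
       accounting = read_accounting(n_raw, sum(keep)),
       discarded = c(adapter5 = sum(drop_reason == "adapter5"),
                     polyA = sum(drop_reason == "polyA"),
                     low_quality = sum(drop_reason == "low_quality"),
                     short = sum(drop_reason == "short")))
}

#' Annotate cleaned reads against contaminant sequence sets
#'
#' A read is annotated as a contaminant class when it aligns full-length to
#' a contaminant sequence with at most 1 mismatch (a local, deterministic
#' stand-in for a loose BLASTN search). Classes are assigned with priority
#' rRNA > tRNA > snRNA > repeat; everything else is `unannotated`.
#'
#' @param cleaned data frame with `sequence` and `count` ([clean_reads()]
#'   output `$reads`).
#' @param contaminant_sets named list of sequence sets (FASTA paths, named
#'   character vectors or `read_sequences()` frames) for classes among
#'   `rRNA`, `tRNA`, `snRNA`, `repeat`; may be empty sets.
#' @param raw_count raw read count for the accounting (defaults to the
#'   cleaned total, i.e. accounting relative to cleaning output).
#' @return list with `reads` (input plus `annotation_class` column) and
#'   `accounting` (a [read_accounting()] whose contaminant counts are read
#'   multiplicity-weighted).
#' @export
annotate_contaminants <- function(cleaned, contaminant_sets = list(),
                                  raw_count = NULL) {
  priority <- c("rRNA", "tRNA", "snRNA", "repeat")
  sets <- lapply(contaminant_sets, function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      .as_named_seqs(read_sequences(x))
    } else {
      .as_named_seqs(x)
    }
  })
  cls <- rep("unannotated", nrow(cleaned))
  for (class_name in intersect(priority, names(sets))) {
    pool <- sets[[class_name]]
    if (length(pool) == 0) next
    subj <- Biostrings::BStringSet(pool)
    todo <- which(cls == "unannotated")
    for (i in todo) {
      hit <- any(Biostrings::vcountPattern(cleaned$sequence[i], subj,
                                           max.mismatch = 1) > 0)
      if (hit) cls[i] <- class_name
    }
  }
  out <- cleaned
  out$annotation_class <- cls
  counts <- vapply(intersect(priority, names(sets)), function(k) {
    sum(out$count[out$annotation_class == k])
  }, integer(1))
  total <- sum(out$count)
  if (is.null(raw_count)) raw_count <- total
  list(reads = out,
       accounting = read_accounting(raw_count, total, counts))
}

# Exact matches of a read (both strands) against a set of references.
# Returns data frame reference_id/start/end/strand.
.exact_hits <- function(read, refs) {
  rows <- list()
  for (ref_id in names(refs)) {
    subj <- Biostrings::BString(refs[[ref_id]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else revcomp_rna(read)
      m <- Biostrings::matchPattern(pat, subj)
      if (length(m) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          reference_id = ref_id, start = BiocGenerics::start(m),
          end = BiocGenerics::end(m), strand = strand)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(reference_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  do.call(rbind, rows)
}

#' Discover miRNA loci from cleaned, unannotated sRNA reads
#'
#' Reads are mapped exact-match to the references on both strands;
#' overlapping read stacks on one reference and strand are merged into loci.
#' Each locus is excised with `flank` nt on both sides, folded, and kept
#' when (a) the dominant (most abundant) read lies entirely within one arm,
#' (b) the six hairpin criteria pass with the dominant read as the mature,
#' and (c) the locus carries at least `min_locus_reads` reads. Multi-mapping
#' reads take part in every matching locus for discovery but are counted
#' once, at their first locus in reference order, for expression.
#'
#' @param reads data frame with `sequence` and `count` (unannotated reads).
#' @param references reference sequences (named character vector or
#'   `read_sequences()` frame).
#' @param min_locus_reads minimum read count per locus (default 2).
#' @param locus_gap read stacks separated by at most this many nt are merged
#'   into one locus (default 50, enough to join the mature and star arms of
#'   a typical precursor across its loop).
#' @param flank flank length for locus excision (default 60).
#' @param model [energy_model()].
#' @return list with `catalog` (data frame: `name`, `mature_sequence`,
#'   `precursor_id`, `precursor_sequence`, `structure`, `dG`,
#'   `reference_id`, `start`, `end`, `strand`, `mature_start`, `mature_end`,
#'   `star_sequence`, `expression_count`, `provenance`) and `rejected`
#'   (data frame of locus spans with the first failing rule).
#' @export
discover_from_reads <- function(reads, references, min_locus_reads = 2,
                                locus_gap = 50, flank = 60,
                                model = energy_model()) {
  refs <- .as_named_seqs(references)
  if (nrow(reads) == 0 || length(refs) == 0) {
    stop("reads and references must be nonempty", call. = FALSE)
  }
  hits <- lapply(seq_len(nrow(reads)), function(i) {
    h <- .exact_hits(reads$sequence[i], refs)
    if (nrow(h) > 0) h$read_idx <- i
    h
  })
  hits <- do.call(rbind, hits[vapply(hits, nrow, integer(1)) > 0])
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(catalog = .empty_catalog(), rejected = data.frame()))
  }

  # loci: merge overlapping stacks per reference+strand
  hits$key <- paste(hits$reference_id, hits$strand)
  loci <- list()
  for (key in unique(hits$key)) {
    sub <- hits[hits$key == key, , drop = FALSE]
    ir <- IRanges::IRanges(sub$start, sub$end)
    red <- IRanges::reduce(ir, min.gapwidth = locus_gap + 1L, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (k in seq_along(red)) {
      members <- sub[revmap[[k]], , drop = FALSE]
      loci[[length(loci) + 1]] <- list(
        reference_id = members$reference_id[1], strand = members$strand[1],
        start = BiocGenerics::start(red)[k], end = BiocGenerics::end(red)[k],
        members = members)
    }
  }
  # deterministic order: reference order, then start
  ord <- order(match(vapply(loci, `[[`, character(1), "reference_id"), names(refs)),
               vapply(loci, `[[`, integer(1), "start"),
               vapply(loci, `[[`, character(1), "strand"))
  loci <- loci[ord]

  # expression: each read counted once, at its first locus in this order
  read_best_locus <- rep(NA_integer_, nrow(reads))
  for (li in seq_along(loci)) {
    idx <- unique(loci[[li]]$members$read_idx)
    take <- idx[is.na(read_best_locus[idx])]
    read_best_locus[take] <- li
  }

  catalog <- list()
  rejected <- list()
  for (li in seq_along(loci)) {
    loc <- loci[[li]]
    locus_count <- sum(reads$count[unique(loc$members$read_idx)])
    reject <- function(reason) {
      rejected[[length(rejected) + 1]] <<- data.frame(
        reference_id = loc$reference_id, start = loc$start, end = loc$end,
        strand = loc$strand, reason = reason)
    }
    if (locus_count < min_locus_reads) { reject("min_locus_reads"); next }
    cand <- extract_candidate(refs[loc$reference_id],
                              list(reference_id = loc$reference_id,
                                   start = loc$start, end = loc$end,
                                   strand = loc$strand), flank = flank)
    fold <- fold_hairpin(cand$sequence, model)
    core <- extract_hairpin_core(cand$sequence, fold$structure, model = model)
    if (is.null(core)) { reject("no_hairpin"); next }
    # dominant read and its span on the excised core
    midx <- loc$members$read_idx
    dom_read <- midx[order(-reads$count[midx], loc$members$start)][1]
    dom_seq <- reads$sequence[dom_read]
    dom_pos <- regexpr(dom_seq, core$sequence, fixed = TRUE)
    if (dom_pos < 0) { reject("dominant_read_unplaced"); next }
    mature_span <- c(dom_pos, dom_pos + nchar(dom_seq) - 1L)
    ann <- tryCatch(annotate_regions(core$structure, mature_span),
                    error = function(e) NULL)
    if (is.null(ann)) { reject("mature_not_in_one_arm"); next }
    crit <- check_hairpin_criteria(core$sequence, mature_span,
                                   structure = core$structure, dG = core$dG,
                                   model = model)
    if (!crit$overall) {
      failing <- names(which(!vapply(crit[grep("_ok$", names(crit))], isTRUE,
                                     logical(1))))[1]
      reject(failing); next
    }
    # star: most abundant read on the opposite arm
    star_seq <- NA_character_
    opp <- ann$antistem_arm
    for (ri in midx[order(-reads$count[midx])]) {
      if (ri == dom_read) next
      p <- regexpr(reads$sequence[ri], core$sequence, fixed = TRUE)
      if (p < 0) next
      span <- p:(p + nchar(reads$sequence[ri]) - 1L)
      if (all(ann$region[span] == opp)) { star_seq <- reads$sequence[ri]; break }
    }
    expr <- sum(reads$count[midx[read_best_locus[midx] == li &
                                   !is.na(read_best_locus[midx])]])
    # core span in plus-strand reference coordinates
    pre <- if (loc$strand == "+") {
      c(cand$location$start + core$span[1] - 1L,
        cand$location$start + core$span[2] - 1L)
    } else {
      c(cand$location$end - core$span[2] + 1L,
        cand$location$end - core$span[1] + 1L)
    }
    catalog[[length(catalog) + 1]] <- data.frame(
      name = sprintf("srna-m%03d", length(catalog) + 1L),
      mature_sequence = dom_seq,
      precursor_id = sprintf("%s:%d-%d", loc$reference_id, pre[1], pre[2]),
      precursor_sequence = core$sequence, structure = core$structure,
      dG = core$dG, reference_id = loc$reference_id,
      start = pre[1], end = pre[2],
      strand = loc$strand, mature_start = mature_span[1],
      mature_end = mature_span[2], star_sequence = star_seq,
      expression_count = expr, provenance = "srna",
      stringsAsFactors = FALSE)
  }
  cat_df <- if (length(catalog)) do.call(rbind, catalog) else .empty_catalog()
  # collapse opposite-strand echoes of one hairpin: a read from one arm also
  # maps, reverse-complemented, to the other arm, producing an overlapping
  # locus with the identical mature
  if (nrow(cat_df) > 1) {
    keep <- rep(TRUE, nrow(cat_df))
    for (j in 2:nrow(cat_df)) {
      for (i in seq_len(j - 1)) {
        if (!keep[i] || !keep[j]) next
        if (cat_df$reference_id[i] == cat_df$reference_id[j] &&
            cat_df$start[i] <= cat_df$end[j] &&
            cat_df$end[i] >= cat_df$start[j] &&
            cat_df$mature_sequence[i] == cat_df$mature_sequence[j]) {
          cat_df$expression_count[i] <- cat_df$expression_count[i] +
            cat_df$expression_count[j]
          keep[j] <- FALSE
        }
      }
    }
    cat_df <- cat_df[keep, , drop = FALSE]
    rownames(cat_df) <- NULL
  }
  list(catalog = cat_df,
       rejected = if (length(rejected)) do.call(rbind, rejected) else data.frame())
}

.empty_catalog <- function() {
  data.frame(name = character(0), mature_sequence = character(0),
             precursor_id = character(0), precursor_sequence = character(0),
             structure = character(0), dG = numeric(0),
             reference_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), mature_start = integer(0),
             mature_end = integer(0), star_sequence = character(0),
             expression_count = integer(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

#' Homology-based miRNA discovery over a set of known matures
#'
#' Deduplicates the known matures, aligns each against the references at the
#' identity threshold, excises candidates with bilateral flanks, folds them
#' and applies the six hairpin criteria. One catalog entry is emitted per
#' distinct precursor locus/mature pair that passes.
#'
#' @param known_matures known mature miRNAs (named character vector or
#'   `read_sequences()` frame, miRBase-style ids).
#' @param references reference contigs.
#' @param min_identity homology identity threshold (default 0.90).
#' @param flank flanking length for precursor excision (default 60).
#' @param model [energy_model()].
#' @return catalog data frame (same columns as [discover_from_reads()]).
#' @export
discover_homology <- function(known_matures, references, min_identity = 0.90,
                              flank = 60, model = energy_model()) {
  uniq <- dedup_matures(known_matures)
  refs <- .as_named_seqs(references)
  entries <- list()
  seen <- character(0)
  for (qi in seq_len(nrow(uniq))) {
    hitset <- align_mirna(uniq$sequence[qi], refs, min_identity = min_identity,
                          query_id = uniq$name[qi])
    for (hi in seq_len(nrow(hitset))) {
      hit <- hitset[hi, ]
      cand <- extract_candidate(refs[hit$reference_id], hit, flank = flank)
      fold <- fold_hairpin(cand$sequence, model)
      core <- extract_hairpin_core(cand$sequence, fold$structure, model = model)
      if (is.null(core) ||
          cand$mature_span[1] < core$span[1] ||
          cand$mature_span[2] > core$span[2]) next
      mspan <- cand$mature_span - core$span[1] + 1L
      ok <- tryCatch(
        check_hairpin_criteria(core$sequence, mspan, structure = core$structure,
                               dG = core$dG, model = model)$overall,
        error = function(e) FALSE)
      if (!ok) next
      # core span in plus-strand reference coordinates
      if (cand$location$strand == "+") {
        pre <- c(cand$location$start + core$span[1] - 1L,
                 cand$location$start + core$span[2] - 1L)
      } else {
        pre <- c(cand$location$end - core$span[2] + 1L,
                 cand$location$end - core$span[1] + 1L)
      }
      key <- sprintf("%s:%d-%d:%s", cand$location$reference_id, pre[1], pre[2],
                     cand$location$strand)
      if (key %in% seen) next
      seen <- c(seen, key)
      mature <- substring(core$sequence, mspan[1], mspan[2])
      entries[[length(entries) + 1]] <- data.frame(
        name = uniq$name[qi], mature_sequence = mature,
        precursor_id = key, precursor_sequence = core$sequence,
        structure = core$structure, dG = core$dG,
        reference_id = cand$location$reference_id,
        start = pre[1], end = pre[2],
        strand = cand$location$strand,
        mature_start = mspan[1], mature_end = mspan[2],
        star_sequence = NA_character_, expression_count = 0L,
        provenance = "homology", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(entries)) do.call(rbind, entries) else .empty_catalog()
  # collapse opposite-strand echoes (the mature also matches the other arm
  # of its own hairpin, reverse-complemented)
  if (nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    for (j in 2:nrow(out)) {
      for (i in seq_len(j - 1)) {
        if (!keep[i] || !keep[j]) next
        if (out$reference_id[i] == out$reference_id[j] &&
            out$start[i] <= out$end[j] && out$end[i] >= out$start[j] &&
            out$mature_sequence[i] == out$mature_sequence[j]) {
          keep[j] <- FALSE
        }
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Merge the homology and sequencing catalogs
#'
#' Entries are merged when their mature sequences are identical, or when one
#' mature is a subsequence of the other and both precursors occupy the same
#' locus (same reference, same strand, overlapping spans). Merged entries
#' carry provenance `"both"`. A miRNA is `conserved` when it was found by
#' homology or its mature is homologous (identity >= `min_identity`) to a
#' known miRNA; otherwise it is `specific`. Conflicting assignments at one
#' locus (overlapping precursors, incompatible matures) are kept separate
#' and flagged for review.
#'
#' @param homology_catalog,srna_catalog catalog data frames.
#' @param known_matures optional known mature set used for the conservation
#'   call on sequencing-only entries.
#' @param min_identity identity threshold for the conservation call.
#' @return list with `catalog` (plus `conservation` and `review` columns)
#'   and `summary` (named counts: total, conserved, specific).
#' @export
merge_catalogs <- function(homology_catalog, srna_catalog, known_matures = NULL,
                           min_identity = 0.90) {
  hc <- homology_catalog
  sc <- srna_catalog
  hc$review <- rep(FALSE, nrow(hc))
  sc$review <- rep(FALSE, nrow(sc))
  if (nrow(hc)) hc$provenance <- "homology"
  if (nrow(sc)) sc$provenance <- "srna"
  merged <- hc
  for (i in seq_len(nrow(sc))) {
    row <- sc[i, , drop = FALSE][, names(merged)]
    same_seq <- which(merged$mature_sequence == row$mature_sequence)
    if (length(same_seq)) {
      merged$provenance[same_seq[1]] <- "both"
      merged$expression_count[same_seq[1]] <-
        merged$expression_count[same_seq[1]] + row$expression_count
      next
    }
    same_locus <- which(merged$reference_id == row$reference_id &
                          merged$strand == row$strand &
                          merged$start <= row$end & merged$end >= row$start)
    if (length(same_locus)) {
      j <- same_locus[1]
      sub <- grepl(row$mature_sequence, merged$mature_sequence[j], fixed = TRUE) ||
        grepl(merged$mature_sequence[j], row$mature_sequence, fixed = TRUE)
      if (sub) {
        merged$provenance[j] <- "both"
        merged$expression_count[j] <- merged$expression_count[j] + row$expression_count
      } else {
        # conflicting mature at one locus: keep both, flag for manual review
        merged <- rbind(merged, row)
        merged$review[nrow(merged)] <- TRUE
        merged$review[j] <- TRUE
      }
      next
    }
    merged <- rbind(merged, row)
  }
  if (nrow(merged) == 0) {
    merged$conservation <- character(0)
    return(list(catalog = merged,
                summary = c(total = 0L, conserved = 0L, specific = 0L)))
  }
  known <- if (!is.null(known_matures)) .as_named_seqs(known_matures) else character(0)
  merged$conservation <- vapply(seq_len(nrow(merged)), function(i) {
    if (merged$provenance[i] %in% c("homology", "both")) return("conserved")
    if (length(known)) {
      for (k in known) {
        if (.pairwise_identity(merged$mature_sequence[i], k) >= min_identity - 1e-9) {
          return("conserved")
        }
      }
    }
    "specific"
  }, character(1))
  list(catalog = merged,
       summary = c(total = nrow(merged),
                   conserved = sum(merged$conservation == "conserved"),
                   specific = sum(merged$conservation == "specific")))
}

#' Detect isomiRs of cataloged miRNAs
#'
#' Reads that align exactly to a precursor, overlap the mature span with
#' identical internal (templated) sequence, and whose 5'/3' ends differ from
#' the mature ends by at most 3 nt, are isomiRs of that miRNA. The
#' reference-identical read itself is not an isomiR.
#'
#' @param reads data frame with `sequence` and `count`.
#' @param catalog catalog data frame with precursor sequences and mature
#'   spans.
#' @param max_shift maximum 5'/3' end shift (default 3).
#' @return data frame: `name`, `sequence`, `start`, `end`, `shift5`,
#'   `shift3`, `count`.
#' @export
detect_isomiRs <- function(reads, catalog, max_shift = 3) {
  rows <- list()
  for (ci in seq_len(nrow(catalog))) {
    pre <- catalog$precursor_sequence[ci]
    ms <- catalog$mature_start[ci]
    me <- catalog$mature_end[ci]
    for (ri in seq_len(nrow(reads))) {
      s <- reads$sequence[ri]
      p <- regexpr(s, pre, fixed = TRUE)
      if (p < 0) next
      st <- as.integer(p); en <- st + nchar(s) - 1L
      if (st == ms && en == me) next       # the mature itself
      if (en < ms || st > me) next         # no overlap with the mature span
      if (abs(st - ms) > max_shift || abs(en - me) > max_shift) next
      rows[[length(rows) + 1]] <- data.frame(
        name = catalog$name[ci], sequence = s, start = st, end = en,
        shift5 = st - ms, shift3 = en - me, count = reads$count[ri],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(name = character(0), sequence = character(0), start = integer(0),
               end = integer(0), shift5 = integer(0), shift3 = integer(0),
               count = integer(0))
  }
}

#' Detect miRNA-offset RNAs (moRNAs) on a precursor
#'
#' Reads matching the precursor at 100% identity, mapping entirely outside
#' the mature and star spans, with their start (or end) within `max_gap` nt
#' of a mature/star boundary, are moRNA candidates.
#'
#' @param reads data frame with `sequence` and `count`.
#' @param precursor precursor sequence (RNA string).
#' @param mature_span 1-based inclusive mature span.
#' @param star_span optional star span.
#' @param max_gap maximum gap to a boundary (default 2).
#' @return data frame: `sequence`, `start`, `end`, `adjacent_to`
#'   (`mature5`/`mature3`/`star5`/`star3`), `count`.
#' @export
detect_moRNAs <- function(reads, precursor, mature_span, star_span = NULL,
                          max_gap = 2) {
  precursor <- as_rna(precursor)
  spans <- list(mature = as.integer(mature_span))
  if (!is.null(star_span)) spans$star <- as.integer(star_span)
  rows <- list()
  for (ri in seq_len(nrow(reads))) {
    s <- reads$sequence[ri]
    p <- regexpr(s, precursor, fixed = TRUE)
    if (p < 0) next
    st <- as.integer(p); en <- st + nchar(s) - 1L
    overlaps <- any(vapply(spans, function(sp) st <= sp[2] && en >= sp[1],
                           logical(1)))
    if (overlaps) next
    adj <- NA_character_
    for (nm in names(spans)) {
      sp <- spans[[nm]]
      if (en < sp[1] && sp[1] - en - 1L <= max_gap) adj <- paste0(nm, "5")
      if (st > sp[2] && st - sp[2] - 1L <= max_gap) adj <- paste0(nm, "3")
    }
    if (is.na(adj)) next
    rows[[length(rows) + 1]] <- data.frame(sequence = s, start = st, end = en,
                                           adjacent_to = adj,
                                           count = reads$count[ri],
                                           stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(sequence = character(0), start = integer(0), end = integer(0),
               adjacent_to = character(0), count = integer(0))
  }
}
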
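#' Read sequences from FASTA or FASTQ
#'
#' Records are returned in file order, with sequences normalised to the RNA
#' alphabet (T mapped to U) and the original alphabet remembered so that
#' [write_sequences()] can round-trip the file. FASTQ quality strings are
#' decoded as Phred+33 scores.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`; guessed from the extension when
#'   missing.
#' @return data frame with columns `id`, `sequence` (RNA alphabet),
#'   `quality` (list column of integer Phred vectors, `NULL` for FASTA),
#'   `description` and `alphabet` (`"DNA"` or `"RNA"` as found on disk).
#'   An empty file yields a zero-row data frame.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    empty <- data.frame(id = character(0), sequence = character(0),
                        description = character(0), alphabet = character(0))
    empty$quality <- list()
    return(empty)
  }
  if (format == "fastq") {
    nl <- length(readLines(path, warn = FALSE))
    if (nl %% 4 != 0) {
      stop(sprintf("malformed fastq file '%s': truncated record near line %d",
                   path, nl), call. = FALSE)
    }
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format, with.qualities = (format == "fastq")),
    error = function(e) stop(sprintf("malformed %s file '%s': %s", format, path,
                                     conditionMessage(e)), call. = FALSE))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  raw <- as.character(set)
  if (anyDuplicated(ids)) {
    warning("duplicate sequence ids kept in file order: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  alphabet <- ifelse(grepl("T", toupper(raw)) | !grepl("U", toupper(raw)), "DNA", "RNA")
  out <- data.frame(id = ids, sequence = as_rna(raw), description = desc,
                    alphabet = alphabet, row.names = NULL)
  out$quality <- if (format == "fastq") {
    lapply(as.character(S4Vectors::mcols(set)$qualities),
           function(q) utf8ToInt(q) - 33L)
  } else {
    rep(list(NULL), nrow(out))
  }
  if (any(nchar(out$sequence) == 0)) {
    stop("empty sequence record in ", path, call. = FALSE)
  }
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' Writes records back in their original alphabet (column `alphabet`), so a
#' read-then-write round trip is the identity on id, sequence and quality.
#'
#' @param records data frame as returned by [read_sequences()]; `quality`
#'   and `alphabet` columns are optional (defaults: no qualities, DNA out
#'   for FASTA input that was DNA).
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  alpha <- if ("alphabet" %in% names(records)) records$alphabet else rep("RNA", nrow(records))
  seqs <- ifelse(alpha == "DNA", as_dna(records$sequence), records$sequence)
  hdr <- ifelse(!is.null(records$description) & nzchar(records$description),
                paste(records$id, records$description), records$id)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", hdr, "\n", seqs), con, sep = "\n")
  } else {
    qual <- vapply(seq_len(nrow(records)), function(i) {
      q <- records$quality[[i]]
      if (is.null(q)) q <- rep(40L, nchar(seqs[i]))
      intToUtf8(q + 33L)
    }, character(1))
    writeLines(paste0("@", hdr, "\n", seqs, "\n+\n", qual), con, sep = "\n")
  }
  invisible(path)
}

#' Read a SNP table (TSV)
#'
#' Expected columns: `reference_id`, `position` (1-based), `ref_allele`,
#' `alt_allele`. Alleles are normalised to the RNA alphabet. Rows with a
#' degenerate SNP (`ref == alt`), multi-nucleotide alleles or non-positive
#' positions are rejected with an error naming the row.
#'
#' @param path TSV file.
#' @return data frame of validated SNP records.
#' @export
read_snp_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reference_id", "position", "ref_allele", "alt_allele")
  if (!all(need %in% names(tab))) {
    stop("SNP table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tab$ref_allele <- as_rna(tab$ref_allele)
  tab$alt_allele <- as_rna(tab$alt_allele)
  validate_snps(tab)
}

#' @rdname read_snp_table
#' @param tab data frame of SNP records to validate.
#' @export
validate_snps <- function(tab) {
  for (i in seq_len(nrow(tab))) {
    if (tab$position[i] < 1) {
      stop(sprintf("row %d: position %s violates the 1-based coordinate convention",
                   i, tab$position[i]), call. = FALSE)
    }
    if (nchar(tab$ref_allele[i]) != 1 || nchar(tab$alt_allele[i]) != 1 ||
        !tab$ref_allele[i] %in% RNA_BASES || !tab$alt_allele[i] %in% RNA_BASES) {
      stop(sprintf("row %d: alleles must be single nucleotides", i), call. = FALSE)
    }
    if (tab$ref_allele[i] == tab$alt_allele[i]) {
      stop(sprintf("row %d: degenerate SNP (ref == alt == %s)", i, tab$ref_allele[i]),
           call. = FALSE)
    }
  }
  tab[, c("reference_id", "position", "ref_allele", "alt_allele")]
}

#' Read SNPs from a minimal VCF
#'
#' Maps CHROM/POS/REF/ALT of a plain-text VCF onto the same record type as
#' [read_snp_table()]; only single-nucleotide biallelic records are kept.
#'
#' @param path uncompressed VCF file.
#' @return data frame of validated SNP records.
#' @export
read_vcf_snps <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  tab <- data.frame(reference_id = fix$CHROM,
                    position = as.integer(fix$POS),
                    ref_allele = as_rna(fix$REF),
                    alt_allele = as_rna(fix$ALT),
                    stringsAsFactors = FALSE)
  keep <- nchar(tab$ref_allele) == 1 & nchar(tab$alt_allele) == 1
  validate_snps(tab[keep, , drop = FALSE])
}

#' Write annotations as GFF3 or TSV
#'
#' Annotations carry 1-based inclusive coordinates and a feature type
#' (`pre_miRNA`, `miRNA`, `miRNA_star`, `cluster`, `target_site`); GFF3
#' output is strand-aware and parseable by standard GFF readers. A `parent`
#' column nests members under their cluster feature.
#'
#' @param annotations data frame with columns `reference_id`, `start`,
#'   `end`, `strand`, `type`, `id`, and optionally `parent` and `score`.
#' @param path output file.
#' @param format `"gff3"` or `"tsv"`.
#' @param reference_lengths optional named vector; when given, locations
#'   outside their reference are refused.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotations, path, format = c("gff3", "tsv"),
                             reference_lengths = NULL) {
  format <- match.arg(format)
  ann <- annotations
  if (nrow(ann) > 0) {
    stopifnot(all(ann$start >= 1), all(ann$start <= ann$end),
              all(ann$strand %in% c("+", "-")))
    if (!is.null(reference_lengths)) {
      len <- reference_lengths[ann$reference_id]
      if (any(is.na(len)) || any(ann$end > len)) {
        stop("annotation location outside its reference length", call. = FALSE)
      }
    }
  }
  if (format == "tsv") {
    utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ann) > 0) {
    attrs <- paste0("ID=", ann$id)
    if ("parent" %in% names(ann)) {
      has_parent <- !is.na(ann$parent) & nzchar(ann$parent)
      attrs[has_parent] <- paste0(attrs[has_parent], ";Parent=", ann$parent[has_parent])
    }
    score <- if ("score" %in% names(ann)) ifelse(is.na(ann$score), ".", ann$score) else "."
    writeLines(paste(ann$reference_id, "mirpipe", ann$type, ann$start, ann$end,
                     score, ann$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read back a GFF3 annotation file written by [write_annotation()]
#'
#' @param path GFF3 file.
#' @return annotation data frame (1-based inclusive coordinates).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(reference_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0), id = character(0),
                      parent = character(0)))
  }
  f <- do.call(rbind, strsplit(lines, "\t"))
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, character(1))
  }
  data.frame(reference_id = f[, 1], start = as.integer(f[, 4]),
             end = as.integer(f[, 5]), strand = f[, 7], type = f[, 3],
             id = attr_get(f[, 9], "ID"), parent = attr_get(f[, 9], "Parent"),
             stringsAsFactors = FALSE)
}

#' Format a ratio as a percentage string with two decimals
#'
#' Round-half-up at two decimal places, matching hand-formatted sequencing
#' summaries (e.g. 7,327,921 / 11,665,437 prints as "62.82").
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return character string, e.g. `"62.82"`.
#' @export
format_percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("undefined ratio: denominator must be > 0", call. = FALSE)
  sprintf("%.2f", round_half_up(100 * numerator / denominator, 2))
}

#' Read-accounting summary
#'
#' Book-keeping for the read-cleaning and contaminant-annotation stages,
#' with the conservation identity `remaining = cleaned - sum(contaminants)`
#' enforced, and the percentage strings the summary figure prints.
#'
#' @param raw_count raw read count.
#' @param cleaned_count reads surviving cleaning (`<= raw_count`).
#' @param contaminants named integer vector of per-class counts (e.g.
#'   `c(rRNA = ..., tRNA = ..., snRNA = ..., repeat. = ...)`).
#' @return object of class `read_accounting`.
#' @export
read_accounting <- function(raw_count, cleaned_count, contaminants = integer(0)) {
  stopifnot(cleaned_count <= raw_count, all(contaminants >= 0))
  remaining <- cleaned_count - sum(contaminants)
  stopifnot(remaining >= 0)
  structure(list(
    raw_count = raw_count,
    cleaned_count = cleaned_count,
    contaminants = contaminants,
    remaining_count = remaining,
    pct_cleaned = if (raw_count > 0) format_percentage(cleaned_count, raw_count)
                  else NA_character_,
    pct_contaminants = if (length(contaminants) && cleaned_count > 0) {
      vapply(contaminants, format_percentage, character(1), denominator = cleaned_count)
    } else character(0),
    pct_remaining = if (cleaned_count > 0) format_percentage(remaining, cleaned_count)
                    else NA_character_
  ), class = "read_accounting")
}

#' @export
print.read_accounting <- function(x, ...) {
  cat(sprintf("raw reads:      %s\n", format(x$raw_count, big.mark = ",")))
  cat(sprintf("cleaned reads:  %s (%s%%)\n", format(x$cleaned_count, big.mark = ","),
              x$pct_cleaned))
  for (k in names(x$contaminants)) {
    cat(sprintf("  %-8s %s (%s%% of clean)\n", paste0(k, ":"),
                format(x$contaminants[[k]], big.mark = ","), x$pct_contaminants[[k]]))
  }
  cat(sprintf("remaining:      %s (%s%% of clean)\n",
              format(x$remaining_count, big.mark = ","), x$pct_remaining))
  invisible(x)
}

#' Average number of target mRNAs per miRNA, as reported
#'
#' @param n_mrnas number of distinct target mRNAs.
#' @param n_mirnas number of miRNAs with at least one target.
#' @param digits decimals in the reported average (round half-up).
#' @return numeric average (e.g. 206 mRNAs over 83 miRNAs reports 2.5).
#' @export
targets_per_mirna <- function(n_mrnas, n_mirnas, digits = 1) {
  if (n_mirnas <= 0) stop("n_mirnas must be positive", call. = FALSE)
  round_half_up(n_mrnas / n_mirnas, digits)
}
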
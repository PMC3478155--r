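#' Construct a synthetic miRNA precursor hairpin
#'
#' Builds a 5' arm (GC-biased so clean stems fold unambiguously), a loop,
#' and the complementary 3' arm, then plants the requested number of
#' mismatches (paired bases broken to non-pairing bases) and single-nt
#' bulges at random admissible interior positions. On a clean construct
#' (no mismatches, no bulges, stem >= 8) the planted dot-bracket is the
#' minimum-energy single-hairpin structure.
#'
#' @param stem_len stem length in pairs (>= 5).
#' @param loop_len loop length (>= 3).
#' @param n_mismatches broken pairs to plant.
#' @param n_bulges single-nt bulges to insert in the 3' arm.
#' @param seed integer seed; the same seed reproduces the construct
#'   byte-for-byte.
#' @param gc GC bias of the arm (default 0.6).
#' @return list with `sequence`, `structure` (planted dot-bracket),
#'   `mature_span` (first min(22, stem_len) arm positions) and `length`.
#' @export
make_hairpin <- function(stem_len = 30, loop_len = 8, n_mismatches = 0,
                         n_bulges = 0, seed = 1, gc = 0.6) {
  if (loop_len < 3) stop("loop_len must be >= 3", call. = FALSE)
  if (stem_len < 5) stop("stem_len must be >= 5", call. = FALSE)
  admissible <- 3:(stem_len - 2)  # keep the closing stacks intact
  if (n_mismatches + n_bulges > length(admissible)) {
    stop("too many mismatches/bulges for this stem length", call. = FALSE)
  }
  .with_seed(seed, {
    arm5 <- .seq_chars(random_rna(stem_len, gc = gc))
    # loop drawn from {A, C} only: no two loop bases can pair, so a clean
    # stem cannot be extended into the loop by the fold engine
    loop <- sample(c("A", "C"), loop_len, replace = TRUE)
    arm3 <- .seq_chars(revcomp_rna(paste(arm5, collapse = "")))
    open5 <- rep("(", stem_len)
    close3 <- rep(")", stem_len)
    picks <- if (n_mismatches + n_bulges > 0) {
      sample(admissible, n_mismatches + n_bulges)
    } else {
      integer(0)
    }
    mm_pos <- picks[seq_len(n_mismatches)]
    bulge_pos <- setdiff(picks, mm_pos)
    for (i in mm_pos) {
      j <- stem_len - i + 1L  # partner index in arm3
      bad <- RNA_BASES[is.na(pair_type(rep(arm5[i], 4), RNA_BASES))]
      arm3[j] <- sample(bad, 1)
      open5[i] <- "."
      close3[j] <- "."
    }
    # single-nt bulges: insert an extra base after the partner position
    arm3_parts <- as.list(arm3)
    close_parts <- as.list(close3)
    for (i in sort(bulge_pos, decreasing = TRUE)) {
      j <- stem_len - i + 1L
      arm3_parts[[j]] <- c(arm3_parts[[j]], sample(RNA_BASES, 1))
      close_parts[[j]] <- c(close_parts[[j]], ".")
    }
    seqn <- paste(c(arm5, loop, unlist(arm3_parts)), collapse = "")
    struct <- paste(c(open5, rep(".", loop_len), unlist(close_parts)),
                    collapse = "")
    list(sequence = seqn, structure = struct,
         mature_span = c(1L, min(22L, stem_len)), length = nchar(seqn))
  })
}

#' Plant precursors in random-background reference contigs
#'
#' Generates background contigs (i.i.d. bases, GC knob) and embeds
#' synthetic precursors at recorded 1-based coordinates. Clustered plants
#' put `cluster_size` precursors on one contig separated by `cluster_gap`
#' nt; minus-strand plants embed the reverse complement.
#'
#' @param n_precursors number of singleton precursors (one per contig).
#' @param contig_length background contig length.
#' @param seed integer seed.
#' @param n_clusters number of clustered contigs to add.
#' @param cluster_size precursors per clustered contig.
#' @param cluster_gap gap between clustered precursors (nt).
#' @param minus_strand logical vector (recycled) marking minus-strand
#'   plants among the singletons.
#' @param stem_len,loop_len,gc passed to [make_hairpin()].
#' @return list with `references` (named character vector of contigs) and
#'   `truth` (data frame: `name`, `reference_id`, `start`, `end`, `strand`,
#'   `precursor`, `structure`, `mature`, `mature_start`, `mature_end` --
#'   precursor coordinates 1-based inclusive on the plus strand).
#' @export
make_reference_with_mirnas <- function(n_precursors = 10, contig_length = 600,
                                       seed = 1, n_clusters = 0,
                                       cluster_size = 2, cluster_gap = 50,
                                       minus_strand = FALSE,
                                       stem_len = 30, loop_len = 8, gc = 0.5) {
  minus_strand <- rep_len(minus_strand, n_precursors)
  refs <- character(0)
  truth <- list()
  k <- 0
  add_plant <- function(contig, name, pos, strand, hp) {
    pre <- hp$sequence
    insert <- if (strand == "-") revcomp_rna(pre) else pre
    end <- pos + nchar(pre) - 1L
    if (end > nchar(contig)) stop("contig too short for requested plants", call. = FALSE)
    contig <- paste0(substring(contig, 1, pos - 1), insert,
                     substring(contig, end + 1))
    list(contig = contig,
         row = data.frame(name = name, start = pos, end = end, strand = strand,
                          precursor = pre, structure = hp$structure,
                          mature = substring(pre, hp$mature_span[1], hp$mature_span[2]),
                          mature_start = hp$mature_span[1],
                          mature_end = hp$mature_span[2],
                          stringsAsFactors = FALSE))
  }
  .with_seed(seed, {
    for (i in seq_len(n_precursors)) {
      k <- k + 1
      hp <- make_hairpin(stem_len, loop_len, seed = .sub_seed(seed, k),
                         gc = max(gc, 0.55))
      contig <- random_rna(contig_length, gc = gc)
      hi <- contig_length - hp$length - 60L
      if (hi < 60L) stop("contig too short for requested plants", call. = FALSE)
      pos <- sample(seq(60L, hi), 1)
      strand <- if (minus_strand[i]) "-" else "+"
      res <- add_plant(contig, sprintf("mir-%03d", k), pos, strand, hp)
      cid <- sprintf("contig%03d", length(refs) + 1L)
      refs[cid] <- res$contig
      res$row$reference_id <- cid
      truth[[length(truth) + 1]] <- res$row
    }
    for (ci in seq_len(n_clusters)) {
      needed <- cluster_size * (2 * stem_len + loop_len + 10) +
        (cluster_size - 1) * cluster_gap + 200
      contig <- random_rna(max(contig_length, needed), gc = gc)
      pos <- 80L
      cid <- sprintf("contig%03d", length(refs) + 1L)
      rows <- list()
      for (m in seq_len(cluster_size)) {
        k <- k + 1
        hp <- make_hairpin(stem_len, loop_len, seed = .sub_seed(seed, k),
                           gc = max(gc, 0.55))
        res <- add_plant(contig, sprintf("mir-%03d", k), pos, "+", hp)
        contig <- res$contig
        res$row$reference_id <- cid
        rows[[m]] <- res$row
        pos <- pos + hp$length + cluster_gap
      }
      refs[cid] <- contig
      truth <- c(truth, rows)
    }
  })
  truth <- do.call(rbind, truth)
  cols <- c("name", "reference_id", "start", "end", "strand", "precursor",
            "structure", "mature", "mature_start", "mature_end")
  list(references = refs, truth = truth[, cols])
}

#' Mutate a mature miRNA to a target sequence identity
#'
#' Plants `ceiling((1 - target_identity) * length)` substitutions at
#' distinct positions, each to a different base, and records the realised
#' identity.
#'
#' @param mature mature sequence.
#' @param target_identity in (0, 1].
#' @param seed integer seed.
#' @return list with `sequence`, `identity` (realised), `positions`.
#' @export
mutate_homolog <- function(mature, target_identity, seed = 1) {
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must be in (0, 1]", call. = FALSE)
  }
  mature <- as_rna(mature)
  len <- nchar(mature)
  k <- ceiling((1 - target_identity) * len - 1e-9)
  if (k > len) stop("more substitutions than positions", call. = FALSE)
  if (k == 0) return(list(sequence = mature, identity = 1, positions = integer(0)))
  .with_seed(seed, {
    pos <- sort(sample(len, k))
    ch <- .seq_chars(mature)
    for (p in pos) ch[p] <- sample(setdiff(RNA_BASES, ch[p]), 1)
    list(sequence = paste(ch, collapse = ""), identity = (len - k) / len,
         positions = pos)
  })
}

#' Simulate a small-RNA sequencing library from planted precursors
#'
#' Draws mature/star/isomiR/moRNA reads from each precursor, appends the 3'
#' adapter and truncates to the instrument read length, injects base errors
#' at the configured rate, and mixes in contaminant fragments, poly(A)
#' junk, too-short inserts, 5'-adapter carryover and low-quality reads.
#' Every emitted read has a ground-truth row.
#'
#' @param truth precursor truth table from [make_reference_with_mirnas()]
#'   (columns `name`, `precursor`, `mature_start`, `mature_end` used).
#' @param depth mature reads per precursor.
#' @param star_depth star-arm reads per precursor.
#' @param isomir_per templated isomiR variants per precursor (each 1 read).
#' @param mor_per moRNA reads per precursor.
#' @param n_contaminant,n_polyA,n_short,n_adapter5,n_lowq junk read counts.
#' @param contaminants named list of contaminant sequence sets (classes
#'   rRNA/tRNA/snRNA/repeat), required when `n_contaminant > 0`; junk
#'   contaminant reads cycle over the classes.
#' @param adapter_3p,adapter_5p adapter sequences.
#' @param read_length instrument read length (default 36).
#' @param error_rate per-base substitution probability in the sRNA insert.
#' @param seed integer seed; identical seeds give byte-identical libraries.
#' @return list with `reads` (data frame ready for [write_sequences()]:
#'   `id`, `sequence`, `quality`, `description`, `alphabet`) and `truth`
#'   (per-read data frame: `id`, `class`, `precursor`).
#' @export
simulate_sreads <- function(truth, depth = 10, star_depth = 2, isomir_per = 0,
                            mor_per = 0, n_contaminant = 0, n_polyA = 0,
                            n_short = 0, n_adapter5 = 0, n_lowq = 0,
                            contaminants = NULL,
                            adapter_3p = "UCGUAUGCCGUCUUCUGCUUG",
                            adapter_5p = "GUUCAGAGUUCUACAGUCCGACGAUC",
                            read_length = 36, error_rate = 0, seed = 1) {
  adapter_3p <- as_rna(adapter_3p)
  adapter_5p <- as_rna(adapter_5p)
  reads <- list()
  rtruth <- list()
  emit <- function(insert, class, precursor = NA_character_, q = 40L) {
    full <- paste0(insert, adapter_3p)
    seqn <- substring(full, 1, read_length)
    id <- sprintf("read%05d", length(reads) + 1L)
    reads[[length(reads) + 1]] <<- data.frame(
      id = id, sequence = seqn, description = "", alphabet = "DNA",
      stringsAsFactors = FALSE)
    attr(reads[[length(reads)]], "qual") <<- rep(q, nchar(seqn))
    rtruth[[length(rtruth) + 1]] <<- data.frame(
      id = id, class = class, precursor = precursor, stringsAsFactors = FALSE)
  }
  corrupt <- function(s, rate) {
    if (rate <= 0) return(s)
    ch <- .seq_chars(s)
    flip <- stats::runif(length(ch)) < rate
    for (i in which(flip)) ch[i] <- sample(setdiff(RNA_BASES, ch[i]), 1)
    paste(ch, collapse = "")
  }
  .with_seed(seed, {
    for (pi in seq_len(nrow(truth))) {
      pre <- truth$precursor[pi]
      nm <- truth$name[pi]
      ms <- truth$mature_start[pi]; me <- truth$mature_end[pi]
      n <- nchar(pre)
      mature <- substring(pre, ms, me)
      for (d in seq_len(depth)) emit(corrupt(mature, error_rate), "mature", nm)
      star_span <- c(n + 1L - me, n + 1L - ms)
      if (star_span[1] > me) {  # star arm distinct from the mature arm
        star <- substring(pre, star_span[1], star_span[2])
        for (d in seq_len(star_depth)) emit(corrupt(star, error_rate), "star", nm)
      }
      if (isomir_per > 0) {
        for (v in seq_len(isomir_per)) {
          s3 <- sample(c(-2L, -1L, 1L, 2L), 1)
          en <- min(me + s3, n)
          emit(substring(pre, ms, en), "isomir", nm)
        }
      }
      if (mor_per > 0 && me + 18 <= n + 1L - me - 1L) {
        for (v in seq_len(mor_per)) {
          emit(substring(pre, me + 1L, me + 18L), "mor", nm)
        }
      }
    }
    if (n_contaminant > 0) {
      stopifnot(!is.null(contaminants), length(contaminants) > 0)
      classes <- names(contaminants)
      for (ci in seq_len(n_contaminant)) {
        cls <- classes[((ci - 1) %% length(classes)) + 1]
        pool <- .as_named_seqs(contaminants[[cls]])
        src <- pool[[sample(length(pool), 1)]]
        p <- sample(max(1, nchar(src) - 21), 1)
        emit(substring(src, p, p + 21), paste0("contaminant:", cls))
      }
    }
    for (ci in seq_len(n_polyA)) emit(strrep("A", 26), "polyA")
    for (ci in seq_len(n_short)) emit(random_rna(sample(8:15, 1)), "short")
    for (ci in seq_len(n_adapter5)) {
      emit(paste0(adapter_5p, random_rna(10)), "adapter5")
    }
    for (ci in seq_len(n_lowq)) emit(random_rna(22), "lowq", q = 5L)
  })
  reads_df <- do.call(rbind, reads)
  reads_df$quality <- lapply(reads, attr, "qual")
  list(reads = reads_df, truth = do.call(rbind, rtruth))
}

# Site sequence (on the UTR, 5'->3') for a canonical seed-type site.
.site_sequence <- function(mirna, site_type) {
  core6 <- revcomp_rna(substring(mirna, 2, 7))
  m8c <- .wc_complement(substring(mirna, 8, 8))
  switch(site_type,
         "6mer" = core6,
         "7mer-m8" = paste0(m8c, core6),
         "7mer-A1" = paste0(core6, "A"),
         "8mer" = paste0(m8c, core6, "A"),
         stop("unknown site type: ", site_type, call. = FALSE))
}

#' Build a synthetic 3'UTR with a planted (or plantable) target site
#'
#' Embeds the exact seed-complement site of the requested type in random
#' background screened to be free of incidental sites for the miRNA under
#' both predictors. `snp_plan = "destroy"` leaves the canonical site in the
#' wild-type UTR and returns a SNP that mutates a seed-pairing position so
#' that neither predictor fires afterwards; `snp_plan = "create"` plants a
#' near-site one substitution away from canonical and returns the SNP that
#' restores it.
#'
#' @param mirna mature miRNA sequence (a GC-balanced seed keeps the planted
#'   duplex below the energy predictor's cutoff).
#' @param site_type one of `8mer`, `7mer-m8`, `7mer-A1`, `6mer`.
#' @param snp_plan `NULL`, `"destroy"` or `"create"`.
#' @param utr_length background length (default 200).
#' @param seed integer seed.
#' @param mrna_id identifier for the UTR record.
#' @param ddG_cutoff energy cutoff used during fixture verification.
#' @param max_retries bounded retries for the incidental-site screen.
#' @return list with `utr` (list `id`, `sequence`), `snp` (one-row data
#'   frame or `NULL`) and `truth` (list `site_start`, `site_end`,
#'   `site_type`, `plan`).
#' @export
make_utr_with_sites <- function(mirna, site_type = "8mer", snp_plan = NULL,
                                utr_length = 200, seed = 1, mrna_id = "utr1",
                                ddG_cutoff = -9, max_retries = 50) {
  mirna <- as_rna(mirna)
  site <- .site_sequence(mirna, site_type)
  slen <- nchar(site)
  for (attempt in seq_len(max_retries)) {
    res <- .with_seed(.sub_seed(seed, attempt), {
      bg <- random_rna(utr_length)
      pos <- floor(utr_length / 2)
      wild <- paste0(substring(bg, 1, pos - 1), site,
                     substring(bg, pos + slen, utr_length))
      span <- c(pos, pos + slen - 1L)
      # screen: the planted site is the only seed site, at exactly the
      # requested type and span (chance flanking bases can upgrade a type),
      # and the energy predictor fires nowhere outside the planted window
      a <- predict_seedtype(mirna, wild)
      ok_a <- nrow(a) == 1 && a$site_type == site_type &&
        a$start == span[1] && a$end == span[2]
      b <- predict_energy(mirna, wild, ddG_cutoff)
      ok_b <- nrow(b) == 0 ||
        all(b$start <= span[2] + 7 & b$end >= span[1] - 7)
      if (!ok_a || !ok_b) return(NULL)
      if (is.null(snp_plan)) {
        return(list(utr = list(id = mrna_id, sequence = wild), snp = NULL,
                    truth = list(site_start = span[1], site_end = span[2],
                                 site_type = site_type, plan = "none")))
      }
      # pick a core seed-pairing position to toggle (middle of the 6mer core)
      core_off <- if (site_type %in% c("7mer-m8", "8mer")) 1L else 0L
      target_pos <- span[1] + core_off + 2L
      canonical <- substring(wild, target_pos, target_pos)
      mir_pos <- 7L - (target_pos - span[1] - core_off)  # miRNA base paired here
      breakers <- RNA_BASES[vapply(RNA_BASES, function(b) {
        b != canonical && is.na(pair_type(b, substring(mirna, mir_pos, mir_pos)))
      }, logical(1))]
      fires <- function(u) {
        a <- predict_seedtype(mirna, u); b <- predict_energy(mirna, u, ddG_cutoff)
        c(a = nrow(a) > 0, b = nrow(b) > 0,
          cons = nrow(consensus_targets(a, b)) > 0)
      }
      for (broken in breakers) {
        mut <- paste0(substring(wild, 1, target_pos - 1), broken,
                      substring(wild, target_pos + 1))
        fw <- fires(wild); fm <- fires(mut)
        ok <- fw[["cons"]] && !fm[["a"]] && !fm[["b"]]
        if (!ok) next
        if (snp_plan == "destroy") {
          return(list(utr = list(id = mrna_id, sequence = wild),
                      snp = data.frame(reference_id = mrna_id,
                                       position = target_pos,
                                       ref_allele = canonical,
                                       alt_allele = broken,
                                       stringsAsFactors = FALSE),
                      truth = list(site_start = span[1], site_end = span[2],
                                   site_type = site_type, plan = "destroy")))
        } else if (snp_plan == "create") {
          return(list(utr = list(id = mrna_id, sequence = mut),
                      snp = data.frame(reference_id = mrna_id,
                                       position = target_pos,
                                       ref_allele = broken,
                                       alt_allele = canonical,
                                       stringsAsFactors = FALSE),
                      truth = list(site_start = span[1], site_end = span[2],
                                   site_type = site_type, plan = "create")))
        } else {
          stop("unknown snp_plan: ", snp_plan, call. = FALSE)
        }
      }
      NULL
    })
    if (!is.null(res)) return(res)
  }
  stop("could not build an unambiguous UTR fixture after bounded retries",
       call. = FALSE)
}
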
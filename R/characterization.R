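#' Find genomic miRNA clusters
#'
#' Single-linkage chaining of precursor annotations on the same reference
#' and strand whose gaps are at most `max_gap` nt. The cluster span runs
#' from the smallest member start to the largest member end (1-based
#' inclusive); singletons are excluded.
#'
#' @param annotations data frame with `id` (or `name`), `reference_id`,
#'   `start`, `end`, `strand`.
#' @param max_gap maximum allowed gap between chained members, in nt
#'   (default 10000; all published carp clusters are far tighter).
#' @return data frame with one row per cluster: `cluster`, `members`
#'   (comma-separated ids), `n_members`, `reference_id`, `strand`, `start`,
#'   `end`, `length` (`end - start + 1`).
#' @export
find_clusters <- function(annotations, max_gap = 10000) {
  ann <- annotations
  if (!"id" %in% names(ann) && "name" %in% names(ann)) ann$id <- ann$name
  out <- list()
  for (key in unique(paste(ann$reference_id, ann$strand))) {
    sub <- ann[paste(ann$reference_id, ann$strand) == key, , drop = FALSE]
    gr <- IRanges::IRanges(sub$start, sub$end)
    red <- IRanges::reduce(gr, min.gapwidth = max_gap + 1L, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (k in seq_along(red)) {
      idx <- revmap[[k]]
      if (length(idx) < 2) next
      members <- sub[idx, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        members = paste(members$id, collapse = ","),
        n_members = length(idx),
        reference_id = members$reference_id[1], strand = members$strand[1],
        start = min(members$start), end = max(members$end),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(cluster = integer(0), members = character(0),
                      n_members = integer(0), reference_id = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$reference_id, res$start), , drop = FALSE]
  res <- cbind(cluster = seq_len(nrow(res)), res)
  res$length <- res$end - res$start + 1L
  rownames(res) <- NULL
  res
}

#' Read a species presence/absence matrix for miRNA families
#'
#' TSV with a `family` column and one column per species code, entries
#' `+`/`-` (or 1/0). Species-to-clade assignments follow the standard
#' metazoan codes; fish species are a subset of vertebrates, which are a
#' subset of deuterostomes.
#'
#' @param path TSV file.
#' @return list with `matrix` (logical, families x species) and `clades`
#'   (named list of species codes per clade).
#' @export
read_presence_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("family" %in% names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), "family"), drop = FALSE])
  mat <- m == "+" | m == "1" | m == "TRUE"
  rownames(mat) <- tab$family
  list(matrix = mat, clades = species_clades(colnames(mat)))
}

#' Clade membership of standard species codes
#'
#' @param codes species codes (e.g. `hsa`, `dre`, `dme`).
#' @return named list with members `protostome`, `deuterostome`,
#'   `vertebrate`, `fish` (each a character vector of codes present in
#'   `codes`).
#' @export
species_clades <- function(codes) {
  protostome <- c("dme", "cel")
  fish <- c("dre", "fru", "tni", "cca", "pma", "ola")
  vertebrate <- c("hsa", "mmu", "gga", "xtr", fish)
  deuterostome <- c(vertebrate, "bfl", "cin", "spu")
  list(protostome = intersect(codes, protostome),
       deuterostome = intersect(codes, deuterostome),
       vertebrate = intersect(codes, vertebrate),
       fish = intersect(codes, fish))
}

#' Assign a miRNA family to a phylogenetic conservation group
#'
#' A family is `shared` (protostome + deuterostome) when present in at least
#' one protostome and one deuterostome; `fish-only` when all its presences
#' are fish species; otherwise `vertebrate-only`. Every family present in at
#' least one species receives exactly one group.
#'
#' @param presence logical (or `+`/`-`) vector named by species code, one
#'   miRNA family row.
#' @param clades clade map as from [species_clades()]; computed from the
#'   names of `presence` when `NULL`.
#' @return one of `"protostome+deuterostome-shared"`, `"vertebrate-only"`,
#'   `"fish-only"`.
#' @export
assign_phylo_group <- function(presence, clades = NULL) {
  if (is.character(presence)) presence <- presence == "+" | presence == "1"
  if (is.null(clades)) clades <- species_clades(names(presence))
  species <- names(presence)[presence]
  if (length(species) == 0) {
    stop("family absent from every species: group undefined", call. = FALSE)
  }
  if (length(intersect(species, clades$protostome)) >= 1 &&
      length(intersect(species, clades$deuterostome)) >= 1) {
    return("protostome+deuterostome-shared")
  }
  if (all(species %in% clades$fish)) return("fish-only")
  "vertebrate-only"
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(gene) - Ct(reference gene); ddCt = dCt(sample) -
#' dCt(calibrator); relative expression = 2^-ddCt, so the calibrator sample
#' is always exactly 1. The log2 column (`log2_rel = -ddCt`) is emitted for
#' heatmaps and clustering.
#'
#' @param ct_table data frame with columns `sample`, `gene`, `ct`.
#' @param gene gene of interest (e.g. a miRNA).
#' @param reference_gene endogenous control (e.g. `U6`, `beta-actin`).
#' @param calibrator sample id used as calibrator.
#' @return data frame: `sample`, `dct`, `ddct`, `relative`, `log2_rel`.
#' @export
ddct_expression <- function(ct_table, gene, reference_gene, calibrator) {
  samples <- unique(ct_table$sample)
  get_ct <- function(s, g) {
    v <- ct_table$ct[ct_table$sample == s & ct_table$gene == g]
    if (length(v) == 0 || anyNA(v)) {
      stop(sprintf("missing Ct for gene '%s' in sample '%s'", g, s), call. = FALSE)
    }
    mean(v)
  }
  dct <- vapply(samples, function(s) get_ct(s, gene) - get_ct(s, reference_gene),
                numeric(1))
  if (!calibrator %in% samples) stop("calibrator sample not found", call. = FALSE)
  ddct <- dct - dct[[calibrator]]
  data.frame(sample = samples, dct = unname(dct), ddct = unname(ddct),
             relative = 2^-unname(ddct), log2_rel = -unname(ddct),
             row.names = NULL)
}

#' Correlate a miRNA expression profile with its target's
#'
#' Pearson correlation on the log2 series with a two-sided t-distribution
#' p-value; the pair is flagged as showing a reciprocal pattern when r < 0
#' and p <= 0.05.
#'
#' @param mirna_log2,target_log2 equal-length numeric log2 expression
#'   series, n >= 3.
#' @return list with `r`, `p`, `n`, `reciprocal`.
#' @export
mirna_target_correlation <- function(mirna_log2, target_log2) {
  if (length(mirna_log2) != length(target_log2) || length(mirna_log2) < 3) {
    stop("profiles must be equal length with n >= 3", call. = FALSE)
  }
  if (stats::sd(mirna_log2) == 0 || stats::sd(target_log2) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(mirna_log2, target_log2, method = "pearson")
  r <- unname(ct$estimate)
  p <- ct$p.value
  list(r = r, p = p, n = length(mirna_log2), reciprocal = (r < 0 && p <= 0.05))
}

#' Hierarchically cluster a log2 expression matrix
#'
#' Agglomerative clustering with Euclidean distance and complete linkage;
#' leaf order is deterministic (ties resolved by row index through the
#' stable distance ordering). Returns the tree and a flat k-group cut.
#'
#' @param mat numeric matrix (rows = genes/miRNAs, columns = samples), no
#'   missing values.
#' @param k number of flat groups to cut (default 2).
#' @return list with `hclust` (an [stats::hclust] tree), `order` (leaf
#'   order, row indices), `groups` (named integer vector from
#'   [stats::cutree]).
#' @export
hierarchical_cluster <- function(mat, k = 2) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix contains missing values", call. = FALSE)
  if (nrow(mat) == 1) {
    return(list(hclust = NULL, order = 1L,
                groups = stats::setNames(1L, rownames(mat))))
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"), method = "complete")
  list(hclust = hc, order = hc$order,
       groups = stats::cutree(hc, k = min(k, nrow(mat))))
}
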
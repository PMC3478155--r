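#' Parse a dot-bracket string into a pair table
#'
#' @param structure dot-bracket string over `(`, `.`, `)`.
#' @return integer vector `pt` with `pt[i]` the 1-based partner of position
#'   `i`, or 0 if unpaired.
#' @examples
#' pair_table("(((....)))")
#' @export
pair_table <- function(structure) {
  ch <- .seq_chars(structure)
  if (any(!ch %in% c("(", ".", ")"))) {
    stop("dot-bracket string may contain only '(', '.', ')'", call. = FALSE)
  }
  pt <- integer(length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (length(open) == 0) stop("unbalanced brackets at position ", i, call. = FALSE)
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(open) > 0) stop("unbalanced brackets: unclosed '(' at position ",
                             open[1], call. = FALSE)
  pt
}

# Pairs of a single-hairpin structure as a matrix ordered outermost-in,
# with validation that the pairs form one nested chain.
.hairpin_chain <- function(pt) {
  i5 <- which(pt > seq_along(pt))
  if (length(i5) == 0) return(matrix(integer(0), ncol = 2))
  ord <- order(i5)
  ch <- cbind(i5[ord], pt[i5][ord])
  # chain condition: each pair strictly contains the next
  if (length(i5) > 1) {
    ok <- all(diff(ch[, 1]) > 0) && all(diff(ch[, 2]) < 0)
    if (!ok) stop("structure is not a single nested hairpin chain", call. = FALSE)
  }
  inner <- ch[nrow(ch), ]
  if (inner[2] - inner[1] - 1 < 3) {
    stop("hairpin loop shorter than 3 nt", call. = FALSE)
  }
  ch
}

#' Fold an RNA sequence into its best single-hairpin structure
#'
#' Finds the minimum-free-energy structure among all pseudoknot-free
#' structures that contain exactly one hairpin loop and no multiloops, under
#' the additive nearest-neighbour [energy_model()]. Allowed pairs are AU, UA,
#' CG, GC, GU, UG; bulge/internal-loop extensions are capped at
#' `model$max_loop` unpaired nucleotides per side. If no structure with
#' negative energy exists the open structure is returned with dG = 0.
#' Ties are broken deterministically in favour of the 5'-most, then
#' longest-spanning, closing pair.
#'
#' @param sequence RNA string, length >= 10. `N` is treated as unpairable.
#' @param model an [energy_model()].
#' @return list with `structure` (dot-bracket string) and `dG` (kcal/mol).
#' @examples
#' fold_hairpin("GGGGGAAAACCCCC")
#' @export
fold_hairpin <- function(sequence, model = energy_model()) {
  sequence <- as_rna(sequence)
  .check_rna(sequence)
  n <- nchar(sequence)
  if (n < 10) stop("sequence must be at least 10 nt", call. = FALSE)
  enc <- .encode_rna(sequence)
  enc[is.na(enc)] <- -1L  # N: cannot pair
  pen <- .penalty_vectors(model, n)
  res <- fold_hairpin_cpp(enc, model$stack, pen$hairpin, pen$bulge,
                          pen$internal, model$max_loop)
  list(structure = res$structure, dG = res$dG)
}

#' Evaluate the free energy of a given single-hairpin structure
#'
#' Deterministic additive score: stack energies between consecutive chain
#' pairs, bulge/internal-loop penalties for interrupted helices, and the
#' hairpin-loop penalty for the innermost loop. The open structure scores 0.
#' Loop penalties are size-only, so substituting an unpaired base never
#' changes the energy of a fixed structure.
#'
#' @param sequence RNA string.
#' @param structure dot-bracket string of the same length, forming a single
#'   nested hairpin chain whose pairs are all allowed pair types.
#' @param model an [energy_model()].
#' @return free energy in kcal/mol.
#' @export
energy_of <- function(sequence, structure, model = energy_model()) {
  sequence <- as_rna(sequence)
  .check_rna(sequence)
  if (nchar(sequence) != nchar(structure)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  pt <- pair_table(structure)
  ch <- .hairpin_chain(pt)
  if (nrow(ch) == 0) return(0)
  b <- .seq_chars(sequence)
  ptype <- pair_type(b[ch[, 1]], b[ch[, 2]])
  if (anyNA(ptype)) {
    k <- which(is.na(ptype))[1]
    stop(sprintf("pair %d-%d (%s:%s) is not an allowed pair type",
                 ch[k, 1], ch[k, 2], b[ch[k, 1]], b[ch[k, 2]]), call. = FALSE)
  }
  e <- 0
  if (nrow(ch) > 1) {
    for (k in seq_len(nrow(ch) - 1)) {
      s1 <- ch[k + 1, 1] - ch[k, 1] - 1
      s2 <- ch[k, 2] - ch[k + 1, 2] - 1
      e <- e + if (s1 == 0 && s2 == 0) {
        model$stack[ptype[k], ptype[k + 1]]
      } else if (s1 == 0 || s2 == 0) {
        model$bulge(s1 + s2)
      } else {
        model$internal(s1 + s2)
      }
    }
  }
  inner <- ch[nrow(ch), ]
  e + model$hairpin(inner[2] - inner[1] - 1)
}

#' Label hairpin regions (5' stem, loop, 3' stem) and the anti-stem arm
#'
#' The loop is the unpaired interval enclosed by the innermost pair; all
#' positions 5' of the loop are `stem5` and all positions 3' of it are
#' `stem3` (the labels partition the precursor; unpaired bases inside a
#' bulge or internal loop belong to their arm, not the loop). If a mature
#' span is supplied, the arm opposite the mature is flagged as the
#' anti-stem side.
#'
#' @param structure dot-bracket string containing exactly one hairpin loop.
#' @param mature_span optional integer length-2 vector (1-based inclusive)
#'   of the mature miRNA within the precursor; must lie within one arm.
#' @return list with `region` (character vector of per-position labels
#'   `stem5`/`loop`/`stem3`), `loop_span`, `arm5_span`, `arm3_span`,
#'   `mature_span`, `mature_arm` and `antistem_arm` (`"stem5"`/`"stem3"` or
#'   `NA` without a mature span).
#' @export
annotate_regions <- function(structure, mature_span = NULL) {
  pt <- pair_table(structure)
  n <- length(pt)
  if (!any(pt > 0)) stop("structure has no hairpin loop", call. = FALSE)
  ch <- tryCatch(.hairpin_chain(pt),
                 error = function(e) stop("structure does not contain exactly one hairpin loop: ",
                                          conditionMessage(e), call. = FALSE))
  inner <- ch[nrow(ch), ]
  loop <- (inner[1] + 1):(inner[2] - 1)
  region <- character(n)
  region[seq_len(inner[1])] <- "stem5"
  region[loop] <- "loop"
  region[inner[2]:n] <- "stem3"
  out <- list(region = region,
              loop_span = c(inner[1] + 1L, inner[2] - 1L),
              arm5_span = c(1L, inner[1]),
              arm3_span = c(inner[2], n),
              mature_span = mature_span,
              mature_arm = NA_character_,
              antistem_arm = NA_character_)
  if (!is.null(mature_span)) {
    mature_span <- as.integer(mature_span)
    if (mature_span[1] < 1 || mature_span[2] > n || mature_span[1] > mature_span[2]) {
      stop("mature span outside the precursor", call. = FALSE)
    }
    labs <- unique(region[mature_span[1]:mature_span[2]])
    arm <- if (all(labs == "stem5")) "stem5"
           else if (all(labs == "stem3")) "stem3"
           else stop("mature span is not contained in a single arm", call. = FALSE)
    out$mature_arm <- arm
    out$antistem_arm <- if (arm == "stem5") "stem3" else "stem5"
  }
  out
}

#' Trim a folded candidate to its hairpin core
#'
#' A candidate excised with long flanks often folds with chance flank
#' helices joined to the central hairpin by large interior loops. The
#' precursor proper is the hairpin core: walking from the innermost pair
#' outward, the chain is kept while every interior loop carries at most
#' `max_interior` unpaired nucleotides, and cut at the first larger loop.
#' The core is returned as its own sequence/structure with its energy
#' re-evaluated additively on the trimmed chain.
#'
#' @param sequence candidate sequence (RNA string).
#' @param structure its single-hairpin dot-bracket from [fold_hairpin()].
#' @param max_interior largest interior loop kept in the core (default 18,
#'   the published bulge bound).
#' @param model [energy_model()].
#' @return `NULL` when the structure has no pairs; otherwise a list with
#'   `span` (1-based core interval on the candidate), `sequence`,
#'   `structure` and `dG` (energy of the trimmed chain).
#' @export
extract_hairpin_core <- function(sequence, structure, max_interior = 18,
                                 model = energy_model()) {
  pt <- pair_table(structure)
  if (!any(pt > 0)) return(NULL)
  ch <- .hairpin_chain(pt)
  outer <- nrow(ch)
  if (nrow(ch) > 1) {
    for (k in (nrow(ch) - 1):1) {
      s <- (ch[k + 1, 1] - ch[k, 1] - 1L) + (ch[k, 2] - ch[k + 1, 2] - 1L)
      if (s > max_interior) break
      outer <- k
    }
  }
  i <- ch[outer, 1]; j <- ch[outer, 2]
  sub_seq <- substring(sequence, i, j)
  sub_struct <- substring(structure, i, j)
  list(span = c(i, j), sequence = sub_seq, structure = sub_struct,
       dG = energy_of(sub_seq, sub_struct, model))
}

#' Fold with a pluggable engine
#'
#' Adapter contract for external secondary-structure engines: any function
#' `sequence -> list(structure = <dot-bracket>, dG = <kcal/mol>)` can stand
#' in for the built-in restricted dynamic program, e.g. to inject values
#' computed by an external thermodynamic folder when parity with published
#' energies matters.
#'
#' @param sequence RNA string.
#' @param engine a folding function with the contract above; defaults to
#'   [fold_hairpin()].
#' @param ... passed on to the engine.
#' @return list with `structure` and `dG`.
#' @export
fold_with <- function(sequence, engine = fold_hairpin, ...) {
  res <- engine(sequence, ...)
  stopifnot(is.list(res), all(c("structure", "dG") %in% names(res)))
  res
}
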
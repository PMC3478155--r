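#' Nearest-neighbour energy model for single-hairpin folding
#'
#' The folding engine scores a structure as the sum of base-pair stack free
#' energies plus size-only loop penalties (Jacobson--Stockmayer extrapolation).
#' Stack values are Turner-like nearest-neighbour free energies in kcal/mol
#' for the six allowed pair types (AU, UA, CG, GC, GU, UG); loop penalties
#' depend on loop size only, never on sequence. Sequence-independent loop
#' penalties make the free-energy change of a loop substitution exactly zero
#' whenever the minimum-energy structure is unchanged.
#'
#' @param max_loop maximum number of unpaired nucleotides allowed on one side
#'   of a bulge or internal loop during folding (the DP band width).
#' @param duplex_init initiation penalty (kcal/mol) applied once to an
#'   intermolecular miRNA:target duplex.
#' @return an object of class `energy_model`: a list with the 6x6 `stack`
#'   matrix (rows = outer pair, cols = inner pair, 5'->3'), penalty functions
#'   `hairpin`, `bulge`, `internal` (vectorised over loop size), `max_loop`
#'   and `duplex_init`.
#' @examples
#' em <- energy_model()
#' em$stack["CG", "GC"]
#' em$hairpin(3:6)
#' @export
energy_model <- function(max_loop = 30L, duplex_init = 4.1) {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  # outer pair in rows, inner pair in columns; all stacks stabilising (< 0)
  stack <- matrix(c(
    # inner:  AU    UA    CG    GC    GU    UG
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,  # outer AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,  # outer UA
    -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,  # outer CG
    -2.4, -2.2, -3.4, -3.3, -1.5, -2.5,  # outer GC
    -1.0, -1.2, -1.9, -1.5, -0.4, -0.4,  # outer GU
    -0.8, -1.0, -2.1, -1.4, -0.4, -0.4), # outer UG
    nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  # RT at 37C ~ 0.616 kcal/mol; 1.75 * RT multiplies the log term
  ljs <- 1.75 * 0.616
  structure(list(
    pairs = pairs,
    stack = stack,
    hairpin  = function(n) ifelse(n < 3, Inf, 5.4 + ljs * log(n / 3)),
    bulge    = function(n) ifelse(n < 1, Inf, 3.3 + ljs * log(n)),
    internal = function(n) ifelse(n < 2, Inf, 1.7 + ljs * log(n / 2)),
    max_loop = as.integer(max_loop),
    duplex_init = duplex_init
  ), class = "energy_model")
}

# Pair-type index used by both the R evaluator and the C++ DP:
# 1 AU, 2 UA, 3 CG, 4 GC, 5 GU, 6 UG, 0 not pairable.
PAIR_INDEX <- local({
  m <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U")))
  m["A", "U"] <- 1L; m["U", "A"] <- 2L
  m["C", "G"] <- 3L; m["G", "C"] <- 4L
  m["G", "U"] <- 5L; m["U", "G"] <- 6L
  m
})

#' Pair type of two RNA bases
#'
#' @param a,b single RNA bases (characters among A, C, G, U).
#' @return pair name ("AU", "UA", "CG", "GC", "GU", "UG") or `NA` if the two
#'   bases cannot pair.
#' @export
pair_type <- function(a, b) {
  idx <- PAIR_INDEX[cbind(match(a, rownames(PAIR_INDEX)),
                          match(b, rownames(PAIR_INDEX)))]
  ifelse(is.na(idx) | idx == 0L, NA_character_,
         c("AU", "UA", "CG", "GC", "GU", "UG")[pmax(idx, 1L)])
}

# Penalty lookup vectors handed to the C++ DP so that R and C++ use the
# identical numbers (single source of truth).
.penalty_vectors <- function(model, n) {
  w <- model$max_loop
  list(
    hairpin  = model$hairpin(seq_len(max(n, 3L))),        # index = loop size
    bulge    = model$bulge(seq_len(2L * w)),              # index = bulge size
    internal = model$internal(seq_len(2L * w))            # index = total size
  )
}
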
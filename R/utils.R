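#' @useDynLib mirpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Uppercases and maps T to U. All internal logic in the package operates on
#' the RNA alphabet; the original alphabet is remembered at the I/O boundary.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over A, C, G, U, N.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("U", "T", toupper(x))

.check_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-RNA characters: %s", what,
                 paste(unique(unlist(strsplit(gsub("[ACGUN]", "", x[bad]), ""))),
                       collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement in the RNA alphabet
#'
#' @param x character vector of RNA strings.
#' @return reverse complement of each element (A<->U, C<->G, N->N).
#' @export
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGUN", "UGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.seq_chars <- function(x) strsplit(x, "")[[1]]

# Encode an RNA string as 0-based integers for the C++ DP (A=0,C=1,G=2,U=3).
.encode_rna <- function(x) {
  match(.seq_chars(x), RNA_BASES) - 1L
}

#' Round half-up
#'
#' Rounds away from the usual banker's rounding: .5 always rounds up, as in
#' hand-formatted percentage tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Deterministic child seed derived from a parent seed (kept below 2^31).
.sub_seed <- function(seed, k) {
  (as.numeric(seed) * 1103 + 12289 * as.numeric(k)) %% 2147483647
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Random RNA string
#'
#' @param n length of the string.
#' @param gc GC content knob: probability mass on G and C (split evenly);
#'   the remainder is split between A and U.
#' @return a single RNA string. Uses the current RNG stream.
#' @export
random_rna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(RNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}
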
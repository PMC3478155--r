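# Independent oracles for the folding engine, written against the same
# energy model but with their own recursion/enumeration code paths.

# Best single-hairpin energy by recursion over closing pairs (memoised on
# the interval), considering every chain of nested pairs with an innermost
# loop of >= 3 nt. No loop-width cap (irrelevant at oracle sizes).
oracle_best_energy <- function(seq, model = energy_model()) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  memo <- matrix(NA_real_, n, n)
  best_closed <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    pt_out <- pair_type(ch[i], ch[j])
    if (is.na(pt_out) || j - i - 1 < 3) {
      memo[i, j] <<- Inf
      return(Inf)
    }
    best <- model$hairpin(j - i - 1)
    if (j - i - 1 >= 5) {
      for (k in (i + 1):(j - 5)) {
        for (l in (k + 4):(j - 1)) {
          sub <- best_closed(k, l)
          if (!is.finite(sub)) next
          s1 <- k - i - 1
          s2 <- j - l - 1
          cost <- if (s1 == 0 && s2 == 0) {
            model$stack[pt_out, pair_type(ch[k], ch[l])]
          } else if (s1 == 0 || s2 == 0) {
            model$bulge(s1 + s2)
          } else {
            model$internal(s1 + s2)
          }
          if (cost + sub < best) best <- cost + sub
        }
      }
    }
    memo[i, j] <<- best
    best
  }
  best <- 0
  for (i in seq_len(n - 4)) {
    for (j in (i + 4):n) {
      v <- best_closed(i, j)
      if (v < best) best <- v
    }
  }
  best
}

# Pure enumeration of every single-hairpin chain (no memoisation), n <= 14.
oracle_enumerated_energy <- function(seq, model = energy_model()) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- 0
  pairable <- function(i, j) !is.na(pair_type(ch[i], ch[j]))
  recurse <- function(i, j, e) {
    best <<- min(best, e + model$hairpin(j - i - 1))
    if (j - i - 1 < 5) return(invisible())
    pt_out <- pair_type(ch[i], ch[j])
    for (k in (i + 1):(j - 5)) {
      for (l in (k + 4):(j - 1)) {
        if (!pairable(k, l)) next
        s1 <- k - i - 1
        s2 <- j - l - 1
        cost <- if (s1 == 0 && s2 == 0) {
          model$stack[pt_out, pair_type(ch[k], ch[l])]
        } else if (s1 == 0 || s2 == 0) {
          model$bulge(s1 + s2)
        } else {
          model$internal(s1 + s2)
        }
        recurse(k, l, e + cost)
      }
    }
  }
  for (i in seq_len(max(0, n - 4))) {
    for (j in (i + 4):n) {
      if (j - i - 1 >= 3 && pairable(i, j)) recurse(i, j, 0)
    }
  }
  best
}

# Additive energy of a fixed structure, recomputed independently of
# energy_of(): own dot-bracket walk.
oracle_structure_energy <- function(seq, structure, model = energy_model()) {
  ch <- strsplit(seq, "")[[1]]
  db <- strsplit(structure, "")[[1]]
  opens <- which(db == "(")
  closes <- rev(which(db == ")"))
  if (length(opens) == 0) return(0)
  stopifnot(length(opens) == length(closes))
  e <- 0
  for (k in seq_along(opens)[-1]) {
    i0 <- opens[k - 1]; j0 <- closes[k - 1]
    i1 <- opens[k]; j1 <- closes[k]
    s1 <- i1 - i0 - 1
    s2 <- j0 - j1 - 1
    e <- e + if (s1 == 0 && s2 == 0) {
      model$stack[pair_type(ch[i0], ch[j0]), pair_type(ch[i1], ch[j1])]
    } else if (s1 == 0 || s2 == 0) {
      model$bulge(s1 + s2)
    } else {
      model$internal(s1 + s2)
    }
  }
  last <- length(opens)
  e + model$hairpin(closes[last] - opens[last] - 1)
}

# Brute-force seed-type scan: test every UTR offset against every site-type
# definition directly (independent of the gregexpr-based implementation).
oracle_seed_scan <- function(mirna, utr) {
  comp <- function(b) chartr("ACGU", "UGCA", b)
  mc <- strsplit(mirna, "")[[1]]
  uc <- strsplit(utr, "")[[1]]
  n <- length(uc)
  rows <- list()
  for (c0 in seq_len(n - 5)) {
    core_ok <- all(uc[c0:(c0 + 5)] == comp(mc[7:2]))
    if (!core_ok) next
    m8 <- c0 > 1 && uc[c0 - 1] == comp(mc[8])
    a1 <- c0 + 6 <= n && uc[c0 + 6] == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else if (a1) "7mer-A1" else "6mer"
    rows[[length(rows) + 1]] <- data.frame(core_start = c0, site_type = type)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(core_start = integer(0), site_type = character(0))
}

random_rna_fixed <- function(n, seed) {
  mirpipe:::.with_seed(seed, random_rna(n))
}
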
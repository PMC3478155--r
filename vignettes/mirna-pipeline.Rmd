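---
title: "Methods: miRNA discovery, targets and SNP effects in mirpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery, targets and SNP effects in mirpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpipe)
```

mirpipe reimplements, as one tested R package, the analysis workflow used to
build a miRNA catalog for a species with fragmentary genome resources (the
motivating system is the common carp, whose genome was unassembled and whose
reference sequences were BAC-end and transcriptome contigs): homology- and
read-based precursor discovery, catalog characterization, dual-predictor
target calling, and the evaluation of SNPs in precursors and in target
3'UTRs. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic data generators do and do not
emulate.

## The folding engine

Precursor validation and the SNP energy analysis only ever score one object:
a single stem-loop. The engine is therefore a restricted dynamic program
over closing pairs $(i, j)$, considering every pseudoknot-free structure
with **exactly one hairpin loop and no multiloops** — a chain of nested
pairs. The recursion is

$$V(i,j) = \min\Big( H(j-i-1),\; \min_{i<k<l<j} \; c\big((i,j),(k,l)\big) + V(k,l) \Big)$$

where $H$ is the hairpin-loop penalty and $c$ is a stack energy when the
inner pair is adjacent, a bulge penalty when one side is interrupted, and an
internal-loop penalty otherwise. Allowed pairs are AU, UA, CG, GC, GU, UG.
Interior extensions are capped at `max_loop = 30` unpaired nucleotides per
side (a precursor bulge never approaches this; the cap bounds the DP at
$O(n^2 w^2)$, and the core loop is compiled C++). The minimum over all
closing pairs is the MFE; when no structure scores below zero the open
structure is returned with $\Delta G = 0$.

The energy model (`energy_model()`) embeds a Turner-like nearest-neighbour
stack table (kcal/mol, all stabilizing) and Jacobson–Stockmayer size-only
loop penalties, $P(n) = a + 1.75\,RT \ln(n/n_0)$. Two properties are design
commitments rather than fitted constants:

* **Loop penalties depend on size only, never on sequence.** A substitution
  at an unpaired position leaves the energy of a fixed structure unchanged,
  so a loop SNP that does not change the MFE structure has
  $\Delta\Delta G = 0$ exactly — the behaviour reported for loop SNPs in
  this kind of analysis.
* **Determinism.** Among equal-energy structures the DP prefers the
  5'-most, then longest-spanning, closing pair; identical input always
  yields the identical dot-bracket string.

Reproducing a specific thermodynamic package's energies bit-for-bit is out
of scope; `fold_with()` accepts any external engine with the contract
`sequence -> list(structure, dG)` when parity with published
$\Delta G$ values matters. The test suite instead proves *internal*
correctness: the DP equals an independent exhaustive enumeration of all
single-hairpin structures on hundreds of random sequences of length 10–20,
and `energy_of()` re-derives every folded energy additively.

Candidates excised with long flanks sometimes fold with chance flank
helices attached to the central hairpin by large interior loops.
`extract_hairpin_core()` trims the chain from the innermost pair outward,
cutting at the first interior loop above 18 nt (the published bulge bound),
and the six criteria are applied to that core — mirroring how
precursor-extraction pipelines isolate the stem-loop from a larger fold.

## The six hairpin criteria

`check_hairpin_criteria()` applies the published screen with boundary
semantics exactly as printed: $\Delta G \le -15$ kcal/mol; at least 80% of
the mature base-paired in the stem; no single bulge/internal loop over
18 nt; hairpin longer than 53 nt (53 fails); terminal loop shorter than
22 nt (22 fails); at most 6 mature positions unpaired against the
anti-stem. Two wordings in the source screen are ambiguous and were fixed
once here: the bulge rule is read as a per-loop size bound (total unpaired
nucleotides in one bulge or internal loop), and "mismatches between the
miRNA and the anti-stem" is counted as mature positions not base-paired in
the predicted structure.

## Discovery

**Homology arm.** Known matures are deduplicated exactly
(`dedup_matures()`), then aligned against both strands of every reference
window by ungapped sliding alignment; identity = matching positions /
query length, threshold 0.90 by default. The 90% figure is itself
recoverable from data: `calibrate_identity_threshold()` returns the minimum
within-family pairwise identity over a family-grouped mature set. Gapped
alignment was considered and rejected: the threshold is an identity
fraction over a ~22-nt query, where a single indel costs more than the
allowed mismatch budget, and a deterministic substitution-only scan keeps
recall/precision properties provable against the generator. Hits are
extended by 60 nt bilateral flanks, folded, core-trimmed and screened.

**Sequencing arm.** `clean_reads()` applies the standard cascade (5'
adapter contamination; leftmost 3'-adapter trim with minimum overlap 6 and
one mismatch allowed per 10 aligned nt; poly(A) = eight consecutive A or
>80% A; mean Phred < 20; length < 18), in that order, with each read
attributed to its first failing rule. These four thresholds are
conventional small-RNA practice and are exposed as arguments.
`annotate_contaminants()` replaces a loose BLASTN against contaminant
databases with full-length matching at $\le 1$ mismatch, with class
priority rRNA > tRNA > snRNA > repeat. `discover_from_reads()` maps reads
exact-match on both strands, merges stacks within 50 nt into loci (enough
to join the mature and star arms across a loop), and keeps a locus when
the dominant read sits in one arm of the folded core, the six criteria
pass with that read as the mature, and the locus carries at least
`min_locus_reads = 2` reads (star reads were retained at frequency 2 in
the motivating study, so 2 is the defensible floor). A read whose reverse
complement matches the opposite arm of its own hairpin creates an
opposite-strand echo locus; echoes are collapsed. Multi-mapping reads
participate in every locus for discovery but are counted once — at their
first locus in reference order — for expression; the study did not state
its counting rule, so this deterministic convention is documented rather
than guessed differently per run.

`merge_catalogs()` unifies the two arms (identical matures, or
subsequence matures at one locus), flags conflicting loci for review, and
calls each miRNA conserved (found by homology, or homologous at $\ge$ 0.90
to a known mature) or specific. isomiRs are precursor-templated reads
overlapping the mature with end shifts of at most 3 nt; moRNAs are
precursor-perfect reads outside the mature/star spans starting or ending
within 2 nt of a span boundary.

## Characterization

Clusters are single-linkage chains of same-reference, same-strand
precursors with gaps at most `max_gap`; the span is min(start)–max(end),
1-based inclusive. The default `max_gap` is 10,000 nt: the published
clusters are all under 1 kb, so the default is deliberately permissive and
config-exposed; no cross-contig merging is attempted (the published
remark that three clusters may be one larger cluster rests on synteny to
another genome, not on a distance rule). Phylogenetic grouping assigns
each family the first matching rule of: shared (present in at least one
protostome *and* one deuterostome), fish-only (presences all fish),
otherwise vertebrate-only — a total partition of non-empty rows.
Table 1-style location strings carry occasional footnote asterisks in the
source; coordinates are treated as plain numbers.

Expression comparisons use a two-sided Mann–Whitney test: exact
enumeration of all $\binom{n_1+n_2}{n_1}$ label arrangements for combined
$n \le 12$ (ties handled on the observed values, $p = \min(1, 2\min(p_{lo},
p_{hi}))$), normal approximation with tie and continuity correction above
that; the approximation agrees with the exact p within 0.02 at $n = 10+10$
in the test suite. RT-qPCR profiling is the $2^{-\Delta\Delta C_T}$ method:
$\Delta C_T = C_T^{gene} - C_T^{ref}$, $\Delta\Delta C_T$ relative to a
calibrator sample (whose relative expression is exactly 1), log2 values
emitted for clustering. Heatmap clustering is agglomerative with Euclidean
distance and complete linkage — the source names only "hierarchical
clustering", so the linkage is a package decision, chosen for its
compact, deterministic groups. miRNA–target correlation is Pearson on the
log2 series (as the published figure legend describes), with a
"reciprocal pattern" flag at $r < 0, p \le 0.05$.

## Target prediction

Two deliberately rule-distinct predictors:

* **A (seed types):** canonical 6mer (miRNA 2–7), 7mer-m8 (2–8), 7mer-A1
  (2–7 + A opposite position 1), 8mer; Watson–Crick only; each seed match
  reported once at its strongest type.
* **B (energy):** seed duplexes of 6–8 nt starting at miRNA position 2,
  zero mismatches, at most one G:U (none in 6mers), duplex
  $\Delta G \le -9$ kcal/mol. The duplex energy is the maximal contiguous
  helix through the seed register under the same stack table, plus a
  duplex initiation of +4.1 kcal/mol. The published cutoff phrase
  ("$\Delta G$ low than $-9$") is read as duplex $\Delta G \le -9$; an
  accessibility term is explicitly out of scope.

A miRNA–mRNA pair is a **consensus target** when both predictors report
sites sharing at least one UTR position (`pair_level = TRUE` relaxes to
pair identity). False positive rates are measured on labeled pair sets as
the fraction of negatives with any predicted site; since the consensus is
an intersection, FPR(consensus) $\le$ min(FPR(A), FPR(B)) holds on every
labeled set — the structural fact behind the published ordering, asserted
as a property rather than as data-dependent percentages. Antisense
miRNAs are exact reverse-complement matches of the full mature inside an
mRNA.

## SNP effects

Precursor SNPs are classified on the wild-type structure into mature
(overriding), loop, anti-stem (arm opposite the mature) or stem.
$\Delta\Delta G = \Delta G_{mutant} - \Delta G_{wild}$, both alleles folded
with the same engine; the sign convention is mutant-minus-wild (the source
tables print both signs without stating one; the convention is fixed and
surfaced in the output). Interpretation uses the 0.3 kcal/mol floor below
which a change is negligible, and the published rule is implemented
literally — energy down means mature production down — despite being
thermodynamically counterintuitive; `rule = "inverted"` provides the
opposite mapping as an explicit escape hatch. Exact reproduction of any
published $\Delta\Delta G$ magnitude is not promised (the source's folding
engine and parameter set are unknown); the sign behaviour and the
loop-zero property are what the tests assert.

UTR SNPs: both predictors run on both alleles, restricted to sites
overlapping the SNP position ± 7 nt (one maximal site length minus one).
A **loss** requires consensus on the wild type and *neither* predictor
firing on the SNP type; a **gain** is the symmetric case; all other
firing patterns are unchanged. The "not predicted … by either" wording was
read as "by neither", by symmetry with the gain definition; the exhaustive
16-pattern enumeration (one loss, one gain, fourteen unchanged) is a test.

## Synthetic data

The generators produce every input the pipeline consumes, with complete
machine-readable truth, and are deterministic to the byte under a seed.
`make_hairpin()` builds GC-biased arms (P(G) = P(C) = 0.3) with a loop
drawn from {A, C} only — no two loop bases can pair, so a clean stem
cannot be extended into the loop and the planted structure is the unique
MFE for clean constructs; mismatches and single-nt bulges are planted at
admissible interior positions. `make_reference_with_mirnas()` embeds
precursors (including clustered pairs and minus-strand plants) in i.i.d.
background contigs. `mutate_homolog()` plants
$\lceil (1-\text{identity}) \times \text{length} \rceil$ substitutions —
note that a 22-mer "at 0.90" therefore realizes 19/22 ≈ 0.864 and falls
below the 0.90 threshold; recall properties are stated at planted
identities $\ge 0.95$ (always recovered) and $\le 0.85$ (never).
`simulate_sreads()` draws mature/star/isomiR/moRNA reads, appends
adapters, truncates to the instrument read length, injects substitution
errors, and mixes in contaminant, poly(A), short, 5'-adapter and
low-quality junk. `make_utr_with_sites()` embeds one canonical site in
background screened so that the planted site is the only one either
predictor reports (chance flanking bases can silently upgrade a site
type, so the screen checks the exact planted type and span), and its SNP
plans toggle one seed-pairing position, verified so that "destroy" kills
both predictors and "create" restores a consensus site.

What the generators do **not** emulate: realistic base-quality error
profiles, ligation bias, tissue-specific expression, genuine sequence
divergence structure (substitutions are uniform), or paper-scale volumes.
Default scales are desk-sized (tens of precursors, hundreds to thousands
of reads; the test suite and the acceptance script run on 4–8 precursors,
~400-read libraries, 500-sequence fold-oracle sweeps and 12–15-pair
labeled sets, all in seconds) — passing tests show the machinery is
correct on unambiguous fixtures, not that real libraries are free of the
usual pathologies.

## Known limitations

* The fold engine's absolute energies are model-specific; compare
  magnitudes across alleles (ddG), not against published tables.
* Homology search is substitution-only; a true indel-divergent homolog
  would be missed at the same identity.
* A protostome-only presence row would fall in the vertebrate-only group;
  the three-group scheme presumes deuterostome representation, as in the
  source matrix.
* Contaminant annotation is exact-matching, not a covariance-model or
  E-value search; divergent contaminant fragments pass through.
* The two target predictors share the stack table; their consensus is
  rule-diverse, not engine-diverse.

## Reproducibility shape

The repository is an analysis workflow: `analysis/01…05` are thin
narrative drivers (simulate inputs → discover → characterize → targets →
SNP effects) that write tables under `results/`; every computation lives
in the package and is exercised by the testthat suite;
`scripts/acceptance.R` recomputes the headline quantities from scratch
under a caller-supplied seed.
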
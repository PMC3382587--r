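---
title: "Methods: egg small-RNA discovery, target prediction and expression statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: egg small-RNA discovery, target prediction and expression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovamir)
```

This vignette documents the models, parameter choices and numerical
decisions behind `ovamir`, in the spirit of a methods section: what each
stage assumes, which knobs matter, and what the synthetic benchmark does
and does not demonstrate.

## 1. Read cleaning: the impurity screen

Raw reads from an adapter-ligated small-RNA library are cleaned in a fixed
order, and every read is attributed to exactly one rejection category or
survives — `filter_reads()` enforces this accounting identity exactly,
which the test suite checks against independent single-rule re-scans.

* **Character validation.** Non-ACGTN reads are counted as `invalid`.
* **Low-resolution screen.** "Low resolution" is not a precisely defined
  term in the field; here it is operationalized as mean Phred quality
  below `min_quality` (default 20) when qualities are present. It is a
  configurable approximation, deliberately separate from the junk rules.
* **Adapter trimming.** The 3' adapter is found as the longest read
  suffix matching an adapter prefix with at least 6 nt overlap and at
  most 1 substitution, leftmost hit first. An empty insert is an adapter
  dimer. Reads without an adapter hit are kept as-is (insert-only
  dialect) because simulated and real libraries differ in whether the
  read length exceeds insert + adapter; `require_adapter = TRUE` flips
  this.
* **Junk rules**, applied to the trimmed insert in order: any single base
  at ≥ 80% of the length; ≥ 3 Ns; alphabet within {A,C} or within {G,T}.
  Residual reads with 1–2 Ns are rejected as `n_content` (a unique tag
  must be N-free).
* **Size and copy filters.** Tags outside 15–26 nt are dropped; tags seen
  fewer than 3 times are dropped last, *after* junk/length removal, so a
  borderline tag cannot be rescued or doomed by junk reads that happen to
  share its sequence. An optional exclusion database (mRNA, RFam,
  Repbase-style FASTA supplied by the user) removes tags equal to or
  contained in any entry; we do not ship those databases.

## 2. Known-miRNA assignment

Tags are matched ungapped against a mature reference with at most one
substitution ("fewer than 2 mismatching bases") at terminal offsets of up
to ±3 nt. Two interpretation decisions:

* **No E-values.** At tag lengths of 15–26 nt a deterministic mismatch
  rule dominates any E-value screen, so the BLAST-style E-value criterion
  is intentionally not implemented.
* **Soft ends.** Tag bases overhanging the mature ends (within the ±3
  offset allowance) are isomiR length variation, not substitutions, and
  are not counted as mismatches. Without this rule, 3'-extended isomiRs
  would be pushed into the novel-prediction stage.

Ties are broken by (fewest mismatches, smallest |offset|, mature name).
Multi-mapping tags are assigned to the single tie-break winner so family
fractions sum to one; `summarize_families()` pools arms, paralog letters
and species prefixes (e.g. `omy-let-7a` and `dre-let-7b` → `let-7`), a
rule that is overridable via an explicit mapping.

## 3. The folding engine and its energy model

Novel-miRNA prediction and target-site accessibility both need secondary
structure. `fold_rna()` computes the single optimal nested structure
(pseudoknot-free, minimum hairpin loop 3 nt) under the package's own
nearest-neighbor-style model:

* a 6 × 6 stacking table over {CG, GC, GU, UG, AU, UA}, derived from
  per-pair strengths (CG 2.6, AU 1.4, GU 0.8 kcal/mol) by a midpoint rule
  plus a 0.3 kcal/mol helix-contiguity bonus, shipped as
  `inst/extdata/nn_stacks.tsv`;
* linear hairpin (4.0 + 0.05·size) and interior/bulge (2.0 + 0.4·u)
  penalties, interior loops capped at 30 unpaired bases;
* an affine multiloop cost (3.4 close + 0.4 per branch + 0.1 per
  unpaired).

This is *not* a fitted Turner parameter set; it is a deliberately simple,
fully documented model whose optimum can be verified by exhaustive
enumeration — the tests do exactly that for all sequences up to 12 nt, for
both unconstrained and constrained folds. An earlier draft short-circuited
sequences under 10 nt; the engine now folds anything that can
geometrically pair (≥ 5 nt), which keeps desk-scale worked examples like
`GGGAAACCC` → `(((...)))` meaningful. Traceback is deterministic (fixed
evaluation order, 5'-most opening pair preferred), so repeated runs give
identical structures.

Duplex free energies (`duplex_energy()`) reuse the same stacking table
over consecutive paired columns of an alignment, plus a +4.1 kcal/mol
initiation penalty, +0.45 per AU/GU helix end, and the interior-loop
penalty for mismatch/gap regions. Using one table for folding and
hybridization keeps ΔΔG internally consistent.

## 4. Hairpin criteria for novel miRNAs

Unmatched tags are mapped to the genome (exact match by default;
cross-species mapping noise is out of scope) and each locus extended by
60 nt on both sides. `call_hairpin()` screens the fold of that window:

1. decompose the structure into stem-loops, walking each helix outward
   across bulges of at most `stem_bulge_max = 2` unpaired bases;
2. the mature's stem is the stem holding most of its paired bases; all of
   the mature's in-stem pairs must lie on a single arm (a mature spanning
   the terminal loop fails);
3. at least 14 mature bases must pair within that stem;
4. the terminal loop must be 3–20 nt;
5. the stem must hold at least 1.2 × the pairs of any stem-loop outside
   its extent ("single dominant stem-loop");
6. fold energy ≤ −18 kcal/mol.

The first two rules deserve comment, because they were refined during
development against the generator's construction guarantees. A naive
"mature stem holds ≥ 50% of all pairs in the window" rule fails on real
positives: 120 nt of flanking sequence folds enough incidental structure
to outvote a perfect 22-bp stem. Conversely, walking stems across large
interior loops lets random sequence chain short helices into long
pseudo-stems. Capping the walk at 2-nt bulges and comparing the mature's
stem only against stems *outside* it makes the criteria behave like the
biological definition (a contiguous mature:star duplex dominating the
window): across development seeds, 118/120 planted precursors pass and
8/600 dinucleotide-shuffled decoys do.

Arm names (`-5p`/`-3p`) follow the mature's position relative to the
terminal loop; duplicate loci with identical precursor sequences are
collapsed.

## 5. UTR partitioning by translated homology

The desk-scale translated search mirrors an ungapped six-frame protein
search: exact 6-residue seeds, BLOSUM62 ungapped X-drop extension,
low-complexity query masking by windowed amino-acid entropy (window 12,
threshold 2.2 bits), E-values from ungapped Karlin–Altschul statistics
(λ = 0.3176, K = 0.134), and acceptance at E ≤ 10 with ≥ 60% coverage of
the shorter of query and subject (query length taken as ⌊cDNA/3⌋
residues). "Maximal match" selects the homolog by aligned length, with
score, E-value and protein id as tie-breaks — the coverage and E-value
knobs are both exposed because which of them dominates depends on the
reference data.

The partition rule itself is fixed: the homology match is the approximate
CDS; the 60 nt upstream are the approximate 5'UTR (typical 5'UTRs run
60–90 nt); everything downstream of the match — including the stop codon,
which protein homology cannot cover — is the approximate 3'UTR.
Reverse-frame matches produce a reverse-complemented model with a flag.

## 6. Dual-scanner target prediction

**Alignment scanner.** A Smith–Waterman complementarity alignment of the
miRNA (antiparallel) against sliding windows, with pair scores +5
(Watson–Crick), +1 (G:U), −3 (mismatch), affine gaps −9/−4, and pair
scores doubled at miRNA positions 2–8 (the seed). These constants are this
package's documented defaults (published scanner versions differ in their
exact tables), while the *acceptance thresholds* are the field-standard
ones: a site is kept iff S ≥ 140 (inclusive) **and**
ΔG < −17 kcal/mol (strict). The boundary semantics are tested bit-exactly.
A perfect 22-mer complement scores S = 7·5·2 + 15·5 = 145.

**Accessibility scanner.** Seed matches of length 8, 7 or 6 starting at
miRNA position 2 (perfect WC; one G:U tolerated in 8-mers only) anchor
candidate sites. Each site's ΔΔG = ΔG_duplex + ΔG_open, where ΔG_open is
the constrained-minus-unconstrained fold energy of the site ± 70 nt
context with the site forced single-stranded (≥ 0 by construction). No
ΔΔG cutoff is applied by default: the workflow relies on the
*intersection* of the two scanners for specificity.

Within one scanner, overlapping sites are resolved greedily (descending S,
or ascending ΔΔG). Consensus targets are gene × miRNA pairs reported by
both scanners in any region; regions are reported with 3'UTR priority,
then CDS, then 5'UTR. Per-gene targeting modes: `single-3UTR`,
`multi-miRNA-3UTR` (≥ 2 miRNAs with 3'UTR sites) and `3UTR-plus-CDS`
(same miRNA in both regions). Because gene models never overlap, a
3'UTR + 5'UTR double target cannot arise — the tests assert this
structural zero.

## 7. Expression statistics

Standard curves are least-squares fits Cq = slope·log10(q) + intercept;
efficiency (10^(−1/slope) − 1)·100 is reported but not used to correct
quantities — quantities come straight from curve interpolation, matching
standard practice for curve-based relative quantification. Normalization
divides by the geometric mean of exactly two reference genes; fold
changes use the lowest *group mean* as calibrator (the alternative —
lowest single value — cannot reproduce group-level fold displays).

The multiple-comparison procedure behind letter displays is a genuine
design choice; Tukey HSD at α = 0.05 with a compact letter display is
used, with letters assigned from maximal cliques of the
"not-significantly-different" graph, which makes the display exact:
groups share a letter iff they are not significantly different. All-equal
inputs yield an undefined F and a single shared letter rather than an
error.

`kw_test()` wraps the tie-corrected Kruskal–Wallis statistic (verified in
tests against the textbook formula, e.g. H = 7.2 for ranks 1..9 in three
groups of three) and reports per-tissue mean ranks, the quantity used for
descriptive cross-tissue comparisons.

## 8. What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the study conditions at desk scale: a
40 kb two-chromosome genome with 20 planted hairpins (22 nt matures,
reverse-complement star arms with 1–2 G:U wobbles — at least one wobble so
a mature maps to exactly one genomic locus under exact matching — and
6–12 nt loops, random strands); a 50,000-read library that is ~55% known
matures, 12% planted novel matures, 21% background, 8% junk, 3% adapter
dimers and 1% low-quality reads, with Zipf-distributed copy numbers
(exponent 1.5, mimicking the heavy skew of real family abundances),
isomiR end jitter at 5% and single substitutions at 2%; 30 transcripts
with 40–60 nt 5'UTRs, back-translated CDSs (proteins are exact
translations, so homology recovery is guaranteed by construction) and
150–300 nt 3'UTRs carrying perfect-complement sites in all three
targeting modes; and a 10-tissue qPCR panel (n = 4, Cq noise σ = 0.2,
curve slope −3.3219 ≙ 100% efficiency so closed-form checks apply) with a
planted 50-fold egg effect.

Background sequence is i.i.d. uniform over ACGT, which keeps decoy
statistics analyzable but means the benchmark does **not** probe:
isochores or repeat structure, sequencing error profiles, GC/ligation
bias, partially conserved miRNA families, or hairpins with large internal
loops. Passing the synthetic benchmark therefore demonstrates algorithmic
correctness against a known truth, not field performance on real
libraries.

## 9. Problem sizes and runtime

The shipped tests and the acceptance script run the complete pipeline on
the default 50,000-read library (about 1–2 minutes on one CPU), plus
oracle checks at enumeration scale: folds up to 12 nt against exhaustive
structure enumeration (100 sequences), tag matching for ~500 tags against
a 200-entry reference versus brute-force Hamming search, 100
dinucleotide-shuffled hairpin decoys, and duplex energies for 100 random
22-mers against all single-substitution variants. These sizes were chosen
so every stage is exercised end-to-end with fully verifiable expected
values.

## 10. Known limitations

* The energy model is intentionally simple; absolute kcal/mol values are
  not comparable to fitted parameter sets, only to themselves. The −18
  kcal/mol hairpin threshold and the −17 kcal/mol duplex threshold are
  calibrated within this model's scale.
* The translated search is ungapped; frameshifted or intron-containing
  homologies will truncate the approximate CDS.
* `pita_scan()` computes accessibility for the full-miRNA window rather
  than separate seed/3' contributions.
* Multi-mapping tags are counted once (tie-break winner); a flag for
  fractional counting is a possible extension.
* The Kruskal–Wallis module consumes normalized expression values; no
  microarray preprocessing is included.
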
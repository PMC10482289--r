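---
title: "Methods: PPR-RNA code matching and C-to-U off-target analysis with pprcue"
author: "pprcue authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPR-RNA code matching and C-to-U off-target analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprcue)
```

# Scope and model

`pprcue` implements the computational core of heterologous-expression studies
of plant C-to-U RNA editing factors, using the moss mitochondrial factor
PPR56 as its packaged reference case. An editing factor of this class is a
PLS-type pentatricopeptide repeat (PPR) protein: an array of P ("canonical",
35 aa), L ("long") and S ("short") helical repeats ending in a deviant
P2-L2-S2 triplet, followed by TPR-like E1/E2 extension motifs and a DYW
cytidine deaminase that performs the C-to-U conversion. Each repeat contacts
one ribonucleotide; the amino acids at repeat positions 5 and "Last" jointly
encode a nucleotide preference (the PPR-RNA code):

| position 5 | position Last | favored |
|---|---|---|
| T or S | N | A |
| T or S | D | G |
| N | D | U |
| N | S | C |
| N | N | C or U (pyrimidine) |

Any other pair is *neutral*: it contributes neither a match nor a mismatch.
The code applies to P- and S-class repeats only; L-class repeats and E1/E2
are reported `not_scored` under the defaults. Repeats are numbered backwards
from the C-terminus, and the terminal S2-1 repeat is juxtaposed with target
position −4 relative to the edited cytidine, giving the anchoring rule
`target offset = repeat index − 3` (E1 → −3, E2 → −2).

The packaged PPR56 array is
`L-14, S-13NS, P-12NN, L-11MD, S-10TD, P-9TN, L-8VD, S-7TD, P-6ND, L-5LD,
S-4TN, P2-3ND, L2-2VD, S2-1ND, E1(N34), E2(K34)`. The 5/Last identities of
L-14 are not established and are stored as unknown, i.e. neutral. Both
native target windows are packaged over offsets −16..+2, which is the range
that can be established base-by-base from the published single-substitution
mutant series; we deliberately do not extrapolate further upstream sequence.

```{r native}
score_window(ppr56(), native_target_window("nad4"))
```

Both native targets match at 7 of the 9 scored P/S positions: nad4eU272SL
mismatches at −16 and −9, nad3eU230SL at −16 and −6.

## Scoring choices

* **Score** is `n_match − n_mismatch` over scored repeats. We do not encode
  any tie-break that would rank the two native targets against each other:
  under the default P/S counting both score 7/9, and the package treats any
  finer ranking as outside the code.
* **Unknown pairs are neutral, never mismatches** — combinations absent from
  the code table (e.g. the MD, VD, LD pairs typical of L-repeats) carry no
  evidence either way. `N` bases are likewise neutral.
* **Optional E1 scoring** (`score_e1 = TRUE`) treats the E1 position-34
  residue as a PPR-like Last residue using the amino/keto half of the code
  (D → G/U, N → A/C, S → C). This is a speculative extension and off by
  default.
* **Shift convention.** `best_offset()` evaluates shifts `s` in
  `[-max_shift, max_shift]`; positive `s` slides the array toward the
  transcript 3' end (a repeat anchored at offset `o` reads base `o + s`).
  Ties break toward 0, then toward negative `s`, so the unshifted anchoring
  is always preferred when equally good. The default `max_shift = 2` is a
  package choice; the shift window used in the original off-target
  classification is not documented, so this knob is exposed everywhere it
  is consumed.

# Nomenclature

Three grammars are parsed and formatted round-trip:

* **Protein mutations** — `PPR56|DYW:G3A` (domain point), `PPR56|P-6ND>TD`
  (repeat 5/Last shorthand), `PPR56|E1:N34D`. Truncations have no published
  grammar; the package extension `PPR56|trunc:P-12` removes all repeats
  N-terminal of, and including, P-12.
* **Editing sites** — locus + `eU` + 1-based position from the A of the
  start codon (negative = upstream, no zero) + codon change, stop as `*`:
  `nad4eU272SL`, `fdhEeU403Q*`, `folDeU-5`. Synonymous changes would be
  rendered with the repeated letter (`eU123PP`); no such case occurs in the
  packaged data, and the form is a documented extension. Sites outside any
  annotation fall back to `contig:position`.
* **Target substitutions** — lowercase RNA, offset relative to the edited
  base with 0 denoting the edited cytidine itself: `nad4eU272SL|u-4g`,
  `nad4eU272SL|c0u` (pre-edited state). `t` is accepted for `u` on input;
  positive offsets are formatted with an explicit `+`.

Codon consequences use the standard genetic code (the bacterial host
introduces no relevant differences for C-to-U changes); `name_site()` is
oracle-tested against whole-CDS translation. Multi-exon coordinates are
counted on the spliced transcript; no intron-containing case arises in the
bacterial data, so this convention is flagged rather than exercised.

# Off-target calling

`call_offtargets()` consumes per-site, per-dataset base-count tables (one
row per position; JACUSA-style exports map onto the native schema via
`col_map`) and applies, in order:

1. **Orientation** — reference C rows are forward candidates (edited = T
   count), reference G rows reverse candidates (edited = A); A/T rows are
   not transition candidates. Both strands at one position are assessed
   independently.
2. **Four criteria per dataset** — coverage ≥ 30; transition purity
   (edited + unedited)/coverage **strictly** > 0.99; DNA reference purity
   strictly > 0.98 (assumed pure, and flagged, when no DNA counts are
   present); edit fraction edited/(edited + unedited) ≥ 0.01. The strict
   versus inclusive comparisons mirror the stated thresholds ("at least"
   versus ">"). The edit fraction is computed on transition reads rather
   than total coverage; given criterion 2 the two differ by under 1%
   relative, and the choice matches the Sanger `T/(T+C)` quantification.
3. **Replicate rule** — a site is called only if it passes all four
   criteria in ≥ 2 datasets from expression of the same protein. Datasets
   of the same protein with different co-delivered targets count as
   interchangeable replicates.
4. **Control exclusion** — any control dataset (wild-type or other factor)
   showing the site with coverage ≥ 10 and edit fraction ≥ 1% vetoes the
   call. These two thresholds are package choices: the source procedure
   states only "not in wild-type", so both knobs sit in `caller_params()`.
5. **Aggregation** — final efficiency adds reads over the supporting
   datasets: `sum(edited)/sum(edited + unedited)`, identical to the
   coverage-weighted mean of the per-dataset fractions.

The caller is property-tested against a naive nested-loop reference
implementation, for monotonicity under threshold tightening, and for strand
symmetry under reverse complementation. Output tables are byte-deterministic
for identical inputs; coordinates are 1-based and fully closed.

# Weighted profiles

`build_profile()` computes efficiency-weighted nucleotide frequencies over
call contexts (window default −20..+5, configurable; the published logos do
not state their exact extent) and per-offset Shannon information content
`2 + Σ f log₂ f` bits without small-sample correction. Weights multiply
sequence contributions before normalization — the frequency-weighting
interpretation — rather than rescaling stacked column heights; `n` bases
are excluded from numerator and denominator. Calls whose best alignment is
shifted (`best_offset ≠ 0`) are partitioned out by `exclude_shifted()`
before profiling, mirroring the published practice of excluding
shift-requiring off-targets from consensus logos.

# The synthetic experiment

`simulate_experiment()` generates everything the caller consumes, at the
per-site count level (no reads, no alignment):

* **Reference**: one random contig (default 20 kb, GC 0.5) with planted
  contexts — the two native windows verbatim, array-matched sampled windows
  (2 code mismatches by default, matching the native targets' 7/9 fit), a
  quarter of sites on the reverse strand.
* **Evidence**: per-site negative-binomial coverage (mean 200, dispersion
  5 — RNA-seq-like overdispersion; the source gives no coverage
  distribution), uniform substitution errors at rate 0.001 so that
  transitions are *not* privileged and the purity criterion is genuinely
  exercised, binomial editing at the planted efficiencies (default 20 sites
  evenly spread over 0.02–0.99), DNA counts at purity 0.995.
* **Decoys**: one site per filter criterion engineered to fail exactly that
  criterion (coverage capped at 29; transition purity forced to 0.98; DNA
  purity forced to 0.98; efficiency 0.005), plus a single-replicate decoy
  and a control-leak decoy.
* **Seeding**: one seed governs everything; per-dataset streams are derived
  from it deterministically, so outputs are byte-reproducible.

Under these default conditions the caller recovers all 20 planted sites and
calls no decoys and no background positions (seeded assertions in the test
suite; the problem sizes above are the package defaults used throughout).
What passing this does **not** show: real RNA-seq exhibits alignment
artifacts, strand-bias, position-correlated errors and coverage structure
that the per-site binomial model does not emulate — the synthetic recovery
validates the filter cascade's logic, not an error model for any particular
sequencing pipeline. At the 1% signal threshold, background positions can
sporadically pass in two datasets by chance at error rates above the
default; this reflects the permissiveness of the published thresholds
rather than a property of the simulator.

Sanger traces are emulated as peak pairs proportional to `(e, 1 − e)` with
truncated Gaussian noise, quantified as `T/(T + C)`.

# Pipeline and degenerate inputs

`run_pipeline()` chains simulate (optional) → call → profile → scan with a
YAML or in-memory configuration, writes TSV outputs plus a YAML report
(per-stage counts, per-filter rejection counts), and is idempotent for
fixed inputs and seed. Degenerate inputs are handled explicitly: empty
count files parse to empty tables; zero-coverage rows are dropped with a
logged count; windows lacking juxtaposed offsets score `not_scored` rather
than fabricating sequence; contig-edge contexts are `n`-padded; undefined
ratios (no transition reads, both Sanger peaks zero) raise errors rather
than returning NaN.

# Known limitations

* The full-scale published off-target counts (133 / 449 / 16 with their
  shifted splits) depend on the deposited multi-megabyte variant-call
  datasets; `validate_offtarget_summary()` implements that comparison for
  users who convert those tables to the native schema, but the data are not
  packaged.
* No binding-energy model, no structure prediction, no machine-learned code
  extensions; SS/LL repeat classes are treated as neutral.
* U-to-C "reverse" editing labels are out of scope.
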
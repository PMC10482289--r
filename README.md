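# pprcue

Analysis toolkit for plant-type C-to-U RNA editing factors studied in
heterologous expression systems, built around the moss mitochondrial factor
**PPR56**.

Plant organelle editing factors are PLS-type pentatricopeptide repeat (PPR)
proteins: an array of P/L/S helical repeats (ending in a deviant P2-L2-S2
triplet) followed by E1/E2 extension motifs and a DYW cytidine deaminase.
Each repeat faces one ribonucleotide of the target; the amino acids at
repeat positions 5 and Last encode a nucleotide preference (the PPR-RNA
code: T/S+N → A, T/S+D → G, N+D → U, N+S → C, N+N → pyrimidine), and the
terminal S2 repeat is anchored at position −4 upstream of the edited
cytidine, so a repeat with index *i* faces target offset *i* − 3. Expressed
in a bacterium, such a factor edits its native targets and dozens to
hundreds of transcriptome off-targets, which are detected as replicated
C-to-T (or G-to-A on the reverse strand) RNA/DNA differences in per-site
variant-call tables.

The package provides, as tested reusable components:

* **`ppr_code`** — PPR array model (`ppr56()` packaged), code-match
  scoring of target windows, transcriptome scanning for candidate sites
  (including pre-edited T-state scanning), best-shift classification, and
  in-silico protein mutation (`S-4TN>TD`, truncations, E-motif points).
* **`nomenclature`** — parsers/formatters for the protein-mutation, target
  -substitution and `eU` site-label grammars (`PPR56|P-6ND>TD`,
  `nad4eU272SL|u-4g`, `fdhEeU403Q*`), site naming from CDS/GFF3
  annotation, and enumeration of stop/start codons creatable by editing.
* **`offtarget_caller`** — the replicate-supported off-target caller:
  coverage ≥ 30, transition purity > 99%, DNA purity > 98%, edit signal
  ≥ 1%, support in ≥ 2 same-protein datasets, control exclusion, and
  read-sum efficiency aggregation; plus the Sanger `T/(T+C)` quantifier.
* **`profiles`** — editing-efficiency-weighted nucleotide frequency
  profiles with information content, with shifted off-targets partitioned
  out before profiling; TSV export for logo tools.
* **`synthetic_data`** — a fully seeded generator of reference sequences,
  planted editing sites, per-dataset count tables, per-criterion decoys and
  Sanger peaks, so the whole pipeline is testable end to end without any
  external data.
* **`run_pipeline()`** — simulate → call → profile → scan orchestration
  with YAML configuration and a run report (a thin CLI wrapper ships in
  `inst/cli/pprcue.R`).

## Worked example

Score the native nad4eU272SL target window against PPR56:

```r
library(pprcue)
score_window(ppr56(), native_target_window("nad4"))
#> match report: 7 match / 2 mismatch (9 scored), score 5
#>    motif kind target_position observed preference    verdict
#> 1   L-14    L             -17     <NA>            not_scored
#> 2   S-13    S             -16        a          C   mismatch
#> 3   P-12    P             -15        u         CU      match
#> 4   L-11    L             -14        a            not_scored
#> 5   S-10    S             -13        g          G      match
#> 6    P-9    P             -12        a          A      match
#> 7    L-8    L             -11        c            not_scored
#> 8    S-7    S             -10        g          G      match
#> 9    P-6    P              -9        g          U   mismatch
#> 10   L-5    L              -8        u            not_scored
#> 11   S-4    S              -7        a          A      match
#> 12  P2-3   P2              -6        u          U      match
#> 13  L2-2   L2              -5        c            not_scored
#> 14  S2-1   S2              -4        u          U      match
#> 15    E1   E1              -3        c            not_scored
#> 16    E2   E2              -2        u            not_scored
```

Seven of the nine P/S-class repeats match the code (mismatches at −16 and
−9 — the guanosine at −9 facing P-6ND is a known peculiarity of this
target); L-class repeats and E1/E2 are outside the code and not scored.
From here, `apply_ppr_mutation(ppr56(), "S-4TN>TD")` re-targets position −7
from A to G, `design_codon_edits(native_target_window("nad4"))` enumerates
the three stop-codon and one start-codon designs reachable by editing, and
`simulate_experiment(sim_config(seed = 1))` plus
`call_offtargets(...)` runs the full detection cascade on synthetic
evidence with known ground truth.

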
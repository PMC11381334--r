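---
title: "Peptide-barcoded pooled LNP screening: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-barcoded pooled LNP screening: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pals)
```

## The screening problem

In-vivo screening of lipid nanoparticles (LNPs) for mRNA delivery is slow and
animal-intensive when every formulation needs its own dosing group. A
proteomics-based alternative pools many LNPs into one group: each LNP carries
the same therapeutic/reporter mRNA, extended at the 3' end of the ORF with a
short unique peptide barcode. After dosing, the expressed barcoded protein is
recovered, trypsin-digested, and each barcode peptide is quantified by
LC-MS/MS from its extracted-ion-chromatogram (XIC) peak area. The relative
barcode signal, normalized within each animal to a reference barcode, ranks
the LNPs by functional delivery.

`pals` implements the computational side of this platform end to end:
barcode panel design, in-silico verification of tryptic release, reverse
translation of the barcoded protein into a GC-targeted ORF, the relative
quantitation and ranking workflow, and a pooled-screen simulator used both
for power exploration and for testing the quantitation code against known
ground truth.

## Peptide chemistry

All mass computation is monoisotopic. A peptide of residues $r_1 \dots r_n$
has mass $M = \sum_i m(r_i) + m_{H_2O}$, with residue masses stored once in
`residue_mass_table()` ($m_{H_2O} = 18.010565$ Da, $m_{H^+} = 1.007276$ Da;
residue values agree with elemental-composition sums to $10^{-4}$ Da, and
$m(I) = m(L)$ exactly). Precursor ions are $(M + z\,m_{H^+})/z$. Fragments
are the singly-protonated b/y series only — $b_i = \sum_{k \le i} m(r_k) +
m_{H^+}$, $y_j = \sum_{k > n-j} m(r_k) + m_{H_2O} + m_{H^+}$ — which
satisfies the complementarity identity $b_i + y_{n-i} = M + 2 m_{H^+}$ used
as a self-check throughout the tests. Higher fragment series, neutral
losses, isotope envelopes and retention-time prediction are out of scope:
the platform uses MS2 qualitatively, through one diagnostic ion. Every
barcode core carries a proline, and the y ion starting at that proline is
reported as the diagnostic fragment (`fragment_ions()$diagnostic_y`).
Cysteine is unmodified by default with a fixed-modification hook
(`residue_mass_table(fixed_mods = c(C = 57.021464))`); barcodes exclude C by
design, so the default never affects them.

## The design cascade

`design_constraints()` holds every tunable rule. Defaults, with reasons:

| parameter | default | why |
|---|---|---|
| `excluded_residues` | M,W,N,Q,C,R,K,D,E | modification-prone residues (oxidation, deamidation, disulfides) lose MS signal; K/R would add tryptic sites inside the barcode |
| `core_length` | 5 | 11 allowed residues give 11^5 = 161,051 candidate cores, ample for panels of tens |
| `proline_rule` | `exactly_one` | guarantees exactly one predictable diagnostic y ion; also the reading under which the filter keeps a round 50,000 cores (at-least-one keeps 61,051) |
| `n_term_flank`, `c_term_flank` | `GSGSGA` / `AGSGSG` | placeholder constant flanks from the allowed alphabet, K/R-free so digestion releases the barcode intact; every cascade count is flank-independent (constant mass offset) |
| `ms1_min_separation` | 0.01 Da | resolvable on a high-resolution instrument at m/z ~1500; the published tolerance is unstated, hence `calibrate_separation()` |
| `ms2_min_separation` | 0.01 Da | same scale at the fragment level |
| `mz_window` | 350–2000 | typical full-scan range; a panel member must be observable at some considered charge |
| `isolation_window` | 1.2 m/z | co-selection of near-isobaric precursors is reported, not filtered — the acquisition window constrains analysis, not necessarily design |
| `charges_considered` | 1–3 | the charge used for XIC extraction is an acquisition decision; all are exported and the quantitation is charge-agnostic |

`enumerate_cores()` → `filter_proline()` → `assemble_barcodes()` →
`select_panel()` is the cascade. Selection has two modes. `strict_unique`
first collapses every exact-mass class to one representative — necessary
because permutations of one residue composition, and I↔L swaps, are exactly
isobaric, so no 5-mer mass is ever unique without the collapse; the
lexicographically smallest core represents its class — then keeps
representatives at least `ms1_min_separation` from every other.
`max_separated` runs a sort-by-mass greedy sweep, which is provably optimal
for maximum-cardinality selection on a line and is verified against an
exhaustive subset oracle in the tests. All tie-breaks are lexicographic on
the core, so identical constraints give byte-identical panels.

Masses of equal-length cores are computed as residue-count dot products
rather than positional sums, so permutations of one composition are
bit-identical doubles and exact-mass grouping is safe in floating point.

Because the tolerance behind any published panel size is typically unstated,
`calibrate_separation()` exploits the monotonicity of panel size in the
tolerance (asserted property) to bisect for the largest tolerance still
achieving a desired size, and reports the bracketing band and the full
profile rather than asserting a count. Under the defaults the exact-mass
collapse leaves a few hundred composition classes, and the tests verify
that a panel of at least 120 members survives up to a bracketed tolerance
of a few hundredths of a Da.

`build_isobaric_library()` addresses larger screens: candidates are grouped
by precursor mass (single linkage along the sorted mass line within
`ms1_min_separation`); within a group, members are retained greedily when
every retained pair differs in at least one b or y ion by
`ms2_min_separation` (same-position I/L swaps have identical fragment series
and can never co-exist). The retained count across multi-member groups is
reported for comparison; with both tolerances at 0.01 Da it is far larger
than a curated published library would be, consistent with publications
applying additional unstated criteria.

## Digestion and construct verification

`trypsin_digest()` applies the classic rule — cleave C-terminal to K/R
except before P, no Keil exceptions — with optional missed cleavages;
0-based half-open coordinates; the zero-missed peptides concatenate back to
the input (tested as a property on random sequences).
`verify_barcode_release()` closes the design loop: a barcoded construct must
release each annotated barcode as exactly one intact tryptic peptide equal
to its panel `full_peptide`, and carrier peptides within
`ms1_min_separation` of any barcode mass are flagged as interferences. The
barcode sits at the protein C-terminus (preceded by a K), so no trailing
cleavage site is needed; note that if the carrier's own C-terminal
processing (e.g. removal of a terminal arginine in secreted EPO) occurred
*after* the barcode extension it would not apply to the barcoded construct,
but this cannot be settled computationally and is left to the user's
construct annotation.

## Reverse translation and mRNA assembly

`reverse_translate()` picks one synonymous codon per residue targeting a GC
fraction (default 0.62, a common optimization point for IVT mRNA
expression). The optimizer is a per-position greedy with running-deficit
correction: at position $i$ it picks the codon whose GC count is nearest to
the clamped deficit target, ties broken toward lower GC and then
lexicographically. The deficit is clamped into the suffix feasibility
envelope (what the remaining residues can still contribute), which keeps the
final GC within one codon of the nearest feasible value even when the
protein ends in a GC-poor stretch — a plain running-deficit greedy can
otherwise miss a feasible target by several bases. Because every residue's
synonymous GC counts form a contiguous integer range, this scheme makes the
achieved GC monotone in the target (tested as a property). Targets outside
the feasible envelope (`gc_envelope()`) are clamped with a warning.
Round-trip identity is tested against an independent translator
(`Biostrings::translate`). `assemble_mrna()` is deliberately plain
concatenation — UTR5 + ORF + UTR3 + 120-A tail by default — with UTR
sequences user-supplied; secondary-structure and codon-usage optimization
are out of scope. Modified-uridine chemistry affects synthesis, not
sequence, and is not modelled.

## Quantitation and ranking

The measured quantity is a per-animal, per-barcode XIC peak area.
`normalize_to_reference()` divides each area by the same animal's
reference-barcode area, so any animal-level multiplicative factor (delivered
dose, expression capacity, recovery) cancels exactly; the reference maps to
1 in every animal, and animals lacking a usable reference are excluded by
name. `rank_lnps()` averages fold changes per LNP (arithmetic mean ± SD,
matching how such screens are reported) and ranks descending with
average-rank ties; ranking is invariant under any strictly monotone
transform of the fold changes.

LOQ handling: `loq_censor()` substitutes at the LOQ by default (a censored
barcode stays in the ranking as "at most this much"), with halve/exclude
alternatives since censoring conventions differ between labs; the original
values are kept in an audit column. The two platform sensitivity constants
in `loq_reference` (2 fmol/uL peptide LOQ; 0.6 ng/mL protein-equivalent LOQ
for a 30 kDa carrier) are deliberately independent entries: they are not
unit-interconvertible without the full processing dilution, so the package
stores both and `pool_loq_total()` works on whichever the user supplies.

Concordance between two rankings of the same LNPs (e.g. pooled vs
individual, MS vs ELISA) uses `wilcoxon_signed_rank_exact()`: the two-sided
p comes from the exact null of all $2^n$ sign assignments of the ranked
absolute paired differences — accumulated by integer convolution over
doubled ranks, which is arithmetically identical to literal enumeration and
is tested against one — with zero differences dropped and average ranks for
ties. At $n = 5$ the minimal attainable two-sided p is $2/2^5 = 0.0625$: a
"no difference in ranking" report at that p is the strongest statement five
pairs can make. No multiplicity correction is applied anywhere by default.
`method_correlation()` is the squared Pearson correlation.

## The screen simulator

`simulate_screen()` generates peak tables with known ground truth. Expected
signal of LNP $\ell$ at dose $d$ is a Hill curve
$E_\ell(d) = E_{max}\, d^{h} / (ED_{50}^{h} + d^{h})$ — in-vivo protein
output is distinctly nonlinear in mRNA dose and the curve shape is
lipid-characteristic. A measured area is
$E_\ell(d) \cdot A_i \cdot \varepsilon_{i\ell}$ with $A_i$ a lognormal
animal factor (CV `animal_cv`) shared by all barcodes in animal $i$, and
$\varepsilon_{i\ell}$ lognormal measurement noise (CV `ms_cv`), both
mean 1; areas below `loq` are censored at it. Multiplicative lognormal noise
is the natural choice for positive, ratio-normalized data: the shared animal
factor cancels *exactly* under reference normalization when `ms_cv = 0`,
giving a parameter-recovery surface on which the quantitation module is
tested (noiseless fold changes, certain recovery of the true order). No
LNP–LNP interaction is modelled in pools — pooling preserving individual
behavior is the platform's empirical premise — so pooled-vs-individual
agreement in the simulator is a self-consistency property, not evidence
about biology.

Defaults are the study conditions of a typical screen: `n_animals = 5`
(matching `group_size_for_effect(2)` ≈ 4, rounded up in practice to 5 for a
2-SD effect at $\alpha$ = 0.05, power 0.8), a 0.5 mg/kg total pool dose cap
(5 LNPs at 0.1 or 10 at 0.05 mg/kg), `animal_cv = 0.3` and `ms_cv = 0.2`
(typical in-vivo biological and targeted-MS variability; neither is
published for this platform, chosen once), and illustrative Hill parameters
in `default_lnp_models()` spacing adjacent lipid potencies about two-fold at
0.1 mg/kg in the order MC3 > KC2 > C12-200 > DLin-DMA > DOTAP. The
parameters are labelled illustrative, not fitted. All randomness derives
from the single design seed; the RNG state of the session is restored after
simulation.

What the simulator does *not* emulate: saturation of the MS detector,
retention-time drift and integration error structure, inter-barcode
ionization efficiency differences (these cancel in fold-change comparisons
*across arms* but would matter for absolute comparisons *between barcodes*),
carrier-protein pharmacokinetics, and any pool-composition interaction.
Passing tests on simulated data therefore demonstrates the correctness of
the quantitation arithmetic and the internal consistency of the design, not
the biological validity of a real screen.

## Problem sizes and runtimes

The test suite runs the full default cascade (161,051 cores; 50,000
assembled candidates), panel calibration and the isobaric library at full
scale (a few seconds each), Monte-Carlo ranking-recovery at 150–400
replicates, and a 100-replicate pooled-vs-individual concordance check —
about half a minute in total. These sizes were chosen as the package's own
verification scale: large enough to exercise every code path at the real
cascade size, small enough to run routinely.

## Known limitations

- The MS2 distinguishability test compares position-wise b/y series at
  charge 1 only; co-eluting isobaric peptides with chimeric spectra are not
  modelled.
- The digestion model has no efficiency term: a "released" barcode is a
  structural statement, not a yield prediction.
- GC targeting optimizes composition only; a GeneArt-style optimizer also
  handles motifs, repeats and structure, which are out of scope.
- The exact Wilcoxon test enumerates up to n = 20 pairs; beyond that a
  normal approximation (not provided) is standard.
- Default flanks are placeholders; users replicating a specific published
  panel must supply that panel's flank sequences.
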
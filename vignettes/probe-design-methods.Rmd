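---
title: "Designing HCR v3 split-initiator probe sets: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing HCR v3 split-initiator probe sets: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcrkit)
```

This vignette explains the science inside `hcrkit`: the models each stage
implements, the free parameters and why their defaults are what they are,
what the synthetic fixtures do and do not emulate, and the design choices
made where more than one defensible option existed.

## The split-initiator design problem

An HCR v3 probe pair binds two adjacent segments of a target mRNA. Each
oligo is `initiator half (18 nt) + flexible connector (2 nt) + binding arm
(25 nt)`; the binding arm is the reverse complement of its target segment.
Only a correctly co-bound pair juxtaposes the two halves of the 36-nt
amplifier initiator, so single non-specifically bound probes do not
amplify. Five orthogonal initiator systems (B1–B5) allow multiplexing; the
designer attaches whichever the user selects. A design is *sufficient* when
it reaches five pairs — fewer still run, but the tool records a
`FEWER_THAN_MIN_PAIRS` warning rather than failing, because deliberately
small designs are legitimate.

## Targets and exon junctions

Probes spanning an exon–exon junction fail to detect unspliced pre-mRNA,
so junctions must be excluded from tiling. Two input conventions are
accepted and made strictly equivalent: a single FASTA record with `N`
between exons, or one record per exon. Internally a run of one or more `N`
is collapsed to a single masked position; every candidate window containing
a masked position is emitted with the `CONTAINS_N` verdict and never
selected. Equivalence is defined at the masked-position level (the
separator length carries no information), and a round-trip through either
convention reproduces the target. `U` is normalized to `T` (RNA input);
IUPAC ambiguity codes are rejected outright, because an ambiguous target
cannot be tiled into definite oligo sequences. Coordinates are 0-based
half-open internally and 1-based inclusive in every report, which states
the convention in its header.

## Thermodynamic model

The filter scores each 25-nt arm as a DNA:DNA duplex against its perfect
complement with the unified nearest-neighbor model: ΔH° and ΔS° are summed
over stacked pairs plus the two initiation terms, and the two-state melting
temperature is evaluated at the total probe concentration (CT/4 for
non-self-complementary duplexes). Monovalent salt enters through the
entropy correction ΔS° += 0.368·(N−1)·ln[Na⁺]. This correction was chosen
over Tm-level corrections deliberately: it is monotone in [Na⁺] for *every*
sequence, a property the package asserts as an invariant, whereas
quadratic-in-ln[Na⁺] Tm corrections invert for extremely GC-rich oligos
near 1 M. Formamide is applied last as a pure −0.6 °C per percent offset,
which keeps the nearest-neighbor core independently checkable by
brute-force summation (the test suite holds it to within 0.01 °C of a
separately coded oracle).

Defaults mirror the hybridization buffer the probes are destined for:
`na_molar = 0.75` (5×SSC), `formamide_pct = 30`, `oligo_conc_molar = 1e-8`
(10 nM). The acceptance windows — arm Tm in [40, 60] °C after the
formamide offset, GC in [0.35, 0.65], homopolymer runs ≤ 4 — are
conventional single-molecule FISH heuristics, not measurements; every one
is exposed in `thermo_config()` and the configuration file. Whether the
original protocol scores DNA:DNA or DNA:RNA duplexes is not documented
anywhere we could rely on; DNA:DNA was chosen as the testable standard
model, and users comparing against other designers should expect constant
offsets, not different rankings.

## Off-target screening

The screen answers one question per candidate: does its 52-nt window share
a contiguous exact match longer than `max_contig_match` (default 16 nt)
with any transcript other than the target's own isoforms? Contiguous-match
length is a deterministic, oracle-checkable proxy for cross-hybridization
risk — deliberately not a thermodynamic ΔG model (out of scope here).
Matching is sense-strand only: probes are reverse complements of the
target, so only sense-identical segments of another transcript can capture
them. The internal backend indexes every N-free k-mer (default
`seed_k = 15`) of the transcriptome and extends each seed hit to its
maximal match; `seed_k ≤ max_contig_match + 1` is enforced so no failing
match can be unseedable. The whole window is screened rather than each arm,
because a match spanning the 2-nt gap still tethers the probe pair region;
the overlapped arm(s) are recorded per hit. An optional `blastn` backend
(`-task blastn-short`, BTOP-parsed exact stretches) exists for parity with
BLAST-database workflows; the internal screen is the default so designs are
reproducible without external executables. Mismatch-tolerant alignment is a
non-goal of the internal backend.

## Selection

"Distributed along the target with no overlap" admits two readings, and
both are offered. `max_count` (default) maximizes the number of selected
windows subject to ≥ `min_inter_probe_gap` nt (default 2) between
consecutive windows, via the greedy earliest-end scan — provably optimal
for unweighted interval selection, O(n log n), and deterministic with ties
broken toward smaller start. `even_spread` returns exactly
`min(target_pairs, achievable)` windows maximizing the minimum
inter-window spacing, by binary search on the spacing with a greedy
feasibility check. The test suite checks `max_count` cardinality against an
exhaustive search oracle on hundreds of random instances.

## Assembly and the validation contract

With `arm1` the 5'-proximal and `arm2` the 3'-proximal target arm, the
package assembles `oligo_P1 = half_up + conn_up + revcomp(arm2)` and
`oligo_P2 = revcomp(arm1) + conn_dn + half_dn`. The exact vendor layout
(which half rides which probe, the connector identity) is not something we
chose to hard-code as truth: instead, `validate_pair()` is the contract.
It simulates antiparallel hybridization of both oligos onto the window —
locating each oligo's longest contiguous duplex by dynamic programming,
requiring full-arm, mismatch-free, flush binding on the window's two arm
intervals — then reads the unbound tails off the bound complex (the tail
presented at the window's 3' side first, each tail 5'→3', connectors
removed at their duplex-adjacent ends) and requires the read-off to equal
the full initiator. Any layout passing this reconstruction is conformant,
so the convention can be swapped to match vendor-issued designs without
touching the validator; swapped halves or a single mutated arm base fail.
The B1–B5 sequences ship as an editable TSV (`inst/extdata/`), following
the published third-generation amplifier definitions, because users with
vendor-issued sequences must be able to substitute them without code
changes. Connectors default to `AA`/`TT` and are validated only for
alphabet.

## Colocalization statistic

Two spot sets (coordinates in nm; anisotropic pixel data are scaled
per-axis at load, there is no anisotropic metric) are compared by neighbor
existence: a spot counts as colocalized when its nearest neighbor in the
other set is strictly within the radius (default 750 nm, matching the
strict inequality of the criterion it implements; a `strict_less = FALSE`
toggle gives ≤). The two directions are independent statistics — neighbor
existence, not one-to-one matching, which is why the two percentages can
differ even with equal pair counts. Search uses a uniform-grid spatial hash
with cell size equal to the radius (27-cell neighborhoods), which is exact:
tests assert identity with the all-pairs computation up to 500 spots.
Because it is not stated whether published percentages of this kind are
averaged per sample or pooled, `summarize_samples()` emits both
aggregations, along with mean counts and the relative percent difference
`100·(mean_A − mean_B)/mean_B` (reported as unavailable when the
denominator is zero).

## Synthetic fixtures: what they do and do not show

The generators are pure functions of a `fixture_spec()` (seed included):

* **targets** — uniform-composition random exons (GC 0.5 by default, so
  thermo-filter pass rates are predictable; a composition parameter exists
  for skewed targets), emitted in both junction conventions with a truth
  record of exon bounds;
* **transcriptomes** — random decoys plus verbatim planted copies of target
  segments; the truth record computes, by interval arithmetic alone, the
  window starts whose plant overlap exceeds the failing threshold;
* **spot fields** — `n_shared` positions duplicated into both fields with
  independent per-axis Gaussian jitter (the standard localization-error
  model) plus exclusive spots, uniform in a cube; the truth record carries
  the implied directional expectations.

Passing tests on these fixtures demonstrates algorithmic correctness —
complete tiling, junction safety, exact off-target recovery, optimal
selection, pair validity, exact neighbor counting — not biological
performance. Real transcriptomes have repeats, paralogs and biased
composition the uniform decoys lack; real spot fields have density
gradients and detection artifacts the uniform cube lacks. The planted
shared fraction is recovered only to within binomial noise plus a small
excess from chance proximity of exclusive spots (at 400 spots in a
(20 µm)³ box and 750 nm radius, roughly 9 % of exclusive spots have a
chance neighbor; the recovery tests use three binomial standard errors,
which covers this at the tested sizes).

## Numerical and degenerate-input choices

Melting temperatures are deterministic to floating-point rounding; duplex
symmetry Tm(s) = Tm(revcomp(s)) is exact because the parameter table is
symmetric under reverse complement. Selection ties break toward the
smaller start coordinate; serialization rounds annotations to four
decimals so that identical runs are byte-identical (asserted end to end
through the command layer). Empty inputs are contracts, not crashes: an
empty passing set yields an empty pair list with `NO_CANDIDATES` and a
probe-map summary that says so; an empty spot file is a valid zero-spot
set; fractions over empty sets are reported as missing rather than zero.
Targets shorter than one window, records shorter than the seed length,
duplicate transcript ids, non-nucleotide characters (with record and
position), NaN spot coordinates (with row number) and unknown
configuration keys (with a nearest-key suggestion) are all named errors.

Problem sizes in the shipped tests and the acceptance script — targets of
0.3–2 kb, transcriptomes of a few decoy kilobases, spot fields of 400–500
points, hundreds of randomized oracle instances — were chosen so the whole
suite re-runs in well under a coffee break on one core while still
exercising every code path against its oracle; all generators scale to
realistic transcriptome sizes by parameter.

## Known limitations

No secondary-structure (hairpin/dimer) screening of the assembled oligos;
no thermodynamic off-target scoring; no RNA:DNA nearest-neighbor
parameters; no mismatch-tolerant internal alignment; no isoform-aware
sequence extraction (the user supplies the transcript sequence and the
isoform ids to exempt from screening); no spot *detection* — the
colocalization module consumes coordinate tables produced by an image
pipeline. Hairpin (H1/H2) design and multi-initiator barcoding are out of
scope. The order sheet is CSV only (with the 96-well plate column
included); spreadsheet export would need a writer dependency this package
deliberately does not carry.
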
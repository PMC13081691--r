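---
title: "Methods: confidence scoring and interface triage of predicted complexes"
author: "ppitriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confidence scoring and interface triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppitriage)
```

## The problem

A prediction screen of candidate protein–protein interactions — say, a panel
of lipid-transfer proteins against phosphoinositide phosphatases — produces
hundreds of complex models, each with a predicted aligned error (PAE)
matrix, per-residue pLDDT and pTM/ipTM summaries. Raw ipTM ranks models but
conflates chain-level and interface-level quality, is sensitive to
disordered tails, and disagrees across predictors. The triage protocol this
package implements combines several partially independent readouts —
summary-score ranking, PAE-kernel interface scores, a
coordinate-plus-pLDDT docking-quality estimate, cross-model interface
convergence, and biological plausibility flags — and only trusts a pair when
they agree.

## Confidence metrics

**Weighted ranking score.** `0.8·ipTM + 0.2·pTM`, read from the predictor's
own summaries (the package never re-derives whole-complex pTM/ipTM). Bands:
`> 0.80` high, `(0.60, 0.80]` intermediate, `(0.40, 0.60]` permissive-pass,
`≤ 0.40` fail. The screen's retention filter uses the permissive 0.40 line
to maximize sensitivity; the price is paid later by the other criteria.

**ipSAE family.** For direction A→B, residue *i* of chain A collects
`S_i = {j ∈ B : PAE(i,j) < c}` with `c = 15 Å`, and scores
`mean_{j∈S_i} 1/(1 + (PAE(i,j)/d0)²)`. The direction score is the best
residue (`0` exactly when every `S_i` is empty), and the reported pair score
is the max of both directions; both directions are always recorded. The
variants differ only in the `n` fed to
`d0(n) = max(1, 1.24(n−15)^{1/3} − 1.8)`:

* `ipsae` — `|S_i|` per residue;
* `d0chn` — the summed chain lengths `L_A + L_B`;
* `d0dom` — the number of residues of either chain with *any* interchain
  PAE under the cutoff, computed per direction from that direction's PAE
  block. `d0dom` is the headline variant for cross-pair comparison because
  it normalizes by interface participation, not chain length, so long
  disordered regions cannot dilute the score.

Numerical choices: the inequality is strict (`PAE < c`; ties at exactly the
cutoff are excluded), the `d0` floor is 1.0 (the raw cube-root expression is
negative or undefined for small *n*; the floor choice only matters for
interfaces of a few residues), and `d0` uses a sign-aware cube root so the
formula is defined for all `n ≥ 1`. Both the PAE cutoff and the companion
inter-residue distance cutoff default to 15 Å; the stricter 10 Å
recommendation is one config key away (`scoring_config(pae_cutoff = 10)`).
Bands: `< 0.20` false-like, `> 0.40` true-like, otherwise indeterminate.

**pDockQ.** `0.724/(1 + exp(−0.052(x − 152.611))) + 0.018` with
`x = ⟨pLDDT over contact residues⟩ · ln(n_contacts)` and contacts defined as
interchain Cβ–Cβ (Cα for glycine) distances `≤ 8 Å`. Zero contacts return
the floor 0.018. These are the original single-interface constants with the
natural logarithm; the multi-interface successor (pDockQ2) is intentionally
out of scope. Bands: 0.23 acceptable, 0.49 medium, 0.80 high; note the
formula's ceiling is 0.742, so the "high" band is unreachable by this
variant — it is kept for compatibility with the published banding.

**Masked interface pTM.** An ipTM-style score restricted to residues in
actual contact: the interface set `I` collects residues with any interchain
heavy-atom distance `≤ 8 Å`; the score is the best per-residue mean of the
TM kernel over interchain pairs within `I`, with `d0 = d0(|I|)`, maximized
over direction, and 0 for an empty interface. This is a deliberate
coordinate-contact approximation of the distogram-weighted actifpTM —
predictors do not expose distograms, so the contact-probability weighting is
replaced by a hard coordinate mask. Outputs label it
`masked_iptm(actifpTM-approx)` to keep the distinction visible. Bands:
`> 0.70` reliable, `[0.60, 0.70]` intermediate, `< 0.60` low.

## Interface analysis

Residue-level interfaces for sharing analyses use a PISA-like minimum
heavy-atom distance of 5.0 Å — deliberately separate from pDockQ's 8 Å Cβ
contacts, because the two cutoffs serve different formulas. The choice of
5.0 Å for "interacting residues" in shared-fraction statements is a
documented default; published shared-interface percentages rarely state
their cutoff, so shared fractions are reported both as a symmetric Jaccard
index and as the directional `|∩|/|interface₁|` reading.

Domain trimming removes residues outside annotated ranges and slices the
PAE matrix and pLDDT to the survivors in their original order — it never
re-predicts. Residues keep their author numbering after trimming (an
index like 317 still refers to residue 317 of the full-length protein),
which keeps annotations and selections valid; internally, global matrix
indices are contiguous 1-based positions in chain order (the natural R
convention; user-facing output is always chain id plus author residue
number).

Membrane proximity flags residues with any atom within 3.5 Å of the upper
leaflet plane (`|z − z_upper| ≤ 3.5`), assuming the model was externally
oriented with the membrane normal along z. Only the upper (cytosolic)
leaflet is tested by default, matching the single-leaflet highlight
convention of membrane-embedding figures; `both_leaflets = TRUE` adds the
lower plane.

## Interface similarity and networks

The superposition-free interface lDDT asks whether two models place the
same residues at the same inter-chain distances, without any global
superposition. With model A as reference, all interchain atom pairs
(backbone N/CA/C/O plus CB) within 15 Å are mapped into model B through a
residue mapping; the preserved fraction (`|d_A − d_B|` under 0.5, 1, 2, 4 Å)
is averaged over the four tolerances, and the edge value is the mean of the
two directions. These are the conventional lDDT parameters; the atom set of
specific clustering tools is not published, so cross-tool values are
expected to correlate rather than match to the second decimal. Pairs with
unmapped atoms are excluded from numerator and denominator and surface as a
coverage statistic; a direction whose reference has no qualifying pairs is
undefined and omitted, and a comparison undefined in both directions is an
error — deliberately distinct from a score of 0.

Cross-paralogue mappings come from global BLOSUM62 alignment (gap open 11,
extend 1), chains paired greedily by alignment score with identical
sequences short-circuited to the identity mapping. Only aligned positions
enter the mapping, mirroring the domain-trimming logic: length differences
between paralogues should not dominate the comparison. A chain pair that
aligns with non-positive score is still mapped but triggers a warning —
the comparison is then between likely non-homologous chains and the
percent identity (reported as identities over alignment length) makes the
unreliability visible.

Networks retain edges at interface lDDT `≥ 0.80` (configurable), keep
isolated nodes, and define clusters as connected components — the minimal
deterministic reading of "groups of complexes with similar interfaces";
components are ordered by their smallest member id for reproducibility. A
greedy density-based alternative was considered and rejected: at desk scale
the thresholded components are identical and auditable.

## The screen

`run_screen()` scores each manifest row's first chain pair and applies the
filters in a documented order: weighted `> 0.40`, then pDockQ `≥ 0.23`.
The two retention filters commute — the retained set is order-independent —
but the recorded exclusion reason is the first failing filter. ipSAE bands
are recorded, never exclusionary on their own: an interface-local score
should inform, not veto, a permissive screen. Rows that fail to parse are
logged and recorded as failed; one bad model never aborts a screen.
Replicated predictions enter as separate rows and the best-by-weighted
replicate represents a pair within each method (predictor pipelines do not
publish their aggregation rule; best-of is the convention used for model
selection by the predictors themselves).

Two plausibility tri-states accompany every record. Localization
compatibility consults a user-supplied protein→compartment table: sets that
intersect are compatible, and otherwise both proteins must expose a
cytosol-facing surface (cytosol, ER, PM, Golgi, outer mitochondrial
membrane, endosome); the ER lumen and other topologically isolated
compartments are incompatible with cytosolic partners; any unannotated
protein yields "unknown". Membrane plausibility flags "no" when the scored
interface engages an annotated transmembrane segment while a membrane frame
is supplied — implausible geometries are flagged, never auto-excluded,
because a wrong TM annotation should not silently delete a record.
Consensus support finally requires retained models of a pair from at least
two methods to fall in the same similarity cluster, tiered three > two >
one.

## Synthetic data: what it emulates, and what it does not

The generator builds each chain as an idealized α-helix (rise 1.5 Å, twist
100°, Cα radius 2.3 Å, N/CA/C/O/CB atoms on fixed cylindrical offsets) and
docks chains at a requested closest approach (4.5 Å by default). Confidence
is fabricated with the statistical structure the analysis assumes: PAE is
`pae_intra_base` (2 Å) within chains and `pae_inter_base` between chains
plus independent Gaussian noise on (i,j) and (j,i) — no symmetrization,
matching real predictor output — clipped to [0, 35]; pLDDT is
`plddt_base = 90` plus noise; and pTM/ipTM follow a monotone map of
`pae_inter_base` (`iptm = clip(1.1·e^{−pae/8}, 0, 0.95)` plus jitter), a
fixture convention documented as non-physical. Default chain lengths are
400 + 300 residues, the scale of a lipid-transfer-domain/phosphatase dimer.
Everything is deterministic under the spec seed.

Screen fixtures sample the two classes the filters are meant to separate:
true-like pairs draw `pae_inter_base ∈ [2, 6]` with ipTM in (0.62, 0.92);
false-like pairs draw `pae_inter_base ∈ [20, 30]` with ipTM in (0.05,
0.28). ipTM is sampled directly here rather than through the monotone map
so the two classes sit unambiguously on either side of the weighted filter.

What passing tests on these fixtures shows: the formulas, slicing,
bookkeeping and filter logic are correct, deterministic, and agree with
independent brute-force implementations. What it does not show: behavior on
real folds — the generator has no side chains beyond CB, no correlated PAE
error structure, no MSA-depth effects, no disordered regions, and its
pTM/ipTM are decoupled from geometry. Conclusions about real screens rest
on the formulas being faithful, not on the fixtures being realistic.

## Problem sizes and runtime choices

Test and example sizes were chosen so the whole suite runs comfortably on a
laptop: oracle equivalence uses 100 random two-chain PAE fixtures of 3–40
residues per chain; lDDT oracle checks use 20+20-residue dimers;
cluster-recovery uses 3 pose groups × 5 models of 30+25 residues over 20
seeds; the screen fixture uses 24 pairs of 120+100-residue dimers. All
scale linearly (PAE memory quadratically) to real model sizes.

## Known limitations

* The masked interface pTM is a coordinate-mask approximation of actifpTM;
  values are comparable in spirit, not numerically identical to the
  distogram-weighted original.
* pDockQ uses the single-interface constants; multi-interface assemblies
  should be scored pairwise.
* ipSAE is defined for chain pairs; no global score is produced for
  assemblies of three or more chains (pairs are scored independently).
* The AF3-server dialect reduction keeps exactly one protein token per
  residue and drops ligand/ion tokens; modified residues represented as
  multiple tokens are collapsed to their first token. Whether upstream
  scripts consumed token- or residue-level PAE is not documented anywhere
  we could find; this reduction is this package's explicit contract.
* Membrane orientation is taken as given (normal along z); the package does
  not compute it.
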
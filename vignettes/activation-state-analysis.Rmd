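---
title: "Activation-state analysis of GPCR structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation-state analysis of GPCR structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrstate)
```

## The problem

Class A G protein-coupled receptors transduce signals through a global
conformational change: the cytoplasmic end of TM6 swings outward and TM7
distorts, opening the G-protein binding site. In most receptors the
connector region relaying the extracellular signal to the cytoplasmic
side contains the conserved P5.50-I3.40-F6.44 microswitch. Cannabinoid
receptor 1 (CB1) conserves none of the three (it carries L5.50, V3.40,
L6.44), and its activation instead involves an unusually large
rearrangement: the side chains of F3.36 (F200) and W6.48 (W356) exchange
positions — the "twin toggle switch" — while TM1/TM2 move inward and the
N-terminus leaves the orthosteric pocket.

This package implements the measurements used to characterize that
mechanism on coordinates (single structures or frame series): named
distance indicators of activation state, a per-frame classifier of the
toggle-switch configuration with an active-configuration ratio,
residue-residue contact scores (RRCS) with |ΔRRCS| ranking across
receptors, 7×7 per-helix RMSD matrices, and a P-I-F motif scan. A
deterministic synthetic-receptor generator supplies ground-truth test
data, so every stage is verifiable without structure downloads.

## Activation indicators

An indicator is a distance between two endpoints, each either a named
atom of a generically numbered (Ballesteros-Weinstein) residue or the
centroid of a side-chain benzene ring. The built-in CB1 set
(`builtin_cb1_indicator_set()`):

| indicator | endpoints | inactive | active |
|---|---|---|---|
| Y5.58-Y7.53 | Tyr294 OH — Tyr397 OH | 10.5 Å | 3.4 Å |
| TM3-TM6 | Arg214 CA — Ala342 CA | 8.2 Å | 13.8 Å |
| TM2-TM1 | Phe174 CZ — Ala120 O | — | — |
| TM2-TM7 | Phe174 CZ — Ala380 O | — | — |
| NT-F3.25 | ring centers Phe102 / Phe189 | — | — |
| NT-ECL2 | ring centers Phe102 / Phe268 | — | — |

Reference distances are attached only where measured on the deposited
structures; the N-terminal indicators carry no active-state reference
because the N-terminal phenylalanine is unresolved in the active
structure, and a structure lacking that residue yields a flagged missing
value rather than an error. "Main-chain O" is the backbone carbonyl
oxygen; Tyr's hydroxyl oxygen ("O-eta") is the PDB atom `OH`, handled by
a small alias table.

`call_state()` labels a frame active-like or inactive-like when the
indicator is within a tolerance (default 1.0 Å, configurable) of the
corresponding reference, with the nearer reference winning when both
match and an exact tie falling to `intermediate`. The default was chosen
as roughly a third of the smallest inactive/active reference gap in the
CB1 set (5.6 Å for TM3-TM6), separating the two wells with margin while
tolerating thermal-scale coordinate noise.

A separate measurement, `toggle_ca_displacement()`, superposes the
active structure onto the inactive one using the TM3 CA atoms and
reports how far the 6.48 CA moved — 6.8 Å between the CB1 inactive and
active structures. The TM3 residue range used for the alignment is an
explicit input (the published analysis does not print it); comparisons
with published values are made at their printed precision (one decimal).

## The twin toggle switch classifier

Each frame is reduced to a `toggle_observation`:

* chi1 of residue 3.36 and chi2 of residue 6.48 (IUPAC sign convention;
  all angle arithmetic wraps at ±180°). The convention matters only for
  consistency — the classifier measures its centroids from the same
  code path that measures frames.
* `pos_reversed`: after TM3 alignment onto the inactive reference, the
  order of the two side-chain positions along the reference axis (the
  inactive 6.48-to-3.36 direction). Positions are anchored at the CB
  atom, which tracks where the residue sits independently of its
  rotamer — the defining feature of the "reversed-inactive"
  configuration is inactive *rotamers* at still-exchanged *positions*,
  so the positional feature must not move when chi changes.
* `ca_slide_648`: the displacement of the frame's 6.48 CA from its
  position in the active reference (both TM3-aligned onto the inactive
  reference). An inactive frame shows the full 6.8 Å; an active frame
  shows 0.

Classification matches (chi1, chi2) to the nearest centroid within an
angular window under the L-infinity torus metric (square acceptance
regions, matching the rectangular rotamer wells seen in chi-chi scatter
plots). Centroids are measured from the reference structures at table
construction rather than hard-coded; the `pushed` centroid — the novel
W6.48 rotamer — defaults to the inactive chi2 displaced by +120° (one
rotameric step) with the active chi1. A match to the inactive centroid
splits on `pos_reversed` into `inactive` versus `reversed_inactive`.
When no centroid matches but chi1 is still active-like and the 6.48
main chain has slid beyond a threshold, the frame is `sliding`;
anything else is `unassigned`. The rule is total and deterministic.

Defaults: window 40°, slide threshold 2.0 Å. Canonical side-chain
rotamer wells are ~120° apart, so a 40° half-width separates adjacent
wells with a 40° dead zone; 2.0 Å is below half the full 6.8 Å slide but
well above coordinate noise. The boundaries between `pushed`, `sliding`
and `reversed-inactive` are only ever shown graphically in published
density panels, so these defaults are declared package choices, not
fitted values, and all of them are configurable.

`active_ratio()` pools frames across runs by default (a per-run average
is available via `per_run_average = TRUE`); in the study design this
statistic is near 1 for full agonists, around 0.85 for partial agonist /
neutral antagonist / apo, and 0 for inverse agonists.

## Contact scores and the 7×7 matrix

RRCS sums, over heavy-atom pairs of two residues, a piecewise-linear
score: 1 at or below `d_full`, 0 at or beyond `d_zero`, linear between.
Defaults follow the published parameterization of the method
(`d_full` 3.23 Å, `d_zero` 4.63 Å); for residue pairs within 4 positions
on the same chain the backbone atoms N/CA/C/O are excluded so the score
reflects side-chain packing. Occupancy weighting is not applied — the
reader resolves alternate locations to a single conformer (highest
occupancy, ties to altloc "A") — and hydrogens never score. |ΔRRCS| of
the 3.36/6.48 pair between inactive and active structures quantifies how
much the toggle interaction changes upon activation;
`rank_receptors()` orders receptors by it (descending, ties broken
lexicographically by id).

The 7×7 matrix aligns one TM helix (row) by Kabsch superposition of its
CA atoms and measures every helix's CA RMSD (column) under that single
transform — no per-column refit, which is why the diagonal is each
column's minimum. CA pairing is by residue number within the segment
ranges; residues unresolved in either structure are dropped
symmetrically with a warning (deposited models differ in resolved
termini). `movement_profile()` counts off-diagonal entries above a
threshold: distributed inter-helical movement (the CB1 pattern) gives a
high count, movement confined to one helix a low one.

## The synthetic receptor generator

`build_bundle()` constructs a seven-helix bundle with CB1-like residue
numbering: ideal α-helical CA traces (1.5 Å rise, 100°/residue) on a
circle of radius 11 Å, backbone N/C/O placed on the same helical
parametrization, and side chains built from internal coordinates
(natural-extension placement), so chi targets are exact by construction
with no rotamer-library dependency. Marker side chains exist where the
indicators need them; all other residues are alanine-like.

Per-state geometry is solved in closed form so the six indicators
reproduce their configured targets exactly:

* TM6 is placed so the 3.50/6.34 CA distance equals the inactive
  target; its halves are hinged at residue 350 (the kink at the
  conserved CWxP region of real receptors). Upon activation the
  cytoplasmic half splays along the 3.50-6.34 line to the active
  target, while the extracellular half slides exactly 6.8 Å along the
  6.48-to-3.36 axis, exchanging the toggle positions. A single rigid
  TM6 cannot do both — the splay direction necessarily points away from
  TM3 — which is the same reason real receptors kink.
* TM5 translates along the hydroxyl-oxygen axis to set Y5.58-Y7.53.
* TM2 and the N-terminal probe residue are placed by a closed-form
  two-sphere intersection (nearest solution to the base position) to
  satisfy their two distance targets simultaneously.
* Toggle side chains are rebuilt at the state's chi targets
  (F3.36 chi1: -175° active / -65° inactive; W6.48 chi2: 95° in both
  states — the tryptophan keeps its rotamer, as in the deposited
  structures).

Targets without published values (TM2-TM1 8/11 Å, TM2-TM7 7/10 Å,
NT-F3.25 6/18 Å, NT-ECL2 5.5/20 Å, inactive/active) were chosen once as
field-plausible pocket- and insertion-scale distances: the two pocket
indicators shrink upon deactivation (the deactivation trajectories show
TM2-TM1 approaching its inactive value from above) and the N-terminal
probe is inside the pocket only in the inactive state. Every build is
verified post hoc against its targets at 0.05 Å.

`generate_trajectory()` holds scheduled states, bridges different
states by linear Cartesian interpolation, and adds i.i.d. Gaussian
coordinate noise; identical seeds give bit-identical output, and the
ground-truth table records per-frame labels and scheduled transition
midpoints. `generate_toggle_frames()` poses frames at each
configuration's canonical geometry with jitter applied directly to the
toggle chi angles (the direct-jitter mode used for classifier tests);
the `sliding` pose puts the TM6 extracellular half at half slide.

What the generator emulates: the marker geometry of the two activation
states, rotamer wells, state transitions, and coordinate noise. What it
does not: packing and sterics, a force field, lipids/water, correlated
thermal motion, or the kinetics of microsecond trajectories. Passing
tests therefore demonstrate the *measurement machinery* is correct on
geometry with known answers — not that the biological conclusions of
any particular simulation would be reproduced. The published ratio
values (≈1 / ≈0.85 / 0) depend on microsecond dynamics that are not
rerun at desk scale; the analysis scripts instead verify the statistic
on frame mixtures with known composition.

## Numerical choices

* Kabsch superposition corrects improper rotations by flipping the
  smallest singular vector, so reflections are never returned;
  collinear point sets are rejected.
* Dihedrals use the IUPAC sign convention; torsions are invariant under
  atom-order reversal (and negate under reflection) — a property the
  tests assert.
* Angle comparisons always use wrapped differences; the wrapped range is
  (-180°, 180°].
* PDB coordinates round-trip at the format's 3-decimal grid; structures
  with coordinates outside the fixed-width field are rejected rather
  than silently truncated. Residue numbering is never changed silently;
  insertion codes are part of the residue key.
* Degenerate classifier inputs never raise: `unassigned` is the total
  fallback. Alanine at either toggle position raises a mutant-detected
  condition, since chi classification is meaningless for the
  F200A/W356A double mutant.

## Problem sizes

The test suite and the acceptance script use the synthetic bundle
(about 1100 atoms), trajectories of 10-100 frames, and 500 posed frames
for classifier-recovery checks; these sizes give stable statistics for
every property tested while keeping a full run in the tens of seconds.

## Known limitations

* PDB input only (no mmCIF); generic numbering is supplied as a map,
  never inferred from sequence.
* The multi-chain case requires an explicit chain selection; nothing is
  guessed.
* The classifier's default centroids come from the supplied reference
  structures; with references whose rotamer wells differ from CB1's the
  window may need adjusting.
* RRCS is reported per labeled pair; no receptor-wide contact-map scan
  is included.
* The synthetic generator is a geometric fixture, not a physical model;
  see above for what that implies about test coverage.
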
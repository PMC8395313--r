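---
title: "Methods: amphipathicity metrics, helicity assignment, and binding-mode classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amphipathicity metrics, helicity assignment, and binding-mode classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helimode)
```

`helimode` packages the computational side of a peptide–membrane binding
study: sequence-level amphipathicity metrics, coordinate-level helicity and
membrane-geometry metrics, and a classifier that turns the resulting time
traces into one of three membrane binding modes. This vignette records the
models, the tunable parameters, the numerical choices, and what the
synthetic test data do and do not establish.

## Sequence amphipathicity

Residues are scored on the Fauchère–Pliska octanol/water partition scale
(stored to the two decimals at which it was published; Gly = 0.00). For a
window of width $w$ (default 11 residues) starting at position $j$,

$$\langle H \rangle_j = \frac{1}{w}\sum_{k=0}^{w-1} H_{j+k}, \qquad
\mu_{H,j} = \frac{1}{w}\left|\sum_{k=0}^{w-1} H_{j+k}\, e^{\,i k \delta}\right|,$$

with $\delta = 100^\circ$ of azimuthal twist per residue, the ideal
α-helix value. The whole-sequence summaries are arithmetic means of the
per-window values over all $L - w + 1$ contiguous windows; a sequence
shorter than the window is scored as a single whole-sequence window. This
"average over 11-residue windows" convention is the one used by
HELIQUEST-style property calculators, and it is the convention under which
the bundled five-peptide panel reproduces its published property table to
two decimals (asserted in the test suite).

Two interpretation points came up while validating against the published
values for the LL-37 segments, and are worth recording:

* The segments conventionally labelled 13–24 and 25–36 of LL-37 reproduce
  their published $\langle H\rangle/\mu_H$ values only when scored as the
  *single 11-residue windows* 13–23 and 25–35. Scoring 12-mers (one or two
  windows) changes $\mu_H$ in the second decimal. `pep_segments()` takes
  explicit 1-based intervals, so either reading is available; the tests
  assert the 11-mer reading, which matches all six published segment
  values exactly.
* Net charge uses integer counting: K/R +1, D/E −1, His 0 (neutral pH,
  no pKa model), +1 for a free N-terminal amine, 0 for an amidated
  C-terminus and −1 for a free acid. This reproduces the published
  charges of the four short amidated peptides. For LL-37 the convention
  gives +7 when amidated and +6 as the free acid while the literature
  commonly lists +6 with amidation stated; both variants are exposed via
  the `amidated` flag and the package takes no position on the peptide's
  actual terminal chemistry.

Rounding for comparison against two-decimal published tables uses
half-up rounding (`round_half_up()`), not banker's rounding.

## Helicity from coordinates

Secondary structure is assigned with the Kabsch–Sander hydrogen-bond
criterion. Amide hydrogens are always reconstructed from geometry — 1.0 Å
from N opposite the previous residue's C→O direction; residue 1 and
prolines get none — so that assignment is deterministic regardless of
whether the input carries hydrogens. The bond energy

$$E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})
\ \text{kcal/mol}$$

is evaluated in Å (package-internal coordinates are nm; the conversion
happens at this one boundary), with a clash guard rejecting any of the
four distances below 0.5 Å. A bond is called at $E < -0.5$ kcal/mol; a
4-turn at $i$ is a bond from the amide of $i{+}4$ to the carbonyl of $i$;
a residue is α-helical when covered by two consecutive 4-turns. The
alphabet is reduced to {H, T, C}: the source analysis counts only
α-helicity, so 3₁₀/π helices and strands are deliberately not
distinguished (a strict-α choice; switching to counting 3₁₀ as helical
would require relaxing the two-consecutive-turns rule, which we do not
do). Helicity is $\#H / (L-2)$ because the two terminal residues cannot
satisfy the turn pattern and are inherently coil.

## Membrane geometry

The bilayer is assumed flat with its normal along z, matching both the
simulation setup the metrics derive from and the synthetic generator; no
curvature handling, and no unwrapping of periodic boundaries (inputs must
be whole-molecule). Phosphorus atoms are split into leaflets by sign
against their median z (ties to the lower leaflet; input with all P within
0.5 nm of the median is rejected as one-sided). The peptide–surface
distance is $|z_{\mathrm{COM}}(\text{peptide}) -
z_{\mathrm{COM}}(\text{nearer leaflet P})|$ with real atomic masses;
whether hydrogens enter the COM is a toggle (`include_h`, default TRUE —
the source definition says "peptide atoms" without excluding them; at the
trace level the difference is far below the 0.1 nm tolerances used
anywhere). Ties between leaflets go to the upper one.

Helix tilt is the angle between the fitted axis and z folded to
$[0^\circ, 90^\circ]$ — $0^\circ$ upright (antenna), $90^\circ$ lying
(carpet) — so it is invariant to axis sign. The axis is the principal
component of CA positions, oriented N→C. Which CAs enter matters: the
assignment labels the geometrically-helical terminal residues as coil by
construction, so the tilt measurement expands each H-run by one residue on
both sides (falling back to all CAs when fewer than five remain). Without
the expansion, the fitted axis of a short helix is biased by up to ~6°
against the axis the generator posed, an artifact of the label convention
rather than of the geometry.

Per-residue insertion depth is the signed z distance of the side-chain
centroid (the SC pseudo-atom; CA for glycine) from the nearer leaflet's
P-COM plane, negative below the phosphate plane, i.e. toward the membrane
interior (the sign flips accordingly for the lower leaflet). Exponential
smoothing $y_t = \alpha x_t + (1-\alpha) y_{t-1}$ is available on all
traces; the default $\alpha = 0.05$ is a package choice (the source
analysis states exponential averaging without a constant) and is recorded
in every trace file header.

## Flow-LD band signs

For a helix on a shear-aligned membrane, the π→π* component near 210 nm is
polarized along the helix axis and the n→π* transition near 222 nm
perpendicular to it. With $\gamma$ the angle between a transition moment
and the membrane normal, the band sign follows $1 - 3\cos^2\gamma$;
averaging the perpendicular moment azimuthally about the axis gives
$f_{222} = -f_{210}/2$ exactly, so the two signs are always opposite or
both zero. Signs are reported as 0 within ±1° of the magic angle
($54.74^\circ$). Only signs are predicted: the magnitude requires the
flow cell's orientation parameter, which is out of scope.

## Binding-mode classification

The classifier consumes the final third of the trajectory (a window with
at least 20 frames; shorter inputs are rejected) and evaluates, in order:

| call | gate |
|---|---|
| unbound | bound fraction (distance < 1.2 nm) below 0.5 |
| I | mean helicity ≥ 0.6 and median tilt ≥ 60° |
| II | mean helicity in [0.2, 0.6) and some residue's mean depth < −0.1 nm |
| III | mean helicity ≥ 0.6, median tilt < 45°, COM above the phosphate plane, and one of residues 1–3 anchored below it |

The source observations are qualitative ("highly helical", "partially
helical", "perpendicular to the surface"), so these cuts are package
defaults, collected in `mode_thresholds()` and chosen to separate the
three regimes cleanly on the synthetic reconstructions. When no gate fires
the nearest rule by normalized slack margin is reported with
`low_confidence = TRUE`; classification is total on valid input. The
azimuth circular variance (the antenna mode's "swing") and the projected
footprint are reported as evidence but are not gates — the swinging is
demonstrated only in simulation, and mixture populations (two coexisting
orientations) are out of scope: a single mode is always called, with the
evidence scores available for inspection.

## The synthetic generator

No deposited peptide–bilayer trajectories exist for this system, so all
structural test inputs are fabricated, at toy scale, by
`generate_mode_trajectory()`:

* backbones are built by forward kinematics from canonical bond geometry
  (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å; φ = −57°,
  ψ = −47° for helix, ±3° of per-frame torsion noise; disordered
  segments resample φ ∈ [−160°, −70°], ψ ∈ [100°, 180°] each frame);
* side chains are single pseudo-atoms at literature-average centroid
  distances from CA carrying the side-chain mass — enough for the depth
  and footprint heuristics, with no rotamer model;
* lipids are reduced to their phosphorus positions (the only lipid atoms
  any in-scope metric touches): two 8×8 grids at ±2 nm with 0.1 nm
  Gaussian z-roughness;
* each mode poses the helix rigidly per frame (mode I lying 0.3 nm above
  the upper plane; mode II with its disordered segment's most hydrophobic
  side chain pinned 0.4 nm below the plane; mode III standing at 20° with
  residues 1–3 at the plane, 0.25 nm anchors, and a 15°/frame azimuthal
  random walk; unbound tumbling 3.5 nm above), plus small rigid and
  per-atom jitter;
* every random draw derives from the spec's single seed, so an identical
  spec reproduces the trajectory byte for byte, through the fixed-width
  PDB writer included.

`example_mode_spec()` pairs each mode with the natural peptide that
characterizes it — FK-16 (I), Lasioglossin LL-III with disordered
residues 1–8 and its Trp3 anchor (II), Temporin-La with its N-terminal
LLR attachment (III), Macropin 1 (unbound) — so the test conditions mirror
the biological assignments rather than arbitrary sequences.

What passing tests show — and do not. Ground-truth recovery (tilt to 5°,
distance and anchor depth to 0.1 nm, ≥95% mode recovery over 100 seeded
trajectories of 100 frames) demonstrates that the measurement and
classification chain is self-consistent and correctly implemented. It does
not validate the generator against physics: the synthetic frames have no
force field, no water, no lipid chains, no kinetics of binding, and
fluctuation amplitudes are chosen, not emulated. Conclusions about real
peptides require real trajectories; the package will analyze any
multi-model PDB with peptide backbone and phosphorus atoms.

## Numerical choices and problem sizes

Internal units are nm and degrees; the Kabsch–Sander formula is the only
Å-unit boundary. Degenerate inputs are defined rather than errors where a
value makes sense (footprint of < 3 or collinear atoms is 0; helicity is
clipped to [0, 1]) and rejected where none does (empty sequences, zero
axis vectors, one-sided "bilayers", intervals out of bounds, trajectories
whose analysis window is shorter than 20 frames). The test suite and the
acceptance checks run at deliberately small scale — trajectories of
60–100 frames, bilayers of 64 P per leaflet, peptides of 13–37 residues —
chosen so the full suite exercises every code path, including the 100-run
recovery sweep, in a few minutes on one core; all tolerances quoted above
are asserted at these sizes.
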
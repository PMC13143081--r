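---
title: "septinAH: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{septinAH: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septinAH)
```

# Scope and model system

septinAH analyses coordinate trajectories of amphipathic-helix (AH)
peptides on planar lipid bilayers. The model system is the 34-residue
"extended AH" of the septin Cdc12 C-terminal region — an 18-residue
amphipathic core flanked by 8 non-amphipathic residues on each side —
on a DOPC:PLPI 75:25 membrane. The package does not run molecular
dynamics; it consumes multi-model PDB trajectories (plus a JSON topology
sidecar) and provides a synthetic-scene generator whose outputs carry
exact ground truth, so each analysis can be validated in closed loop.

Units are Angstrom for length, nanoseconds for time, and degrees for
reported angles (radians internally). Residue numbering is 1-based with
inclusive ranges; the default peptide regions are the N-terminal patch
(1–8), AH core (9–26), C-terminal patch (27–34) and "second half"
(17–34). Boxes are orthorhombic only — the lateral membrane patches this
package targets are rectangular, and all cutoff-based analyses use the
orthorhombic minimum-image convention; triclinic input is rejected
explicitly rather than silently mishandled.

# Peptide constructs and the charge model

Constructs are assembled from four canonical segments: N-flank
`ERIRLNGD`, AH core `LEEIQGKVKKLEEQVKSL`, C-flank `QVKKSHLK` and the
GS-rich linker `GSGSRSGSGS`. "Flipping" a domain in the palindromic
CN-NC tandems means reversing its residue order only; no D-amino-acid
chemistry is implied, as dictated by the printed CN-NC sequence itself.

The charge model is integer-valued at pH 7.4: D/E −1, K/R +1, histidine
neutral. Histidine's standard pKa (~6) leaves it predominantly neutral at
pH 7.4, and this assignment is the one consistent with the +3 net charge
of the C-flank `QVKKSHLK`, which contains a histidine. Fractional
Henderson–Hasselbalch charges are out of scope. Both termini default to
neutral caps, mirroring the capped simulation constructs; `cCap = "free"`
subtracts the one unit that capping removes from the native C-terminus.

# Helix bending and curvature

## Axis reconstruction

The local bending analysis needs a smooth helix-axis polyline. The
default estimator uses the discrete second difference of the Cα trace,

$$A_i = P_i + \frac{H_i}{2\,(1-\cos\omega)},\qquad
  H_i = P_{i-1} - 2P_i + P_{i+1},$$

with the helical twist $\omega$ estimated from the rotation of successive
$H$ vectors (median over the chain). On an ideal helix this
reconstruction is *exact*: $H_i$ points exactly at the axis and its
magnitude is $2r(1-\cos\omega)$. A sliding-window centroid axis
(`method = "centroid"`) is also provided for comparison, but it is not
the default for a quantitative reason: the centroid of $w$ consecutive
points of a helix with ~100° twist retains an off-axis wobble of
$|\sum_{k<w} e^{ik\omega}|/w \approx 0.11$ of the helix radius for
$w = 4$, i.e. ~0.26 Å at radius 2.3 Å. That wobble is of the same order
as the signal of a 60 Å arc over one turn and would spoil the closed-form
validation below.

## Local bending angle

At each axis point, two chords of arc length *side* are drawn backward
and forward along the polyline (linear interpolation between axis
points); the bending angle is the turn between the chord directions, so a
straight axis scores 0°. *side* defaults to 7.2 Å, the Cα–Cα chord
across roughly one helical turn: this choice balances locality against
thermal noise, and the profile is validated against the closed-form
turning angle of a circle, $2\,\arcsin(\mathrm{side}/2R)$, on generated
arcs (within 2% for $R \in [30, 200]$ Å). The local radius of curvature
is $\mathrm{side}/\theta_{\mathrm{rad}}$, reported as `Inf` on straight
segments and `NA` within one chord of the axis ends where the chords do
not fit. Axis points are labelled by their anchor residue (the interior
residue of the second difference).

## Global circle fit

Overall curvature is the radius of a circle fitted to the Cα positions
projected onto their PCA best-fit plane (the plane of the two leading
principal components). The fit is the algebraic Kåsa least-squares
solution followed by one geometric Gauss–Newton refinement pass; on
noiseless circles Kåsa is already exact, and the single refinement pass
removes most of its small-radius bias under noise. Near-collinear input
(second singular value below $10^{-6}$ of the first) raises a
degenerate-geometry error, since the radius is unbounded.

A caveat the tests make explicit: fitting the raw Cα positions of a bent
*helix* (rather than its axis) is poorly conditioned, because the ±2.3 Å
helical wobble acts as structured noise on a short arc. The recommended
pipeline is `fitCirclePCA(helixAxisPoints(...))`.

## Helicity

Per-residue helicity is a dihedral-basin criterion: a residue is helical
in a frame when $(\phi, \psi) \in [-100°, -30°] \times [-80°, -5°]$.
This stands in for heavier secondary-structure machinery (DSSP) to keep
the core contract dependency-free; it is exact on the synthetic fixtures
(ideal helices score 1, extended chains 0) but, on real trajectories, it
will count some near-helical conformers that DSSP would not. Terminal
residues lack a dihedral and are reported `NA`.

# Membrane order

## Leaflets and the midplane

Lipids are assigned to leaflets by the sign of their phosphate *z*
relative to the global phosphate mean; the midplane is the mean of the
two leaflet means. This is robust for the planar patches in scope and
intentionally simple; undulating or highly asymmetric membranes would
need a local-normal treatment that is out of scope (the membrane normal
is fixed to +z throughout).

## Area per lipid

APL uses an exact periodic 2D Voronoi tessellation of the phosphate XY
positions: each seed's cell is clipped by the bisector half-planes
against all other seeds and all 8 periodic images, with a
nearest-first early exit once no remaining bisector can cut the cell.
Because the cells tile the box, per-lipid areas sum to the box XY area
exactly — this conservation is asserted on every call and is the
property that makes APL contrasts interpretable (a local increase near a
binding site is necessarily compensated elsewhere). This is a
methodological substitute for neighborhood-based APL tools used in the
field; it reproduces the same qualitative near-peptide contrasts with an
exactly testable partition. The raster for plotting (default bin 2 Å —
the bin size is a package choice, not derived from any publication)
assigns each grid cell its owning lipid's area. An optional mode inserts
peptide heavy atoms in the leaflet band as area-excluding seeds; it is
off by default, and the conservation assertion is disabled in that mode.

## Nematic order parameter

Per lipid, $S = \langle (3\cos^2\theta - 1)/2 \rangle$ over all
consecutive tail-bead C–C bond vectors of all chains, with $\theta$
measured against +z. All tail bonds are used (no glycerol-adjacent
exclusion; the choice is documented because conventions differ).
Canonical values — 1 aligned, 0 at the magic angle 54.7356°, −0.5
perpendicular — are recovered to 1e-6 on fixed-tilt fixtures.

The near/far comparison labels a lipid "near" a peptide when the lateral
minimum-image distance from its phosphate to the nearest peptide heavy
atom is ≤ 10 Å, and "far" at ≥ 25 Å, with intermediate lipids excluded.
The two cutoffs are package defaults (exposed as parameters): "near"
spans roughly one lipid shell around the binding footprint, and "far"
puts a full exclusion annulus between the groups so the far set is a
clean unperturbed reference within an ~11 nm patch.

# Contacts and salt bridges

Residue contact maps follow two conventions, both exposed: Cα distances
with a 7.5 Å cutoff (long/flexible side chains are accommodated by the
generous cutoff) for the residue-residue maps, and heavy-atom distances
with 3.5 Å for residue-class statistics. A residue pair with several
close atom pairs counts once. Domain-level maps average the residue-pair
frequencies over the N-patch/core/C-patch blocks in contiguous time
windows (default 4 windows; the last absorbs any remainder).

Salt bridges use side-chain carboxylate oxygens (D: OD1/OD2, E: OE1/OE2)
against basic side-chain nitrogens (K: NZ; R: NH1/NH2/NE) within 3.2 Å —
the common default criterion of trajectory salt-bridge tools. Histidine
is excluded, consistent with its neutral charge at pH 7.4. Occupancy is
active frames over total frames, aggregated across replicas as mean ± sd
(the sd is across replicas, and labelled so). Lifetimes are maximal runs
of consecutive active frames; runs separated by at most `gapTolerance`
inactive frames merge into one event (default 0 — no smoothing — since
event counts depend on this choice it is an exposed flag). The 95th
percentile of event durations uses linear interpolation between order
statistics (R's type-7 quantile); quantile conventions differ enough
between tools that this is stated explicitly.

# Orientation classifier

Each peptide's axis vector runs from the heavy-atom centroid of its
N-terminal patch to that of its C-terminal patch; cos θ between the two
axes distinguishes antiparallel (≈ −1) from parallel (≈ +1)
arrangements. The centroid is unweighted: for heavy-atom-only peptide
selections, mass weighting changes the COM by a negligible amount, and a
flag is not worth the interface cost; the geometric centroid is the
documented convention.

A counts residue-level heavy-atom contacts (< 4.5 Å, strict) between the
N-patch of either peptide and the second half (17–34) of the other,
summed over both directions; P is the analogous C-patch count. A frame is
"interacting" when T = A + P strictly exceeds the threshold (default
T > 5). T = A + P is one of two defensible readings of the contact-count
threshold (the other being all inter-peptide contacts); it is chosen
because A and P are the two quantities the classification is defined in
terms of, and `countMode = "atom_pairs"` exposes the atom-level
alternative for sensitivity checks. Interacting frames are labelled
`antiparallel_like` when A > P, `parallel_like` when P > A, and `mixed`
on the tie A = P, a case the orientation language does not otherwise
define.

# The synthetic-scene generator

The generator's job is to produce inputs whose analysis results are known
*by construction*, not to be physically realistic. No force field,
thermal ensemble or solvent is modelled, and membranes are planar only.
Concretely:

- **Helices** are built in internal coordinates (ideal bond lengths and
  angles, φ = −57°, ψ = −47°, ω = 180°), which makes the 1.5 Å rise,
  ~100° twist and 3.8 Å Cα spacing emerge rather than being painted on,
  and guarantees the helicity criterion scores 1. Side chains are a
  single Cβ pseudo-atom (1.53 Å, tetrahedral) — enough for heavy-atom
  COM and contact semantics without rotamer modelling. Bending maps the
  finished helix onto a circular arc with parallel-transported frames:
  the internal geometry is preserved exactly, so arc curvature is the
  *only* signal the bending analyser sees.
- **Bilayers** place one lipid per lattice site (default 8 Å spacing →
  ground-truth APL 64 Å² exactly), each a phosphate bead plus straight
  collinear tail beads along a single tilted director, so the per-lipid
  S equals the analytic $(3\cos^2\theta-1)/2$ of its drawn tilt with no
  sampling error. Species are assigned with exact floor-then-fill counts
  (75 DOPC : 25 PLPI per 100-lipid leaflet at the default composition),
  deterministically shuffled by the seed — composition is a statement,
  not a binomial draw. Default patches are smaller than the ~11 × 11 nm²
  membranes of the motivating simulations; lattice analytics are
  size-independent, so nothing is lost at desk scale.
- **Two-peptide scenes** prescribe the inter-axis angle and plant exact
  A/P contact counts as pseudo-atom bead pairs at 4.0 Å on lateral rails
  in the inter-peptide gap, 8 Å apart so no unintended residue pair
  crosses the 4.5 Å cutoff. Peptide-2 partner residues are drawn from
  the second half *outside* its C-patch so the beads never perturb
  peptide 2's axis; peptide 1's axis is computed after bead placement and
  peptide 2 is rotated (Rodrigues) to meet the requested angle exactly.
  The manifest records the achieved cos θ (construction aborts beyond
  0.5°).
- **Telegraph series** sample an alternating-exponential on/off process;
  truth is occupancy $\mu_{on}/(\mu_{on}+\mu_{off})$ and the mean
  on-dwell. Event statistics estimated from a *sampled* series carry an
  O(dt) discretisation bias (short off-dwells below dt merge adjacent
  events), so closed-loop tests sample at dt = 0.1 ns against 20 ns
  dwells; occupancy is unbiased at any dt.

All generators are seed-deterministic and restore the caller's RNG
state. A green closed-loop test therefore establishes that the analysis
code computes its stated definition correctly — it does not establish
anything about force-field-level realism, convergence of real MD
ensembles, or the values (radius ≈ 60 Å, replica outcome splits,
hundreds-of-ns lifetimes) that require the original trajectories.

# Numerical choices and degenerate inputs

- Minimum-image distances assume wrapped or near-box coordinates
  (nearest-integer image); all generators emit coordinates in-box.
- Coincident Voronoi seeds are perturbed by 1e-6 Å with a warning.
- Collinear circle-fit input and zero-length axis vectors raise
  degenerate-geometry errors rather than returning huge radii.
- PDB I/O is fixed-width with 1e-3 Å precision; coordinates beyond the
  field width are a formatting error, and model blocks with mismatched
  atom counts or ordering are structural errors with the offending line
  reported where possible.
- The pipeline (`runAll`) skips membrane stages when a scene has no
  lipids, skips salt bridges when no named side-chain O/N atoms exist
  (the synthetic Cβ-only peptides), clamps the window count to the frame
  count, and records per-stage status, timings and collected warnings in
  a JSON manifest; any failed stage makes the run fail after the
  manifest is written.

# Known limitations

- Planar membranes with a fixed +z normal; no curvature mapping, no
  lipid-packing-defect detector beyond APL contrasts.
- The helicity criterion is a φ/ψ basin, not DSSP.
- The frame stride is exposed but defaults to 1; no trajectory
  alignment/superposition is performed (analyses are either invariant to
  rigid motion or explicitly membrane-frame quantities).
- Contact counting is O(n²) per frame by design — the brute-force-equal
  invariant is part of the contract — which is comfortable for
  peptide-scale selections but not for whole-membrane atom sets.
- Binary trajectory formats (XTC/DCD) are not read; convert to
  multi-model PDB upstream.
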
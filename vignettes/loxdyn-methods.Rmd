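---
title: "Methods and design of the loxdyn trajectory-analysis toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the loxdyn trajectory-analysis toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`loxdyn` quantifies how a peripheral membrane enzyme complex —
15-lipoxygenase-1 (15LOX-1) bound to the scaffold PEBP1 — rearranges at a
lipid bilayer so that its buried catalytic iron can reach a
membrane-embedded phospholipid substrate (SAPE). This vignette documents
the models behind each analysis, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical and design choices a maintainer should know.

## The opening-angle order parameter

The complex is partitioned into three bodies: the 15LOX-1 β-barrel (PLAT)
domain, the 15LOX-1 catalytic domain, and PEBP1. Per frame,

θ = angle at **B** between **B→A** and **B→C**,

where A, B, C are the mass centers of β-barrel, catalytic domain and
scaffold. θ is reported in degrees within [0, 180] and is invariant under
global rotation and translation, so no superposition is applied (the test
suite asserts invariance to 1e-9 degrees under random rigid motions).

Design choices where the convention was genuinely open:

- **Vertex.** The three bodies are conventionally listed
  barrel–catalytic–scaffold; the middle body (the catalytic domain, which
  physically connects the other two) is the vertex. `opening_angle_series()`
  accepts a `vertex` override.
- **Weighting.** Centers are mass-weighted over *all* atoms of each set —
  the literal reading of "center of mass". `weighting = "geometric"` gives
  unweighted centroids; on near-homogeneous pseudo-atom clouds the two
  differ negligibly, on real all-atom input they can differ by a few
  tenths of a degree.
- **Domain boundaries.** For real 15LOX-1 input the β-barrel/catalytic
  split is configuration (the PLAT-domain convention puts the boundary
  near residue 114 of the 15LOX-1 chain); nothing is hard-coded, and the
  pipeline requires an explicit chain map rather than guessing chain
  identities.

`angle_shift(a, b)` is the difference of trailing-window means (default
window fraction 0.25), b minus a, positive = opening.
`state_conditional_shift()` instead conditions on known state labels and is
the estimator used for parameter recovery against the generator (difference
of conditional means; its standard error at 2000 frames and 2 degrees of
per-frame noise is below 0.1 degrees, comfortably inside the 0.5-degree
recovery band the tests enforce).

## RMSD triage

`kabsch_superpose()` implements the standard SVD solution with the
determinant correction to enforce a proper rotation; collinear or
fewer-than-three-point inputs raise a degenerate-geometry error rather
than returning an ill-defined rotation. `rmsd_series()` superposes every
frame onto a reference frame over a chosen atom set (convention: Cα atoms
of the protein chains, which suppresses side-chain noise) before taking
the RMSD.

`classify_stability()` takes the median RMSD over the trailing half of the
series and applies two thresholds: stable at or below `stable_cut = 4.5` Å
(the upper edge of the 3–4 Å band typical of well-behaved complex models,
plus margin), unstable at or above `unstable_factor × stable_cut` with
factor 3 (a model running at three times the stable band), intermediate
between. The median over a trailing window is robust both to early
equilibration and to brief excursions; the label is by construction
monotone in the RMSD level (property-tested).

## Interface contacts and hydrogen bonds

A residue pair is *in contact* when the minimum heavy-atom distance is at
or below 4.5 Å — a standard heavy-atom criterion chosen because the
contact definition is otherwise unspecified in this problem domain; both
cutoff and atom subset are configurable. Contact frequencies over a
trajectory carry a `normalized` column equal to raw count divided by the
maximum raw count, so the most frequent pair reads 1.0; this
interpretation of "normalized counts" is stated in the output metadata
because other conventions (per-frame fractions) exist.

Hydrogen bonds use the geometric criterion: donor–acceptor distance at
most 3.5 Å *and* donor–hydrogen–acceptor angle at least 140° for some
hydrogen within 1.2 Å of the donor. Models without explicit hydrogens
(including all synthetic fixtures) fall back to a distance-only criterion
with a tighter 3.2 Å default — the usual compensation for the missing
angular filter. `hbond_reorganization()` compares mean per-residue bond
counts between the first and last 10 % of frames (both fractions
configurable, validated non-overlapping); positive delta = bonds gained,
the signature of β-barrel residues anchoring into the bilayer.

## Regioselectivity statistics

Oxygenation at C15 versus C12 of the arachidonoyl chain follows hydrogen
abstraction at C13 versus C10, so the occupancy of close-approach poses of
each carbon to the catalytic iron is the structural readout.
`reactive_fraction()` is the fraction of frames with Fe–C distance at or
below 7.5 Å — just above the ~7.2 Å distance characteristic of reactive
poses, and deliberately configuration rather than constant.
`predicted_product_ratio()` is the ratio of the two reactive fractions.

This proxy is labelled `statistic = "proxy"` in every output: it assumes
abstraction propensity proportional to close-approach occupancy and
ignores abstraction kinetics, orientation and oxygen insertion, so it
supports the *direction* and rough magnitude of product imbalance, not a
quantitative product ratio. When the C10 channel never enters the cutoff
the result is flagged infinite instead of raising, because a dominant-C13
trajectory is a legitimate observation, not an error.

Histograms use half-open 0.1 Å bins anchored at a multiple of the bin
width; counts conserve the frame count exactly, and the reported mean is
the arithmetic series mean, not a bin-weighted estimate.

## Tunnel detection

Space around the structure is discretized into a clearance grid: voxel
value = distance from the voxel center to the nearest atom surface
(negative inside an atom). The grid covers the bounding box plus a 4 Å
margin so that boundary voxels are solvent by construction, and "reaching
the grid boundary" defines surface exit. The tunnel from a seed (the
catalytic iron, itself excluded from the occupancy) is the **maximin
path**: among all 6-connected voxel paths from seed to boundary with
clearance at or above the probe radius, one maximizing the minimum
clearance. That minimum is the bottleneck radius.

Numerical choices:

- Best-first expansion in decreasing path-width order; the first boundary
  contact yields the exact optimal bottleneck (the widest-path property of
  Dijkstra-type search). A second breadth-first pass on the
  bottleneck-thresholded subgraph selects, among maximin paths, one with
  fewest steps, breaking remaining ties by smallest linear voxel index —
  fully deterministic output.
- 6-connectivity (face neighbors) keeps per-voxel clearances meaningful as
  path widths; diagonal moves would tunnel through corners.
- Defaults: probe 1.4 Å (water), spacing 0.8 Å. Spacing bounds the
  discretization error of the bottleneck by about one voxel diagonal
  (0.8·√3 ≈ 1.39 Å); the tests assert recovery of a generator-carved
  channel within that bound and exactness against an exhaustive
  connectivity oracle on small random grids.
- Grid fill and search are implemented in C++ (Rcpp): the fill is
  O(atoms × voxels) and a desk-scale structure already produces ~10⁵–10⁶
  voxels.

Not implemented by design: Voronoi-based tunnels, multiple-tunnel ranking,
and any third-party tunnel-file compatibility.

## Coarse interface electrostatics

The charge model is one formal charge per ionizable residue: Asp/Glu −1 at
the side-chain carboxylate centroid (residue centroid when side-chain
atoms are absent, as in pseudo-atom models), Lys/Arg +1 at the terminal
nitrogen(s), His 0 by default (pKa near 6 at physiological pH;
configurable to a small positive partial charge), termini ignored.
Potentials are linear Debye–Hückel:

φ(r) = Σᵢ qᵢ (l_B / |r−rᵢ|) exp(−κ|r−rᵢ|)  [kT/e],

with Bjerrum length l_B = e²/(4πε₀ε_r k_B T) (≈ 7.1 Å at ε_r 78.5, 300 K)
and κ from the ionic strength (0.15 M default, Debye length ≈ 7.9 Å).
Every output carries `model = "DH-coarse"`: these values support *sign and
direction* comparisons (is a patch negative? does a mutation make it more
negative?) and must never be read as Poisson–Boltzmann magnitudes.

Point mutations are charge-only: `apply_mutation()` rewrites the residue
name and leaves coordinates untouched — no side-chain rebuild, because the
conformational response to a mutation is the business of the simulation,
not of this coarse model. A singularity guard rejects evaluation points
within 0.1 Å of a charge site, and patch summaries sample a fixed-seed
uniform sphere (default 256 points at 5 Å) around the patch centroid,
discarding points buried inside atoms.

One caveat discovered in testing: the screening-monotonicity property
(|φ| non-increasing in ionic strength at every point) holds for
same-signed charge sets and is asserted for those; for mixed-sign
distributions cancellation can locally break it, which is physical, not a
bug.

## The synthetic generator

`build_toy_complex()` and `simulate_two_state_trajectory()` impose the
statistical structure the analyses assume — they test the analyses, they
do not simulate physics. What they emulate:

- three Gaussian pseudo-atom clouds at configurable domain centers
  (defaults: 120/240/90 atoms, centers 25 Å from the catalytic center,
  cloud spread 2.5 Å, initial θ 90°);
- a lipid slab of DOPC/DOPE/SAPE pseudo-lipids at 50/30/20 mol%
  (`round(fraction × n)` adjusted to sum exactly), four atoms per lipid
  with N/O head-group atoms so hydrogen-bond statistics have substrate;
- one SAPE-like substrate with C13 and C10 atoms placed at configured
  iron distances (defaults 7.2 and 9.0 Å, sd 0.5 Å — the spread is a free
  fixture parameter, chosen as a realistic per-frame fluctuation), one FE
  pseudo-atom;
- two-state closed/open Markov dynamics: per frame the scaffold and
  β-barrel clouds are counter-rotated about the catalytic mass center so
  the realized θ equals the state target plus Normal(0, σ_θ); presets:
  `membrane` 90°→110° (+20° on membrane association), `substrate`
  110°→105° (≈−5° on substrate binding), `solution` closed-only;
- scripted contact pairs with per-state contact probabilities; the
  realized per-frame schedule is returned so recovered frequencies can be
  compared to ground truth within one frame quantum;
- isotropic positional noise (default 0.08 Å) on all atoms;
- an optional carved channel: a spherical pocket wall (Fibonacci-lattice
  shell, spacing well under the probe diameter so it is water-tight) with
  a ring-calibrated aperture whose on-axis clearance equals the configured
  bottleneck exactly.

Determinism: every stochastic step runs under a pinned RNG
(Mersenne-Twister/Inversion/Rejection, recorded in the manifest) seeded
from the `complex_spec`/`dynamics_spec` object, without touching the
caller's RNG state; identical seeds
give bit-identical structures and trajectories, which the byte-identical
pipeline report relies on.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: force-field energetics and emergent
conformational coupling, lipid-tail conformational sampling, water,
membrane insertion of the β-barrel (lipid–protein hydrogen-bond deltas on
default fixtures are ~0 because the toy barrel never approaches the
slab), explicit hydrogens (H-bond detection on fixtures always runs in
distance-only mode), and realistic side-chain chemistry (coarse charges
fall back to residue centroids). Parameter recovery on fixtures validates
the estimators, not the biology.

## Pipeline and reproducibility

`run_pipeline()` validates its configuration first — every referenced
selection must resolve non-empty against the model before any stage runs —
then executes seven stages (angle, stability, contacts, hbonds, regio,
tunnel, electro), each wrapped so a stage failure is recorded in the
report while independent stages still run. The report carries a
provenance block (config hash, master seed, RNG, package version) and
serializes byte-identically for identical configurations; timestamps and
timings are deliberately excluded from the report (they go to the log).
Externally produced structures and trajectories enter through
`read_structure()` / `read_trajectory()` (PDB, multi-model PDB, DCD) and
the same stage functions.

Problem sizes used throughout the tests and the acceptance script — 2000
frames for parameter recovery, 10⁵ draws for the normal-tail oracles, 100
random grids of at most 10³ voxels for the maximin oracle, 500-frame
default pipeline runs — were chosen so that each statistical tolerance is
a small multiple of the estimator's standard error at that size; they are
the package's documented study conditions, not tuned values.

## Known limitations

- Selection grammar covers fields, ranges and boolean composition only; no
  geometric selections (`within ... of`) — compose with
  `contact_map()` instead.
- One trajectory format family (PDB multi-model, DCD); no times are read
  from either, so frame times are synthesized unless supplied.
- The electrostatics never matches nonlinear Poisson–Boltzmann magnitudes
  by design; only directions are comparable.
- `classify_stability` thresholds are calibrated for Cα RMSD of
  multi-domain complexes; single-domain proteins would warrant a lower
  stable band.
- The tunnel finder returns one best tunnel; branching or multiple exits
  are reported only through their effect on the single maximin path.
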
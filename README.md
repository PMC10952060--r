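# loxdyn

Trajectory analysis of membrane-gated lipoxygenase complexes.

## The problem

15-lipoxygenase-1 (15LOX-1) in complex with the scaffold protein PEBP1
generates hydroperoxy-phospholipids (15-HpETE-PE, 12-HpETE-PE) — the lipid
death signals of ferroptosis — by oxygenating the sn-2 arachidonoyl chain of
membrane SAPE. Whether the catalytic site can reach its membrane-embedded
substrate depends on the conformation of the complex at the bilayer: the
N-terminal β-barrel (PLAT) domain, the catalytic domain and PEBP1 rearrange
on membrane association, opening a substrate-access channel toward the
catalytic iron.

`loxdyn` packages the trajectory-analysis layer needed to quantify that
mechanism from molecular-dynamics output (or from its bundled synthetic
generator), for structural biologists and simulators working on peripheral
membrane enzymes:

- **Domain-opening order parameter** θ: the angle at the catalytic-domain
  mass center B between the directions to the β-barrel (A) and scaffold (C)
  mass centers, `θ = ∠(A, B, C)` with mass-weighted centers; rigid-motion
  invariant, reported per frame in degrees.
- **RMSD stability triage**: Kabsch superposition per frame, median RMSD
  over a trailing window, labels `stable` / `intermediate` / `unstable`
  (defaults 4.5 Å and 3 × 4.5 Å).
- **Interface statistics**: residue–residue contact maps and frequencies
  (minimum heavy-atom distance ≤ 4.5 Å), geometric hydrogen-bond detection
  (3.5 Å / 140° with hydrogens, 3.2 Å distance-only without), and
  per-residue H-bond reorganization between the initial and final stages of
  a run.
- **Regioselectivity statistics**: Fe–C13 and Fe–C10 distance series and
  histograms, reactive fractions `P(d ≤ 7.5 Å)`, and their ratio as a proxy
  for the 15- vs 12-HpETE-PE product balance.
- **Tunnel finder**: clearance-grid discretization plus an exact maximin
  (widest-path) search from the catalytic iron to the protein surface;
  reports the bottleneck radius.
- **Coarse interface electrostatics**: one formal charge per ionizable
  residue, screened-Coulomb (Debye–Hückel) potentials in kT/e
  (`φ(r) = Σ qᵢ (l_B/rᵢ) e^{−κrᵢ}`), point-mutation deltas such as P112E —
  directional comparisons only, tagged `DH-coarse`.
- **Synthetic generator**: deterministic toy complexes (three pseudo-atom
  domains, DOPC/DOPE/SAPE 50/30/20 lipid slab, substrate, iron, optional
  carved channel of known bottleneck) and two-state closed/open Markov
  trajectories with configurable angle shift, distance distributions,
  scripted contacts and noise — ground truth for every analysis.

## Worked example

```r
library(loxdyn)

model <- build_toy_complex(complex_spec(seed = 7))
part  <- toy_partition(model)

sim <- simulate_two_state_trajectory(
  model, dynamics_spec(preset = "membrane", n_frames = 1000, seed = 7))
theta <- opening_angle_series(sim$trajectory, part)
state_conditional_shift(theta, sim$labels)

s13 <- fe_carbon_distance_series(sim$trajectory, part$fe, part$substrate_c13, "C13")
s10 <- fe_carbon_distance_series(sim$trajectory, part$fe, part$substrate_c10, "C10")
predicted_product_ratio(s13, s10, cutoff = 7.5)

tun <- build_toy_complex(complex_spec(
  seed = 7, carved_channel = list(direction = c(0, 0, 1), bottleneck = 1.8)))
tunnel_from_structure(tun, "name FE")

patch <- select_atoms(model, "chain P and resid 112")
wt  <- patch_potential_summary(model, patch, seed = 7)
mut <- patch_potential_summary(apply_mutation(model, "P", 112, "GLU"),
                               patch, seed = 7)
```

Formatted summary of these results (actual run, seed 7):

```
opening angle: 89.9 deg (closed) -> 109.9 deg (open), shift 20.00 deg
Fe-C13 mean 7.21 A, Fe-C10 mean 9.02 A
reactive fractions: C13 0.727, C10 0.001
tunnel bottleneck: 1.75 A over 15 path points
interface patch potential: wt +0.000 kT/e, P112E -0.752 kT/e
```

Reading: the membrane-preset dynamics open the complex by the configured
20°; C13 sits near the iron far more often than C10 (the structural basis
of 15-HpETE-PE dominance); the carved 1.8 Å channel is recovered to within
the voxel resolution; and the Pro→Glu substitution at the interface residue
makes the local electrostatic patch strictly more negative.

The full workflow — angle, stability, contacts, H-bonds, regioselectivity,
tunnel, electrostatics — runs as one deterministic pipeline:

```r
report <- run_pipeline(default_pipeline_config(seed = 1))
write_report(report, "report.json")
```

A thin command-line wrapper lives at `inst/scripts/loxdyn`
(`loxdyn simulate ...`, `loxdyn run ...`).

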
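---
title: "dimerscope: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dimerscope: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

dimerscope analyzes ensembles of pairwise membrane-protein association
simulations — many independent replicates of two identical transporter
protomers ("protomer A" and "protomer B") diffusing and dimerizing in a
lipid bilayer — and provides a synthetic generator that emulates such
ensembles at desk scale. The analyses are: relative-orientation coordinates
and toroidal density clustering, residue–residue interface contact maps
with a bundle-domain exclusion screen, umbrella-sampling window planning
and WHAM free-energy profiles of dimer separation, lipid order-parameter
and bilayer-thickness maps, and ensemble convergence diagnostics.

The motivating system is a neurotransmitter:sodium-symporter-like
transporter whose fold separates into a mobile *bundle* domain (TMH1, 2,
6, 7) that rotates during the transport cycle, and a membrane-anchoring
*scaffold* domain (the remaining helices). A dimer interface that engaged
the bundle surface would lock the transporter in one conformation; the
package's statistics are designed to quantify exactly this exclusion.

# The orientation coordinates

Each protomer carries a body-fixed in-plane reference vector (pointing
towards TMH4). For a dimer, `beta` is the in-plane angle from protomer A's
reference vector to the A→B center-of-mass direction; `chi` is the angle
from protomer B's reference vector to the B→A direction. Both are reduced
to [0°, 360°). Because each protomer measures the angle *to its partner*
in its own frame, relabeling the protomers of a homodimer maps
(beta, chi) to (chi, beta) exactly — this is the symmetry that makes the
orientation density of a converged homodimer ensemble mirror-symmetric
about its diagonal, and it is the convergence measure used by
`symmetry_ratio()`.

Handedness convention: the membrane normal is +z (extracellular side up);
angles increase counterclockwise when the bilayer is viewed from the
intracellular side (observer at −z); a pose rotation of +90° maps the +x
reference vector onto +y. The source material never fixes a handedness, so
this is a package convention, applied consistently by the generator, the
coordinate functions and the file readers.

# The synthetic ensemble generator

`generate_daft_ensemble()` runs overdamped rigid-body Brownian dynamics of
two protomers in two dimensions (in-plane translation plus rotation about
the membrane normal) in a periodic box. Tilt and internal dynamics are not
modeled: every implemented statistic is a function of the in-plane pose
only. Each replicate draws from its own RNG stream derived from
`(seed, replicate)`, so any single replicate is bit-reproducible
independently of ensemble size.

The pair potential (an `interaction_map`) is:

* a set of Gaussian wells on the (beta, chi) torus, each multiplied by a
  smoothstep distance switching function that turns on between the
  encounter distance (6 nm) and the well's contact distance (4.15 nm);
  off-diagonal wells are stored once and implicitly carry their
  label-swapped twin;
* a weak isotropic contact attraction (3 kJ/mol) standing in for generic
  membrane-mediated forces;
* a harmonic core repulsion below 4.1 nm; and
* a soft positive ridge (8 kJ/mol) applied when either protomer faces its
  partner with the bundle sector of its surface — the package's rendering
  of the membrane-mediated force that opposes dimerization at the bundle
  domain.

Per-frame interaction energies are evaluated with exactly the same
potential, so the energy table equals the potential at the stored
(beta, chi, distance) by construction.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| replicates × duration | 512 × 2 µs-equivalent | the reference docking-assay protocol |
| start separation | 8.4 nm | stated protocol; gives > 2 nm initial bead clearance |
| box | 18 × 18 nm | holds the 8.4 nm start with room for diffusion |
| D_trans | 4 nm²/µs | coarse-grained-scale lateral diffusion; calibrated so that >60% of replicates are dimeric at 2 µs while a monomer fraction persists |
| D_rot | 15000 deg²/µs | orientations decorrelate (~100°) within the time between encounters |
| timestep | 2×10⁻⁴ µs | stable Euler–Maruyama integration of the stiffest well (drift per step ≪ well width) |
| frame stride | 0.02 µs | 5 frames per 0.1 µs terminal window, matching the contact-map budget |
| well depths | 45–55 kJ/mol | inside the 30–90 kJ/mol range of stable-dimer separation free energies; deep enough not to leak on the 2 µs scale, near-equal so no capture basin is swallowed by a deeper neighbour |
| attractor layout | 4 diagonal + 4 off-diagonal wells, ≥ ~48° apart | all face directions ≥ 40° from bundle helix centers so the bundle surface stays out of stable interfaces |

One deliberate geometric choice: the bundle helix ring is recessed 0.5 nm
behind the extracellular-loop rim. This mirrors the structural argument
that EL3 floats in the headgroup region and limits how much bundle surface
can reach a partner, and it is what makes TMH1/2/7 contacts vanish from
the interface maps of the full-size template.

The spec-level description of diffusion constants uses per-step units; the
implementation uses per-microsecond coefficients with an explicit
timestep, which keeps them physical and timestep-independent.

## What a green test does and does not establish

The generator is a stated world, not a force field. A green cluster-count
or bundle-exclusion test establishes that the *analysis* recovers planted
structure of realistic size and noise; it says nothing about real
transporter energetics, lipid chemistry (PIP2, cholesterol), protomer
flexibility, or three-dimensional tilt, none of which are modeled.

# Orientation density and cluster detection

Densities are toroidal n×n histograms (default 72×72, i.e. 5° cells) of
the replicates that are dimeric at the requested time slice (minimum
bead–bead distance below 0.6 nm — one coarse bead diameter beyond contact;
the inclusion cutoff is a package default, not a stated value).
Enrichment is count over the uniform expectation, so the cell mean is
exactly 1 for any non-empty density. Optional smoothing uses a periodic
Gaussian kernel (bandwidth 5° in the pipeline defaults).

`detect_clusters()` thresholds the (smoothed) enrichment at 2 and labels
every above-threshold cell by steepest ascent to its local maximum under
toroidal 8-neighbour adjacency, merging maxima closer than 12°. This is a
deliberate deviation from plain connected components: on finite ensembles
single stray frames create above-threshold bridges that fuse peaks 40–60°
apart into one component, while watershed-by-ascent still separates them.
A plain component is the special case of one maximum. Cluster centers are
circular means of member frames; clusters within 15° of the diagonal are
symmetric; asymmetric clusters are paired with their label-swapped twin
within 20°; clusters need at least 3 member replicates (the noise floor
against isolated stray frames). Ties in nearest-cluster assignment break
to the lower cluster id.

# Contact maps and the bundle screen

A residue pair (i on A, j on B) counts once per frame when any bead of i
is within 0.5 nm of any bead of j (all beads, not only backbone — the
bead convention is not stated in the source protocol). Counts accumulate
over 5 frames sampled evenly from the final 0.1 µs of every replicate
(nearest stored frames to an even schedule) and over both labelings, so
the ensemble homodimer map is exactly symmetric. `filter_contacts()`
retains pairs seen strictly more than 5 times. Helix-pairing orientation
is the principal-axis slope of the above-threshold cells of a helix-pair
block (anisotropy ≥ 2:1 required); interface periodicity is the
periodogram maximum of the interfacial-residue indicator over periods
3–4.5 residues (a heptad repeat appears near 3.5).

`bundle_screen()` flags a replicate when, for at least 2 consecutive
stored contact frames, at least half of its residue contacts involve a
bundle-domain residue on either side. First-contact, separation and
lifetime are reported; the ensemble summary is `count` and
`100·count/n` as a percentage (one decimal, as conventionally reported —
7 of 512 prints as 1.4).

# Umbrella windows, WHAM and errors

`plan_windows()` unions a coarse grid (0.1 nm spacing over 1.6 nm) and a
fine grid (0.025 nm over the first 0.4 nm). Including both endpoints this
gives 29 unique centers; the reference protocol reports 32 umbrellas
without stating the construction, so the planner warns and accepts
explicit center lists. Force-constant units are interpreted as
kJ·mol⁻¹·nm⁻² (the conventional harmonic umbrella form).

`wham()` is the standard self-consistent iteration on shared histogram
bins (default 200 bins over the sampled range), converged when the window
constants move by less than 10⁻⁷ kT, with the free energy gauged to zero
at the largest sampled separation. Bins carrying fewer than 5 pooled
samples are reported as NA rather than as meaningless free energies.
The first half of every window series is discarded as equilibration
(the protocol's stated relaxation behaviour), configurable.

`bootstrap_errors()` resamples each window in blocks of its estimated
integrated autocorrelation time and re-solves WHAM warm-started from the
full-data solution. The resulting error bars are lower boundaries —
variability on timescales beyond a window is not resampled — and the
profile metadata says so. `integrate_profile()` is the trapezoidal
integral of the gauged profile, one number per profile as in the
summary-table convention.

Temperature is fixed at 310 K throughout (kT ≈ 2.577 kJ/mol).

# Membrane statistics

The second-rank order parameter is S = (3⟨cos²θ⟩ − 1)/2 with θ the angle
between a tail bond and the membrane normal; the average runs over all
bonds pooled into a grid cell (per-bond pooling; whether the source
averaged per-bond or per-lipid first is unstated, and for the affine
transform involved the two differ only in weighting). S is 1 for bonds
along the normal, −0.5 in-plane, 0 isotropic. Thickness is the
upper-leaflet headgroup surface minus the lower, per 0.4 nm cell, with
empty cells filled by inverse-distance interpolation from the 3×3
neighbourhood and flagged NA when a leaflet is absent altogether. Both
maps average the trailing half of the supplied frames by default. The
membrane normal is the global +z axis (flat bilayers only).

`interface_mismatch()` scores the thickness deviations of the two
half-annuli facing the dimer interface as −(mean_A · mean_B): positive
when thinning on one side meets thickening on the other (the
transient-dimer signature), negative when the deviations match (stable
dimers).

The synthetic bilayer places jittered-grid lipids in two mirrored
leaflets (default 180 per leaflet at 0.65 nm² per lipid, bulk thickness
4 nm, 4 tail beads), with protein-induced thickness sectors and annular
order perturbations that decay to zero beyond a 2.5 nm annulus.

# Convergence diagnostics

`vigintile_bands()` computes the 21 five-percent quantile levels (type-7
linear interpolation between order statistics — one of several quantile
conventions, fixed here) plus the ensemble mean of the per-replicate
interaction-energy series, over all replicates (not only interacting
pairs). `plateau_check()` fits the mean's tail slope (final quarter) and
calls the ensemble leveled when |slope| is below 1% of the mean-energy
range per tail duration.

A known property of the default generator world: with capture still
ongoing at 2 µs (the monomer fraction is still declining slowly), the
strict 1%-per-tail criterion is generally *not* met, even though the
mean visibly decelerates — which matches the source's own description of
convergence as robust but not complete. The test suite therefore asserts
deceleration (tail slope well below the early slope) rather than strict
leveling for the default world, and asserts the strict criterion on
constructed series.

# Numerical choices and degenerate inputs

* Angles are degrees everywhere; toroidal differences are signed into
  (−180°, 180°]; circular means use vector averaging.
* Initial placements retry (up to 100 times) when the minimum bead
  distance falls below the configured clearance (2 nm at the default
  8.4 nm start), then error.
* `beta_chi()` errors on coincident centers of mass; the reference vector
  errors when its in-plane norm is below 10⁻⁶.
* Energies: the harmonic-well analytic truth rejoins the zero baseline at
  minimum ± width; the gaussian well adds a harmonic wall 1.5 widths
  below the minimum.
* WHAM residuals decrease geometrically but the max-norm may wiggle by a
  fraction of a percent between iterations; convergence is judged by the
  tolerance, not by strict monotonicity.

# Known limitations

* Rigid 2-D bodies: no tilt, no conformational change, no flexible loops.
* One lipid species, flat bilayer, no curvature, no PIP2 chemistry.
* The interaction potential is a phenomenological stand-in; absolute
  energies have meaning only relative to its own stated parameters.
* The expected-random-encounter count exposes `encounter_probability` and
  the bundle `angular_fraction` as parameters because the underlying
  encounter model in the source is not stated.
* XTC/TRR binary trajectories are out of scope; GRO and multi-model PDB
  text dialects only.
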
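# dimerscope

Ensemble analysis of membrane-protein dimerization in R.

Neurotransmitter transporters and other polytopic membrane proteins form
dimers through several competing interfaces. A direct computational route
to those interfaces is ensemble docking by simulation: embed two copies of
the protein in a bilayer in a random relative orientation, let them
diffuse and associate, and repeat hundreds of times. dimerscope implements
the complete analysis chain for such ensembles — and a seeded synthetic
generator that stands in for the expensive simulations — for
computational biophysicists who want the statistics without a cluster:

* **Relative orientation.** For each dimer the angles (β, χ) measure where
  protomer B sits in protomer A's body frame and vice versa: β is the
  in-plane angle from A's reference vector to the A→B center-of-mass
  direction, χ the angle from B's reference vector to the B→A direction.
  On the (β, χ) torus, symmetric dimers lie on the diagonal and each
  asymmetric dimer appears twice, mirrored — the basis of both cluster
  taxonomy and the symmetry-ratio convergence measure.
* **Toroidal density clustering** with enrichment normalization,
  watershed peak detection, symmetry classification and pairing of
  mirror-related clusters.
* **Interface contact maps.** Residue–residue contact counts (0.5 nm
  cutoff, 5 frames from the final 100 ns-equivalents of every replicate),
  per-helix interface composition, helix-pairing orientation
  (parallel/antiparallel from the contact-band slope), heptad-repeat
  periodicity, and a screen for transient dimers centered on the mobile
  bundle domain (TMH1, 2, 6, 7), which stable interfaces avoid.
* **Separation free energies.** Umbrella-window planning (0.1 nm coarse +
  0.025 nm fine schedule), WHAM

  ρ(ξ_b) = Σᵢ hᵢ(ξ_b) / Σᵢ Nᵢ exp[(fᵢ − wᵢ(ξ_b))/kT],
  fᵢ = −kT log Σ_b ρ(ξ_b) exp[−wᵢ(ξ_b)/kT],

  block-bootstrap error bars, and profile integrals, with analytic well
  fixtures for validation.
* **Membrane perturbation.** Lipid second-rank order parameter
  S = ½(3⟨cos²θ⟩ − 1), gridded bilayer-thickness maps, annular-shell
  statistics and a thickness-mismatch score across the dimer interface.
* **Convergence diagnostics.** Vigintile (5%-quantile) bands of the
  interaction energy over time, plateau detection, dimerized-fraction
  time course.

## Worked example

```r
library(dimerscope)

template <- build_protomer_template()          # hDAT-like 12-helix body
ens <- generate_daft_ensemble(
  template, default_interaction_map(),
  ensemble_config(n_replicates = 128, duration = 2, seed = 42))

frames <- orientation_frames(ens, times = c(0.5, 1, 1.5, 2))
sapply(c(0.5, 1, 1.5, 2), function(t) dimer_fraction(frames, at_time = t))
#> 0.180 0.406 0.531 0.672          # >60% dimeric by 2 us, monomers persist

dens <- orientation_density(frames, at_time = 2, bandwidth = 5)
dens
#> orientation_density: 72x72 grid, 86 dimer frames at t = 2 us
cl <- detect_clusters(dens)
count_merged_clusters(cl)
#> 8                                 # 4 diagonal + 4 mirror-paired clusters
symmetry_ratio(cl)
#> 1                                 # above/below-diagonal populations match

smry <- interface_summary(residue_contact_map(ens))
smry$bundle_fraction
#> 4e-04                             # bundle surface essentially absent
attr(bundle_screen(ens), "percentage")
#> 0                                 # no stable bundle-centered dimer

truth <- analytic_pmf("gaussian_well_plus_wall", depth = 60,
                      width = 0.3, minimum = 4.5)
cen <- plan_windows(origin = 4.2)              # 29 centers (warns re: 32)
kk <- ifelse(abs(cen - 4.2) <= 0.4 &
               (round((cen - 4.2) / 0.025) %% 4 != 0), 5000, 1000)
wins <- generate_umbrella_samples(truth, cen, k_bias = kk,
                                  n_samples = 1500, seed = 7)
prof <- bootstrap_errors(wins, n_boot = 16, seed = 8)
-min(prof$profile$G, na.rm = TRUE)
#> 57.7                              # planted 60 kJ/mol well, within errors
integrate_profile(prof)
#> -33.4                             # kJ/mol/nm, gauged G(xi_max) = 0
```

The dimer fractions say how much of the ensemble has associated at each
time slice; the 8 merged clusters are the distinct dimer conformations
(each off-diagonal mirror pair counted once); a symmetry ratio near 1
indicates a converged homodimer ensemble; the near-zero bundle fraction
quantifies the exclusion of the mobile four-helix bundle from interfaces;
and the recovered well depth (57.7 ± bootstrap error vs 60 planted) shows
the free-energy machinery reproducing ground truth.

## Command line

```sh
Rscript inst/cli/dimerscope.R simulate --seed 1 --replicates 8 --out sim
Rscript inst/cli/dimerscope.R orient   --traj-dir sim --template sim/template.json \
                                       --times 0,0.5,1.0,1.5,2.0 --out orient
Rscript inst/cli/dimerscope.R pmf      --windows windows/windows_manifest.csv \
                                       --temp 310 --nboot 50 --seed 1 --out pmf
Rscript inst/cli/dimerscope.R all      --seed 1 --out run1
```

Subcommands: `simulate`, `orient`, `contacts`, `pmf`, `membrane`,
`converge`, `all`.

## Documentation

`vignettes/dimerscope-methods.Rmd` describes the models, defaults,
numerical choices and limitations; every exported function carries
roxygen documentation.
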
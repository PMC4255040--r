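# npbilayer

Region-resolved structure and dynamics of a phospholipid bilayer around a
single gold nanoparticle, from molecular-dynamics trajectories.

When a bare (non-passivated) gold nanoparticle adsorbs onto a lipid membrane,
the lipids in direct contact are deformed and slowed, while lipids far from
the adhesion site become *more* ordered: thicker bilayer, smaller area per
head group, lower lateral diffusion. Quantifying that long-range effect
requires analysing the two populations separately. `npbilayer` implements the
full analysis chain for such simulations, for membrane biophysicists working
with united-atom bilayer/nanoparticle trajectories in GROMACS-style GRO
format:

* **Nanoparticle construction** — spherical gold particles cut from the fcc
  lattice (conventional cell `a = 0.4078` nm, sphere centered on a lattice
  atom, inclusive boundary `d ≤ r`), with composition arithmetic, surface-atom
  detection (coordination < 12), and pair-distance diagnostics.
* **Region partitioning** — the nanoparticle-facing ("interacting") leaflet is
  split by the 3D distance from each lipid's head-group nitrogen to the
  nanoparticle center of mass: short-range (SR) within `r + 1.5` nm, a 0.5 nm
  buffer shell (excluded from analyses), and long-range (LR) beyond
  `r + 2` nm; tags are refreshed every 10 ns epoch.
* **Structural observables** — partial density profiles ρ(z); 2D water
  density maps ρ(x, z); head-group–gold contact distance distributions;
  radial distribution functions g(r); head-group angle and dihedral
  distributions; deuterium order parameters −S_CD per chain carbon
  (molecular-frame reconstruction for united atoms,
  `S_CD = (2/3) S_xx + (1/3) S_yy`); GridMAT-style 50×50 grid bilayer
  thickness; LR area per lipid `(lx·ly − π d_buf²)/n_LR`.
* **Dynamics** — mean square displacement of tagged subsets over 2 ns
  time-origin intervals, lateral and normal to the bilayer, and diffusion
  coefficients by the Einstein relation (`MSD = 4Dτ` lateral) with a
  two-segment uncertainty.
* **Synthetic trajectories with ground truth** — a kinematic generator that
  imposes tilt order, gauche fraction, leaflet separation, area per lipid and
  per-region diffusion constants, so every analysis stage is validated by
  parameter recovery.

All user-facing functions take the trajectory object first and return tibbles
(or small classed objects with `tidy()`/`glance()` methods), chain with the
pipe, and have `autoplot()` methods.

## Worked example

```r
library(npbilayer)

# a 3.5 nm gold nanoparticle
np <- build_fcc_sphere(1.75)
nrow(np$coords)                      # 1289 gold atoms
length(identify_surface_gold(np))    # 522 surface atoms

# synthetic bilayer + 2 nm nanoparticle trajectory, 20 ns at 0.1 ns/frame
sim  <- generate_trajectory(generator_config(n_frames = 201, dt = 0.1, seed = 7))
traj <- sim$trajectory               # 12748 sites x 201 frames

b    <- region_boundaries(1.0)       # SR <= 2.5 nm, buffer < 3.0 nm, LR beyond
tags <- tag_trajectory(traj, b)      # re-tagged every 10 ns
region_counts(tags)
#>   epoch  n_SR n_BUFFER  n_LR
#> 1     1    32       12    20
#> 2     2    36       13    15

grid_thickness(traj, boundaries = b, window = 20)$mean   # 3.997 nm (truth 4.0)
attr(area_per_lipid_lr(traj, tags, b, window = 20), "mean")  # 0.666 nm^2

msd(traj, tags, subset = "LR", window = 10, interval = 2) |>
  diffusion_coefficient() |> tidy()
#> D = 1.73e-07 cm^2/s  (x1e7: 1.73, imposed LR truth 1.42)
```

The thickness recovers the imposed 4 nm leaflet separation; the LR area per
lipid slightly exceeds the imposed 0.62 nm² because the excluded disc
`π (r + 2)²` over-counts the area actually occupied by SR+buffer lipids; the
diffusion estimates preserve the imposed SR < LR ordering on the 10⁻⁷ cm²/s
scale typical of fluid phosphatidylcholines.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/npbilayer.R build-np --radius 1.0 --out np.gro   # prints: 249 gold atoms
Rscript inst/cli/npbilayer.R run --config run.yaml
```

## Vignette

`vignettes/npbilayer-methods.Rmd` documents the model and conventions: the
order-parameter reconstruction, the region-boundary and epoch rules, the
grid-fill convention for bilayer thickness, the disc-subtraction area model,
what the synthetic generator does and does not emulate, and the package's
numerical choices.
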
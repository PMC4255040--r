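---
title: "Methods: region-resolved bilayer analysis around a gold nanoparticle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-resolved bilayer analysis around a gold nanoparticle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npbilayer)
```

`npbilayer` analyses molecular-dynamics trajectories of a united-atom
phosphatidylcholine bilayer with a single adsorbed gold nanoparticle. This
vignette is the package's account of the science it implements: the models,
the conventions chosen where several were defensible, and the limits of what
the synthetic validation shows.

## The system and its representation

The lipid is AOPC (1-arachidoyl-2-oleoyl-sn-glycero-3-phosphocholine): a
saturated 20-carbon *sn1* chain, a monounsaturated 18-carbon *sn2* chain, and
a phosphocholine head group, at 56 united-atom sites per lipid. Site naming
follows the head-group names used in the source force field (N, C25, C24,
O6, P, O3–O6); the acyl-chain numbering is a self-consistent scheme defined
by this package: *sn1* is C1 (carbonyl) through C20, *sn2* is C29 (carbonyl)
through C46, which places the oleoyl Δ9 cis double bond on C37–C38. We do
not claim this numbering matches any particular published structure figure;
only the names appearing in head-group analyses are externally constrained.

Units are fixed package-wide: nm, ns, atomic mass units. Mass densities are
reported in kg/m³ via the factor 1.66054 from u/nm³ (the convention of
GROMACS-style partial-density plots). Boxes are orthorhombic only — a
triclinic box line in a GRO file raises an explicit error — and the bilayer
normal is fixed to z, with no director fitting. Coordinates are stored
as-read; every analysis that needs whole molecules re-wraps each molecule
about its first site with the minimum-image convention.

## Nanoparticle construction

Gold nanoparticles are cut from the fcc lattice: conventional cubic cell
with the standard gold lattice constant `a = 0.4078` nm (exposed as a
parameter), one lattice atom at the origin as the sphere center, and every
atom with `|p| ≤ r` retained (inclusive boundary, 1e-9 nm tolerance against
floating-point ties on shells). Two facts follow from this construction and
are exploited by the tests:

* the particle is inversion-symmetric about its center, so the atom count is
  odd — `2 × (pairs) + 1`;
* the counts are reproduced exactly by an independent enumeration of integer
  triples `(i, j, k)` with `i + j + k` even and
  `(i² + j² + k²)(a/2)² ≤ r²`, which the test suite uses as an oracle.

Surface atoms are those with coordination below 12 at a 0.35 nm cutoff
(between the first shell at `a/√2 ≈ 0.288` nm and the second at `a`). By
this rule the center atom of the 13-atom cluster is bulk — it has the full
12 neighbours — and the 12 shell atoms are surface. No energy minimisation or
thermal relaxation of the particle is performed; the builder provides the
ideal initial structure plus shape diagnostics (pair-distance distribution).

## Region partitioning

Around a particle of radius `r`, lipids of the interacting leaflet are
classified by the 3D minimum-image distance `d` from their head-group N site
to the nanoparticle center of mass:

* **SR** (short-range): `d ≤ r + 1.5` nm — the 1.5 nm margin mirrors the
  simulations' short-range interaction cutoff;
* **buffer**: the next 0.5 nm shell, excluded from all analyses except the
  region-count table and the order-parameter comparison;
* **LR** (long-range): `d ≥ r + 2` nm.

Design choices that the defining text left open, fixed here: the distance is
3D (the worked example "2.5 nm from the center of mass" describes a sphere);
ties at the exact boundaries go to the non-buffer region (the buffer is
defined with strict inequalities); the interacting leaflet is the one whose
mean P-site z lies nearer the particle, ties to the upper leaflet; without a
particle all lipids are LR (reference-system behaviour). Tags are refreshed
on 10 ns epochs; boundaries are evaluated on the first frame at or after
each epoch start, with the nanoparticle center of mass recomputed there
(a per-epoch single-frame evaluation, not a running average — the
alternative was not described and is not implemented). A trajectory whose
final frame lands exactly on an epoch boundary assigns it to the last epoch,
so 100 ns at 10 ns epochs gives exactly 10 epochs.

## Order parameters for united-atom chains

United-atom chains have no hydrogens, so the deuterium order parameter is
reconstructed from the molecular frame of each scored carbon `i`:
`z_mol = unit(C(i−1) → C(i+1))`, `x_mol` the unit normal of the
C(i−1), C(i), C(i+1) plane, `y_mol` completing a right-handed frame. With
`S_aa = ⟨(3 cos² θ_a − 1)/2⟩` (θ against the lab normal, averaged over the
region's molecules and the window's frames),

```
S_CD = (2/3) S_xx + (1/3) S_yy,    reported as −S_CD ∈ [−1, 0.5].
```

Two closed-form anchors pin the implementation: an all-trans chain along the
normal gives exactly 0.5, and an azimuthally symmetric rigid chain at tilt θ
gives `−S_CD = (3⟨cos²θ⟩ − 1)/4` (`expected_scd()`), 0 in the isotropic
limit ⟨cos²θ⟩ = 1/3. The scored carbons default to all interior carbons of
each chain (C2–C19 for *sn1*, C30–C45 for *sn2*); end carbons lack a
neighbour and cannot be scored. The analysis window defaults to the last
20 ns (the defining text fixes windows for the other observables but not for
−S_CD; 20 ns matches the area/MSD convention and is configurable).

## Thickness, area per lipid, densities, distributions

**Grid thickness.** The xy box is divided into a 50×50 mesh; per frame and
leaflet the head-group N z-coordinates are averaged per cell and the cell
thickness is the upper-minus-lower difference. Cells empty in a leaflet are
filled from that leaflet's nearest occupied cell, with cell-center distances
measured minimum-image so filling works across the periodic boundary. The LR
distribution is accumulated over frames and the cells whose centers lie at
least `d_buf` (in xy) from the particle; an `SR` mask (cells within `d_sr`)
is also available.

**Area per lipid (LR).** Per frame,
`A_LR = (lx·ly − π d_buf²) / n_LR`. The disc of radius `d_buf = r + 2` nm is
the geometric realization of the classification boundary; the defining text
says only that the SR-plus-buffer area is subtracted, without a formula, so
the disc is the default and a convex-hull alternative (hull of the SR+buffer
N sites) is available behind the `excluded` argument. Without a particle the
plain `lx·ly / n_leaflet` is returned.

**Densities.** ρ(z) is the mass-weighted z histogram divided by the bin
volume and frame count; mass density is the default with a number-density
switch (the axis convention of the original figures is not labelled; mass
density is the GROMACS default). The 2D water map bins (x, z), averages over
y and frames, and reports nm⁻³; its window defaults to the last 10 ns.

**Gold-contact distances.** Per frame, surface gold atoms are restricted to
those within 0.6 nm of any head-group site ("in the vicinity" of the
membrane); each head-group site of the requested name within 1 nm of that
set contributes its *minimum* distance to the set. Heights are divided by
the number of contributing site-frames and the bin width, so a fixture with
every site at one distance has height `1/bin`. The per-site minimum is the
contact-layer reading of the original measure; an all-pairs variant is
available behind a flag.

**RDF.** Standard pair correlation normalized by the ideal-gas shell count
at the target's mean number density; `r_max` beyond half the smallest box
edge is clipped with a warning because minimum-image distances are unique
only below it.

**Angles/dihedrals.** Interior angle at the middle site; signed dihedral in
the IUPAC convention (cis = 0°, trans = 180°, range (−180°, 180°]), from
minimum-image displacement vectors; per-region unit-area histograms.
Collinear triples make a dihedral undefined; those lipid-frames are skipped
and counted.

## Mean square displacement and diffusion

The MSD window (default last 20 ns) is cut into consecutive, non-overlapping
2 ns intervals; displacements are measured from each interval's first frame
and averaged over intervals and molecules — the "all intervals of 2 ns"
averaging of the original protocol. A molecule enters an interval only if
its region tag is constant across it (10 ns epochs are whole multiples of
2 ns intervals, so intervals never straddle epochs when windows align; the
implementation also checks tags at both interval ends). Lipid position is
the center of mass of all 56 sites by default (N-site alternative behind a
flag), computed from unwrapped coordinates: inter-frame jumps exceeding half
a box edge are folded back, and an exact half-box jump is rejected as
ambiguous rather than guessed. Leaflet center-of-mass motion is *not*
removed by default (the original protocol does not mention it); a
`remove_drift` flag subtracts the subset's mean displacement.

`D` is the least-squares slope of MSD(τ) over the central 10–90% of the lag
range, divided by `2d` (d = 2 lateral, 1 normal, 3 full), converted via
1 nm²/ns = 10⁻⁵ cm²/s. The uncertainty is a declared convention, not an
inference of the original authors' method: half the absolute difference of
the slopes fitted on the two halves of the fit range. For Gaussian segment
estimates this half-range covers the truth with probability exactly 1/2
(and ≈ 0.70 at twice the half-range) — it is a scale indicator, not a
confidence interval, and the tests assert exactly that calibration.
A negative fitted slope is clamped to `D = 0` with a flag.

## The synthetic generator: what it does and does not emulate

`generate_trajectory()` is kinematic, not a physics engine. Every observable
is *imposed*: lipids sit on a jittered grid at the configured area per
lipid; head groups use a fixed internal geometry (backbone angles 111°,
backbone dihedrals trans), so angle/dihedral distributions are deltas at
known values; tails grow with bond 0.153 nm, angle 111°, dihedrals trans
with probability `1 − gauche_probability` (else ±60°); each tail is rigidly
rotated so its axis (the trans repeat vector C3−C1, which for an all-trans
chain equals every scored C(i−1)→C(i+1) segment — this is what makes the
−S_CD = 0.5 anchor exact at zero tilt) makes a *fixed* angle
`θ = acos(√⟨cos²θ⟩)` with the normal, with uniform azimuth and uniform roll
about the axis. The fixed tilt realizes the configured ⟨cos²θ⟩ exactly with
the lowest variance; the uniform roll supplies the azimuthal averaging the
closed form assumes. Lipids translate rigidly: a lateral Gaussian walk with
per-axis step variance `2 D(region) dt` (region fixed at t = 0) and a
vertical Ornstein–Uhlenbeck fluctuation (stationary σ configurable,
relaxation 1 ns). Waters are single OW sites (all water observables use the
oxygen), uniform outside the bilayer slab, plus a cluster riding within
0.5 nm of the particle surface inside the slab. The particle is the rigid
fcc sphere on a linear z path; a retreating path is how region-crossing
fixtures are generated (growing every N-to-center distance moves
boundary-adjacent lipids SR → buffer between epochs).

Default conditions emulate a fluid AOPC bilayer with a 2 nm particle:
64 lipids per leaflet (the self-assembled patch size), area per lipid
0.62 nm² (typical fluid phosphatidylcholine), N-to-N leaflet separation
4 nm, water number density 33.4 nm⁻³ (SPC-like), lateral diffusion
0.0098/0.012/0.0142 nm²/ns for SR/buffer/LR — the ~10⁻⁷ cm²/s scale and
SR < LR ordering measured for such systems — tilt ⟨cos²θ⟩ 0.45/0.55/0.62
and gauche probability 0.25/0.20/0.15 (SR most disordered), frame spacing
0.1 ns. A fixed seed gives bit-identical output; the RNG state of the caller
is restored.

Because observables are imposed, parameter recovery is a valid oracle for
the *analysis* code; it says nothing about real membranes. The generator has
no inter-lipid forces, no undulations or collective modes, no lipid
flip-flop, no emergent response of the bilayer to the particle, and its
conformations are static in time (only rigid translations move). Passing
recovery tests therefore validates the estimators — binning, frames,
normalizations, tag bookkeeping, the Einstein fit — not the physics of
nanoparticle–membrane interaction.

## Numerical choices and degenerate inputs

* Histogram bins are half-open `[left, right)` with the final edge closed;
  a value exactly on an interior edge goes right. Bin grids are built by
  integer multiples of the width (never `seq` over floats, which can emit a
  spurious extra bin).
* The fcc boundary, SR boundary and half-box comparisons use 1e-9
  tolerances against floating-point ties.
* A center of mass within numerical noise of the upper box face wraps to 0.
* Degenerate inputs error loudly and specifically: monolayers in leaflet
  assignment, missing N sites (naming the lipid), empty selections, zero LR
  lipids in the area formula, leaflets or masks with no cells, half-box
  jumps in unwrapping, fewer than 10 lag points in the diffusion fit.
* Problem sizes in the test suite are chosen for sharp statistics at desk
  scale: closed-form −S_CD recovery on 512-lipid bilayers (tolerance 0.02),
  diffusion recovery on 2000 tracers × 2000 frames (tolerance 5%),
  isotropic-order checks on 10⁴ Haar-rotated chains. The region-resolved
  checks use 25–100 lipids per leaflet in 10×10 nm boxes so that all three
  regions are populated around a 1 nm particle.

## Known limitations

* Only orthorhombic boxes and the (multi-frame) GRO format are read; binary
  trajectory formats (XTC/TRR) are not supported and raise an explicit
  error suggesting conversion.
* The leaflet assignment is a z-median split on P sites; strongly curved or
  porated membranes would need a local normal, which is out of scope.
* The disc-subtraction area model over-counts the excluded area when the
  SR+buffer lipids do not fill their disc, biasing LR area per lipid
  slightly upward; the convex-hull option reduces but does not remove this.
* The two-segment diffusion uncertainty is a scale indicator (see above).
* Epoch tagging evaluates boundaries on a single frame per epoch; systems
  with fast boundary fluctuations would see tag noise that per-epoch
  averaging (not implemented) would smooth.
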
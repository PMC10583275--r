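---
title: "Localising protein nuclei from lanthanoid-tag pseudocontact shifts"
author: "pcsloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localising protein nuclei from lanthanoid-tag pseudocontact shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsloc)
```

## The model

A lanthanoid ion rigidly attached to a protein shifts every nuclear
resonance by a pseudocontact shift (PCS) that depends on where the nucleus
sits relative to the ion's anisotropic magnetic susceptibility tensor. In
the principal frame of the anisotropy tensor,

$$\delta^{\mathrm{PCS}}(r, \theta, \phi) \;=\;
\frac{10^4}{12\pi r^3}\left[\Delta\chi_{ax}\,(3\cos^2\theta - 1) +
\tfrac{3}{2}\Delta\chi_{rh}\,\sin^2\theta\cos 2\phi\right]\;
\mathrm{ppm},$$

with $r$ in Ångström and $\Delta\chi$ in $10^{-32}\,\mathrm{m}^3$
(`pcs_forward()`). The package stores tensors in the equivalent Cartesian
form — five independent components of a traceless symmetric tensor plus the
metal position (`chi_tensor()`) — because the PCS is *linear* in those five
components at fixed geometry, which makes the inner fitting problem a
plain linear least-squares solve. The principal-frame view
($\Delta\chi_{ax}$, $\Delta\chi_{rh}$, ZYZ Euler angles under the unique
$|\chi_{zz}| \ge |\chi_{yy}| \ge |\chi_{xx}|$ ordering) is provided by
`principal_form()` for reporting and comparison.

Each measured PCS (a paramagnetic-minus-diamagnetic chemical-shift
difference) constrains its nucleus to lie near one isosurface of this
field. Several tags at different sites give several intersecting
isosurfaces, and the intersection localises the nucleus — the core idea
the package implements.

## Tensor fitting

`pcs_fit()` fits one tensor per dataset to backbone-amide ¹H PCSs, with
all datasets from one tagging site (e.g. the Tb³⁺ and Tm³⁺ data of the
same tag) sharing a single metal position. The outer search over the three
position coordinates uses BFGS with the analytic profiled gradient (the
tensor components are linearly optimal at every step, so only the explicit
position dependence contributes); a multi-start screen over a spherical
shell of radius 4–14 Å around the start hint (26 lattice directions, the
tagged cysteine's Cβ as centre) guards against the inversion-image local
minimum that position fits of even-symmetric fields are prone to. Fits are
unweighted: measurement uncertainties are retained for reporting only.
Fit quality is summarised by
$Q = \sqrt{\sum(\delta_{obs}-\delta_{calc})^2 / \sum\delta_{obs}^2}$
(`q_factor()`), which is also the ranking statistic of
`rank_structures()` when several candidate coordinate sets are available.
Amide protons missing from crystal structures are placed by
`place_amide_protons()` at 1.02 Å along the in-plane external bisector of
C(i−1)–N–CA — the PCS varies smoothly on the 0.02 Å scale, so any standard
placement is adequate.

Tensor uncertainty is propagated the way the study design prescribes:
`pcs_bootstrap()` repeats the fit 20 times with a random 20 % of the
backbone PCS data omitted (per dataset, without replacement), each member
seeded from `(seed, member)` so ensembles are exactly reproducible.

## The RMSD field and localisation spaces

For a target nucleus with observed PCSs $\delta_d$ (one per dataset $d$),
ensemble member $m$ contributes at every point $x$

$$\mathrm{RMSD}_m(x) = \sqrt{\tfrac{1}{D}\sum_d
\left(\delta_d - \delta^{calc}_{d,m}(x)\right)^2},$$

and the field (`rmsd_field()`) is the mean of $\mathrm{RMSD}_m$ over the
members — averaging per-fit results rather than pooling residuals, so the
spread of the ensemble widens the field's basins in proportion to the
tensor uncertainty. The localisation space (`extract_space()`) is the set
of grid nodes at or below a maximal-RMSD cutoff, summarised by its
centroid and extent; `export_space()` writes the field as an OpenDX grid
and the space as PDB pseudo-atoms (field value in the B-factor column) for
molecular-graphics rendering.

Numerical choices that matter:

* **Grid.** Coarse spacing 1 Å over the structure's bounding box plus a
  10 Å margin, then a 0.25 Å pass (0.1 Å in the simulation experiments)
  in a 6 Å box around the winning basin. Runtime is dominated by the
  number of grid nodes times ensemble members; these sizes keep a
  60-amide, 3-site, 20-member analysis at a few seconds.
* **Global basin search.** The RMSD basins are typically *narrower than
  the coarse spacing* (the field grows at the local PCS-gradient rate,
  ~0.1–0.3 ppm/Å, from a floor of a few mppm), so refining around the
  single lowest coarse node would pick an arbitrary basin. `localise()`
  instead thins the lowest coarse nodes to ≥ 2 Å mutual separation,
  polishes each by Nelder–Mead on the ensemble-mean-tensor RMSD (a cheap
  surrogate with the same basin structure), scores every polished
  candidate with the full member-averaged RMSD, and only then refines on
  the fine grid.
* **Plausibility bounds.** Candidate basins are restricted to the
  molecular region — within the grid margin of an actual atom rather than
  merely inside the bounding box — and to points at least 2.5 Å (H–H van
  der Waals contact) from atoms already present. Both bounds encode prior
  knowledge that the target is a proton *of the molecule*; neither uses
  the generator's ground truth.
* **Cutoff.** User-supplied in ppm when reproducing a published figure;
  the default rule is *field minimum + 0.5 × noise estimate* (noise
  estimated as the full-fit RMS residual), and the simulation experiments
  use *minimum + 2σ*. A boundary referenced to the achievable floor is
  the only defensible choice for an ensemble-averaged field, whose
  minimum already contains the propagated tensor uncertainty: an absolute
  cutoff below the floor yields an empty space.
* **Ties.** `rank_structures()` breaks exact ties by input order;
  assignment ties are flagged ambiguous and broken by candidate index.

## Why three datasets can be ambiguous

Three observed PCSs give three equations in three coordinates. The
intersection curve of two isosurfaces is a closed curve; a closed curve
generically crosses the third (closed, lobed) isosurface an *even* number
of times, so a second exact root — a ghost — usually exists besides the
true position. Nothing measured distinguishes the two: in simulation the
ghost basin is as deep, as stable under bootstrap resampling, and as well
conditioned as the true one. The plausibility bounds above remove ghosts
that fall outside the molecular region or inside the protein's occupied
volume, but a residual ambiguity remains in roughly a quarter to a half
of random geometries when only three single-metal datasets are used. This
is an identifiability limit of the experiment design, not of the
algorithm: a fourth dataset (a second tag chemistry at one site, or a
fourth site) makes the system overdetermined and eliminates the ghost.
Users with only three datasets should inspect both candidate basins
(`localise()` reports the winning one; the coarse field retains the
rest). The dedicated simulation experiments report medians over 20
repeated studies for exactly this reason.

## Isosurface intersection angles and dataset selection

Localisation precision is anisotropic: it is best where isosurfaces cross
near 90° and collapses where they are near-parallel.
`isosurface_angle()` returns the acute angle between the PCS gradients of
two tensors at a point. Two lanthanoids in the same rigid tag produce
tensors of different magnitude and sign but closely similar orientation,
so their isosurfaces through the target intersect at shallow angles;
small tensor-orientation errors then displace the intersection a long
way. `dataset_selection_report()` evaluates all pairwise angles at the
field minimum and flags same-site, same-tag pairs with different metals
below a configurable 20° threshold; the default pipeline policy (`auto`)
excludes the smaller-$|\Delta\chi_{ax}|$ member of each flagged pair,
keeping the metal that constrains the fit more strongly.
`shallow_angle_experiment()` reproduces the effect quantitatively: with a
3° orientation error injected into every fitted tensor, localisation from
one site's combined two-metal data is several times worse than from
single-metal data spread over three sites.

## Peak assignment

`assign_peaks()` matches observed paramagnetically shifted peaks to
candidate nuclei by exact minimum-cost one-to-one matching (a bitmask
dynamic programme; exhaustive-equivalent, feasible for the ≤ 16 candidates
that occur in practice), with cost the mean squared
predicted-minus-observed PCS over the datasets a peak was observed in —
partially observed peaks are matched on the datasets they share with the
predictions. The exact second-best matching is computed by forbidding
each optimal pairing in turn; a result within 10 % flags the assignment
ambiguous. `pre_screen()` adds the qualitative paramagnetic
relaxation-enhancement argument: candidates within a configurable 13 Å of
the metal are expected broadened beyond detection, which both explains
missing peaks and supplies forbidden pairings to the matcher.

## What the synthetic generator emulates — and what it does not

`simulate_study()` generates the reference conditions used throughout the
tests: 60 amide protons packed at ≥ 3.3 Å inside a sphere of radius
$(3n)^{1/3}\cdot 2$ Å (a density similar to a small globular protein's
amide spacing); three tag sites with surface Cβ anchors at least 60°
apart (emulating a sensible choice of spread tagging sites) and metals
8.2–9.4 Å from the Cβ in an outward cone of half-angle 30° (the geometry
of a cysteine-attached tag arm); per site a Tb-like tensor
($\Delta\chi_{ax}, \Delta\chi_{rh}$) = (25, 8) and a Tm-like tensor
(−15, −5) in $10^{-32}$ m³ sharing the base orientation to within a 5°
jitter — magnitudes chosen to give backbone PCS ranges of roughly ±1 ppm
at 10–25 Å; Gaussian noise of 0.01 ppm; 20 % of the amides unobserved per
dataset, uniformly at random; and an indole-like target proton pair
exactly 2.9 Å apart, 5 Å outside the amide cloud. Every stage draws from
its own substream of one root seed, so each artefact is individually
reproducible.

Deliberately not modelled: real polypeptide covalent geometry, the true
missingness mechanism (spectral overlap and exchange broadening are not
uniform), residual anisotropic chemical shifts of heteronuclei, tag-arm
flexibility (a single tensor per dataset is itself an approximation), and
internal motion of the target — so a passing simulation shows the
statistical machinery recovers a rigid ground truth under honest noise,
not that every feature of experimental data is reproduced.

## Reference experiment sizes

`fit_recovery_experiment()`, `localisation_experiment()` and
`shallow_angle_experiment()` each run one full study per seed; the
package's acceptance checks use 20 seeds per experiment (about two to
three minutes in total), the sample size at which medians of the reported
quantities stabilise to well inside the tolerances being checked.

## A worked run

```{r example, eval = FALSE}
res <- localisation_experiment(seed = 2)
res$per_nucleus
res$separation          # centroid separation of the two indole protons
res$fits                # per-site position error, metal-CB distance, Q
```

## Known limitations

* Three-dataset localisation is bimodal in a sizeable fraction of
  geometries (see above); medians over repeated studies are reported for
  the simulation experiments, and real analyses should add a fourth
  dataset where possible.
* Fits assume one rigid tensor per dataset; mobile tags violate this and
  bias the localisation spaces toward averages.
* The pipeline fits only ¹H PCSs; heteronuclear shifts would require
  residual-anisotropic-chemical-shift corrections that are out of scope.
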
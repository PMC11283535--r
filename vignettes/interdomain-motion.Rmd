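---
title: "Interdomain motion and NMR state analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interdomain motion and NMR state analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomorph)
```

# The problem

Two-domain enzymes such as β-phosphoglucomutase (βPGM) close a helical cap
domain over an α/β core to assemble their active site. Different liganded
states arrest the enzyme at different degrees of closure — an open
substrate-free form, partially closed near-attack conformers (NAC I,
NAC III and a twisted NAC III variant) and a fully closed near-transition
state form. Two complementary observables report on these states: the
relative orientation of the domains in crystal structures, and the backbone
amide chemical shifts of reporter residues in solution. This package
implements both readouts plus the population/affinity arithmetic that links
them, with synthetic generators so every stage can be exercised without
external data.

# The intrinsic Euler-angle model

## Canonical frame

All angles are expressed in a frame owned by the *reference* structure's cap
domain. `canonicalize_reference()` translates the model so the centroid of
its cap Cα atoms is at the origin and rotates it so the principal axes of
the cap Cα positional covariance coincide with the coordinate axes, largest
variance first. Eigenvectors have an arbitrary sign, so the frame is pinned
deterministically: each axis is oriented to have a positive projection onto
the vector from the core centroid to the cap centroid (falling back to a
positive component on the file-frame axis of the same index when the
projection is near zero), and the third axis is flipped if needed to keep
the basis right-handed. With these rules the operation is idempotent and
independent of the input pose. If two cap variances tie to within 1e-12 the
frame is not statistically meaningful; the code warns and breaks the tie by
eigenvalue order.

## The interdomain rotation

For each structure, `interdomain_transform()` performs two Kabsch
superpositions onto the canonical reference — one over shared cap Cα atoms,
one over shared core Cα atoms — and returns the transform taking the
cap-aligned pose to the core-aligned pose. Cα atoms are used for both
alignments: sidechains differ between point mutants and complexes, and the
cap frame itself is defined on Cα. Atom pairing matches on residue number
and atom name and drops residues whose names disagree, so point mutants
(e.g. D10N, P146A) compare cleanly against wild type.

The rotation *R* of that transform is decomposed by `euler_from_rotation()`
as intrinsic Tait–Bryan rotations in the canonical frame,

$$R = R_x(\mathrm{roll}) \; R_y(\mathrm{pitch}) \; R_z(\mathrm{yaw}),$$

so that pitch is a closing rotation about the cap's second principal axis,
roll a twist about its long axis, and yaw a lateral rotation. The
convention tag (`"xyz"`, with `"zyx"` selectable) is stored with every
result. The total hinge angle is the axis–angle magnitude
$\arccos((\mathrm{tr}\,R - 1)/2)$; it approximates the hinge-closure angle
that dynamic-domain programs report, without attempting to localise the
hinge axis.

Numerical edge cases: reflections are excluded in the superposition
(determinant forced to +1); near-collinear point sets are rejected rather
than silently fitted; at gimbal lock (|pitch| within 1e-6 of 90°) roll and
yaw are not separable, so roll is set to zero, yaw absorbs the free angle
and a warning is raised — the reconstructed rotation is still exact.

## Conformer classes

The literature prints no numeric Euler-angle boundaries between conformer
classes, so none are hard-coded. `conformer_centroids()` averages
pitch/roll/yaw over labelled results (e.g. reference structures of known
conformation) and `classify_conformer()` assigns the nearest centroid in
(pitch, roll, yaw) space, with `"unassigned"` beyond a cutoff (default 8°,
a conservative fraction of the ~26–35° spacing between closure states) and
deterministic, logged tie-breaking by centroid order. Geometry alone cannot
reliably separate NAC III from its twisted variant; that distinction is
made from NMR reporters (below).

# NMR observables

## Weighted chemical-shift perturbations

`weighted_csp()` computes, per residue shared by two species,
$\Delta\delta = [(\delta_{HN,X}-\delta_{HN,Y})^2 +
(0.13\,(\delta_{N,X}-\delta_{N,Y}))^2]^{1/2}$. The 0.13 nitrogen weight is
the standard amide scaling; the same weighted metric is reused as the
distance for reporter classification so one metric governs both analyses.
Residues missing from either table are absent from the profile rather than
zero, and the profile is symmetric and invariant under a common referencing
offset.

## Reporter classification

Reporter residues map global states onto single amide positions: A143 and
D180 for the cis/trans state of the K145–X146 peptide bond, I84 and S88 for
hinge closure, A115 ¹HN for transient-Mg²⁺ (MgT) occupancy, and P146 ¹³Cβ
for the proline isomer. Classification is nearest-cluster in the weighted
amide distance, with an overall call requiring reporter agreement within a
cutoff (default 0.25 ppm — roughly a conservative fraction of the smallest
printed cluster separations) and `"ambiguous"` otherwise. Within the NAC III
family, the I84 ¹HN sub-rule splits NAC III (≈7.00 ppm) from NAC III^t
(≈7.17 ppm) at the midpoint, 7.085 ppm; when the two amide reporters
disagree only within that family, the I84 sub-rule resolves the call.
`classify_proline_isomer()` uses ±1.0 ppm bands around 35.0 ppm (cis) and
32.0 ppm (trans), with an ambiguous midband. `detect_mgt()` reports the
A115 upfield displacement relative to an MgT-free reference and calls
occupancy above 0.8 ppm, half the full library displacement of 1.6 ppm.

The library shipped in `inst/extdata/reporter_library.tsv` contains *only*
coordinates printed in the literature; complete cluster coordinates live in
deposited BMRB entries and must be supplied by the user. For simulation and
testing, `synthetic_reporter_library()` provides a fully populated library
whose unprinted points are invented but realistic, and is documented as
synthetic.

## Populations, K_d and species matching

`estimate_populations()` turns per-residue peak intensities of coexisting
species into fractions: per residue, the fraction of each species is its
share of the row total; the population is the mean over residues where all
species are quantified (so the fractions sum to one exactly), with the
between-residue SD as dispersion. The mean, rather than the median, keeps
the sum-to-one property exact; the default of at least 20 complete residues
reflects the "substantial number of residues" such estimates need.

`estimate_kd()` applies the two-state relation
$K_d = L\,p_\mathrm{free}/p_\mathrm{bound}$ under the excess-ligand
approximation; at millimolar ligand against ~0.5 mM protein the depletion
is below ~10 %, and an optional `protein_total` argument applies the exact
free-ligand correction. Summary output rounds to one significant figure
(e.g. "~2 mM"); machine output keeps full precision.

`correlation_match()` ranks candidate assignments of an unknown species by
the Pearson correlations of its ¹HN and ¹⁵N shifts with each candidate over
shared residues, using the conservative statistic min(r_H, r_N), and
attaches a Fisher z-test of each runner-up against the leader. The Fisher
transform is implemented as atanh(r) = ½ ln[(1+r)/(1−r)], the standard form
for the two-sample z statistic
$z = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$.

# The synthetic generators

`make_two_domain_structure()` emulates the geometry problem, not a protein
fold: each domain is an antiparallel four-helix bundle of idealised
α-helical Cα traces (rise 1.5 Å, radius 2.3 Å, 100° per residue), numbered
so the default cap 16–87 / core 1–15, 88–221 definition applies unchanged.
The assembled reference is canonicalised, the cap is rotated by exactly
`rotation_from_euler(angles)` about a hinge point (the Cα of the core
residue preceding the cap — an arbitrary but fixed choice; only rotations
are compared, so recovery is independent of it), and isotropic Gaussian
noise is added to all atoms.

Two geometry choices deserve a note. A *single* straight helix has a
rotationally degenerate cross-section (its two perpendicular principal
variances tie), which would leave the cap frame ill-defined; the four-helix
bundle with unequal grid spacings (18 Å × 12 Å) gives three well-separated
variances. The spacings were sized from the error-propagation bound for a
rotation estimated from N noisy points,
$\mathrm{sd}(\theta) \approx \sigma / \sqrt{N\,(\lambda_i + \lambda_j)}$,
so that at σ = 0.2 Å the weakest angle (roll) has a standard error of
~0.12°, making the 0.5° recovery envelope used in the tests a comfortable
>3σ bound. Observed worst-case errors over the test grid are ~0.4°.

`make_species_shift_tables()` draws reporter residues from their labelled
clusters and gives all non-reporter residues a shared per-residue baseline
across species, so cross-species correlations are high except where states
differ; noise is Gaussian, with ¹⁵N noise scaled by 1/0.13 so it is
isotropic in the weighted metric. `make_intensity_table()` multiplies a
per-residue base intensity by the species population and log-normal noise.
All generators are pure functions of their parameters and seed.

What the generators do *not* emulate — and hence what passing tests cannot
show — includes real protein folds and packing, sidechain atoms, missing
residues and crystallographic disorder, peak overlap, exchange broadening
and intensity systematics beyond multiplicative noise. Validation against
deposited crystal structures and chemical-shift sets is the corresponding
real-data exercise and requires downloads; the package's batch tools accept
those files directly.

# Problem sizes and determinism

The shipped tests and the acceptance script run on desk-scale problems
chosen to exercise every code path while completing in seconds: 221-residue
Cα models, a 4 × 3 × 3 pitch/roll/yaw grid (noise-free and at σ = 0.2 Å),
100-instance superposition cross-checks against an independently
implemented quaternion-eigenvalue oracle, 100-replicate population
recoveries at 60 residues and 10 % noise, and 100-replicate reporter
classification at 0.02 ppm noise. Every stochastic step takes an explicit
integer seed and is bit-reproducible.

# Known limitations

- The hinge angle is the total cap/core rotation magnitude under *fixed*
  domain definitions; it does not localise a hinge axis or detect domains.
- Euler angles depend on the reference structure and its cap frame;
  results from different references are not comparable row-for-row.
- Geometric conformer classification requires user-supplied or
  data-derived centroids and cannot separate NAC III from NAC III^t.
- The shipped reporter library is intentionally partial; classification
  beyond the printed reporters needs user-supplied cluster points.
- mmCIF support is read-only; PDB writing has no hybrid-36 extension, so
  residue numbers above 9999 are rejected.
- The K_d estimator assumes a two-state system and, by default, negligible
  ligand depletion.
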
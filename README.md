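# allomorph

Tools for characterising how a two-domain enzyme opens and closes over its
active site, and for reading the same conformational states out of solution
NMR data. The package grew out of the analysis of conformational allomorphy
in β-phosphoglucomutase (βPGM) — a cap domain (residues T16–V87) hinging
over an α/β core (M1–D15, S88–K221) — but every residue range, reference
structure and threshold is a parameter.

## What it computes

**Interdomain geometry.** The cap/core relationship of each structure is
described by intrinsic Euler angles in a frame set by the reference
structure's cap domain:

1. The reference is canonicalised: translated so its cap Cα centroid sits at
   the origin and rotated so the cap's principal axes (eigenvectors of the
   Cα positional covariance, decreasing variance) coincide with x, y, z.
2. Each structure is least-squares superposed (Kabsch, reflections
   excluded) onto the reference first by shared cap Cα atoms, then by shared
   core Cα atoms.
3. The rotation *R* taking the cap-aligned pose to the core-aligned pose is
   decomposed as intrinsic Tait–Bryan rotations
   *R = R_x(roll) · R_y(pitch) · R_z(yaw)*, so pitch reads as a cap–core
   closing angle, roll as a twisting motion and yaw as a left-to-right
   lateral rotation. The total hinge angle is the axis–angle magnitude
   arccos((tr *R* − 1)/2).

Batch runs emit one row per structure/chain with pitch/roll/yaw, hinge
angle, non-H RMSD to the reference and a nearest-centroid conformer class
(open, NAC I, NAC III, NAC III<sup>t</sup>, closed).

**Solution NMR.** Weighted backbone-amide chemical-shift perturbations
Δδ = [(δ_HN,X − δ_HN,Y)² + (0.13 (δ_N,X − δ_N,Y))²]^1/2; reporter-residue
state classification (A143/D180 for the K145–X146 cis/trans peptide bond,
I84/S88 for hinge closure with the I84 ¹HN ≈ 7.00/7.17 ppm split between
NAC III and NAC III<sup>t</sup>, A115 ¹HN for transient-Mg²⁺ occupancy,
P146 ¹³Cβ ≈ 35.0 ppm for cis-proline); species populations from per-residue
TROSY peak intensities; the two-state dissociation constant
K_d = L·p_free/p_bound; and Pearson-correlation species matching with
Fisher z-tests.

**Synthetic data.** Ground-truthed generators for two-domain Cα structures
with a known cap rotation, multi-species shift tables drawn from a reporter
library, and intensity tables at known populations, so the full pipeline is
testable with no downloads.

## Worked example

```r
library(allomorph)

# a synthetic structure whose cap was closed by pitch 26, roll -8, yaw 5
# degrees, with 0.2 A coordinate noise
gen <- make_two_domain_structure(angles = euler_angles(26, -8, 5),
                                 noise_sigma = 0.2, seed = 11)
motion_profile(gen$model, gen$reference, gen$domains)
#>           structure_id pitch   roll   yaw hinge_angle rmsd_to_reference_nonH
#> 1 synthetic_p26_r-8_y5 25.67 -7.922 4.706       26.94                  4.897

# populations of a bound/free pair from noisy peak intensities, and the
# dissociation constant at 5 mM ligand
pops <- estimate_populations(
  make_intensity_table(c(bound = 0.72, free = 0.28), n_residues = 60,
                       noise_sigma = 0.1, seed = 11)$table)
pops
#> Populations over 60 residues:
#>   bound                 71.6% (SD 3.1%)
#>   free                  28.4% (SD 3.1%)
estimate_kd(pops, ligand_total = 5)
#> Kd = 1.981 mM (~2 mM) at 5 mM total ligand (bound 71.6%, free 28.4%; excess_ligand)
```

The recovered angles sit within ~0.3° of the applied rotation (pitch 26,
roll −8, yaw 5; hinge ≈ 27° since the three rotations compose), the
populations land within 1 % of the generating 72/28 split, and the
dissociation constant comes out at ~2 mM — the value expected for a 72 %
bound fraction in 5 mM ligand.

A command-line wrapper is installed as `exec/allomorph` with subcommands
`motion`, `csp`, `classify`, `match`, `populations`, `kd` and `simulate`,
e.g.

```sh
allomorph kd --ligand-mM 5 --bound 0.72 --free 0.28
allomorph simulate structure --pitch 35 --seed 1 --out-prefix demo
allomorph motion --reference demo_reference.pdb --mobile demo_structure.pdb \
  --cap 16-87 --core 1-15,88-221 --out motion.tsv
```

## Vignette

`vignettes/interdomain-motion.Rmd` documents the model and its assumptions,
the Euler convention and sign rules, what the synthetic generators emulate
(and what they deliberately do not), the numerical choices, and known
limitations.
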
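---
title: "Comparing kinase-domain conformations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing kinase-domain conformations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KinaseScape)
```

KinaseScape quantifies how the two lobes of a protein-kinase domain
move relative to each other across an ensemble of crystal structures,
and whether a blob of solvent density modelled in such a structure is
geometrically consistent with a monovalent cation. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic benchmarks do and do not
demonstrate about real data.

## Coordinates in, one conformation per file

`readStructure()` keeps the first model of a PDB or mmCIF file:
crystal structures are single-model, and for the rare multi-model file
a single unambiguous conformation is what every downstream geometry
operation needs. Alternate locations are collapsed to the
highest-occupancy copy, ties going to the alphabetically first label —
the standard convention when a single conformer must be chosen.
Residues are addressed by *author* numbering throughout, because that
is how structural papers name residues (His274, Glu91, ...);
insertion codes are carried in every matching key. Waters and
heteroatoms are retained since the ion-site module needs them.

Selections are chain + residue-interval + atom-name triples
(`"A:180-270,271-450"`). Residues absent from a model are silently
absent from a selection: crystallographic disorder is data, not an
error.

## Residue correspondence

Same-protein comparisons pair residues by identical (chain, number,
insertion code). Cross-homolog comparisons use global
Needleman–Wunsch alignment with affine gaps; the defaults (BLOSUM62,
gap open −11, extend −1, a gap of length *L* costing
`open + L·extend`) are the classical protein-alignment settings. The
traceback tie-break is fixed — prefer the diagonal, then a gap in the
second sequence, then a gap in the first — so the correspondence is
bit-reproducible. The alignment scores are cross-checked in the test
suite against an independent aligner and, for tiny cases, against
exhaustive enumeration of all alignments.

## Superposition

`kabsch()` is the SVD solution of the least-squares rotation problem,
with the determinant-sign correction that forbids reflections. Global
RMSD between two structures is computed over *all* shared Cα atoms of
the correspondence, unweighted, in a single pass — no outlier
rejection or iterative trimming. This is a deliberate scope decision:
trimmed-core RMSDs are not comparable across papers unless the trim
rule is reported, whereas the all-shared-Cα number is fully determined
by the two files. Near-collinear point sets are flagged as degenerate
(the rotation about the line is undetermined) rather than silently
returned.

## Interlobe rotation

The interdomain angle between two states uses the standard two-stage
rigid-body decomposition: superpose on the small lobe, then fit the
rotation carrying state A's large lobe onto state B's in that common
frame. The angle is `arccos((tr R − 1)/2)` and the axis is read from
the skew part of **R** (eigenvector fallback near 0°/180°). The
measure is symmetric in its arguments and invariant to global rigid
motions of either input; on noise-free synthetic pairs it recovers the
generating opening delta to machine precision. With 0.3 Å Gaussian
coordinate noise the recovery error on 60/120-residue lobes is
typically 0.3–0.5° — that is the statistical limit of fitting a
rotation from that many noisy points, which is worth remembering when
interpreting a "~16°" interlobe angle from real coordinates: the
residue windows chosen for the two lobes move such angles by a degree
or two, noise does not.

Helix axes are the leading principal axis of the window's Cα
coordinates, sign-fixed N→C; interhelix angle changes are differences
of orientation-aware angles in [0°, 180°]. Residue-pair distances
default to the closest-heavy-atom convention because the interactions
one usually tracks across an opening transition (salt bridges,
hydrogen bonds) live on side chains; a Cα mode is provided as a
robustness check.

## Ensemble PCA of conformation

`alignEnsemble()` iterates superpose-onto-mean / recompute-mean
(generalised Procrustes), seeded at the reference member for
determinism. The iteration is run to a mean-shift tolerance of 1e-9 Å
RMSD (cap 64 iterations), tighter than the 1e-4 Å at which the mean is
visually converged, followed by one final realignment onto the
converged mean. The tight tolerance is what makes two invariants hold
to 1e-6: projecting a training member through `projectStructure()`
reproduces its training score, and training scores are exactly
zero-mean — with a looser stop, the stored mean and the alignment
target differ by the last mean shift and both properties degrade
proportionally. Convergence is fast in practice (4 iterations for a
30-member synthetic ensemble).

The PCA itself is an SVD of the row-centred n × 3m coordinate matrix;
variances are covariance eigenvalues in Å², and projections are in Å
because coordinates are unweighted (no mass weighting). All
min(n − 1, 3m) modes are kept, so reconstruction from the full score
vector is exact.

Mode signs are arbitrary in principle; here PC1 is oriented so that
the member with the largest interlobe opening projects positively
(open = positive), and every other mode has its first non-zero
component positive. "Opening" is measured as the distance between the
Cα centroids of the two lobe selections — a rigid-invariant proxy that
is monotone in the generator's opening angle and needs no reference
state. When no lobe selections are supplied the first-non-zero rule
applies to PC1 as well.

The number of "real" modes is reported by `significantModes()`: a mode
counts when its variance exceeds 3× the median positive variance.
With a few genuine motions on top of isotropic coordinate noise the
median sits at the noise floor, so the rule needs no per-dataset
threshold; it is not meant for ensembles where most modes are real.

## Ion-site classification

The coordination shell of a candidate site is every O/N atom within
3.5 Å (a radius that bounds first-shell O/N contacts of K⁺). The rule
cascade encodes the textbook geometry: K⁺ sits at ~2.8 Å from ~6
oxygens, Na⁺ at ~2.4 Å, and the window boundary is placed at 2.6 Å to
bisect those anchors; a site with ≥ 4 acceptor-only contacts
(backbone-carbonyl or water oxygens) cannot be an ordered water, which
would have to donate four hydrogen bonds with its two protons. All
thresholds are arguments. Two genuine limitations are stated in every
rationale string: the classifier sees geometry only — the
refinement-side evidence that settles hard cases (B-factors relative
to surroundings, difference density) requires maps, which are out of
scope — and no bond-valence sums are computed in this version, so the
output is a screen, not a verdict.

## The synthetic generator

The generator exists so that every stage has ground truth. Lobes are
compact bundles of ideal 15-residue α-helices (rise 1.5 Å/residue,
100°/residue, radius 2.3 Å) placed on a 12 Å circle, giving each lobe
comparable spatial extent along all three axes so rigid-body fits are
well-conditioned. The small lobe (default 60 residues) is fixed above
a hinge at the origin; the large lobe (default 120 residues) is
twisted by φ about the lobe-connecting axis and then opened by θ about
a perpendicular hinge axis. Applying twist before opening makes the
recovered interlobe rotation equal the θ-difference *exactly* for
equal twists, which is what turns the angle-recovery tests into exact
checks rather than approximations. The centroid-to-centroid distance
between lobes grows monotonically with θ over the sampled range, which
is what the PC1 sign convention keys on. Noise is isotropic Gaussian,
sd per coordinate, seeded; identical parameters and seed are
bitwise-reproducible, and ensemble member seeds derive as
`base + index` so ensembles extend without collisions.

The default random-ensemble conditions — 30 members, opening
θ ~ N(20°, 15°²), twist φ ~ N(0°, 4°²), 0.2 Å noise — emulate the
spread seen across a kinase crystal-structure family: opening varies
over tens of degrees and dominates, twist is a few degrees, and 0.2 Å
is a realistic coordinate uncertainty at ~2.5–3 Å resolution. The 20°
mean opening is a mid-range value chosen once; correlations between
PC scores and generator angles are insensitive to it.

What passing these benchmarks does *not* show: real kinase lobes are
not rigid (activation loops and the P-loop deform internally), real
ensembles mix crystal forms and space groups with systematically
different lattice contacts, and real conformational axes need not be
orthogonal in Cartesian coordinate space. The synthetic results
validate the machinery — that the estimators recover known rigid-body
ground truth at the noise level — not the biological interpretation of
any particular PC axis.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
data: 180-residue two-lobe models, ensembles of 10–30 members, 100 ion
sites, and a 20-instance Kabsch-vs-brute-force comparison (quaternion
grid of 4000 plus derivative-free polishing). These sizes were chosen
so the whole suite completes in well under a minute while leaving each
estimate's sampling error far below the tolerances tested. All
stochastic steps take explicit integer seeds.

## Known limitations

* mmCIF reading relies on `bio3d::read.cif`, which handles atom-site
  records and cell metadata but not every exotic category; PDB output
  refuses (rather than truncates) residue numbers outside the
  fixed-column range.
* Cross-homolog correspondence is sequence-based; no structure-based
  alignment (TM-align/DALI style) is attempted, so very remote
  homologs with shifted cores should be mapped with care.
* Domain definitions are user-supplied selections; there is no
  automatic domain decomposition, and no screw-axis translation
  component is reported for interdomain motions.
* Absolute PC coordinates depend on ensemble membership and core
  selection; only comparisons within one fitted landscape are
  meaningful.
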
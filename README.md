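# KinaseScape

Structural-comparison toolkit for crystallographic ensembles of protein
kinase domains, written for structural biologists who want the numbers
behind a multi-structure comparison — global Cα RMSDs, interlobe hinge
angles, a principal-component map of the open/closed conformational
landscape, and a geometric sanity check of modelled monovalent-cation
sites — reproducibly, from coordinate files, without a graphics program
in the loop.

## What it computes

**Superposition and RMSD.** Residue correspondences are built either by
shared author numbering (same-protein comparisons) or by global
Needleman–Wunsch alignment with affine gaps (cross-homolog
comparisons, BLOSUM62, gap open −11 / extend −1). Rigid-body fits use
the Kabsch algorithm: for paired coordinate sets *a*, *b* the proper
rotation **R** (det +1) and translation **t** minimise

    RMSD² = (1/n) Σᵢ ‖aᵢ − (R bᵢ + t)‖²

with the reflection case corrected by a sign flip of the smallest
singular vector.

**Conformational PCA.** An ensemble of structures sharing a common Cα
core is aligned to its evolving mean conformation (generalised
Procrustes iteration), then the covariance of the flattened 3m-vector
coordinates is eigendecomposed. Modes are orthonormal; projections
carry Å units. For kinase domains PC1 captures the "Pac-Man"-like
opening/closing of the small and large lobes and PC2 the subtler
interlobe twist; PC1's sign is oriented so more-open structures project
positively.

**Domain geometry.** Interdomain motion between two states is
decomposed by a two-stage fit: superpose on the fixed domain (e.g. the
kinase small lobe), then fit the rotation of the moving domain (large
lobe) and report its angle, arccos((tr **R** − 1)/2), and axis. Helix
axes are leading principal axes of a segment's Cα coordinates
(sign-fixed N→C), giving interhelix angle changes; residue-pair
distances come in Cα and closest-heavy-atom flavours.

**Ion-site geometry.** Candidate monovalent-cation sites are classified
from their coordination shell (O/N ligands within 3.5 Å): CN ≥ 5 with
mean ligand distance in [2.6, 3.1] Å calls K⁺, CN ≥ 4 in [2.2, 2.6) Å
calls Na⁺, ≥ 4 acceptor-only contacts (backbone-carbonyl or water
oxygens) exclude water, CN ≤ 3 is water. `scanSolventSites()`
re-evaluates every deposited water and ion so "waters" that are really
buried cations surface at the top of the list.

**Synthetic ground truth.** A deterministic generator produces two-lobe
Cα proteins with controllable opening and twist angles plus Gaussian
noise, ideal α-helices, and octahedrally coordinated ion sites — so
every stage above is testable against known answers with no downloads.

## Worked example

```r
library(KinaseScape)

# two synthetic states: closed, and opened by 16 degrees, 0.2 A noise
closed <- makeTwoLobe(twoLobeParams(thetaOpen = 0,  noiseSd = 0.2, seed = 1))
open   <- makeTwoLobe(twoLobeParams(thetaOpen = 16, noiseSd = 0.2, seed = 2))
sels   <- twoLobeSelections()

core <- matchCoreByNumber(closed$structure, open$structure, sels$all)
superposeStructures(closed$structure, open$structure, core)$result
#> SuperpositionResult: RMSD 2.145 A over 180 atoms

interlobeRotation(closed$structure, open$structure, sels$small, sels$large)
#> RotationDecomposition: 16.23 deg about (1.000, -0.006, -0.022)
#>   60 aligned / 120 moving Calpha

site <- makeIonSite("potassium", 2.8, 6, distortionSd = 0.1, seed = 7)
classifySite(coordinationShell(site$structure, c(0, 0, 0)))
#> IonClassification: potassium (CN 6, mean distance 2.77 A)
```

The global RMSD (2.15 Å over all 180 shared Cα) reflects the moving
large lobe; the two-stage decomposition recovers the generating 16°
opening to within the noise level, and the distorted octahedral site at
~2.8 Å mean ligand distance is called as K⁺.

For file-based work the same operations run from a declarative YAML
config (see `inst/extdata/grk5-comparisons.yaml` for a GRK5-flavoured
template with the canonical domain selections) through `runPipeline()`
or the CLI:

```sh
Rscript inst/cli/kinasescape.R simulate --out sim --n 6 --seed 3
Rscript inst/cli/kinasescape.R run --config sim-cfg.yaml
```

which writes `projections.csv` (PC coordinates per structure),
`comparisons.csv` (RMSD, interlobe angle/axis, interhelix deltas,
pair-distance deltas), `ion_sites.csv` and a JSON report.

## Vignette

`vignettes/kinase-conformational-analysis.Rmd` documents the models,
parameter choices, numerical tolerances and known limitations.
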
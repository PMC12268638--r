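#' @import methods
NULL

.ATOM_COLS <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
                "insert", "o", "b", "x", "y", "z", "elesy")

#' Structure: parsed macromolecular coordinates
#'
#' Holds one model of a coordinate file as an ordered atom table plus
#' crystallographic metadata when present.  Atoms are stored as a
#' `data.frame` with columns `type` (ATOM/HETATM), `eleno`, `elety`
#' (atom name), `alt` (altloc, "" when absent), `resid` (3-letter
#' residue name), `chain`, `resno` (author numbering), `insert`
#' (insertion code, "" when absent), `o` (occupancy), `b` (B-factor,
#' A^2), `x`, `y`, `z` (A) and `elesy` (element symbol).
#'
#' After normalisation atoms are ordered by (chain, resno, insert, elety)
#' and exactly one altloc is retained per atom.
#'
#' @slot identifier character, accession or filename stem.
#' @slot atoms data.frame of atom records (see above).
#' @slot model integer, model number retained (always the first).
#' @slot unitCell numeric(6) `a,b,c,alpha,beta,gamma` or numeric(0).
#' @slot spaceGroup character(1) or character(0).
#' @exportClass Structure
setClass("Structure",
  representation(identifier = "character", atoms = "data.frame",
                 model = "integer", unitCell = "numeric",
                 spaceGroup = "character"),
  prototype(identifier = NA_character_, model = 1L,
            unitCell = numeric(0), spaceGroup = character(0)))

setValidity("Structure", function(object) {
  a <- object@atoms
  msgs <- character(0)
  if (!all(.ATOM_COLS %in% names(a)))
    msgs <- c(msgs, paste("atom table must have columns:",
                          paste(setdiff(.ATOM_COLS, names(a)), collapse = ", ")))
  else {
    if (nrow(a) > 0) {
      if (any(!is.finite(as.matrix(a[, c("x", "y", "z")]))))
        msgs <- c(msgs, "atom positions must be finite")
      if (any(is.na(a$o)) || any(a$o < 0 | a$o > 1))
        msgs <- c(msgs, "occupancy must lie in [0, 1]")
      if (any(is.na(a$elesy) | a$elesy == ""))
        msgs <- c(msgs, "element symbols must be non-empty")
    }
    if (length(object@unitCell) != 0 && length(object@unitCell) != 6)
      msgs <- c(msgs, "unitCell must be numeric(0) or numeric(6)")
  }
  if (length(msgs)) msgs else TRUE
})

#' AtomSelection: chain/residue-range/atom-name selection
#'
#' @slot chain character(1); `"*"` is a wildcard matching every chain.
#' @slot ranges 2-column integer matrix of inclusive residue-number
#'   intervals, non-overlapping and sorted after normalisation; a
#'   0-row matrix selects all residue numbers.
#' @slot atomNames character vector of atom names (default `"CA"`).
#' @exportClass AtomSelection
setClass("AtomSelection",
  representation(chain = "character", ranges = "matrix",
                 atomNames = "character"),
  prototype(chain = "*", ranges = matrix(integer(0), ncol = 2),
            atomNames = "CA"))

setValidity("AtomSelection", function(object) {
  r <- object@ranges
  if (ncol(r) != 2) return("ranges must have two columns")
  if (nrow(r) > 0) {
    if (any(r[, 1] > r[, 2])) return("each interval needs lower <= upper")
    if (nrow(r) > 1) {
      o <- order(r[, 1])
      if (any(r[o, 1][-1] <= r[o, 2][-nrow(r)]))
        return("intervals must be non-overlapping after normalisation")
    }
  }
  if (length(object@atomNames) < 1) return("need at least one atom name")
  TRUE
})

#' CoreMap: ordered residue correspondence between two structures
#'
#' @slot pairs data.frame with columns `chainA, resnoA, insertA,
#'   chainB, resnoB, insertB`, ordered by structure A's residue order.
#' @slot atomName atom matched in both structures (usually `"CA"`).
#' @exportClass CoreMap
setClass("CoreMap",
  representation(pairs = "data.frame", atomName = "character"),
  prototype(atomName = "CA"))

setValidity("CoreMap", function(object) {
  p <- object@pairs
  need <- c("chainA", "resnoA", "insertA", "chainB", "resnoB", "insertB")
  if (!all(need %in% names(p))) return("pairs missing required columns")
  keyA <- paste(p$chainA, p$resnoA, p$insertA)
  keyB <- paste(p$chainB, p$resnoB, p$insertB)
  if (anyDuplicated(keyA) || anyDuplicated(keyB))
    return("no residue may appear twice on either side")
  TRUE
})

#' SuperpositionResult: rigid-body fit of one point set onto another
#'
#' @slot rotation 3x3 proper rotation matrix (applied to set B).
#' @slot translation numeric(3), A.
#' @slot rmsd numeric(1), A, computed after the transform.
#' @slot nAtoms integer(1) number of paired atoms.
#' @slot degenerate logical(1), TRUE when the point sets are (near)
#'   collinear so the rotation about the line is undetermined.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtoms = "integer",
                 degenerate = "logical"),
  prototype(degenerate = FALSE))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthogonal within 1e-9")
  if (abs(det(R) - 1) > 1e-9) return("rotation must have det +1 within 1e-9")
  if (length(object@translation) != 3) return("translation must be length 3")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  if (object@nAtoms < 3L) return("nAtoms must be >= 3")
  TRUE
})

#' EnsembleCore: common Calpha core across an ensemble
#'
#' @slot referenceId identifier of the reference member.
#' @slot members character vector of member identifiers.
#' @slot coreMaps named list of [CoreMap] objects (reference -> member),
#'   all of identical size, ordered by the reference residue order.
#' @slot selection the [AtomSelection] that defined the core.
#' @exportClass EnsembleCore
setClass("EnsembleCore",
  representation(referenceId = "character", members = "character",
                 coreMaps = "list", selection = "AtomSelection"))

setValidity("EnsembleCore", function(object) {
  if (!object@referenceId %in% object@members)
    return("referenceId must be one of the members")
  if (!setequal(names(object@coreMaps), object@members))
    return("coreMaps must be named by members")
  sizes <- vapply(object@coreMaps, function(m) nrow(m@pairs), integer(1))
  if (length(unique(sizes)) > 1)
    return("all per-member cores must have identical size")
  if (sizes[1] < 10L) return("core must contain at least 10 residues")
  TRUE
})

#' ConformationPCA: principal components of an aligned ensemble
#'
#' Modes are unit 3m-vectors over the flattened (x1,y1,z1,...) core
#' coordinates; variances are eigenvalues of the coordinate covariance
#' in A^2, sorted non-increasing.  Projections (scores) carry A units.
#'
#' @slot meanCoords m x 3 matrix, mean aligned conformation (A).
#' @slot modes 3m x k matrix of orthonormal columns.
#' @slot variances numeric(k), A^2, non-increasing.
#' @slot nMembers integer(1).
#' @slot memberIds character(n).
#' @slot scores n x k matrix of training projections (A).
#' @slot refKeys data.frame (chain, resno, insert) naming the core
#'   residues on the reference, in mode order.
#' @exportClass ConformationPCA
setClass("ConformationPCA",
  representation(meanCoords = "matrix", modes = "matrix",
                 variances = "numeric", nMembers = "integer",
                 memberIds = "character", scores = "matrix",
                 refKeys = "data.frame"))

setValidity("ConformationPCA", function(object) {
  k <- ncol(object@modes)
  if (length(object@variances) != k)
    return("one variance per mode required")
  if (any(object@variances < -1e-12)) return("variances must be >= 0")
  if (is.unsorted(rev(object@variances), strictly = FALSE))
    return("variances must be non-increasing")
  G <- crossprod(object@modes)
  if (max(abs(G - diag(k))) > 1e-8)
    return("modes must be orthonormal within 1e-8")
  TRUE
})

#' RotationDecomposition: interdomain rotation between two states
#'
#' @slot angle degrees in [0, 180].
#' @slot axis unit 3-vector (rotation axis of the moving set).
#' @slot alignSelection,movingSelection the [AtomSelection]s used.
#' @slot nAlign,nMoving matched Calpha counts in each selection.
#' @exportClass RotationDecomposition
setClass("RotationDecomposition",
  representation(angle = "numeric", axis = "numeric",
                 alignSelection = "AtomSelection",
                 movingSelection = "AtomSelection",
                 nAlign = "integer", nMoving = "integer"))

setValidity("RotationDecomposition", function(object) {
  if (object@angle < 0 || object@angle > 180)
    return("angle must lie in [0, 180] degrees")
  if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-9)
    return("axis must be a unit vector within 1e-9")
  TRUE
})

#' HelixAxis: fitted axis of a helical segment
#'
#' @slot centroid numeric(3), A.
#' @slot direction unit 3-vector, sign fixed N->C.
#' @slot residueRange integer(2).
#' @slot nAtoms integer(1) >= 4.
#' @exportClass HelixAxis
setClass("HelixAxis",
  representation(centroid = "numeric", direction = "numeric",
                 residueRange = "integer", nAtoms = "integer"))

setValidity("HelixAxis", function(object) {
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("direction must be a unit vector")
  if (object@nAtoms < 4L) return("need at least 4 atoms")
  TRUE
})

#' CoordinationShell: ligand atoms around a candidate ion centre
#'
#' @slot center numeric(3), A.
#' @slot ligands data.frame (one row per ligand O/N atom) with the atom
#'   record columns plus `distance` (A) and `category` in
#'   `backbone_carbonyl_O, sidechain_O, sidechain_N, water_O, other`,
#'   sorted ascending by distance.
#' @slot cutoff numeric(1), A.
#' @exportClass CoordinationShell
setClass("CoordinationShell",
  representation(center = "numeric", ligands = "data.frame",
                 cutoff = "numeric"))

setValidity("CoordinationShell", function(object) {
  lg <- object@ligands
  if (nrow(lg) > 0) {
    if (any(lg$distance > object@cutoff + 1e-9))
      return("all ligand distances must be <= cutoff")
    if (is.unsorted(lg$distance)) return("ligands must be sorted by distance")
  }
  TRUE
})

#' IonClassification: species call for a coordination shell
#'
#' @slot call one of `potassium, sodium, water, unclassified`.
#' @slot coordinationNumber integer, number of shell ligands.
#' @slot meanDistance arithmetic mean ligand distance, A (NA if empty).
#' @slot acceptorOnlyContacts count of ligands (carbonyl/water O) that a
#'   central water would have to donate a hydrogen bond to.
#' @slot rationale human-readable justification of the call.
#' @exportClass IonClassification
setClass("IonClassification",
  representation(call = "character", coordinationNumber = "integer",
                 meanDistance = "numeric", acceptorOnlyContacts = "integer",
                 rationale = "character"))

setValidity("IonClassification", function(object) {
  if (!object@call %in% c("potassium", "sodium", "water", "unclassified"))
    return("unknown species call")
  TRUE
})
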
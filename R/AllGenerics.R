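#' @include AllClasses.R
NULL

#' Accessors for KinaseScape objects
#'
#' Small accessor generics so downstream code never touches slots.
#'
#' @param x an object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))
#' @rdname accessors
#' @export
setGeneric("unitCell", function(x) standardGeneric("unitCell"))
#' @rdname accessors
#' @export
setGeneric("spaceGroup", function(x) standardGeneric("spaceGroup"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("corePairs", function(x) standardGeneric("corePairs"))
#' @rdname accessors
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))
#' @rdname accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("variances", function(x) standardGeneric("variances"))
#' @rdname accessors
#' @export
setGeneric("modes", function(x) standardGeneric("modes"))
#' @rdname accessors
#' @export
setGeneric("meanCoords", function(x) standardGeneric("meanCoords"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("ionCall", function(x) standardGeneric("ionCall"))
#' @rdname accessors
#' @export
setGeneric("coordinationNumber", function(x) standardGeneric("coordinationNumber"))
#' @rdname accessors
#' @export
setGeneric("meanDistance", function(x) standardGeneric("meanDistance"))
#' @rdname accessors
#' @export
setGeneric("ligands", function(x) standardGeneric("ligands"))

setMethod("atoms", "Structure", function(x) x@atoms)
setMethod("identifier", "Structure", function(x) x@identifier)
setMethod("unitCell", "Structure", function(x) x@unitCell)
setMethod("spaceGroup", "Structure", function(x) x@spaceGroup)
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
setMethod("corePairs", "CoreMap", function(x) x@pairs)
setMethod("rmsd", "SuperpositionResult", function(x) x@rmsd)
setMethod("rotation", "SuperpositionResult", function(x) x@rotation)
setMethod("translation", "SuperpositionResult", function(x) x@translation)
setMethod("nAtoms", "SuperpositionResult", function(x) x@nAtoms)
setMethod("variances", "ConformationPCA", function(x) x@variances)
setMethod("modes", "ConformationPCA", function(x) x@modes)
setMethod("meanCoords", "ConformationPCA", function(x) x@meanCoords)
setMethod("scores", "ConformationPCA", function(x) x@scores)
setMethod("ionCall", "IonClassification", function(x) x@call)
setMethod("coordinationNumber", "IonClassification", function(x) x@coordinationNumber)
setMethod("meanDistance", "IonClassification", function(x) x@meanDistance)
setMethod("coordinationNumber", "CoordinationShell", function(x) nrow(x@ligands))
setMethod("ligands", "CoordinationShell", function(x) x@ligands)

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure", sQuote(object@identifier), "\n")
  cat(" ", nrow(a), "atoms,", length(unique(a$chain)), "chain(s):",
      paste(unique(a$chain), collapse = " "), "\n")
  if (length(object@unitCell) == 6)
    cat("  unit cell:", paste(format(object@unitCell, digits = 5),
                              collapse = " "),
        if (length(object@spaceGroup)) paste0("(", object@spaceGroup, ")"),
        "\n")
  invisible(object)
})

setMethod("show", "AtomSelection", function(object) {
  rng <- if (nrow(object@ranges) == 0) "all residues" else
    paste(apply(object@ranges, 1, function(r)
      if (r[1] == r[2]) r[1] else paste0(r[1], "-", r[2])), collapse = ",")
  cat("AtomSelection chain", object@chain, "residues", rng,
      "atoms", paste(object@atomNames, collapse = ","), "\n")
  invisible(object)
})

setMethod("show", "CoreMap", function(object) {
  cat("CoreMap of", nrow(object@pairs), "residue pairs on atom",
      object@atomName, "\n")
  invisible(object)
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: RMSD %.3f A over %d atoms%s\n",
              object@rmsd, object@nAtoms,
              if (object@degenerate) " (degenerate point set)" else ""))
  invisible(object)
})

setMethod("show", "EnsembleCore", function(object) {
  cat("EnsembleCore:", length(object@members), "members, core size",
      nrow(object@coreMaps[[1]]@pairs), "| reference",
      sQuote(object@referenceId), "\n")
  invisible(object)
})

setMethod("show", "ConformationPCA", function(object) {
  v <- object@variances
  tot <- sum(v)
  cat("ConformationPCA:", object@nMembers, "members,",
      nrow(object@meanCoords), "core residues,", length(v), "modes\n")
  k <- min(3, length(v))
  if (tot > 0)
    cat("  variance explained:",
        paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * v[seq_len(k)] / tot),
              collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "RotationDecomposition", function(object) {
  cat(sprintf("RotationDecomposition: %.2f deg about (%.3f, %.3f, %.3f)\n",
              object@angle, object@axis[1], object@axis[2], object@axis[3]))
  cat(" ", object@nAlign, "aligned /", object@nMoving, "moving Calpha\n")
  invisible(object)
})

setMethod("show", "HelixAxis", function(object) {
  cat(sprintf("HelixAxis over residues %d-%d (%d atoms), direction (%.3f, %.3f, %.3f)\n",
              object@residueRange[1], object@residueRange[2], object@nAtoms,
              object@direction[1], object@direction[2], object@direction[3]))
  invisible(object)
})

setMethod("show", "CoordinationShell", function(object) {
  cat("CoordinationShell:", nrow(object@ligands), "ligands within",
      object@cutoff, "A\n")
  invisible(object)
})

setMethod("show", "IonClassification", function(object) {
  cat(sprintf("IonClassification: %s (CN %d, mean distance %.2f A)\n",
              object@call, object@coordinationNumber, object@meanDistance))
  cat(" ", object@rationale, "\n")
  invisible(object)
})
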
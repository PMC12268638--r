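#' @include superpose.R
NULL

.rotation_angle_axis <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  # axis from the skew part; near 0/180 degrees fall back to the
  # eigenvector of eigenvalue +1
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(v^2)) > 1e-8) {
    axis <- v / sqrt(sum(v^2))
  } else {
    e <- eigen(R)
    i <- which.min(abs(e$values - 1))
    axis <- Re(e$vectors[, i])
    axis <- axis / sqrt(sum(axis^2))
  }
  list(angle = ang * 180 / pi, axis = axis)
}

#' Interlobe (interdomain) rotation between two conformational states
#'
#' Two-stage rigid-body decomposition: structure B is superposed onto
#' structure A over the alignment selection (e.g. the kinase small
#' lobe); a second Kabsch fit between the two structures' moving-set
#' Calpha atoms, in that common frame, gives the rotation carrying the
#' moving domain (e.g. the large lobe) from state A to state B.  The
#' reported angle is `arccos((trace(R) - 1)/2)` in degrees.
#'
#' @param a,b [Structure-class] objects.
#' @param alignSel,movingSel [AtomSelection-class] objects defining the
#'   fixed and moving domains (Calpha matched; >= 3 residues each).
#' @param correspondence `"by_number"` or `"by_alignment"`.
#' @return a [RotationDecomposition-class].
#' @export
interlobeRotation <- function(a, b, alignSel, movingSel,
                              correspondence = c("by_number",
                                                 "by_alignment")) {
  correspondence <- match.arg(correspondence)
  mc <- function(sel) {
    if (correspondence == "by_number") matchCoreByNumber(a, b, sel)
    else matchCoreByAlignment(a, b, sel)
  }
  coreAlign <- mc(alignSel)
  coreMove <- mc(movingSel)
  sup <- superposeStructures(a, b, coreAlign)
  bt <- sup$transformed
  p <- corePairs(coreMove)
  ca <- .residue_atom_coords(a, data.frame(chain = p$chainA,
                                           resno = p$resnoA,
                                           insert = p$insertA),
                             coreMove@atomName)
  cb <- .residue_atom_coords(bt, data.frame(chain = p$chainB,
                                            resno = p$resnoB,
                                            insert = p$insertB),
                             coreMove@atomName)
  fit <- kabsch(ca, cb)
  aa <- .rotation_angle_axis(rotation(fit))
  new("RotationDecomposition", angle = aa$angle, axis = aa$axis,
      alignSelection = alignSel, movingSelection = movingSel,
      nAlign = nAtoms(sup$result), nMoving = nAtoms(fit))
}

#' Fit the axis of a helical segment
#'
#' The direction is the leading principal axis of the segment's Calpha
#' coordinates, sign-fixed N-to-C (positive dot product with the
#' last-minus-first Calpha vector).
#'
#' @param s a [Structure-class].
#' @param range integer(2) inclusive residue interval.
#' @param chain chain identifier (default `"A"`).
#' @return a [HelixAxis-class].
#' @export
helixAxis <- function(s, range, chain = "A") {
  sel <- atomSelection(chain, list(as.integer(range)))
  ca <- selectAtoms(s, sel)
  if (nrow(ca) < 4)
    stop("need at least 4 Calpha atoms in the range (found ",
         nrow(ca), ")")
  X <- as.matrix(ca[, c("x", "y", "z")])
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  dir <- svd(Xc, nu = 0, nv = 3)$v[, 1]
  nc <- X[nrow(X), ] - X[1, ]
  if (sum(dir * nc) < 0) dir <- -dir
  new("HelixAxis", centroid = ctr, direction = dir,
      residueRange = as.integer(range), nAtoms = nrow(ca))
}

#' Change in the angle between two helices across two states
#'
#' For each structure the orientation-aware angle (degrees, in
#' [0, 180], using N-to-C signed axes) between the helices in `range1`
#' and `range2` is computed; the returned value is
#' `angle(a) - angle(b)`.
#'
#' @param a,b [Structure-class] objects.
#' @param range1,range2 integer(2) residue intervals of the two
#'   helices.
#' @param chain chain identifier (default `"A"`).
#' @return numeric(1), degrees.
#' @export
interhelixAngleChange <- function(a, b, range1, range2, chain = "A") {
  ang <- function(s) {
    h1 <- helixAxis(s, range1, chain)
    h2 <- helixAxis(s, range2, chain)
    d <- sum(h1@direction * h2@direction)
    acos(max(-1, min(1, d))) * 180 / pi
  }
  ang(a) - ang(b)
}

.parse_residue_id <- function(resId) {
  # "A:91" / list(chain=, resno=, insert=)
  if (is.character(resId)) {
    parts <- strsplit(resId, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2)
      return(list(chain = parts[1],
                  resno = as.integer(sub("[A-Za-z]$", "", parts[2])),
                  insert = sub("^[0-9]+", "", parts[2])))
    return(list(chain = "A", resno = as.integer(parts[1]), insert = ""))
  }
  if (is.null(resId$insert)) resId$insert <- ""
  resId
}

#' Distance between two residues
#'
#' `calpha` mode measures the Calpha-Calpha distance; `closest_heavy`
#' (the default, appropriate for salt bridges and hydrogen bonds) the
#' minimum over all non-hydrogen atom pairs.
#'
#' @param s a [Structure-class].
#' @param resA,resB residue identifiers, either `"chain:resno"` strings
#'   or lists with `chain`, `resno` and optional `insert`.
#' @param mode `"closest_heavy"` or `"calpha"`.
#' @return numeric(1) distance in A.
#' @export
pairDistance <- function(s, resA, resB,
                         mode = c("closest_heavy", "calpha")) {
  mode <- match.arg(mode)
  ra <- .parse_residue_id(resA)
  rb <- .parse_residue_id(resB)
  a <- atoms(s)
  pick <- function(r) {
    sub <- a[a$chain == r$chain & a$resno == r$resno &
             a$insert == r$insert, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("residue ", r$chain, ":", r$resno, r$insert, " not present")
    sub
  }
  sa <- pick(ra); sb <- pick(rb)
  if (mode == "calpha") {
    sa <- sa[sa$elety == "CA", , drop = FALSE]
    sb <- sb[sb$elety == "CA", , drop = FALSE]
    if (nrow(sa) == 0 || nrow(sb) == 0)
      stop("Calpha atom missing for one of the residues")
  } else {
    sa <- sa[sa$elesy != "H", , drop = FALSE]
    sb <- sb[sb$elesy != "H", , drop = FALSE]
  }
  xa <- as.matrix(sa[, c("x", "y", "z")])
  xb <- as.matrix(sb[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}
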
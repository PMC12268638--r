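#' @include structure-io.R
NULL

#' Match a Calpha core by author residue numbering
#'
#' Residues within the selection carrying the named atom in both
#' structures are paired by identical (chain, residue number,
#' insertion code); used for same-protein comparisons that share a
#' numbering scheme.
#'
#' @param a,b [Structure-class] objects.
#' @param sel an [AtomSelection-class] (its first atom name is matched).
#' @return a [CoreMap-class], ordered by structure A's residue order.
#' @export
matchCoreByNumber <- function(a, b, sel = atomSelection()) {
  atomName <- sel@atomNames[1]
  selA <- initialize(sel, atomNames = atomName)
  atA <- selectAtoms(a, selA)
  atB <- selectAtoms(b, selA)
  keyA <- paste(atA$chain, atA$resno, atA$insert, sep = "\r")
  keyB <- paste(atB$chain, atB$resno, atB$insert, sep = "\r")
  keep <- keyA %in% keyB
  pairs <- data.frame(chainA = atA$chain[keep], resnoA = atA$resno[keep],
                      insertA = atA$insert[keep],
                      chainB = atA$chain[keep], resnoB = atA$resno[keep],
                      insertB = atA$insert[keep],
                      stringsAsFactors = FALSE)
  if (nrow(pairs) < 3)
    stop("insufficient core: only ", nrow(pairs),
         " matched residues (need >= 3)")
  new("CoreMap", pairs = pairs, atomName = atomName)
}

#' Alignment parameters for cross-homolog correspondence
#'
#' @param substitutionMatrix name of a Biostrings substitution matrix
#'   (default `"BLOSUM62"`).
#' @param gapOpen,gapExtend gap penalties (non-positive).  A gap of
#'   length L scores `gapOpen + L * gapExtend`.
#' @return a list of parameters for [alignSequences].
#' @export
alignmentParams <- function(substitutionMatrix = "BLOSUM62",
                            gapOpen = -11, gapExtend = -1) {
  if (gapOpen > 0 || gapExtend > 0) stop("gap penalties must be <= 0")
  list(substitutionMatrix = substitutionMatrix,
       gapOpen = gapOpen, gapExtend = gapExtend)
}

.get_submat <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Deterministic traceback: at score ties prefer the diagonal (match)
#' state, then a gap in sequence B (consume A, "up"), then a gap in
#' sequence A ("left").  A gap of length L scores
#' `gapOpen + L * gapExtend`.
#'
#' @param seqA,seqB non-empty character strings (one-letter amino
#'   acids; unknown letters score via the matrix's `*` column when
#'   present, else 0).
#' @param params see [alignmentParams].
#' @return a list with `pairs` (2-column matrix of 1-based aligned
#'   positions, non-gap columns only) and `score`.
#' @export
alignSequences <- function(seqA, seqB, params = alignmentParams()) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be non-empty")
  S <- .get_submat(params$substitutionMatrix)
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  n <- length(a); m <- length(b)
  sub_score <- function(x, y) {
    if (x %in% rownames(S) && y %in% colnames(S)) return(S[x, y])
    if ("*" %in% rownames(S)) return(S["*", "*"])
    0
  }
  go <- params$gapOpen; ge <- params$gapExtend
  NEG <- -1e9
  # M: a[i] aligned to b[j]; X: gap in B (A consumed, "up"); Y: gap in A
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- go + (i - 1) * ge
  for (j in 2:(m + 1)) Y[1, j] <- go + (j - 1) * ge
  for (i in 2:(n + 1)) {
    si <- a[i - 1]
    for (j in 2:(m + 1)) {
      sc <- sub_score(si, b[j - 1])
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] + go + ge, X[i - 1, j] + ge)
      Y[i, j] <- max(M[i, j - 1] + go + ge, Y[i, j - 1] + ge)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback; tie preference: M (diagonal) > X (up) > Y (left)
  state <- c("M", "X", "Y")[which.max(c(M[n + 1, m + 1], X[n + 1, m + 1],
                                        Y[n + 1, m + 1]))]
  i <- n + 1; j <- m + 1
  pa <- integer(0); pb <- integer(0)
  tol <- 1e-9
  while (i > 1 || j > 1) {
    if (state == "M") {
      pa <- c(i - 1, pa); pb <- c(j - 1, pb)
      sc <- sub_score(a[i - 1], b[j - 1])
      prev <- M[i, j] - sc
      state <- if (abs(M[i - 1, j - 1] - prev) < tol) "M"
               else if (abs(X[i - 1, j - 1] - prev) < tol) "X" else "Y"
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      state <- if (abs(M[i - 1, j] + go + ge - X[i, j]) < tol) "M" else "X"
      i <- i - 1
    } else {
      state <- if (abs(M[i, j - 1] + go + ge - Y[i, j]) < tol) "M" else "Y"
      j <- j - 1
    }
    if (i == 1 && j > 1) state <- "Y"
    if (j == 1 && i > 1) state <- "X"
  }
  list(pairs = cbind(posA = pa, posB = pb), score = score)
}

#' Match a Calpha core across homologs by sequence alignment
#'
#' Global Needleman-Wunsch alignment of the two chain sequences gives
#' the residue correspondence; aligned non-gap columns restricted to
#' the selection on structure A, with both residues Calpha-resolved,
#' become the core.  Degenerates to [matchCoreByNumber] for identical
#' sequences and numbering.
#'
#' @param a,b [Structure-class] objects.
#' @param selA selection applied on structure A's residues.
#' @param params see [alignmentParams].
#' @param chainA,chainB chains to align; default is each structure's
#'   first polymer chain.
#' @return a [CoreMap-class].
#' @export
matchCoreByAlignment <- function(a, b, selA = atomSelection(),
                                 params = alignmentParams(),
                                 chainA = NULL, chainB = NULL) {
  firstChain <- function(s) {
    at <- atoms(s)
    ch <- unique(at$chain[.is_polymer_ca(at)])
    if (!length(ch)) stop("no polymer chain in ", sQuote(identifier(s)))
    ch[1]
  }
  if (is.null(chainA)) chainA <- if (selA@chain != "*") selA@chain else
    firstChain(a)
  if (is.null(chainB)) chainB <- firstChain(b)
  sa <- chainSequence(a, chainA)
  sb <- chainSequence(b, chainB)
  aln <- alignSequences(sa$sequence, sb$sequence, params)
  p <- aln$pairs
  pairs <- data.frame(chainA = chainA, resnoA = sa$resno[p[, 1]],
                      insertA = sa$insert[p[, 1]],
                      chainB = chainB, resnoB = sb$resno[p[, 2]],
                      insertB = sb$insert[p[, 2]],
                      stringsAsFactors = FALSE)
  keep <- .in_selection_res(
    data.frame(chain = pairs$chainA, resno = pairs$resnoA), selA)
  pairs <- pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) < 3)
    stop("insufficient core: only ", nrow(pairs),
         " aligned residues within the selection (need >= 3)")
  new("CoreMap", pairs = pairs, atomName = selA@atomNames[1])
}

#' Kabsch least-squares superposition of paired point sets
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' RMSD of `coordsB` onto `coordsA` (i.e. of `R b + t` against `a`).
#' A reflection in the SVD solution is corrected by flipping the sign
#' of the smallest singular vector.  Near-collinear inputs set the
#' `degenerate` flag (the rotation about the line is undetermined).
#'
#' @param coordsA,coordsB n x 3 matrices with corresponding rows,
#'   n >= 3, finite values.
#' @return a [SuperpositionResult-class].
#' @export
kabsch <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (!is.numeric(A) || !is.numeric(B) || anyNA(A) || anyNA(B) ||
      any(!is.finite(A)) || any(!is.finite(B)))
    stop("coordinates must be finite and non-missing")
  if (nrow(A) != nrow(B)) stop("point sets must have equal size")
  n <- nrow(A)
  if (n < 3) stop("need at least 3 paired points")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Bc, Ac)              # sum_i b_i a_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ca - as.numeric(R %*% cb)
  diff <- Ac - Bc %*% t(R)
  rms <- sqrt(sum(diff^2) / n)
  sva <- svd(Ac, nu = 0, nv = 0)$d
  svb <- svd(Bc, nu = 0, nv = 0)$d
  degen <- (sva[2] <= 1e-8 * max(sva[1], 1)) ||
           (svb[2] <= 1e-8 * max(svb[1], 1))
  if (degen)
    warning("degenerate (near-collinear) point set; ",
            "rotation about the line is undetermined")
  new("SuperpositionResult", rotation = R, translation = t,
      rmsd = rms, nAtoms = as.integer(n), degenerate = degen)
}

#' Superpose one structure onto another over a core
#'
#' Applies [kabsch] over the core's matched atoms and returns both the
#' fit statistics and a transformed copy of the whole of structure B
#' (all atoms moved, not only the core).
#'
#' @param a,b [Structure-class] objects.
#' @param core a [CoreMap-class] valid for both structures.
#' @return list with `result` (a [SuperpositionResult-class]) and
#'   `transformed` (structure B after the fit).
#' @export
superposeStructures <- function(a, b, core) {
  p <- corePairs(core)
  ca <- .residue_atom_coords(a, data.frame(chain = p$chainA,
                                           resno = p$resnoA,
                                           insert = p$insertA),
                             core@atomName)
  cb <- .residue_atom_coords(b, data.frame(chain = p$chainB,
                                           resno = p$resnoB,
                                           insert = p$insertB),
                             core@atomName)
  res <- kabsch(ca, cb)
  list(result = res,
       transformed = transformStructure(b, rotation(res), translation(res)))
}

#' Export a core map as a two-column residue-pair table
#'
#' @param core a [CoreMap-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCoreMap <- function(core, path) {
  p <- corePairs(core)
  out <- data.frame(residueA = paste0(p$chainA, ":", p$resnoA, p$insertA),
                    residueB = paste0(p$chainB, ":", p$resnoB, p$insertB))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a superposition result as JSON
#'
#' @param x a [SuperpositionResult-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeSuperposition <- function(x, path) {
  jsonlite::write_json(list(rotation = rotation(x),
                            translation = translation(x),
                            rmsd = rmsd(x), n_atoms = nAtoms(x)),
                       path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
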
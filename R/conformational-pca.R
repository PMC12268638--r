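#' @include superpose.R
NULL

#' Build the common Calpha core of an ensemble
#'
#' Each member is mapped onto the reference (by shared author numbering
#' or by global sequence alignment); the core is the set of reference
#' residues present, with the selected atom, in every member, ordered
#' by reference residue order.
#'
#' @param structures named list of [Structure-class] objects (names are
#'   the member identifiers) or an unnamed list (identifiers taken from
#'   the structures).
#' @param selection an [AtomSelection-class] over the reference.
#' @param mode `"by_number"` or `"by_alignment"`.
#' @param referenceId identifier of the reference member (default: the
#'   first).
#' @return an [EnsembleCore-class].
#' @export
buildEnsembleCore <- function(structures,
                              selection = atomSelection(),
                              mode = c("by_number", "by_alignment"),
                              referenceId = NULL) {
  mode <- match.arg(mode)
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, identifier, character(1))
  if (length(structures) < 3) stop("need at least 3 structures")
  if (is.null(referenceId)) referenceId <- names(structures)[1]
  if (!referenceId %in% names(structures))
    stop("referenceId ", sQuote(referenceId), " not among the members")
  ref <- structures[[referenceId]]
  maps <- lapply(names(structures), function(id) {
    s <- structures[[id]]
    if (mode == "by_number") matchCoreByNumber(ref, s, selection)
    else matchCoreByAlignment(ref, s, selection)
  })
  names(maps) <- names(structures)
  refkey <- function(m) {
    p <- corePairs(m)
    paste(p$chainA, p$resnoA, p$insertA, sep = "\r")
  }
  common <- Reduce(intersect, lapply(maps, refkey))
  if (length(common) < 10) {
    sizes <- vapply(maps, function(m) sum(refkey(m) %in% common),
                    integer(1))
    lim <- names(sizes)[order(vapply(maps, function(m) nrow(corePairs(m)),
                                     integer(1)))][1:min(3, length(sizes))]
    stop("insufficient ensemble core (", length(common),
         " residues, need >= 10); most limiting members: ",
         paste(lim, collapse = ", "))
  }
  # restrict each map to the common reference residues, reference order
  refOrder <- refkey(maps[[referenceId]])
  common <- refOrder[refOrder %in% common]
  maps <- lapply(maps, function(m) {
    p <- corePairs(m)
    idx <- match(common, refkey(m))
    initialize(m, pairs = {
      q <- p[idx, , drop = FALSE]; rownames(q) <- NULL; q
    })
  })
  new("EnsembleCore", referenceId = referenceId,
      members = names(structures), coreMaps = maps,
      selection = selection)
}

.core_ref_keys <- function(core) {
  p <- corePairs(core@coreMaps[[core@referenceId]])
  data.frame(chain = p$chainA, resno = p$resnoA, insert = p$insertA,
             stringsAsFactors = FALSE)
}

.member_core_coords <- function(core, s, memberId) {
  m <- core@coreMaps[[memberId]]
  p <- corePairs(m)
  .residue_atom_coords(s, data.frame(chain = p$chainB, resno = p$resnoB,
                                     insert = p$insertB), m@atomName)
}

#' Iteratively align an ensemble to its mean conformation
#'
#' Generalised-Procrustes style alignment: starting from the reference
#' member's frame, every member is Kabsch-superposed onto the current
#' mean conformation and the mean recomputed, until the mean shifts by
#' less than `tol` (RMSD, A) or `maxIter` iterations are reached (then
#' a warning is issued and the last iterate is used).
#'
#' @param core an [EnsembleCore-class].
#' @param structures the named list used to build the core.
#' @param tol convergence tolerance on the mean shift (A RMSD).
#' @param maxIter iteration cap.
#' @return an n x 3m matrix of aligned flattened coordinates
#'   (x1,y1,z1,x2,...), rownames = member ids, with attributes
#'   `iterations`, `converged` and `refKeys`.
#' @export
alignEnsemble <- function(core, structures, tol = 1e-9, maxIter = 64L) {
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, identifier, character(1))
  coords <- lapply(core@members, function(id)
    .member_core_coords(core, structures[[id]], id))
  names(coords) <- core@members
  m <- nrow(coords[[1]])
  meanC <- coords[[core@referenceId]]
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    coords <- lapply(coords, function(x) {
      f <- kabsch(meanC, x)
      sweep(x %*% t(rotation(f)), 2, -translation(f))
    })
    newMean <- Reduce(`+`, coords) / length(coords)
    shift <- sqrt(sum((newMean - meanC)^2) / m)
    meanC <- newMean
    if (shift < tol) { converged <- TRUE; break }
    if (iterations >= maxIter) break
  }
  if (!converged)
    warning("ensemble alignment did not converge in ", maxIter,
            " iterations; proceeding with the last iterate")
  # final realignment onto the converged mean so every row is exactly
  # the Kabsch image of its member on the stored mean
  coords <- lapply(coords, function(x) {
    f <- kabsch(meanC, x)
    sweep(x %*% t(rotation(f)), 2, -translation(f))
  })
  mat <- do.call(rbind, lapply(coords, function(x) as.numeric(t(x))))
  rownames(mat) <- core@members
  attr(mat, "iterations") <- iterations
  attr(mat, "converged") <- converged
  attr(mat, "refKeys") <- .core_ref_keys(core)
  mat
}

#' Fit principal components of conformation
#'
#' Eigen-decomposition (via SVD) of the covariance of the row-centred
#' aligned coordinates.  Modes are unit 3m-vectors; variances are the
#' covariance eigenvalues (A^2), non-increasing.  Sign convention: when
#' a per-member `openness` score is supplied, PC1 is flipped so the
#' most-open member projects positively; every other mode (and PC1
#' otherwise) has its first non-zero component positive.
#'
#' @param mat n x 3m aligned coordinate matrix (see [alignEnsemble]),
#'   n >= 3.
#' @param openness optional numeric(n) interlobe-opening score per
#'   member (larger = more open), used only to orient PC1.
#' @return a [ConformationPCA-class].
#' @export
fitConformationPCA <- function(mat, openness = NULL) {
  n <- nrow(mat)
  if (n < 3) stop("need at least 3 ensemble members")
  mu <- colMeans(mat)
  X <- sweep(mat, 2, mu)
  k <- min(n - 1L, ncol(mat))
  sv <- svd(X, nu = k, nv = k)
  vars <- sv$d[seq_len(k)]^2 / (n - 1)
  V <- sv$v
  sc <- X %*% V
  for (j in seq_len(k)) {
    flip <- FALSE
    if (j == 1 && !is.null(openness)) {
      if (length(openness) != n)
        stop("openness must have one value per member")
      flip <- sc[which.max(openness), 1] < 0
    } else {
      nz <- which(abs(V[, j]) > 1e-9)
      flip <- length(nz) > 0 && V[nz[1], j] < 0
    }
    if (flip) { V[, j] <- -V[, j]; sc[, j] <- -sc[, j] }
  }
  dimnames(sc) <- list(rownames(mat), paste0("PC", seq_len(k)))
  refKeys <- attr(mat, "refKeys")
  if (is.null(refKeys)) refKeys <- data.frame()
  new("ConformationPCA",
      meanCoords = matrix(mu, ncol = 3, byrow = TRUE),
      modes = V, variances = vars, nMembers = as.integer(n),
      memberIds = if (is.null(rownames(mat))) character(n) else
        rownames(mat),
      scores = sc, refKeys = refKeys)
}

#' Count modes above the noise floor
#'
#' A mode is called significant when its variance exceeds `factor`
#' times the median of all positive variances; with a few real motions
#' on top of isotropic coordinate noise the median sits at the noise
#' level, so this separates structure from noise without a tunable
#' per-dataset threshold.
#'
#' @param model a [ConformationPCA-class].
#' @param factor multiple of the median variance (default 3).
#' @return integer count of significant modes.
#' @export
significantModes <- function(model, factor = 3) {
  v <- variances(model)
  v <- v[v > 1e-12]
  if (!length(v)) return(0L)
  sum(v > factor * stats::median(v))
}

#' Project a structure into an ensemble PC space
#'
#' The structure's core Calpha coordinates (ordered by the model's
#' reference residue order via `coreMap`) are Kabsch-superposed onto
#' the model mean; the centred displacement is dotted with each mode.
#' Scores carry A units.
#'
#' @param model a [ConformationPCA-class].
#' @param structure a [Structure-class] providing all core residues.
#' @param coreMap a [CoreMap-class] from the model's reference (A side)
#'   to `structure` (B side), e.g. from [matchCoreByNumber].
#' @return named numeric vector of PC scores (A).
#' @export
projectStructure <- function(model, structure, coreMap) {
  p <- corePairs(coreMap)
  keyMap <- paste(p$chainA, p$resnoA, p$insertA, sep = "\r")
  rk <- model@refKeys
  if (nrow(rk) > 0) {
    want <- paste(rk$chain, rk$resno, rk$insert, sep = "\r")
    idx <- match(want, keyMap)
    if (anyNA(idx)) {
      miss <- rk[is.na(idx), , drop = FALSE]
      stop("core residues missing from the supplied map: ",
           paste(paste0(miss$chain, ":", miss$resno, miss$insert),
                 collapse = ", "))
    }
    p <- p[idx, , drop = FALSE]
  }
  x <- .residue_atom_coords(structure,
                            data.frame(chain = p$chainB, resno = p$resnoB,
                                       insert = p$insertB),
                            coreMap@atomName)
  f <- kabsch(model@meanCoords, x)
  aligned <- sweep(x %*% t(rotation(f)), 2, -translation(f))
  disp <- as.numeric(t(aligned)) - as.numeric(t(model@meanCoords))
  out <- as.numeric(disp %*% model@modes)
  names(out) <- paste0("PC", seq_along(out))
  out
}

#' Reconstruct an aligned conformation from PC scores
#'
#' @param model a [ConformationPCA-class].
#' @param scores numeric vector of PC scores (recycled to the stored
#'   mode count with zeros).
#' @return m x 3 coordinate matrix.
#' @export
reconstructConformation <- function(model, scores) {
  k <- ncol(model@modes)
  s <- numeric(k)
  s[seq_along(scores)] <- scores
  flat <- as.numeric(t(model@meanCoords)) + as.numeric(model@modes %*% s)
  matrix(flat, ncol = 3, byrow = TRUE)
}

#' Serialise a ConformationPCA model to JSON
#'
#' @param model a [ConformationPCA-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePCAModel <- function(model, path) {
  jsonlite::write_json(
    list(mean = model@meanCoords, modes = model@modes,
         variances = model@variances, n_members = model@nMembers,
         member_ids = model@memberIds),
    path, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  invisible(path)
}
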
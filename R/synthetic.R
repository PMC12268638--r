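#' @include structure-io.R
NULL

.rot_x <- function(deg) {
  r <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(r), -sin(r), 0, sin(r), cos(r)), 3, 3,
         byrow = TRUE)
}
.rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), -sin(r), 0, sin(r), cos(r), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# rotation taking unit vector u onto unit vector v (Rodrigues)
.rot_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u; ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Ideal alpha-helical Calpha trace
#'
#' Generates an ideal helix (default rise 1.5 A/residue, 100 degrees
#' per residue, radius 2.3 A) along a requested axis direction.
#'
#' @param nRes number of residues (>= 4).
#' @param rise rise per residue, A.
#' @param twist rotation per residue, degrees.
#' @param radius helix radius, A.
#' @param axis direction of the helix axis (any non-zero 3-vector).
#' @param origin start of the axis, A.
#' @param chain chain id.
#' @param startRes first residue number.
#' @param id structure identifier.
#' @return a [Structure-class] fragment (Calpha only, all ALA).
#' @export
makeHelix <- function(nRes, rise = 1.5, twist = 100, radius = 2.3,
                      axis = c(0, 0, 1), origin = c(0, 0, 0),
                      chain = "A", startRes = 1L, id = "helix") {
  if (nRes < 4) stop("need at least 4 residues for a helix")
  i <- seq_len(nRes) - 1
  ang <- i * twist * pi / 180
  local <- cbind(radius * cos(ang), radius * sin(ang), i * rise)
  R <- .rot_between(c(0, 0, 1), axis)
  xyz <- local %*% t(R)
  xyz <- sweep(xyz, 2, -as.numeric(origin))
  newStructure(data.frame(chain = chain,
                          resno = startRes + i,
                          resid = "ALA", elety = "CA", elesy = "C",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
               id = id)
}

# Compact helical-bundle lobe scaffold: antiparallel 15-residue
# helices packed 8 A apart on a 2-D grid, so the bundle has comparable
# extent along every axis and rigid-body fits are well-conditioned.
# Deterministic given n.  Returns an n x 3 coordinate matrix.
.lobe_scaffold <- function(n) {
  per <- 15L
  coords <- matrix(0, n, 3)
  res <- 1L
  h <- 0L
  while (res <= n) {
    k <- min(per, n - res + 1L)
    i <- seq_len(k) - 1
    ang <- i * 100 * pi / 180
    z <- i * 1.5
    if (h %% 2L == 1L) z <- (per - 1) * 1.5 - z   # antiparallel
    nh <- ceiling(n / per)
    ctr <- if (nh == 1) c(0, 0) else
      12 * c(cos(2 * pi * h / nh), sin(2 * pi * h / nh))
    coords[res:(res + k - 1L), ] <- cbind(2.3 * cos(ang) + ctr[1],
                                          2.3 * sin(ang) + ctr[2],
                                          z)
    res <- res + k
    h <- h + 1L
  }
  coords
}

#' Parameters of the synthetic two-lobe model
#'
#' @param nSmall,nLarge residues per lobe (>= 10; defaults 60 / 120,
#'   matching the relative sizes of a kinase small and large lobe).
#' @param thetaOpen opening angle, degrees: rotation of the large lobe
#'   about a hinge axis (x) through the interlobe junction, swinging
#'   the lobes apart like a jaw.
#' @param phiTwist twist angle, degrees: rotation of the large lobe
#'   about the lobe-connecting (z) axis.
#' @param noiseSd isotropic Gaussian coordinate noise per atom, A.
#' @param seed integer RNG seed.
#' @return a validated parameter list.
#' @export
twoLobeParams <- function(nSmall = 60L, nLarge = 120L, thetaOpen = 0,
                          phiTwist = 0, noiseSd = 0, seed = 1L) {
  if (nSmall < 10 || nLarge < 10) stop("lobes need >= 10 residues")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  list(nSmall = as.integer(nSmall), nLarge = as.integer(nLarge),
       thetaOpen = thetaOpen, phiTwist = phiTwist, noiseSd = noiseSd,
       seed = as.integer(seed))
}

#' Synthetic two-lobe Calpha protein with controllable opening/twist
#'
#' Two compact helical-bundle lobes joined at a hinge at the origin.
#' The small lobe (residues `1..nSmall`, centred above the hinge) is
#' fixed; the large lobe (residues `nSmall+1..nSmall+nLarge`, centred
#' below) is rotated by `phiTwist` about the lobe-connecting axis
#' through its own centroid, then by `thetaOpen` about the hinge axis,
#' so that for equal twists the recovered interlobe rotation equals
#' the opening-angle difference exactly, and the inter-lobe centroid
#' distance grows monotonically with opening.  Gaussian noise is added
#' with the stated seed; identical parameters and seed give bitwise-
#' identical coordinates.
#'
#' @param params see [twoLobeParams].
#' @param id structure identifier.
#' @return list with `structure` (a [Structure-class], chain A) and
#'   `truth` (data.frame of the generating parameters).
#' @export
makeTwoLobe <- function(params = twoLobeParams(), id = "twolobe") {
  p <- params
  small <- .lobe_scaffold(p$nSmall)
  large <- .lobe_scaffold(p$nLarge)
  # small lobe centred at (0, 12, 10); large at (0, 12, -10); hinge at
  # the origin between them
  small <- sweep(small, 2, colMeans(small))
  small <- sweep(small, 2, -c(0, 12, 10))
  large <- sweep(large, 2, colMeans(large))
  largeCtr <- c(0, 12, -10)
  large <- large %*% t(.rot_z(p$phiTwist))        # twist about lobe axis
  large <- sweep(large, 2, -largeCtr)
  large <- large %*% t(.rot_x(-p$thetaOpen))      # opening about hinge
  xyz <- rbind(small, large)
  if (p$noiseSd > 0) {
    set.seed(p$seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, p$noiseSd),
                        ncol = 3)
  }
  n <- p$nSmall + p$nLarge
  s <- newStructure(data.frame(chain = "A", resno = seq_len(n),
                               resid = "ALA", elety = "CA", elesy = "C",
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                    id = id)
  truth <- data.frame(id = id, theta_open = p$thetaOpen,
                      phi_twist = p$phiTwist, noise_sd = p$noiseSd,
                      seed = p$seed, n_small = p$nSmall,
                      n_large = p$nLarge, stringsAsFactors = FALSE)
  list(structure = s, truth = truth)
}

#' Default lobe selections of the synthetic two-lobe model
#'
#' @param nSmall,nLarge lobe sizes used at generation.
#' @return named list of [AtomSelection-class]: `small`, `large`, `all`.
#' @export
twoLobeSelections <- function(nSmall = 60L, nLarge = 120L) {
  list(small = atomSelection("A", list(c(1L, nSmall))),
       large = atomSelection("A", list(c(nSmall + 1L, nSmall + nLarge))),
       all = atomSelection("A", list(c(1L, nSmall + nLarge))))
}

#' Ensemble of synthetic two-lobe structures
#'
#' Per-member seeds are derived as `seed + index` so an ensemble can be
#' extended without seed collisions.
#'
#' @param thetaList,phiList opening/twist angles, degrees.  With
#'   `sampling = "paired"` the lists are matched element-wise (the
#'   shorter recycled); `"grid"` takes their Cartesian product.
#' @param noiseSd coordinate noise, A.
#' @param seed base seed.
#' @param sampling `"paired"` or `"grid"`.
#' @param nSmall,nLarge lobe sizes.
#' @return list with `structures` (named list) and `truth` (data.frame,
#'   one row per member).
#' @export
makeEnsemble <- function(thetaList, phiList = 0, noiseSd = 0, seed = 1L,
                         sampling = c("paired", "grid"),
                         nSmall = 60L, nLarge = 120L) {
  sampling <- match.arg(sampling)
  if (!length(thetaList) || !length(phiList))
    stop("angle lists must be non-empty")
  if (sampling == "grid") {
    g <- expand.grid(theta = thetaList, phi = phiList)
  } else {
    n <- max(length(thetaList), length(phiList))
    g <- data.frame(theta = rep_len(thetaList, n),
                    phi = rep_len(phiList, n))
  }
  out <- lapply(seq_len(nrow(g)), function(i) {
    makeTwoLobe(twoLobeParams(nSmall, nLarge, g$theta[i], g$phi[i],
                              noiseSd, seed + i),
                id = sprintf("m%03d", i))
  })
  structures <- lapply(out, `[[`, "structure")
  names(structures) <- vapply(structures, identifier, character(1))
  list(structures = structures,
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Random two-lobe ensemble with independent opening and twist
#'
#' Opening angles are drawn from N(`thetaMean`, `thetaSd`^2) and twists
#' from N(0, `phiSd`^2), independently, then structures are generated
#' as in [makeEnsemble].
#'
#' @param n number of members.
#' @param thetaMean,thetaSd opening distribution, degrees.
#' @param phiSd twist standard deviation, degrees.
#' @param noiseSd coordinate noise, A.
#' @param seed base seed (used for the angle draws; member noise seeds
#'   are `seed + index`).
#' @return as [makeEnsemble].
#' @export
makeRandomEnsemble <- function(n = 30L, thetaMean = 20, thetaSd = 15,
                               phiSd = 4, noiseSd = 0.2, seed = 11L) {
  set.seed(seed)
  theta <- stats::rnorm(n, thetaMean, thetaSd)
  phi <- stats::rnorm(n, 0, phiSd)
  makeEnsemble(theta, phi, noiseSd, seed, sampling = "paired")
}

.octahedral_dirs <- function(cn) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1),
                c(1, 1, 1) / sqrt(3), c(-1, -1, -1) / sqrt(3))
  dirs[seq_len(cn), , drop = FALSE]
}

#' Synthetic coordinated cation site
#'
#' A central monatomic ion (K+ or Na+) surrounded by `cn` water oxygens
#' at octahedral (or cn-truncated) vertices; radial distances are
#' `meanDistance + N(0, distortionSd)`, seeded.
#'
#' @param species `"potassium"` or `"sodium"`.
#' @param meanDistance target ligand distance, A.
#' @param cn coordination number in \[2, 8\].
#' @param distortionSd radial distortion, A.
#' @param seed integer seed.
#' @param center site position, A.
#' @param id structure identifier.
#' @return list with `structure` ([Structure-class]) and `truth`
#'   (data.frame: species, mean_distance, coordination_number, the
#'   realised mean distance, seed).
#' @export
makeIonSite <- function(species = c("potassium", "sodium"),
                        meanDistance = 2.8, cn = 6L, distortionSd = 0,
                        seed = 1L, center = c(0, 0, 0), id = "ionsite") {
  species <- match.arg(species)
  if (cn < 2 || cn > 8) stop("cn must lie in [2, 8]")
  elem <- if (species == "potassium") "K" else "NA"
  set.seed(seed)
  r <- meanDistance + stats::rnorm(cn, 0, distortionSd)
  dirs <- .octahedral_dirs(cn)
  lig <- sweep(dirs * r, 2, -as.numeric(center))
  atomsDf <- rbind(
    data.frame(chain = "A", resno = 1L, resid = elem, elety = elem,
               elesy = elem, type = "HETATM",
               x = center[1], y = center[2], z = center[3]),
    data.frame(chain = "A", resno = 100L + seq_len(cn), resid = "HOH",
               elety = "O", elesy = "O", type = "HETATM",
               x = lig[, 1], y = lig[, 2], z = lig[, 3]))
  s <- newStructure(atomsDf, id = id)
  truth <- data.frame(id = id, species = species,
                      mean_distance = meanDistance,
                      realised_mean_distance = mean(r),
                      coordination_number = cn,
                      distortion_sd = distortionSd, seed = seed,
                      stringsAsFactors = FALSE)
  list(structure = s, truth = truth)
}
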
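# Shared fixtures and independent oracles, built in code.

# minimal hand-written PDB text: 3 Calpha residues on chain A plus
# configurable extras
write_toy_pdb <- function(path, lines = NULL) {
  base <- c(
    "CRYST1   78.000   80.000   70.000  90.00  90.00  90.00 P 21 21 21    4",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 10.00           C",
    "ATOM      2  CA  GLY A   2       4.000   2.000   3.000  1.00 10.00           C",
    "ATOM      3  CA  SER A   3       7.000   2.000   3.000  1.00 10.00           C")
  writeLines(c(base, lines, "END"), path)
  path
}

# Calpha-only toy chain: residues `resnos` on a line, 3.8 A apart
toy_chain <- function(resnos, chain = "A", offset = c(0, 0, 0),
                      id = "toy") {
  n <- length(resnos)
  newStructure(data.frame(chain = chain, resno = resnos, resid = "ALA",
                          elety = "CA", elesy = "C",
                          x = 3.8 * seq_len(n) + offset[1],
                          y = offset[2] + 0.3 * seq_len(n)^1.5,
                          z = offset[3] + sin(seq_len(n))),
               id = id)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quat_to_rot(q)
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Independent superposition oracle: brute-force minimisation of RMSD
# over rotations parameterised by quaternions -- a random fine grid
# followed by derivative-free polishing of the best grid point.  Never
# touches the SVD route used by kabsch().
oracle_min_rmsd <- function(A, B, n_grid = 4000) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(q) {
    q <- q / sqrt(sum(q^2))
    R <- quat_to_rot(q)
    sqrt(sum((Ac - Bc %*% t(R))^2) / nrow(A))
  }
  qs <- matrix(stats::rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj)
  best <- qs[which.min(vals), ]
  fit <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-15, maxit = 5000))
  min(vals, fit$value, fit2$value)
}

# Brute-force enumeration of all global alignments of two tiny
# sequences under the same affine scheme (gap of length L costs
# gapOpen + L*gapExtend); independent of the DP implementation.
enumerate_alignments <- function(sa, sb, S, gapOpen, gapExtend) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  best <- list(score = -Inf, alignments = list())
  rec <- function(i, j, cols, lastState) {
    if (i > length(a) && j > length(b)) {
      sc <- score_alignment(cols, S, gapOpen, gapExtend)
      if (sc > best$score + 1e-9) {
        best$score <<- sc
        best$alignments <<- list(cols)
      } else if (abs(sc - best$score) < 1e-9) {
        best$alignments[[length(best$alignments) + 1]] <<- cols
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, c(cols, list(c(i, j))), "M")
    if (i <= length(a)) rec(i + 1, j, c(cols, list(c(i, NA))), "X")
    if (j <= length(b)) rec(i, j + 1, c(cols, list(c(NA, j))), "Y")
  }
  score_alignment <- function(cols, S, go, ge) {
    sc <- 0; inGapX <- FALSE; inGapY <- FALSE
    for (cl in cols) {
      if (!is.na(cl[1]) && !is.na(cl[2])) {
        sc <- sc + S[a[cl[1]], b[cl[2]]]
        inGapX <- inGapY <- FALSE
      } else if (is.na(cl[2])) {
        sc <- sc + ge + if (!inGapX) go else 0
        inGapX <- TRUE; inGapY <- FALSE
      } else {
        sc <- sc + ge + if (!inGapY) go else 0
        inGapY <- TRUE; inGapX <- FALSE
      }
    }
    sc
  }
  rec(1, 1, list(), "")
  best
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
})
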
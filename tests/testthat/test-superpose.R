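test_that("core matching by number intersects resolved residues", {
  a <- toy_chain(1:10)
  b <- toy_chain(1:10)
  core <- matchCoreByNumber(a, b, atomSelection("A", NULL))
  expect_equal(nrow(corePairs(core)), 10L)
  # A missing residue 5, B missing residue 7 -> 8 pairs
  a2 <- toy_chain(setdiff(1:10, 5))
  b2 <- toy_chain(setdiff(1:10, 7))
  core2 <- matchCoreByNumber(a2, b2, atomSelection("A", list(c(1, 10))))
  expect_equal(nrow(corePairs(core2)), 8L)
  expect_false(any(c(5, 7) %in% corePairs(core2)$resnoA))
  expect_error(matchCoreByNumber(toy_chain(1:3), toy_chain(4:6)),
               "insufficient core")
})

test_that("global alignment matches a brute-force enumeration oracle", {
  # identical sequences: identity mapping
  aln <- alignSequences("ACDE", "ACDE")
  expect_equal(aln$pairs[, "posA"], 1:4, ignore_attr = TRUE)
  expect_equal(aln$pairs[, "posB"], 1:4, ignore_attr = TRUE)
  # tiny gapped case against exhaustive enumeration of all alignments
  p <- alignmentParams(gapOpen = -10, gapExtend = -1)
  aln2 <- alignSequences("ACDE", "ADE", p)
  oracle <- enumerate_alignments("ACDE", "ADE", blosum62, -10, -1)
  expect_equal(aln2$score, oracle$score)
  # the optimum aligns A-A, D-D, E-E with C gapped
  expect_equal(unname(aln2$pairs),
               cbind(c(1L, 3L, 4L), c(1L, 2L, 3L)), ignore_attr = TRUE)
  # another random tiny pair: score must equal the enumeration optimum
  aln3 <- alignSequences("WNDQ", "WQ", p)
  oracle3 <- enumerate_alignments("WNDQ", "WQ", blosum62, -10, -1)
  expect_equal(aln3$score, oracle3$score)
})

test_that("alignment traceback tie-break is deterministic", {
  # AAAA vs AAA: several equal-scoring alignments exist; the stated
  # preference (diagonal, then gap-in-B, then gap-in-A) pushes the gap
  # to the front of A
  expected <- cbind(posA = 2:4, posB = 1:3)
  for (i in 1:3)
    expect_equal(alignSequences("AAAA", "AAA")$pairs, expected)
})

test_that("alignment scores agree with an independent aligner", {
  aa <- rownames(blosum62)[1:20]
  set.seed(42)
  for (i in 1:5) {
    sa <- paste(sample(aa, sample(8:15, 1), TRUE), collapse = "")
    sb <- paste(sample(aa, sample(6:12, 1), TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      sa, sb, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(alignSequences(sa, sb)$score, ref)
  }
})

test_that("kabsch recovers exact transforms and flags degeneracy", {
  set.seed(7)
  A <- matrix(rnorm(18, sd = 5), ncol = 3)
  r0 <- kabsch(A, A)
  expect_equal(rmsd(r0), 0, tolerance = 1e-12)
  expect_equal(rotation(r0), diag(3), tolerance = 1e-9)
  # known rotation + translation
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  B <- sweep(A %*% t(R), 2, -c(1, 2, 3))
  fit <- kabsch(B, A)            # maps A onto B; B = R A + t
  expect_lt(rmsd(fit), 1e-9)
  ang <- acos((sum(diag(rotation(fit))) - 1) / 2) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-9)
  expect_equal(abs(det(rotation(fit))), 1, tolerance = 1e-12)
  # NaN input errors; collinear input warns and flags
  A2 <- A; A2[1, 1] <- NaN
  expect_error(kabsch(A2, A), "finite")
  line <- cbind(1:5, 0, 0)
  expect_warning(fitd <- kabsch(line, line), "degenerate")
  expect_true(fitd@degenerate)
})

test_that("reflection-only relationships yield a proper rotation", {
  set.seed(8)
  A <- matrix(rnorm(24, sd = 4), ncol = 3)
  B <- A %*% diag(c(-1, 1, 1))            # mirror image
  fit <- kabsch(A, B)
  expect_equal(det(rotation(fit)), 1, tolerance = 1e-12)
  expect_gt(rmsd(fit), 0.1)               # a mirror cannot be rotated away
})

test_that("rmsd is symmetric and rigid-transform invariant", {
  set.seed(21)
  for (i in 1:5) {
    A <- matrix(rnorm(27, sd = 6), ncol = 3)
    B <- A + matrix(rnorm(27, sd = 0.8), ncol = 3)
    r1 <- rmsd(kabsch(A, B))
    r2 <- rmsd(kabsch(B, A))
    expect_equal(r1, r2, tolerance = 1e-9)
    R <- random_rotation()
    Bt <- sweep(B %*% t(R), 2, -c(3, -2, 9))
    expect_equal(rmsd(kabsch(A, Bt)), r1, tolerance = 1e-9)
  }
})

test_that("superposition transforms the whole structure, not the core", {
  tl <- makeTwoLobe(twoLobeParams())
  s <- tl$structure
  set.seed(5)
  R <- random_rotation()
  s2 <- transformStructure(s, R, c(4, 5, 6))
  core <- matchCoreByNumber(s, s2, atomSelection("A", list(c(1, 60))))
  out <- superposeStructures(s, s2, core)
  expect_lt(rmsd(out$result), 1e-9)
  expect_equal(nAtoms(out$result), 60L)
  # every atom (including those outside the fitted core) returns home
  d <- as.matrix(atoms(out$transformed)[, c("x", "y", "z")]) -
       as.matrix(atoms(s)[, c("x", "y", "z")])
  expect_lt(max(abs(d)), 1e-8)
})

test_that("alignment-based cores degenerate to numbering for identical sequences", {
  a <- toy_chain(1:30)
  b <- toy_chain(1:30, offset = c(2, 1, -1))
  sel <- atomSelection("A", list(c(1, 30)))
  byNum <- corePairs(matchCoreByNumber(a, b, sel))
  byAln <- corePairs(matchCoreByAlignment(a, b, sel))
  expect_equal(byAln, byNum)
})

test_that("alignment-based core excludes an insertion in the homolog", {
  # homolog with a 2-residue insertion after position 10: same spatial
  # chain, distinctive sequence so the alignment is unambiguous
  seqA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
            "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
            "THR", "TRP", "TYR", "VAL")
  mk <- function(resids, resnos) {
    n <- length(resids)
    newStructure(data.frame(chain = "A", resno = resnos, resid = resids,
                            elety = "CA", elesy = "C",
                            x = 3.8 * seq_len(n),
                            y = 0.3 * seq_len(n)^1.5,
                            z = sin(seq_len(n))))
  }
  a <- mk(seqA, 1:20)
  bResids <- append(seqA, c("GLY", "GLY"), after = 10)
  b <- mk(bResids, 1:22)
  core <- matchCoreByAlignment(a, b, atomSelection("A", list(c(1, 20))))
  p <- corePairs(core)
  expect_equal(nrow(p), 20L)               # all of A maps around the gap
  expect_equal(p$resnoA, 1:20)
  expect_equal(p$resnoB, c(1:10, 13:22))   # insertion skipped on B
  # map export round-trips as a two-column table
  f <- tempfile(fileext = ".tsv")
  writeCoreMap(core, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 20L)
})
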
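make_test_ensemble <- function(thetas, phis = 0, noise = 0, seed = 1) {
  makeEnsemble(thetas, phis, noiseSd = noise, seed = seed)
}

test_that("ensemble core is the intersection of resolved residues", {
  structs <- lapply(1:5, function(i) toy_chain(1:40, id = paste0("s", i)))
  names(structs) <- paste0("s", 1:5)
  sel <- atomSelection("A", list(c(1, 40)))
  core <- buildEnsembleCore(structs, sel)
  expect_equal(nrow(corePairs(core@coreMaps[[1]])), 40L)
  # one member missing residues 20-25 shrinks the core for everyone
  structs$s3 <- toy_chain(setdiff(1:40, 20:25), id = "s3")
  core2 <- buildEnsembleCore(structs, sel)
  sizes <- vapply(core2@coreMaps, function(m) nrow(corePairs(m)),
                  integer(1))
  expect_true(all(sizes == 34L))
  expect_false(any(20:25 %in% corePairs(core2@coreMaps$s1)$resnoA))
  expect_error(buildEnsembleCore(structs[1:2], sel), "at least 3")
  # core below 10 residues names the limiting member
  structs$s2 <- toy_chain(1:5, id = "s2")
  expect_error(buildEnsembleCore(structs, sel), "insufficient.*s2")
})

test_that("aligning rigid copies collapses them onto one conformation", {
  base <- makeTwoLobe(twoLobeParams(thetaOpen = 20))$structure
  set.seed(3)
  structs <- lapply(1:5, function(i) {
    s <- transformStructure(base, random_rotation(), rnorm(3, sd = 20))
    initialize(s, identifier = paste0("c", i))
  })
  names(structs) <- paste0("c", 1:5)
  core <- buildEnsembleCore(structs, atomSelection("A", NULL))
  mat <- alignEnsemble(core, structs)
  expect_true(attr(mat, "converged"))
  spread <- apply(mat, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
})

test_that("two members end equidistant from the converged mean", {
  e <- make_test_ensemble(c(5, 25, 15))
  core3 <- buildEnsembleCore(e$structures, atomSelection("A", NULL))
  # restrict to a two-member ensemble over the same core
  core2 <- new("EnsembleCore", referenceId = core3@referenceId,
               members = core3@members[1:2],
               coreMaps = core3@coreMaps[1:2],
               selection = core3@selection)
  mat <- alignEnsemble(core2, e$structures[1:2])
  mu <- colMeans(mat)
  d1 <- sqrt(mean((mat[1, ] - mu)^2))
  d2 <- sqrt(mean((mat[2, ] - mu)^2))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("alignment converges quickly on a synthetic ensemble", {
  e <- makeEnsemble(seq(0, 47.5, by = 2.5), 0, noiseSd = 0.1, seed = 1)
  expect_length(e$structures, 20L)
  core <- buildEnsembleCore(e$structures, atomSelection("A", NULL))
  mat <- alignEnsemble(core, e$structures, tol = 1e-4, maxIter = 10L)
  expect_true(attr(mat, "converged"))
  expect_lte(attr(mat, "iterations"), 4L)
})

test_that("degenerate ensembles give zero variance", {
  structs <- lapply(1:4, function(i) toy_chain(1:20, id = paste0("s", i)))
  names(structs) <- paste0("s", 1:4)
  core <- buildEnsembleCore(structs, atomSelection("A", NULL))
  mat <- alignEnsemble(core, structs)
  m <- fitConformationPCA(mat)
  expect_true(all(variances(m) < 1e-12))
})

test_that("a single degree of freedom concentrates on one mode", {
  e <- make_test_ensemble(seq(0, 45, by = 5))
  core <- buildEnsembleCore(e$structures, atomSelection("A", NULL))
  mat <- alignEnsemble(core, e$structures)
  m <- fitConformationPCA(mat)
  v <- variances(m)
  expect_gte(v[1] / sum(v), 0.99)
})

test_that("opening and twist are recovered on separate leading modes", {
  e <- makeRandomEnsemble(n = 30, thetaMean = 20, thetaSd = 15,
                          phiSd = 4, noiseSd = 0.2, seed = 11)
  sels <- twoLobeSelections()
  core <- buildEnsembleCore(e$structures, sels$all)
  mat <- alignEnsemble(core, e$structures)
  open <- vapply(e$structures, function(s) {
    a1 <- selectAtoms(s, sels$small); a2 <- selectAtoms(s, sels$large)
    sqrt(sum((colMeans(a1[, c("x", "y", "z")]) -
              colMeans(a2[, c("x", "y", "z")]))^2))
  }, numeric(1))
  m <- fitConformationPCA(mat, openness = open)
  expect_equal(significantModes(m), 2L)
  sc <- scores(m)
  expect_gte(abs(cor(sc[, 1], e$truth$theta_open)), 0.95)
  expect_gte(abs(cor(sc[, 2], e$truth$phi_twist)), 0.9)
  # sign convention: the most open member projects positively on PC1
  expect_gt(sc[which.max(open), 1], 0)
})

test_that("PCA reconstruction and score invariants hold", {
  e <- make_test_ensemble(seq(0, 40, by = 5), seq(-4, 4, by = 1),
                          noise = 0.1, seed = 9)
  core <- buildEnsembleCore(e$structures, atomSelection("A", NULL))
  mat <- alignEnsemble(core, e$structures)
  m <- fitConformationPCA(mat)
  sc <- scores(m)
  # scores are zero-mean per mode
  expect_lt(max(abs(colMeans(sc))), 1e-8)
  # mean + sum(score * mode) reproduces each aligned conformation
  for (i in c(1, 5, 9)) {
    rec <- reconstructConformation(m, sc[i, ])
    expect_equal(as.numeric(t(rec)), unname(mat[i, ]), tolerance = 1e-6)
  }
})

test_that("projection reproduces training scores and ignores rigid moves", {
  e <- make_test_ensemble(seq(0, 40, by = 10), c(0, 2, -2, 1, -1),
                          noise = 0.15, seed = 13)
  core <- buildEnsembleCore(e$structures, atomSelection("A", NULL))
  mat <- alignEnsemble(core, e$structures)
  m <- fitConformationPCA(mat)
  id3 <- core@members[3]
  p3 <- projectStructure(m, e$structures[[id3]], core@coreMaps[[id3]])
  expect_equal(unname(p3), unname(scores(m)[3, ]), tolerance = 1e-6)
  # arbitrary rigid transform before projection changes nothing
  set.seed(2)
  moved <- transformStructure(e$structures[[id3]], random_rotation(),
                              c(30, -12, 7))
  pM <- projectStructure(m, moved, core@coreMaps[[id3]])
  expect_equal(unname(pM), unname(p3), tolerance = 1e-6)
  # projecting the mean conformation gives all-zero scores
  mean_s <- newStructure(data.frame(
    chain = "A", resno = corePairs(core@coreMaps[[1]])$resnoA,
    resid = "ALA", elety = "CA", elesy = "C",
    x = meanCoords(m)[, 1], y = meanCoords(m)[, 2],
    z = meanCoords(m)[, 3]))
  keys <- corePairs(core@coreMaps[[1]])
  selfMap <- new("CoreMap",
                 pairs = data.frame(chainA = keys$chainA,
                                    resnoA = keys$resnoA,
                                    insertA = keys$insertA,
                                    chainB = keys$chainA,
                                    resnoB = keys$resnoA,
                                    insertB = keys$insertA),
                 atomName = "CA")
  p0 <- projectStructure(m, mean_s, selfMap)
  expect_lt(max(abs(p0)), 1e-8)
  # missing core residues are reported by name
  short <- newStructure(atoms(e$structures[[id3]])[-(1:3), ])
  expect_error(projectStructure(m, short, core@coreMaps[[id3]]),
               "missing")
})

test_that("a held-out opening lands between its neighbours on PC1", {
  e <- make_test_ensemble(seq(0, 40, by = 10))  # 0,10,20,30,40
  core <- buildEnsembleCore(e$structures, atomSelection("A", NULL))
  mat <- alignEnsemble(core, e$structures)
  m <- fitConformationPCA(mat)
  held <- makeTwoLobe(twoLobeParams(thetaOpen = 15), id = "held")
  coreH <- matchCoreByNumber(e$structures[[1]], held$structure,
                             atomSelection("A", NULL))
  pH <- projectStructure(m, held$structure, coreH)
  sc1 <- scores(m)[, 1]
  lo <- sc1[e$truth$theta_open == 10]
  hi <- sc1[e$truth$theta_open == 20]
  expect_true((pH[1] > min(lo, hi)) && (pH[1] < max(lo, hi)))
})
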
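# Medoid central structure, PCA with shared basis, free-energy surfaces and
# basin assignment.

# ensemble of near-rigid structures displaced along internal modes that are
# orthogonal to the 6 rigid-body degrees of freedom of the reference
internalModeEnsemble <- function(nAtoms = 8, nFrames = 300, sds = c(3, 1),
                                 amplitude = 1e-3, seed = 5) {
  set.seed(seed)
  X0 <- matrix(rnorm(nAtoms * 3), nAtoms, 3)
  X0 <- sweep(X0, 2, colMeans(X0))
  # rigid modes: 3 translations + 3 infinitesimal rotations
  rigid <- matrix(0, 3 * nAtoms, 6)
  for (k in 1:3) rigid[(k - 1) * nAtoms + seq_len(nAtoms), k] <- 1
  gen <- list(cbind(0, -X0[, 3], X0[, 2]),
              cbind(X0[, 3], 0, -X0[, 1]),
              cbind(-X0[, 2], X0[, 1], 0))
  for (k in 1:3) rigid[, 3 + k] <- as.vector(gen[[k]])
  Qr <- qr.Q(qr(rigid))
  ortho <- function(v) {
    v <- v - Qr %*% crossprod(Qr, v)
    v / sqrt(sum(v^2))
  }
  v1 <- ortho(rnorm(3 * nAtoms))
  v2 <- ortho(rnorm(3 * nAtoms))
  v2 <- v2 - v1 * sum(v1 * v2)
  v2 <- v2 / sqrt(sum(v2^2))
  a <- rnorm(nFrames); a <- (a - mean(a)) / sd(a) * sds[1]
  b <- rnorm(nFrames); b <- b - mean(b)
  b <- b - a * sum(a * b) / sum(a * a)   # exactly uncorrelated scores
  b <- b / sd(b) * sds[2]
  X <- array(NA_real_, c(nFrames, nAtoms, 3))
  for (f in seq_len(nFrames)) {
    d <- amplitude * (a[f] * v1 + b[f] * v2)
    X[f, , ] <- X0 + matrix(d, nAtoms, 3)
  }
  list(ens = Ensemble(X, beadTopology(nAtoms)), v1 = v1, v2 = v2,
       scores = cbind(a, b) * amplitude)
}

test_that("Kabsch superposition recovers a known rigid rotation", {
  set.seed(19)
  P <- matrix(rnorm(24), 8, 3)
  P <- sweep(P, 2, colMeans(P))
  th <- 0.7
  Rtrue <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- P %*% Rtrue
  R <- idpens:::kabschRotation(P, Q)
  expect_equal(R, Rtrue, tolerance = 1e-10)
  expect_equal(det(R), 1, tolerance = 1e-10)
  expect_lt(max(abs(P %*% R - Q)), 1e-10)
})

test_that("the medoid central structure behaves as a medoid", {
  # identical frames: first index wins the tie
  topo <- beadTopology(5)
  P <- matrix(rnorm(15), 5, 3)
  same <- ensembleFromFrames(replicate(6, P, simplify = FALSE), topo)
  expect_equal(centralStructure(same, selection = 1:5), 1)

  # 80/20 clusters: the medoid lies in the dominant cluster
  set.seed(23)
  A <- matrix(rnorm(15), 5, 3)
  B <- A + 5
  frames <- c(lapply(1:16, function(i) A + 0.01 * matrix(rnorm(15), 5, 3)),
              lapply(1:4, function(i) B + 0.01 * matrix(rnorm(15), 5, 3)))
  e <- ensembleFromFrames(frames, topo)
  med <- centralStructure(e, selection = 1:5)
  expect_lte(med, 16)

  # medoid mean RMSD <= overall mean pairwise RMSD
  X <- coords(e)
  R <- idpens:::cpp_pairwise_rmsd(X)
  expect_lte(mean(R[med, -med]), mean(R[upper.tri(R)]))
})

test_that("PCA recovers planted directions and exact variance fractions", {
  im <- internalModeEnsemble()
  # without superposition the decomposition is exact
  b0 <- fitPCA(im$ens, selection = 1:8, superpose = FALSE)
  ang <- function(u, v)
    acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
  expect_lt(ang(b0@rotation[, 1], im$v1), 2)
  expect_lt(ang(b0@rotation[, 2], im$v2), 2)
  expect_equal(varianceFractions(b0)[1], 0.9, tolerance = 1e-6)
  expect_equal(varianceFractions(b0)[2], 0.1, tolerance = 1e-6)
  expect_equal(varianceReport(b0), 1.0, tolerance = 1e-9)

  # with superposition onto the medoid, directions still recovered closely
  b1 <- fitPCA(im$ens, selection = 1:8)
  expect_lt(ang(b1@rotation[, 1], im$v1), 2)
  expect_lt(ang(b1@rotation[, 2], im$v2), 2)
})

test_that("the PCA basis is complete and orthonormal", {
  e <- generateIdealChain(10, 0.38, 120, seed = 25)
  b <- fitPCA(e, selection = 1:10)
  # projecting onto all components and reconstructing returns the centred
  # aligned coordinates
  allPC <- projectOntoBasis(b, e, nComponents = ncol(b@rotation))
  flat <- idpens:::alignFlatten(coords(e), 1:10, b@refCoords, TRUE)
  rec <- sweep(allPC %*% t(b@rotation), 2, -b@center)
  expect_lt(max(abs(rec - flat)), 1e-8)
  # fractions descending in [0, 1]
  vf <- varianceFractions(b)
  expect_true(all(vf >= 0 & vf <= 1))
  expect_true(all(diff(vf) <= 1e-12))
})

test_that("shared-basis projections live in one coordinate frame", {
  e1 <- generateIdealChain(8, 0.38, 60, seed = 26)
  e2 <- generateIdealChain(8, 0.38, 60, seed = 27)
  b <- fitPCA(list(e1, e2), selection = 1:8)
  p1 <- projectOntoBasis(b, e1)
  p2 <- projectOntoBasis(b, e2)
  pc <- projectOntoBasis(b, idpens:::concatEnsembles(list(e1, e2)))
  expect_equal(rbind(p1, p2), pc, tolerance = 1e-12)

  # duplicated ensemble: identical projections for both copies
  bd <- fitPCA(list(e1, e1), selection = 1:8)
  expect_equal(projectOntoBasis(bd, e1), projectOntoBasis(bd, e1))
})

test_that("superposition removes six rigid degrees of freedom", {
  # isotropic displacements around a structure: top-2 fraction ~ 2/(3N-6)
  set.seed(29)
  nAtoms <- 10; nFrames <- 2000
  X0 <- matrix(rnorm(nAtoms * 3), nAtoms, 3)
  X <- array(NA_real_, c(nFrames, nAtoms, 3))
  for (f in seq_len(nFrames))
    X[f, , ] <- X0 + 0.05 * matrix(rnorm(nAtoms * 3), nAtoms, 3)
  e <- Ensemble(X, beadTopology(nAtoms))
  b <- fitPCA(e, selection = seq_len(nAtoms))
  expect_lt(abs(varianceReport(b) - 2 / (3 * nAtoms - 6)) /
              (2 / (3 * nAtoms - 6)), 0.25)
})

test_that("a single Gaussian cloud yields one basin with zero minimum", {
  set.seed(71)
  proj <- cbind(rnorm(5000, 0, 0.6), rnorm(5000, 0, 0.4))
  fes <- freeEnergySurface(proj, bandwidth = c(0.2, 0.2), capRT = 6)
  E <- energyGrid(fes)
  expect_equal(min(E, na.rm = TRUE), 0)
  fes <- assignBasins(fes)
  expect_equal(nrow(basinMinima(fes)), 1)
  # free energy grows monotonically outward from the minimum along the axes
  ij <- which(E == 0, arr.ind = TRUE)[1, ]
  row <- E[ij[1], ]
  right <- row[ij[2]:length(row)]
  right <- right[!is.na(right)]
  expect_true(all(diff(right) > -1e-9))
  left <- rev(row[1:ij[2]])
  left <- left[!is.na(left)]
  expect_true(all(diff(left) > -1e-9))
})

test_that("two separated clouds give two basins with the analytic depth gap", {
  set.seed(72)
  n <- 5000
  z <- rbinom(n, 1, 0.3)
  proj <- cbind(rnorm(n, ifelse(z == 1, 3, 0), 0.5), rnorm(n, 0, 0.5))
  fes <- assignBasins(freeEnergySurface(proj, bandwidth = c(0.25, 0.25),
                                        capRT = 6))
  m <- basinMinima(fes)
  expect_equal(nrow(m), 2)
  expect_lt(abs(abs(diff(m$energy)) - log(7 / 3)), 0.15)
  # basin labels partition the unmasked grid
  expect_true(all(!is.na(basinLabels(fes)[!is.na(energyGrid(fes))])))
  expect_true(all(is.na(basinLabels(fes)[is.na(energyGrid(fes))])))

  # equal-weight clouds: the basin boundary sits near the density saddle,
  # which for symmetric clouds is the midpoint
  z2 <- rbinom(n, 1, 0.5)
  proj2 <- cbind(rnorm(n, ifelse(z2 == 1, 3, 0), 0.5), rnorm(n, 0, 0.5))
  fes2 <- assignBasins(freeEnergySurface(proj2, bandwidth = c(0.25, 0.25),
                                         capRT = 6))
  lab <- basinLabels(fes2)
  jmid <- which.min(abs(fes2@pc2))
  colLab <- lab[, jmid]
  change <- which(diff(colLab[!is.na(colLab)]) != 0)
  xs <- fes2@pc1[!is.na(colLab)]
  expect_lt(abs(xs[change[1]] - 1.5), 0.3)
})

test_that("landscape convergence toward the analytic depth gap", {
  set.seed(73)
  gapErr <- vapply(c(1e3, 1e5), function(n) {
    z <- rbinom(n, 1, 0.3)
    proj <- cbind(rnorm(n, ifelse(z == 1, 3, 0), 0.5), rnorm(n, 0, 0.5))
    fes <- assignBasins(freeEnergySurface(proj, bandwidth = c(0.25, 0.25),
                                          capRT = 6))
    m <- basinMinima(fes)
    abs(abs(diff(sort(m$energy)[1:2])) - log(7 / 3))
  }, numeric(1))
  expect_lt(gapErr[2], 0.05)
  expect_lt(gapErr[2], gapErr[1] + 0.03)
})

test_that("landscapes are deterministic given fixed projections", {
  set.seed(74)
  proj <- cbind(rnorm(500), rnorm(500))
  f1 <- assignBasins(freeEnergySurface(proj))
  f2 <- assignBasins(freeEnergySurface(proj))
  expect_identical(energyGrid(f1), energyGrid(f2))
  expect_identical(basinLabels(f1), basinLabels(f2))
})
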
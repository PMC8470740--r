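# Synthetic-ensemble generators: ideal-chain statistics, backbone geometry
# round trips, planted contacts, reference-curve synthesis.

test_that("ideal chain reproduces closed-form size statistics", {
  # single bond: Ree fixed exactly
  e2 <- generateIdealChain(2, 0.38, 50, seed = 1)
  expect_equal(endToEnd(e2, "caca"), rep(0.38, 50), tolerance = 1e-12,
               ignore_attr = TRUE)

  b <- 0.38
  e <- generateIdealChain(50, b, 20000, seed = 1)
  ree2 <- endToEnd(e, "caca")^2
  se <- sd(ree2) / sqrt(length(ree2))
  expect_lt(abs(mean(ree2) - 49 * b^2), 3 * se)

  rg2 <- radiusOfGyration(e)^2
  theory <- b^2 * (50^2 - 1) / (6 * 50)
  seRg <- sd(rg2) / sqrt(length(rg2))
  expect_lt(abs(mean(rg2) - theory), 3 * seRg)
})

test_that("ideal chain generation is bit-reproducible and validates input", {
  a <- generateIdealChain(50, 0.38, 100, seed = 7)
  b <- generateIdealChain(50, 0.38, 100, seed = 7)
  expect_identical(coords(a), coords(b))
  expect_error(generateIdealChain(1, 0.38, 10), "nBeads")
  expect_error(generateIdealChain(5, -1, 10), "bondLength")
  expect_error(generateIdealChain(5, 0.38, 0), "nFrames")
})

test_that("Ree^2/Rg^2 ratio approaches 6 for long ideal chains", {
  e <- generateIdealChain(200, 0.38, 50000, seed = 11)
  ratio <- mean(endToEnd(e, "caca")^2) / mean(radiusOfGyration(e)^2)
  expect_lt(abs(ratio - 6) / 6, 0.05)
})

test_that("backbone builder round-trips dihedrals within 0.5 degrees", {
  bb <- buildBackbone(strrep("A", 10), -57, -47)
  dh <- computeDihedrals(bb)
  expect_equal(dh$phi[1, 2:10], rep(-57, 9), tolerance = 0.5 / 57)
  expect_equal(dh$psi[1, 1:9], rep(-47, 9), tolerance = 0.5 / 47)

  # a mixed set of dihedrals round-trips too
  phis <- c(NA, -70, -120, -60, 50)
  psis <- c(140, 130, -40, 45, NA)
  bb2 <- buildBackbone("GGGGG", c(-57, phis[-1]), c(psis[-5], 180))
  dh2 <- computeDihedrals(bb2)
  expect_equal(dh2$phi[1, 2:5], phis[-1], tolerance = 1e-6)
  expect_equal(dh2$psi[1, 1:4], psis[-5], tolerance = 1e-6)
})

test_that("backbone builder honours chain-end conventions and geometry", {
  # 2 residues: trailing psi ignored, build succeeds
  bb <- buildBackbone("AA", -57, -47)
  expect_s4_class(bb, "Ensemble")
  expect_equal(nResidues(bb), 2)

  # PPII-like dihedrals give trans-peptide CA-CA spacing ~0.38 nm
  bb6 <- buildBackbone(strrep("A", 6), -75, 145)
  topo <- topology(bb6)
  ica <- which(topo$name == "CA")
  P <- coords(bb6)[1, ica, ]
  d <- sqrt(rowSums((P[-1, ] - P[-6, ])^2))
  expect_true(all(abs(d - 0.38) < 0.02))

  # proline gets no amide hydrogen
  bbp <- buildBackbone("APA", -75, 145)
  tp <- topology(bbp)
  expect_false(any(tp$name == "H" & tp$resid == 2))
  expect_error(buildBackbone("AAAA", c(-57, -57), c(-47, -47)), "pair")
})

test_that("planted contacts hit their target fractions", {
  base <- generateIdealChain(16, 0.38, 3000, seed = 3)
  specs <- list(list(i = 2, j = 9, fraction = 0.6, cutoff = 0.5),
                list(i = 5, j = 14, fraction = 0.25, cutoff = 0.5))
  out <- plantContacts(base, specs, seed = 4)
  expect_equal(nFrames(out), 3000)

  # brute-force recount on the output
  X <- coords(out)
  frac <- c(0, 0)
  for (f in seq_len(dim(X)[1])) {
    P <- X[f, , , drop = TRUE]
    D <- as.matrix(dist(P))
    frac <- frac + c(D[2, 9] < 0.5, D[5, 14] < 0.5)
  }
  frac <- frac / dim(X)[1]
  expect_lt(abs(frac[1] - 0.6), 0.02)
  expect_lt(abs(frac[2] - 0.25), 0.02)

  # zero target: no contact frame remains
  out0 <- plantContacts(base, list(list(i = 2, j = 9, fraction = 0,
                                        cutoff = 0.5)), seed = 5)
  X0 <- coords(out0)
  any_contact <- FALSE
  for (f in seq_len(dim(X0)[1])) {
    D <- as.matrix(dist(X0[f, , , drop = TRUE]))
    if (D[2, 9] < 0.5) any_contact <- TRUE
  }
  expect_false(any_contact)
})

test_that("planted contacts preserve frame coordinates exactly", {
  base <- generateIdealChain(8, 0.38, 200, seed = 9)
  out <- plantContacts(base, list(list(i = 2, j = 7, fraction = 0.5,
                                       cutoff = 0.6)), seed = 10)
  # each output frame must be bit-identical to some base frame
  Xb <- coords(base); Xo <- coords(out)
  keyB <- apply(Xb, 1, function(m) paste(m, collapse = ","))
  keyO <- apply(Xo, 1, function(m) paste(m, collapse = ","))
  expect_true(all(keyO %in% keyB))
})

test_that("planted contacts detect infeasible targets", {
  base <- generateIdealChain(16, 0.38, 200, seed = 6)
  expect_error(
    plantContacts(base, list(list(i = 1, j = 16, fraction = 0.5,
                                  cutoff = 0.01)), seed = 1),
    "infeasible")
})

test_that("reference-curve synthesis applies the affine map and noise", {
  q <- seq(0.1, 3, length.out = 40)
  cv <- gaussianChainIntensity(q, Rg = 1.5)
  idc <- synthesizeReferenceCurve(cv, f = 1, c = 0, sigma = 0)
  expect_equal(intensities(idc), intensities(cv), tolerance = 1e-15)

  aff <- synthesizeReferenceCurve(cv, f = 2, c = 1, sigma = 0)
  expect_equal(intensities(aff), 2 * intensities(cv) + 1, tolerance = 1e-15)

  n1 <- synthesizeReferenceCurve(cv, sigma = 0.01, seed = 42)
  n2 <- synthesizeReferenceCurve(cv, sigma = 0.01, seed = 42)
  expect_identical(intensities(n1), intensities(n2))
  expect_equal(intensityErrors(n1), rep(0.01, length(q)))
  expect_error(synthesizeReferenceCurve(cv, sigma = -1), "sigma")
})
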
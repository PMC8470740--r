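# Shared builders for synthetic test fixtures. Everything is generated in
# code; no data files are read except the bundled extdata fixtures.

# minimal bead topology
beadTopology <- function(n, mass = 110, name = "CA", resname = "BEA") {
  data.frame(name = name, element = "C", mass = mass, resid = seq_len(n),
             resname = resname, stringsAsFactors = FALSE)
}

# ensemble from an explicit list of atoms x 3 frame matrices
ensembleFromFrames <- function(frames, topo) {
  X <- array(NA_real_, c(length(frames), nrow(topo), 3))
  for (f in seq_along(frames)) X[f, , ] <- frames[[f]]
  Ensemble(X, topo)
}

# random rigid motion (proper rotation + translation) applied to every frame
randomRigidMotion <- function(ens) {
  M <- matrix(rnorm(9), 3, 3)
  qr <- qr(M)
  R <- qr.Q(qr)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t <- rnorm(3, sd = 2)
  X <- coords(ens)
  for (f in seq_len(dim(X)[1]))
    X[f, , ] <- sweep(X[f, , , drop = TRUE] %*% R, 2, -t)
  Ensemble(X, topology(ens), frameTimes(ens))
}

# Two-residue donor/acceptor system for salt-bridge tests:
# residue 1 = LYS side-chain donor (NZ + one H), residue 2 = GLU carboxylate
# acceptor (OE1). The acceptor is placed at distance rDA from NZ, at angle
# theta (degrees) from the N-H direction, per frame.
saltBridgeFrame <- function(rDA, thetaDeg) {
  th <- thetaDeg * pi / 180
  rbind(
    c(0, 0, 0),                                   # NZ
    c(0.10, 0, 0),                                # HZ1 (0.10 nm from NZ)
    c(rDA * cos(th), rDA * sin(th), 0),           # OE1
    c(rDA * cos(th) + 0.1, rDA * sin(th), 0))     # CD (carboxylate C, inert)
}

saltBridgeTopology <- function() {
  data.frame(
    name = c("NZ", "HZ1", "OE1", "CD"),
    element = c("N", "H", "O", "C"),
    mass = c(14.007, 1.008, 15.999, 12.011),
    resid = c(1L, 1L, 2L, 2L),
    resname = c("LYS", "LYS", "GLU", "GLU"),
    stringsAsFactors = FALSE)
}

# ensemble with the H-bond geometry satisfied in exactly `fracOn` of frames
saltBridgeEnsemble <- function(nFrames, fracOn, rOn = 0.28, rOff = 0.8) {
  on <- round(nFrames * fracOn)
  frames <- c(
    replicate(on, saltBridgeFrame(rOn, 0), simplify = FALSE),
    replicate(nFrames - on, saltBridgeFrame(rOff, 0), simplify = FALSE))
  # deterministic interleave so the indicator series is not one long block
  ord <- order((seq_len(nFrames) * 0.61803) %% 1)
  ensembleFromFrames(frames[ord], saltBridgeTopology())
}

# brute-force recount of qualifying H-bond frames (independent of the
# implementation's atom-set machinery)
bruteForceBridgeCount <- function(ens, dist0 = 0.33, k = 0.000044) {
  X <- coords(ens)
  hits <- 0
  for (f in seq_len(dim(X)[1])) {
    P <- X[f, , , drop = TRUE]
    rDA <- sqrt(sum((P[3, ] - P[1, ])^2))
    v1 <- P[2, ] - P[1, ]; v2 <- P[3, ] - P[1, ]
    th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (rDA < dist0 - k * th^2) hits <- hits + 1
  }
  hits / dim(X)[1]
}

# exhaustive-permutation delta_max oracle for compositions up to ~length 12:
# enumerates all sign sequences with the given composition on a base-3 grid
permutationDeltaMax <- function(nPlus, nMinus, nZero) {
  n <- nPlus + nMinus + nZero
  grid <- as.matrix(expand.grid(rep(list(c(1, -1, 0)), n)))
  keep <- rowSums(grid == 1) == nPlus & rowSums(grid == -1) == nMinus
  grid <- grid[keep, , drop = FALSE]
  max(apply(grid, 1, idpens:::chargeDelta))
}

# sequence string for a sign vector (E/K/G alphabet)
signsToSequence <- function(s) {
  paste(c("G", "K", "E")[match(s, c(0, 1, -1))], collapse = "")
}
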
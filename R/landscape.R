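# Free-energy landscapes over the first two principal components of
# superposed backbone coordinates: medoid reference structure, PCA with a
# shared basis across ensembles, Gaussian-KDE density, conditional free
# energy in RT units, and steepest-ascent basin assignment.

# default PCA selection: backbone N, CA, C, O atoms
backboneSelection <- function(ens) {
  topo <- topology(ens)
  which(topo$name %in% c("N", "CA", "C", "O"))
}

#' Central (medoid) structure of an ensemble
#'
#' The frame minimising the mean backbone RMSD (after optimal Kabsch
#' superposition) to all other frames. For ensembles larger than `maxFrames`
#' the medoid is found on a deterministic evenly spaced subsample. Ties break
#' to the earliest frame.
#'
#' @param ens an [Ensemble-class] with >= 2 frames.
#' @param selection atom indices used for the RMSD (default backbone
#'   N, CA, C, O; all atoms if none match).
#' @param maxFrames subsample cap, default 2000.
#' @return Frame index (into the full ensemble).
#' @export
centralStructure <- function(ens, selection = NULL, maxFrames = 2000) {
  nf <- nFrames(ens)
  if (nf < 2) stop("need >= 2 frames")
  if (is.null(selection)) {
    selection <- backboneSelection(ens)
    if (!length(selection)) selection <- seq_len(nAtoms(ens))
  }
  idx <- if (nf > maxFrames)
    unique(round(seq(1, nf, length.out = maxFrames))) else seq_len(nf)
  X <- coords(ens)[idx, selection, , drop = FALSE]
  R <- cpp_pairwise_rmsd(X)
  idx[which.min(rowMeans(R))]
}

#' Principal-component basis of superposed backbone coordinates
#'
#' All frames are superposed (translational + rotational least squares,
#' Kabsch) onto the central structure; the covariance of the selected
#' Cartesian coordinates is then eigendecomposed. Passing a list of
#' ensembles concatenates their frames and computes one shared basis, so the
#' per-ensemble projections are directly comparable.
#'
#' @param ens an [Ensemble-class] or a list of ensembles sharing a topology.
#' @param selection atom indices (default backbone N, CA, C, O).
#' @param superpose superpose frames onto the central structure first
#'   (default). Disable only for coordinates that are already aligned.
#' @return A [PCABasis-class].
#' @export
fitPCA <- function(ens, selection = NULL, superpose = TRUE) {
  if (is.list(ens)) ens <- concatEnsembles(ens)
  if (is.null(selection)) {
    selection <- backboneSelection(ens)
    if (!length(selection)) selection <- seq_len(nAtoms(ens))
  }
  ref <- if (superpose) centralStructure(ens, selection) else 1L
  refSel <- coords(ens)[ref, selection, , drop = TRUE]
  refSel <- sweep(refSel, 2, colMeans(refSel))
  X <- alignFlatten(coords(ens), selection, refSel, superpose)
  if (all(apply(X, 2, var) < 1e-20))
    stop("decomposition error: zero-variance coordinates")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  new("PCABasis", center = pc$center, rotation = pc$rotation,
      varFractions = vf, refCoords = refSel,
      atomIndices = as.integer(selection), superpose = superpose)
}

concatEnsembles <- function(lst) {
  stopifnot(length(lst) >= 1)
  topo <- topology(lst[[1]])
  for (e in lst[-1])
    if (!identical(topology(e)$name, topo$name) ||
        !identical(topology(e)$resid, topo$resid))
      stop("shared-basis mode requires a common topology")
  X <- do.call(abindFrames, lapply(lst, coords))
  Ensemble(X, topo)
}

abindFrames <- function(...) {
  arrs <- list(...)
  nf <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  na <- dim(arrs[[1]])[2]
  out <- array(NA_real_, c(nf, na, 3))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# Flatten selected-atom coordinates to frames x 3m, optionally Kabsch-aligned
# onto the centred reference Q0 (column-major atom-then-axis layout).
alignFlatten <- function(X, selection, Q0, superpose = TRUE) {
  nf <- dim(X)[1]
  m <- length(selection)
  out <- matrix(NA_real_, nf, 3 * m)
  for (f in seq_len(nf)) {
    Psel <- X[f, selection, , drop = TRUE]
    if (superpose) {
      Pc <- colMeans(Psel)
      R <- kabschRotation(sweep(Psel, 2, Pc), Q0)
      Psel <- sweep(Psel, 2, Pc) %*% R
    }
    out[f, ] <- as.vector(Psel)
  }
  out
}

#' Project an ensemble onto a PCA basis
#'
#' Frames are superposed onto the basis's reference structure before
#' projection, so projections from different ensembles share the coordinate
#' frame.
#'
#' @param basis a [PCABasis-class].
#' @param ens an [Ensemble-class].
#' @param nComponents number of components to keep, default 2.
#' @return `frames x nComponents` matrix of projections.
#' @export
projectOntoBasis <- function(basis, ens, nComponents = 2) {
  sel <- basis@atomIndices
  flat <- alignFlatten(coords(ens), sel, basis@refCoords, basis@superpose)
  sweep(flat, 2, basis@center) %*%
    basis@rotation[, seq_len(nComponents), drop = FALSE]
}

#' Fraction of variance in the first two components
#'
#' @param basis a [PCABasis-class].
#' @return Numeric fraction in `[0, 1]`.
#' @export
varianceReport <- function(basis) {
  sum(head(basis@varFractions, 2))
}

# Scott's rule bandwidth per dimension for a 2D KDE
scottBandwidth <- function(proj) {
  n <- nrow(proj)
  apply(proj, 2, sd) * n^(-1 / 6)
}

#' Conditional free-energy surface over two principal components
#'
#' Gaussian kernel density estimation (product kernel, Scott's rule per
#' dimension by default) on a regular grid padded 10% per axis, converted to
#' conditional free energy `F = -ln(rho / rho_max)` in RT units. Cells above
#' the cap are masked (`NA`); the minimum over the grid is exactly 0.
#'
#' @param proj `n x 2` projection matrix (n >= 100).
#' @param grid grid points per axis, default 150.
#' @param bandwidth length-2 bandwidth override (same units as `proj`).
#' @param padding fractional range padding per axis, default 0.1.
#' @param capRT free-energy cap (RT), default 10.
#' @return A [FreeEnergyLandscape-class] (basins unassigned; see
#'   [assignBasins()]).
#' @export
freeEnergySurface <- function(proj, grid = 150, bandwidth = NULL,
                              padding = 0.1, capRT = 10) {
  proj <- as.matrix(proj)
  if (ncol(proj) < 2) stop("need two projection columns")
  proj <- proj[, 1:2, drop = FALSE]
  if (nrow(proj) < 100) stop("need >= 100 projected points")
  if (is.null(bandwidth)) bandwidth <- scottBandwidth(proj)
  if (any(bandwidth <= 0))
    stop("degenerate-density error: zero-variance projections")
  ax <- lapply(1:2, function(k) {
    r <- range(proj[, k])
    pad <- padding * diff(r)
    seq(r[1] - pad, r[2] + pad, length.out = grid)
  })
  # separable Gaussian product kernel: density = t(Gx) %*% Gy / (n hx hy)
  Gx <- outer(proj[, 1], ax[[1]], function(p, g)
    stats::dnorm((g - p) / bandwidth[1]))
  Gy <- outer(proj[, 2], ax[[2]], function(p, g)
    stats::dnorm((g - p) / bandwidth[2]))
  dens <- crossprod(Gx, Gy) / (nrow(proj) * bandwidth[1] * bandwidth[2])
  FE <- -log(dens / max(dens))
  FE[FE > capRT] <- NA_real_
  basins <- matrix(0L, grid, grid)
  basins[is.na(FE)] <- NA_integer_
  new("FreeEnergyLandscape", pc1 = ax[[1]], pc2 = ax[[2]], energy = FE,
      density = dens, basins = basins,
      minima = data.frame(), capRT = capRT)
}

#' Assign basins by steepest ascent on the density
#'
#' Every unmasked cell follows the steepest density ascent over its
#' 8-neighbourhood until it reaches a local density maximum; cells reaching
#' the same maximum form one basin. Ties break toward the lower linear cell
#' index, making the assignment deterministic. Each basin's minimum-energy
#' cell is reported with its depth band (<= 1, <= 2, <= 3 RT, or deeper).
#'
#' @param surface a [FreeEnergyLandscape-class].
#' @return The surface with basin labels and the minima table filled in.
#' @export
assignBasins <- function(surface) {
  dens <- surface@density
  FE <- surface@energy
  ng1 <- nrow(dens); ng2 <- ncol(dens)
  unmasked <- which(!is.na(FE))
  # steepest-ascent pointer for every unmasked cell (linear indices)
  ptr <- integer(length(FE))
  for (cell in unmasked) {
    i <- (cell - 1) %% ng1 + 1
    j <- (cell - 1) %/% ng1 + 1
    best <- cell
    bestDens <- dens[cell]
    for (dj in -1:1) for (di in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > ng1 || jj < 1 || jj > ng2) next
      lin <- ii + (jj - 1) * ng1
      if (is.na(FE[lin])) next
      if (dens[lin] > bestDens ||
          (dens[lin] == bestDens && lin < best)) {
        best <- lin
        bestDens <- dens[lin]
      }
    }
    ptr[cell] <- best
  }
  # pointer jumping to the attracting maximum (over unmasked cells only)
  reach <- ptr[unmasked]
  repeat {
    nxt <- ptr[reach]
    if (all(nxt == reach)) break
    reach <- nxt
  }
  maxima <- sort(unique(reach))
  basins <- matrix(NA_integer_, ng1, ng2)
  basins[unmasked] <- match(reach, maxima)
  minima <- data.frame(
    basin = seq_along(maxima),
    pc1 = surface@pc1[(maxima - 1) %% ng1 + 1],
    pc2 = surface@pc2[(maxima - 1) %/% ng1 + 1],
    energy = FE[maxima])
  minima$depthBand <- cut(minima$energy, c(-Inf, 1, 2, 3, Inf),
                          labels = c("<=1RT", "<=2RT", "<=3RT", ">3RT"))
  out <- surface
  out@basins <- basins
  out@minima <- minima
  out
}
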
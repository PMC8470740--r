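AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Ensemble of conformations
#'
#' Holds a molecular trajectory as a `frames x atoms x 3` coordinate array in
#' nanometres together with a per-atom topology (atom name, element, mass in
#' amu, 1-based residue index and residue name) and optional frame times in
#' picoseconds.
#'
#' @slot coords numeric array, `frames x atoms x 3`, nm.
#' @slot topology data.frame with columns `name`, `element`, `mass`, `resid`,
#'   `resname`; one row per atom.
#' @slot times numeric vector of frame times (ps), or `numeric(0)`.
#' @export
setClass("Ensemble",
  representation(coords = "array", topology = "data.frame", times = "numeric"))

setValidity("Ensemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (!all(is.finite(object@coords)))
    return("coords must be finite")
  req <- c("name", "element", "mass", "resid", "resname")
  if (!all(req %in% names(object@topology)))
    return(paste("topology must have columns:", paste(req, collapse = ", ")))
  if (nrow(object@topology) != d[2])
    return("topology rows must equal atom count")
  if (is.unsorted(object@topology$resid))
    return("residue indices must be non-decreasing")
  if (length(object@times) && length(object@times) != d[1])
    return("times length must equal frame count")
  TRUE
})

#' Construct an Ensemble
#'
#' @param coords `frames x atoms x 3` array (nm). A single `atoms x 3` matrix
#'   is promoted to a one-frame ensemble.
#' @param topology per-atom data.frame (`name`, `element`, `mass`, `resid`,
#'   `resname`).
#' @param times optional frame times (ps).
#' @return An [Ensemble-class] object.
#' @export
Ensemble <- function(coords, topology, times = numeric(0)) {
  if (is.matrix(coords))
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  topology$resid <- as.integer(topology$resid)
  new("Ensemble", coords = coords,
      topology = as.data.frame(topology, stringsAsFactors = FALSE),
      times = as.numeric(times))
}

#' Annotated peptide sequence
#'
#' One-letter residue codes plus the set of phosphorylated positions and the
#' fixed-charge assignment at physiological pH: Asp/Glu -1, Lys/Arg +1, His 0,
#' phosphorylated Ser/Thr -2. Terminal charges (+1 N-terminus, -1 C-terminus)
#' are recorded separately and can be toggled.
#'
#' @slot residues character vector of one-letter codes.
#' @slot phosphosites integer vector of 1-based phosphorylated positions
#'   (subset of Ser/Thr positions).
#' @slot charges numeric per-residue charge (e) at the stated pH.
#' @slot includeTermini logical; whether terminal charges are counted by
#'   consumers that use net charge.
#' @export
setClass("AnnotatedSequence",
  representation(residues = "character", phosphosites = "integer",
                 charges = "numeric", includeTermini = "logical"))

setValidity("AnnotatedSequence", function(object) {
  if (length(object@residues) < 1L) return("sequence must have length >= 1")
  if (!all(object@residues %in% AA_CODES))
    return("residues must be standard one-letter amino-acid codes")
  if (length(object@charges) != length(object@residues))
    return("charges must match sequence length")
  ps <- object@phosphosites
  if (length(ps)) {
    if (any(ps < 1L | ps > length(object@residues)))
      return("phosphosites out of range")
    if (!all(object@residues[ps] %in% c("S", "T")))
      return("phosphosites must be Ser or Thr positions")
  }
  TRUE
})

#' Scattering curve
#'
#' A small-angle scattering intensity profile: ascending momentum-transfer
#' grid `q` (nm^-1), intensities `I` (arbitrary units), and optional per-point
#' errors `sigma`.
#'
#' @slot q numeric, strictly increasing, nm^-1.
#' @slot I numeric intensities.
#' @slot sigma numeric per-point errors (possibly `numeric(0)`).
#' @export
setClass("ScatteringCurve",
  representation(q = "numeric", I = "numeric", sigma = "numeric"))

setValidity("ScatteringCurve", function(object) {
  if (length(object@q) != length(object@I))
    return("q and I must have equal length")
  if (length(object@q) > 1 && any(diff(object@q) <= 0))
    return("q must be strictly increasing")
  if (!all(is.finite(object@I))) return("I must be finite")
  if (length(object@sigma)) {
    if (length(object@sigma) != length(object@q))
      return("sigma must match q length")
    if (any(object@sigma <= 0)) return("sigma must be positive where present")
  }
  TRUE
})

#' Construct a ScatteringCurve
#'
#' @param q momentum transfer grid (nm^-1), strictly increasing.
#' @param I intensities.
#' @param sigma optional per-point errors.
#' @return A [ScatteringCurve-class] object.
#' @export
ScatteringCurve <- function(q, I, sigma = numeric(0)) {
  new("ScatteringCurve", q = as.numeric(q), I = as.numeric(I),
      sigma = as.numeric(sigma))
}

#' Secondary-structure matrix
#'
#' Per-frame, per-residue secondary-structure codes:
#' H (alpha helix), G (3-10 helix), I (pi helix), E (strand), B (bridge),
#' T (turn), S (bend), P (polyproline II), C (irregular).
#'
#' @slot codes character matrix, frames in rows, residues in columns.
#' @export
setClass("SSMatrix", representation(codes = "matrix"))

SS_CODES <- c("H", "G", "I", "E", "B", "T", "S", "P", "C")

setValidity("SSMatrix", function(object) {
  if (!is.character(object@codes)) return("codes must be a character matrix")
  if (!all(object@codes %in% SS_CODES))
    return(paste("codes must be in:", paste(SS_CODES, collapse = "")))
  TRUE
})

#' Construct an SSMatrix
#' @param codes character matrix of per-frame (rows), per-residue (columns)
#'   codes from `H G I E B T S P C`.
#' @return An [SSMatrix-class] object.
#' @export
SSMatrix <- function(codes) new("SSMatrix", codes = codes)

#' PCA basis for backbone coordinates
#'
#' Principal-component basis of superposed Cartesian backbone coordinates:
#' the mean coordinate vector, orthonormal component vectors (columns), the
#' per-component variance fractions, and the reference (central) structure
#' used for superposition.
#'
#' @slot center numeric mean coordinate vector (length 3m).
#' @slot rotation matrix of component vectors in columns.
#' @slot varFractions numeric variance fraction per component, descending.
#' @slot refCoords matrix `m x 3`; selected-atom coordinates of the
#'   superposition reference, centred at the origin.
#' @slot atomIndices integer indices of the atoms used.
#' @slot superpose logical; whether frames are superposed onto the reference
#'   before decomposition/projection.
#' @export
setClass("PCABasis",
  representation(center = "numeric", rotation = "matrix",
                 varFractions = "numeric", refCoords = "matrix",
                 atomIndices = "integer", superpose = "logical"))

setValidity("PCABasis", function(object) {
  vf <- object@varFractions
  if (any(vf < -1e-12)) return("variance fractions must be non-negative")
  if (is.unsorted(rev(vf), strictly = FALSE) && any(diff(vf) > 1e-9))
    return("variance fractions must be descending")
  if (sum(vf) > 1 + 1e-6) return("variance fractions must sum to <= 1")
  G <- crossprod(object@rotation)
  if (max(abs(G - diag(ncol(G)))) > 1e-6)
    return("component vectors must be orthonormal")
  TRUE
})

#' Free-energy landscape over two principal components
#'
#' Gridded conditional free energy `F = -ln(rho/rho_max)` in RT units over
#' (PC1, PC2), with the underlying kernel density, an optional basin label per
#' unmasked cell, and the basin minima.
#'
#' @slot pc1,pc2 numeric grid axes.
#' @slot energy matrix of free energies (RT); `NA` where masked (beyond cap).
#' @slot density matrix of kernel density estimates.
#' @slot basins integer matrix of basin labels (`NA` where masked; 0 before
#'   [assignBasins] has run).
#' @slot minima data.frame of basin minima (`basin`, `pc1`, `pc2`, `energy`,
#'   `depthBand`).
#' @slot capRT numeric free-energy cap (RT).
#' @export
setClass("FreeEnergyLandscape",
  representation(pc1 = "numeric", pc2 = "numeric", energy = "matrix",
                 density = "matrix", basins = "matrix", minima = "data.frame",
                 capRT = "numeric"))

setValidity("FreeEnergyLandscape", function(object) {
  E <- object@energy
  if (!all(dim(E) == c(length(object@pc1), length(object@pc2))))
    return("energy grid must be length(pc1) x length(pc2)")
  un <- E[!is.na(E)]
  if (!length(un)) return("landscape has no unmasked cells")
  if (abs(min(un)) > 1e-12) return("minimum free energy must be exactly 0")
  if (any(un < 0)) return("free energies must be >= 0")
  TRUE
})

#' Affine chi-square fit result
#'
#' Result of fitting `I_ref ~ f * I_obs + c` by minimising the reduced
#' chi-square with the Nelder-Mead simplex, together with the closed-form
#' weighted least-squares cross-check.
#'
#' @slot f,c fitted scale and offset.
#' @slot chi2 minimised chi-square (normalised per point).
#' @slot nPoints number of reference points used.
#' @slot norm normalisation convention, `"n"` or `"n-1"`.
#' @slot crosscheck list with the closed-form weighted least-squares solution
#'   (`f`, `c`, `chi2`).
#' @export
setClass("Chi2FitResult",
  representation(f = "numeric", c = "numeric", chi2 = "numeric",
                 nPoints = "integer", norm = "character", crosscheck = "list"))

setValidity("Chi2FitResult", function(object) {
  if (object@chi2 < 0) return("chi2 must be >= 0")
  if (object@nPoints < 3L) return("fit needs >= 3 points")
  TRUE
})

#' Block-averaging error estimate
#'
#' Flyvbjerg-Petersen blocking analysis of a correlated scalar series: the
#' standard error of block means at each doubling level, the plateau estimate,
#' and whether a plateau was detected.
#'
#' @slot blockSizes integer block sizes (1, 2, 4, ...).
#' @slot errors numeric standard-error estimate per level.
#' @slot plateau numeric plateau standard-error estimate.
#' @slot converged logical; `FALSE` if no plateau was detected and the
#'   maximum-level estimate is reported instead.
#' @export
setClass("BlockErrorEstimate",
  representation(blockSizes = "integer", errors = "numeric",
                 plateau = "numeric", converged = "logical"))

setValidity("BlockErrorEstimate", function(object) {
  if (length(object@blockSizes) != length(object@errors))
    return("blockSizes and errors must have equal length")
  if (any(object@errors < 0)) return("error estimates must be >= 0")
  if (is.unsorted(object@blockSizes, strictly = TRUE))
    return("block sizes must be strictly increasing")
  TRUE
})

#' Residue contact map
#'
#' Symmetric matrix of residue-residue contact probabilities, where two
#' residues are in contact in a frame iff the minimum distance between any two
#' of their atoms is below the cutoff (strict `<`).
#'
#' @slot probabilities symmetric numeric matrix in `[0, 1]`, diagonal 1.
#' @slot cutoff contact cutoff (nm).
#' @export
setClass("ContactMap",
  representation(probabilities = "matrix", cutoff = "numeric"))

setValidity("ContactMap", function(object) {
  P <- object@probabilities
  if (nrow(P) != ncol(P)) return("probability matrix must be square")
  if (any(P < 0 | P > 1)) return("probabilities must lie in [0, 1]")
  if (max(abs(P - t(P))) > 1e-12) return("contact map must be symmetric")
  if (any(abs(diag(P) - 1) > 1e-12)) return("diagonal is defined as 1")
  if (object@cutoff <= 0) return("cutoff must be positive")
  TRUE
})
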
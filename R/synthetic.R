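# Synthetic-ensemble generators with known ground truth: freely jointed
# chains, ideal-geometry peptide backbones, planted residue-residue contacts,
# and noisy affine-transformed reference scattering curves.

#' Standard backbone geometry
#'
#' Canonical trans-peptide bond lengths (nm) and angles (degrees) used by
#' [buildBackbone()]: N-CA 0.1458, CA-C 0.1525, C-N 0.1329, C=O 0.1231,
#' N-H 0.098; angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8.
#'
#' @param ... named overrides of any element.
#' @return Named list of geometry parameters.
#' @export
backboneGeometry <- function(...) {
  geo <- list(bNCA = 0.1458, bCAC = 0.1525, bCN = 0.1329,
              bCO = 0.1231, bNH = 0.098,
              aNCAC = 111.2, aCACN = 116.2, aCNCA = 121.7, aCACO = 120.8)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(geo))
    if (length(bad)) stop("unknown geometry parameter: ", paste(bad, collapse = ", "))
    geo[names(over)] <- over
    if (any(unlist(geo[c("bNCA", "bCAC", "bCN", "bCO", "bNH")]) <= 0))
      stop("bond lengths must be positive")
  }
  geo
}

#' Generate a freely jointed (ideal) chain ensemble
#'
#' Each frame is a random walk of `nBeads` beads with fixed bond length and
#' i.i.d. uniformly random bond directions. The ensemble obeys the ideal-chain
#' statistics `<Ree^2> = (n-1) b^2` and `<Rg^2> = b^2 (n^2 - 1) / (6 n)`,
#' which downstream tests use as ground truth. Deterministic given `seed`.
#'
#' @param nBeads number of beads (>= 2).
#' @param bondLength bond length (nm).
#' @param nFrames number of frames (>= 1).
#' @param seed integer RNG seed (the caller's RNG state is untouched).
#' @param beadMass mass per bead (amu); only mass ratios matter downstream.
#' @return An [Ensemble-class] with one CA bead per residue.
#' @export
generateIdealChain <- function(nBeads, bondLength = 0.38, nFrames = 1000,
                               seed = NULL, beadMass = 110) {
  if (nBeads < 2) stop("nBeads must be >= 2")
  if (bondLength <= 0) stop("bondLength must be positive")
  if (nFrames < 1) stop("nFrames must be >= 1")
  if (beadMass <= 0) stop("beadMass must be positive")
  X <- withSeed(seed, {
    # uniform directions: normalised standard-normal triples
    g <- array(rnorm(nFrames * (nBeads - 1) * 3),
               dim = c(nFrames, nBeads - 1, 3))
    nrm <- sqrt(g[, , 1]^2 + g[, , 2]^2 + g[, , 3]^2)
    steps <- g * array(rep(bondLength / nrm, 3), dim = dim(g))
    out <- array(0, dim = c(nFrames, nBeads, 3))
    for (k in 1:3)
      for (j in 2:nBeads)
        out[, j, k] <- out[, j - 1, k] + steps[, j - 1, k]
    out
  })
  topo <- data.frame(name = "CA", element = "C", mass = beadMass,
                     resid = seq_len(nBeads), resname = "BEA",
                     stringsAsFactors = FALSE)
  Ensemble(X, topo)
}

#' Build an ideal-geometry peptide backbone
#'
#' Places backbone atoms (N, H, CA, C, O per residue; no amide H on proline)
#' by sequential internal-coordinate (NeRF) construction from per-residue
#' (phi, psi) dihedrals with trans peptide bonds (omega 180 degrees by
#' default). Recomputing the dihedrals from the coordinates returns the
#' inputs to well under half a degree. The amide H is placed 0.098 nm from N,
#' trans to the preceding carbonyl O in the peptide plane (the Kabsch-Sander
#' reconstruction convention); the first residue takes the in-plane direction
#' opposite the N-CA/N-(own C) bisector since it has no preceding peptide
#' plane.
#'
#' @param sequence an [AnnotatedSequence-class] or a plain one-letter string.
#' @param phi,psi per-residue dihedrals (degrees), recycled if scalar.
#'   `phi[1]` and trailing `psi` values are not used (chain-end convention).
#' @param omega peptide-bond dihedral (degrees), default 180 (trans).
#' @param geometry from [backboneGeometry()].
#' @return A single-frame [Ensemble-class].
#' @export
buildBackbone <- function(sequence, phi, psi, omega = 180,
                          geometry = backboneGeometry()) {
  if (is.character(sequence)) sequence <- parseSequence(sequence)
  res <- residues(sequence)
  n <- length(res)
  if (length(phi) == 1) phi <- rep(phi, n)
  if (length(psi) == 1) psi <- rep(psi, n)
  if (length(phi) != n || length(psi) < n - 1)
    stop("need one (phi, psi) pair per residue")
  psi <- c(psi, 180)[seq_len(n)]  # trailing psi ignored / defaulted
  g <- geometry

  N <- CA <- C <- O <- H <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$bNCA, 0, 0)
  a <- g$aNCAC * pi / 180
  C[1, ] <- CA[1, ] + g$bCAC * c(cos(pi - a), sin(pi - a), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- nerfPlace(N[i, ], CA[i, ], C[i, ], g$bCN, g$aCACN, psi[i])
    CA[i + 1, ] <- nerfPlace(CA[i, ], C[i, ], N[i + 1, ], g$bNCA, g$aCNCA, omega)
    C[i + 1, ] <- nerfPlace(C[i, ], N[i + 1, ], CA[i + 1, ], g$bCAC, g$aNCAC,
                            phi[i + 1])
  }
  for (i in seq_len(n))
    O[i, ] <- nerfPlace(N[i, ], CA[i, ], C[i, ], g$bCO, g$aCACO, psi[i] + 180)
  for (i in seq_len(n)) {
    if (res[i] == "P") next
    dir <- if (i > 1) vunit(C[i - 1, ] - O[i - 1, ])
           else -vunit(vunit(CA[1, ] - N[1, ]) + vunit(C[1, ] - N[1, ]))
    H[i, ] <- N[i, ] + g$bNH * dir
  }

  am <- c(N = 14.007, H = 1.008, C = 12.011, O = 15.999)
  rows <- list()
  xyz <- list()
  for (i in seq_len(n)) {
    nm <- c("N", if (res[i] != "P") "H", "CA", "C", "O")
    el <- substr(nm, 1, 1)
    rows[[i]] <- data.frame(name = nm, element = el, mass = am[el],
                            resid = i, resname = aaThree(res[i]),
                            stringsAsFactors = FALSE)
    P <- rbind(N[i, ], if (res[i] != "P") H[i, ], CA[i, ], C[i, ], O[i, ])
    xyz[[i]] <- P
  }
  topo <- do.call(rbind, rows)
  rownames(topo) <- NULL
  Ensemble(do.call(rbind, xyz), topo)
}

# one-letter to three-letter residue names (PDB convention)
aaThree <- function(a) {
  map <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  unname(map[a])
}

#' Plant residue-residue contact fractions by stratified resampling
#'
#' Resamples the frames of `base` so that, for each requested residue pair,
#' the fraction of frames whose minimum inter-residue atom distance is below
#' the cutoff equals the target within +/- 0.02. Frames are drawn with
#' replacement within the strata defined by the joint contact pattern, with
#' stratum counts set by largest-remainder apportionment of the product
#' (independence) distribution of the targets. Per-frame coordinates are
#' preserved exactly; only the frame multiset changes, and the frame count is
#' kept.
#'
#' @param base an [Ensemble-class].
#' @param specs list of specs, each a list with elements `i`, `j` (residue
#'   indices), `fraction` (target in `[0, 1]`) and optional `cutoff` (nm,
#'   default 0.4).
#' @param seed integer RNG seed.
#' @return An [Ensemble-class] with the same frame count as `base`.
#' @export
plantContacts <- function(base, specs, seed = NULL) {
  topo <- topology(base)
  nf <- nFrames(base)
  K <- length(specs)
  if (!K) return(base)
  for (s in specs) {
    if (s$i == s$j) stop("contact spec must name two distinct residues")
    if (s$fraction < 0 || s$fraction > 1)
      stop("target fraction must lie in [0, 1]")
    if (!all(c(s$i, s$j) %in% topo$resid))
      stop("contact spec names residues absent from the topology")
  }
  # per-frame contact indicator for each spec
  ind <- matrix(FALSE, nf, K)
  X <- coords(base)
  cutoffs <- vapply(specs, function(s) if (is.null(s$cutoff)) 0.4 else s$cutoff,
                    numeric(1))
  for (f in seq_len(nf)) {
    md <- cpp_res_min_dist(X[f, , , drop = TRUE], topo$resid)
    for (k in seq_len(K))
      ind[f, k] <- md[specs[[k]]$i, specs[[k]]$j] < cutoffs[k]
  }
  # strata = joint contact patterns; target mass = product of marginals
  pat <- ind %*% (2 ^ (seq_len(K) - 1))
  targets <- vapply(specs, `[[`, numeric(1), "fraction")
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), K)))
  mass <- apply(patterns, 1, function(p)
    prod(ifelse(p, targets, 1 - targets)))
  codes <- patterns %*% (2 ^ (seq_len(K) - 1))
  avail <- vapply(codes, function(cd) sum(pat == cd), numeric(1))
  if (any(mass > 0 & avail == 0))
    stop("infeasible: base ensemble has no frame for a required contact pattern")
  # largest-remainder apportionment of nf frames over strata
  raw <- mass / sum(mass) * nf
  cnt <- floor(raw)
  rem <- nf - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  idx <- withSeed(seed, {
    out <- integer(0)
    for (p in seq_along(codes)) {
      if (cnt[p] == 0) next
      pool <- which(pat == codes[p])
      out <- c(out, pool[sample.int(length(pool), cnt[p], replace = TRUE)])
    }
    out
  })
  base[sort(idx)]
}

#' Synthesize a noisy affine reference scattering curve
#'
#' Produces `I_ref(q) = f * I_calc(q) + c + N(0, sigma)` with the per-point
#' error column set to `sigma` (or a supplied vector), emulating an
#' experimental reference curve for the affine chi-square fit.
#'
#' @param calc a [ScatteringCurve-class].
#' @param f,c scale and offset of the affine map.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @param sigmaValues optional per-point error vector overriding `sigma`.
#' @return A [ScatteringCurve-class] with errors set.
#' @export
synthesizeReferenceCurve <- function(calc, f = 1, c = 0, sigma = 0,
                                     seed = NULL, sigmaValues = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  q <- qValues(calc)
  I <- f * intensities(calc) + c
  if (sigma > 0)
    I <- I + withSeed(seed, rnorm(length(q), 0, sigma))
  err <- if (!is.null(sigmaValues)) sigmaValues
         else if (sigma > 0) rep(sigma, length(q)) else rep(1, length(q))
  ScatteringCurve(q, I, err)
}
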
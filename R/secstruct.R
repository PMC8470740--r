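# Kabsch-Sander secondary-structure assignment extended with polyproline II
# detection, plus grouped content summaries.

#' Reconstruct amide hydrogens
#'
#' Adds an H atom to every backbone N that lacks one (except proline and the
#' first residue), placed 0.098 nm from N along the direction of the
#' preceding residue's C -> O vector reversed — i.e. trans to the carbonyl O
#' in the peptide plane, the standard reconstruction used by
#' secondary-structure programs for heavy-atom-only inputs.
#'
#' @param ens an [Ensemble-class] with backbone N, CA, C, O atoms.
#' @param bNH N-H bond length (nm).
#' @return An [Ensemble-class] with hydrogens present.
#' @export
reconstructAmideH <- function(ens, bNH = 0.098) {
  topo <- topology(ens)
  res <- sort(unique(topo$resid))
  need <- res[-1]
  need <- need[vapply(need, function(r) {
    rn <- topo$resname[match(r, topo$resid)]
    rn != "PRO" && is.na(atomIndex(topo, r, "H"))
  }, logical(1))]
  if (!length(need)) return(ens)
  X <- coords(ens)
  nf <- dim(X)[1]
  newRows <- list(); newXYZ <- list()
  for (r in need) {
    iN <- atomIndex(topo, r, "N")
    iCprev <- atomIndex(topo, r - 1L, "C")
    iOprev <- atomIndex(topo, r - 1L, "O")
    if (is.na(iN) || is.na(iCprev) || is.na(iOprev))
      stop("backbone atoms missing around residue ", r)
    H <- array(NA_real_, c(nf, 1, 3))
    for (f in seq_len(nf)) {
      dir <- vunit(X[f, iCprev, ] - X[f, iOprev, ])
      H[f, 1, ] <- X[f, iN, ] + bNH * dir
    }
    newRows[[length(newRows) + 1]] <- data.frame(
      name = "H", element = "H", mass = 1.008, resid = r,
      resname = topo$resname[match(r, topo$resid)], stringsAsFactors = FALSE)
    newXYZ[[length(newXYZ) + 1]] <- list(after = iN, xyz = H)
  }
  # splice each H directly after its N so residue blocks stay contiguous
  ord <- order(vapply(newXYZ, `[[`, integer(1), "after"), decreasing = TRUE)
  Xout <- X; topoOut <- topo
  for (k in ord) {
    at <- newXYZ[[k]]$after
    na <- dim(Xout)[2]
    Xnew <- array(NA_real_, c(nf, na + 1, 3))
    Xnew[, seq_len(at), ] <- Xout[, seq_len(at), , drop = FALSE]
    Xnew[, at + 1, ] <- newXYZ[[k]]$xyz[, 1, ]
    if (at < na)
      Xnew[, (at + 2):(na + 1), ] <- Xout[, (at + 1):na, , drop = FALSE]
    Xout <- Xnew
    topoOut <- rbind(topoOut[seq_len(at), ], newRows[[k]],
                     if (at < na) topoOut[(at + 1):na, ])
  }
  rownames(topoOut) <- NULL
  Ensemble(Xout, topoOut, frameTimes(ens))
}

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic model
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol with
#' distances in Angstrom between the donor's N, H and the acceptor's C, O.
#' A hydrogen bond is assigned when `E < -0.5` kcal/mol.
#'
#' @param ens an [Ensemble-class] (amide hydrogens present or reconstructable).
#' @param donor,acceptor residue indices (donor contributes N-H, acceptor
#'   C=O).
#' @param frame frame index.
#' @return Energy in kcal/mol.
#' @export
backboneHBondEnergy <- function(ens, donor, acceptor, frame = 1) {
  topo <- topology(ens)
  iN <- atomIndex(topo, donor, "N")
  iH <- atomIndex(topo, donor, "H")
  iC <- atomIndex(topo, acceptor, "C")
  iO <- atomIndex(topo, acceptor, "O")
  if (anyNA(c(iN, iH, iC, iO)))
    stop("topology error: backbone N/H/C/O required (donor ", donor,
         ", acceptor ", acceptor, ")")
  P <- coords(ens)[frame, , , drop = TRUE]
  d <- function(i, j) 10 * sqrt(sum((P[i, ] - P[j, ])^2))  # nm -> Angstrom
  0.084 * 332 * (1 / d(iO, iN) + 1 / d(iC, iH) - 1 / d(iO, iH) - 1 / d(iC, iN))
}

# per-frame donor x acceptor H-bond matrix (TRUE where E < cutoff)
ksHBondMatrix <- function(P, iN, iH, iC, iO, cutoff = -0.5) {
  nr <- length(iN)
  HB <- matrix(FALSE, nr, nr)
  for (don in seq_len(nr)) {
    if (is.na(iH[don])) next  # proline / first residue: no donor
    for (acc in seq_len(nr)) {
      if (abs(don - acc) < 2) next  # self and adjacent excluded
      rON <- 10 * sqrt(sum((P[iO[acc], ] - P[iN[don], ])^2))
      if (rON > 7) next  # beyond plausible H-bond range
      rCH <- 10 * sqrt(sum((P[iC[acc], ] - P[iH[don], ])^2))
      rOH <- 10 * sqrt(sum((P[iO[acc], ] - P[iH[don], ])^2))
      rCN <- 10 * sqrt(sum((P[iC[acc], ] - P[iN[don], ])^2))
      E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      HB[don, acc] <- E < cutoff
    }
  }
  HB
}

#' Assign secondary structure (Kabsch-Sander rules)
#'
#' Per frame: backbone hydrogen bonds from the electrostatic model
#' ([backboneHBondEnergy()]), n-turns (n = 3, 4, 5) from i -> i+n bonds,
#' helices G/H/I from two or more consecutive turns of the respective n,
#' strands E and isolated bridges B from parallel/antiparallel bridge
#' patterns, turns T from isolated n-turns, bends S where the
#' CA(i-2)-CA(i)-CA(i+2) direction change exceeds 70 degrees, and C
#' otherwise. Priority: H > E > B > G > I > T > S > C. Chains shorter than
#' three residues are all C. Missing amide hydrogens are reconstructed.
#'
#' @param ens an [Ensemble-class] with backbone atoms N, CA, C, O.
#' @param bendAngle bend threshold (degrees), default 70.
#' @return An [SSMatrix-class].
#' @export
assignDSSP <- function(ens, bendAngle = 70) {
  ens <- reconstructAmideH(ens)
  topo <- topology(ens)
  res <- sort(unique(topo$resid))
  nr <- length(res)
  X <- coords(ens)
  nf <- dim(X)[1]
  codes <- matrix("C", nf, nr)
  if (nr < 3) return(SSMatrix(codes))
  iN <- vapply(res, function(r) atomIndex(topo, r, "N"), integer(1))
  iH <- vapply(res, function(r) atomIndex(topo, r, "H"), integer(1))
  iCA <- vapply(res, function(r) atomIndex(topo, r, "CA"), integer(1))
  iC <- vapply(res, function(r) atomIndex(topo, r, "C"), integer(1))
  iO <- vapply(res, function(r) atomIndex(topo, r, "O"), integer(1))
  if (anyNA(c(iN, iCA, iC, iO)))
    stop("topology error: backbone N, CA, C, O required for every residue")

  for (f in seq_len(nf)) {
    P <- X[f, , , drop = TRUE]
    HB <- ksHBondMatrix(P, iN, iH, iC, iO)
    # turn_n[i]: H-bond from donor i+n to acceptor i
    turn <- list()
    for (n in 3:5) {
      tn <- rep(FALSE, nr)
      idx <- seq_len(nr - n)
      tn[idx] <- HB[cbind(idx + n, idx)]
      turn[[as.character(n)]] <- tn
    }
    helix <- matrix(FALSE, 3, nr)  # rows: n = 3, 4, 5
    for (n in 3:5) {
      tn <- turn[[as.character(n)]]
      for (i in which(tn)) {
        if (i > 1 && tn[i - 1])
          helix[n - 2, i:(i + n - 1)] <- TRUE
      }
    }
    # bridges
    bridge <- rep(FALSE, nr)
    partner <- rep(NA_integer_, nr)
    for (i in seq_len(nr)) {
      for (j in seq_len(nr)) {
        if (j - i < 3) next
        para <- (safeHB(HB, j, i - 1) && safeHB(HB, i + 1, j)) ||
                (safeHB(HB, i, j - 1) && safeHB(HB, j + 1, i))
        anti <- (safeHB(HB, j, i) && safeHB(HB, i, j)) ||
                (safeHB(HB, j + 1, i - 1) && safeHB(HB, i + 1, j - 1))
        if (para || anti) {
          bridge[i] <- bridge[j] <- TRUE
          partner[i] <- j; partner[j] <- i
        }
      }
    }
    # extended strand: ladders of >= 2 consecutive bridged residues
    strand <- bridge & (c(FALSE, bridge[-nr]) | c(bridge[-1], FALSE))
    # turns: interior residues of isolated n-turns
    tflag <- rep(FALSE, nr)
    for (n in 3:5) {
      for (i in which(turn[[as.character(n)]])) {
        span <- (i + 1):(i + n - 1)
        tflag[span[span <= nr]] <- TRUE
      }
    }
    # bends
    bend <- rep(FALSE, nr)
    if (nr >= 5) {
      for (i in 3:(nr - 2)) {
        a <- bondAngle(P[iCA[i - 2], ], P[iCA[i], ], P[iCA[i + 2], ])
        # direction change: angle between (CA_i - CA_{i-2}) and
        # (CA_{i+2} - CA_i) = 180 - angle at the vertex
        bend[i] <- (180 - a) > bendAngle
      }
    }
    code <- rep("C", nr)
    code[bend] <- "S"
    code[tflag] <- "T"
    code[helix[3, ]] <- "I"
    code[helix[1, ]] <- "G"
    code[bridge & !strand] <- "B"
    code[strand] <- "E"
    code[helix[2, ]] <- "H"
    codes[f, ] <- code
  }
  SSMatrix(codes)
}

safeHB <- function(HB, don, acc) {
  nr <- nrow(HB)
  don >= 1 && don <= nr && acc >= 1 && acc <= nr && HB[don, acc]
}

#' Extend an assignment with polyproline II detection
#'
#' Residues currently irregular (C) whose backbone dihedrals fall inside the
#' PPII window (phi in [-104, -46], psi in [116, 174] degrees) for at least
#' `minRun` consecutive residues are relabelled P. No other code is touched,
#' so helix/strand/turn/bend content can only stay equal or a C residue is
#' upgraded.
#'
#' @param ss an [SSMatrix-class].
#' @param dihedrals list with `phi`, `psi` matrices (from
#'   [computeDihedrals()]); alternatively pass `ens`.
#' @param ens optional [Ensemble-class] from which dihedrals are computed.
#' @param phiRange,psiRange PPII window bounds (degrees).
#' @param minRun minimum run length of window residues, default 2.
#' @return An [SSMatrix-class] with P labels added.
#' @export
extendPPII <- function(ss, dihedrals = NULL, ens = NULL,
                       phiRange = c(-104, -46), psiRange = c(116, 174),
                       minRun = 2) {
  if (is.null(dihedrals)) {
    if (is.null(ens)) stop("need dihedrals or an ensemble")
    dihedrals <- computeDihedrals(ens)
  }
  codes <- ssCodes(ss)
  phi <- dihedrals$phi; psi <- dihedrals$psi
  stopifnot(all(dim(codes) == dim(phi)))
  inWin <- !is.na(phi) & !is.na(psi) &
    phi >= phiRange[1] & phi <= phiRange[2] &
    psi >= psiRange[1] & psi <= psiRange[2]
  for (f in seq_len(nrow(codes))) {
    elig <- inWin[f, ] & codes[f, ] == "C"
    r <- rle(elig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= minRun))
      codes[f, starts[k]:ends[k]] <- "P"
  }
  SSMatrix(codes)
}

#' Grouped secondary-structure summary
#'
#' Mean content per reported group — helix (H+G+I), beta strand (E+B), turn
#' (T), bend (S), PPII (P), irregular (C) — over all frames and residues,
#' with block-averaging errors from the per-frame group-fraction series
#' (NA when fewer than 16 frames).
#'
#' @param ss an [SSMatrix-class].
#' @return data.frame with `group`, `fraction`, `blockError`; fractions sum
#'   to 1.
#' @export
ssSummary <- function(ss) {
  codes <- ssCodes(ss)
  if (!length(codes)) stop("empty assignment")
  groups <- list(helix = c("H", "G", "I"), strand = c("E", "B"),
                 turn = "T", bend = "S", ppii = "P", irregular = "C")
  nf <- nrow(codes)
  perFrame <- vapply(groups, function(g)
    rowMeans(matrix(codes %in% g, nf, ncol(codes))), numeric(nf))
  perFrame <- matrix(perFrame, nrow = nf)
  fr <- colMeans(perFrame)
  be <- if (nf >= 16) apply(perFrame, 2, function(s) blockError(s)@plateau)
        else rep(NA_real_, length(groups))
  data.frame(group = names(groups), fraction = fr, blockError = be,
             row.names = NULL)
}
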
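# Vector geometry: torsions, internal-coordinate placement, Kabsch
# superposition. Angles are in degrees at the user surface, coordinates in nm.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vunit <- function(v) v / sqrt(sum(v * v))

#' Torsion angle of four points
#'
#' IUPAC-signed dihedral angle defined by four positions, in degrees in
#' `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return Angle in degrees.
#' @export
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  # negated atan2 branch: matches the protein-structure sign convention
  # (bio3d::torsion.xyz agrees) and round-trips with nerfPlace()
  -ang
}

#' Angle at p2 formed by p1-p2-p3, in degrees
#' @param p1,p2,p3 numeric length-3 coordinates.
#' @return Angle in degrees in `[0, 180]`.
#' @export
bondAngle <- function(p1, p2, p3) {
  v1 <- vunit(p1 - p2); v2 <- vunit(p3 - p2)
  acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
}

# Natural-extension reference frame: place D at bond length r from C, with
# angle(B, C, D) = ang and torsion(A, B, C, D) = tor (degrees).
nerfPlace <- function(A, B, C, r, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  bc <- vunit(C - B)
  n <- vunit(vcross(B - A, bc))
  m <- vcross(n, bc)
  d <- r * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Optimal rotation R (applied as P %*% R) aligning centred P onto centred Q:
# with svd(P^T Q) = U S V^T, R = U diag(1, 1, det(U V^T)) V^T.
kabschRotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Superpose every frame of an ensemble onto frame `ref` using the atoms in
# `selection` for the fit; the rigid motion is applied to all atoms.
superposeFrames <- function(ens, ref = 1L, selection = NULL) {
  X <- coords(ens)
  nf <- dim(X)[1]
  if (is.null(selection)) selection <- seq_len(dim(X)[2])
  Qsel <- X[ref, selection, , drop = TRUE]
  Qc <- colMeans(Qsel)
  Q0 <- sweep(Qsel, 2, Qc)
  out <- X
  for (f in seq_len(nf)) {
    Psel <- X[f, selection, , drop = TRUE]
    Pc <- colMeans(Psel)
    R <- kabschRotation(sweep(Psel, 2, Pc), Q0)
    out[f, , ] <- sweep(sweep(X[f, , , drop = TRUE], 2, Pc) %*% R, 2, -Qc)
  }
  Ensemble(out, topology(ens), frameTimes(ens))
}

# Indices of the residue's backbone atom with the given name, NA if absent.
atomIndex <- function(topo, resid, name) {
  i <- which(topo$resid == resid & topo$name == name)
  if (length(i)) i[1] else NA_integer_
}

#' Backbone dihedral angles of every frame
#'
#' Computes per-residue phi and psi torsions from the backbone N, CA, C atoms.
#' phi is undefined for the first residue and psi for the last (returned as
#' `NA`).
#'
#' @param ens an [Ensemble-class] with backbone atoms named N, CA, C.
#' @return List with `phi` and `psi`, each a `frames x residues` matrix in
#'   degrees.
#' @export
computeDihedrals <- function(ens) {
  topo <- topology(ens)
  res <- sort(unique(topo$resid))
  nr <- length(res)
  X <- coords(ens)
  nf <- dim(X)[1]
  iN <- vapply(res, function(r) atomIndex(topo, r, "N"), integer(1))
  iCA <- vapply(res, function(r) atomIndex(topo, r, "CA"), integer(1))
  iC <- vapply(res, function(r) atomIndex(topo, r, "C"), integer(1))
  if (anyNA(c(iN, iCA, iC)))
    stop("computeDihedrals: backbone atoms N, CA, C required for every residue")
  phi <- psi <- matrix(NA_real_, nf, nr)
  for (f in seq_len(nf)) {
    P <- X[f, , , drop = TRUE]
    for (r in seq_len(nr)) {
      if (r > 1)
        phi[f, r] <- torsionAngle(P[iC[r - 1], ], P[iN[r], ], P[iCA[r], ],
                                  P[iC[r], ])
      if (r < nr)
        psi[f, r] <- torsionAngle(P[iN[r], ], P[iCA[r], ], P[iC[r], ],
                                  P[iN[r + 1], ])
    }
  }
  list(phi = phi, psi = psi)
}
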
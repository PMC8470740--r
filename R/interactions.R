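# Residue contact maps, distance-angle hydrogen-bond detection, and
# salt-bridge occupancy with block-averaged errors.

#' Hydrogen-bond criterion parameters
#'
#' Distance-angle coupled criterion: a bond exists iff the donor-acceptor
#' heavy-atom distance satisfies `r_DA < dist0 - k * theta^2`, where `theta`
#' is the hydrogen-donor-acceptor angle in degrees. Defaults: `dist0` 0.33 nm
#' and `k` 4.4e-5 nm/deg^2 (the angular-softening form used by trajectory
#' analysis libraries); both are configurable so the criterion is auditable.
#'
#' @param dist0 base distance cutoff (nm).
#' @param k angular softening constant (nm per squared degree).
#' @return Named list with `dist0` and `k`.
#' @export
hbondCriterion <- function(dist0 = 0.33, k = 0.000044) {
  if (dist0 <= 0 || k < 0) stop("invalid criterion constants")
  list(dist0 = dist0, k = k)
}

#' Residue-residue contact map
#'
#' Two residues are in contact in a frame iff the shortest distance between
#' any two of their atoms (hydrogens included) is below the cutoff
#' (strict `<`). The map holds the per-pair fraction of frames in contact;
#' the diagonal is defined as 1.
#'
#' @param ens an [Ensemble-class] with >= 2 residues.
#' @param cutoff contact cutoff (nm), default 0.4.
#' @return A [ContactMap-class].
#' @export
contactMap <- function(ens, cutoff = 0.4) {
  topo <- topology(ens)
  nr <- length(unique(topo$resid))
  if (nr < 2) stop("contact map needs >= 2 residues")
  X <- coords(ens)
  nf <- dim(X)[1]
  P <- matrix(0, nr, nr)
  for (f in seq_len(nf)) {
    md <- cpp_res_min_dist(X[f, , , drop = TRUE], topo$resid)
    P <- P + (md < cutoff)
  }
  P <- P / nf
  diag(P) <- 1
  new("ContactMap", probabilities = P, cutoff = cutoff)
}

# hydrogens covalently attached to a heavy atom, by distance in one frame
attachedHydrogens <- function(P, topo, heavy, attachDist = 0.12) {
  hs <- which(topo$element == "H")
  if (!length(hs)) return(integer(0))
  d <- sqrt(rowSums(sweep(P[hs, , drop = FALSE], 2, P[heavy, ])^2))
  hs[d < attachDist]
}

#' Detect hydrogen bonds in one frame
#'
#' Evaluates the distance-angle criterion of [hbondCriterion()] for every
#' (donor heavy atom, attached hydrogen, acceptor) triple. Hydrogens are
#' associated with a donor by covalent distance (< 0.12 nm) in the frame.
#'
#' @param ens an [Ensemble-class].
#' @param donors indices of donor heavy atoms (must carry >= 1 hydrogen).
#' @param acceptors indices of acceptor atoms.
#' @param frame frame index.
#' @param criterion from [hbondCriterion()].
#' @return data.frame with `donor`, `hydrogen`, `acceptor`, `rDA` (nm),
#'   `theta` (degrees); zero rows when no bond is present.
#' @export
detectHBonds <- function(ens, donors, acceptors, frame = 1,
                         criterion = hbondCriterion()) {
  topo <- topology(ens)
  P <- coords(ens)[frame, , , drop = TRUE]
  out <- list()
  for (d in donors) {
    hyd <- attachedHydrogens(P, topo, d)
    if (!length(hyd))
      stop("topology error: donor atom ", d, " carries no hydrogen")
    for (a in acceptors) {
      if (a == d) next
      rDA <- sqrt(sum((P[a, ] - P[d, ])^2))
      for (h in hyd) {
        theta <- bondAngle(P[h, ], P[d, ], P[a, ])
        if (rDA < criterion$dist0 - criterion$k * theta^2)
          out[[length(out) + 1]] <- data.frame(
            donor = d, hydrogen = h, acceptor = a, rDA = rDA, theta = theta)
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), rDA = numeric(0),
                      theta = numeric(0)))
  do.call(rbind, out)
}

# Donor heavy atoms of a residue (side chains and the N-terminal ammonium).
# His is excluded by default: the peptides under study form no relevant His
# contacts, and protonation is ambiguous at fixed charges.
donorAtomsOf <- function(topo, resid, includeHis = FALSE) {
  rn <- topo$resname[match(resid, topo$resid)]
  names <- switch(rn,
    ARG = c("NE", "NH1", "NH2"),
    LYS = "NZ",
    HIS = if (includeHis) c("ND1", "NE2") else character(0),
    character(0))
  if (resid == min(topo$resid)) names <- c(names, "N")  # N-terminal ammonium
  which(topo$resid == resid & topo$name %in% names)
}

# Acceptor atoms: phosphate oxygens of phospho-Ser/Thr, carboxylate oxygens
# of Asp/Glu, and the C-terminal carboxylate.
acceptorAtomsOf <- function(topo, resid) {
  rn <- topo$resname[match(resid, topo$resid)]
  names <- switch(rn,
    SEP = , TPO = c("O1P", "O2P", "O3P"),
    ASP = c("OD1", "OD2"),
    GLU = c("OE1", "OE2"),
    character(0))
  if (resid == max(topo$resid)) names <- c(names, "O", "OXT")  # C-terminus
  which(topo$resid == resid & topo$name %in% names)
}

#' Salt-bridge occupancy per residue pair
#'
#' A pair is bridged in a frame iff at least one hydrogen bond (per
#' [hbondCriterion()]) links the donor atom set of its positively charged
#' residue (Arg NE/NH1/NH2, Lys NZ, the N-terminal ammonium; His optional)
#' with the acceptor atom set of its negatively charged residue (phosphate
#' oxygens, carboxylate oxygens, the C-terminal carboxylate). Occupancy is
#' the fraction of bridged frames; its error comes from [blockError()]
#' applied to the per-frame 0/1 indicator (NA for short series).
#'
#' @param ens an [Ensemble-class].
#' @param pairs data.frame (or 2-column matrix) of residue index pairs; the
#'   donor/acceptor roles are resolved from residue chemistry, so declaration
#'   order does not matter.
#' @param criterion from [hbondCriterion()].
#' @param includeHis treat His as a donor.
#' @return data.frame with `donorRes`, `acceptorRes`, `occupancy`,
#'   `blockError`.
#' @export
saltBridgeOccupancy <- function(ens, pairs, criterion = hbondCriterion(),
                                includeHis = FALSE) {
  topo <- topology(ens)
  X <- coords(ens)
  nf <- dim(X)[1]
  pairs <- as.matrix(pairs)
  res <- lapply(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    if (i == j) stop("donor and acceptor residue must differ")
    di <- donorAtomsOf(topo, i, includeHis); ai <- acceptorAtomsOf(topo, i)
    dj <- donorAtomsOf(topo, j, includeHis); aj <- acceptorAtomsOf(topo, j)
    if (length(di) && length(aj)) {
      don <- i; acc <- j; datoms <- di; aatoms <- aj
    } else if (length(dj) && length(ai)) {
      don <- j; acc <- i; datoms <- dj; aatoms <- ai
    } else {
      stop("topology error: residues ", i, "/", j,
           " do not form a donor/acceptor salt-bridge pair")
    }
    ind <- numeric(nf)
    for (f in seq_len(nf)) {
      hb <- detectHBonds(ens, datoms, aatoms, frame = f, criterion = criterion)
      ind[f] <- as.numeric(nrow(hb) > 0)
    }
    be <- if (nf >= 16) blockError(ind)@plateau else NA_real_
    data.frame(donorRes = don, acceptorRes = acc, occupancy = mean(ind),
               blockError = be)
  })
  do.call(rbind, res)
}
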
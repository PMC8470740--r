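# Sequence parsing and charge-patterning metrics (FCR, NCPR, kappa) with
# phosphorylated residues equalized to negatively charged residues.

#' Parse an annotated peptide sequence
#'
#' Accepts a plain one-letter string, a single-record FASTA string, or a path
#' to either. Residue charges are assigned for a fixed physiological-pH state:
#' Asp/Glu -1, Lys/Arg +1, His 0, and phosphorylated Ser/Thr -2.
#'
#' @param text sequence text (or path to a file containing it).
#' @param phosphosites integer vector of 1-based phosphorylated positions;
#'   must be Ser or Thr positions.
#' @param includeTermini logical; record terminal charges (+1 N-terminus,
#'   -1 C-terminus) for consumers that use them.
#' @return An [AnnotatedSequence-class].
#' @export
parseSequence <- function(text, phosphosites = integer(0),
                          includeTermini = TRUE) {
  if (length(text) == 1 && !grepl("[\n>]", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^>", lines)]
  s <- toupper(gsub("[[:space:]]", "", paste(lines, collapse = "")))
  if (!nchar(s)) stop("empty sequence")
  res <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(res), AA_CODES)
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  phosphosites <- as.integer(phosphosites)
  if (length(phosphosites)) {
    if (any(phosphosites < 1 | phosphosites > length(res)))
      stop("phosphosite position out of range")
    notST <- phosphosites[!res[phosphosites] %in% c("S", "T")]
    if (length(notST))
      stop("phosphosite(s) not Ser/Thr: position ",
           paste(notST, collapse = ", "))
  }
  ch <- numeric(length(res))
  ch[res %in% c("D", "E")] <- -1
  ch[res %in% c("K", "R")] <- 1
  ch[phosphosites] <- -2
  new("AnnotatedSequence", residues = res, phosphosites = phosphosites,
      charges = ch, includeTermini = includeTermini)
}

# Signed charge pattern used by FCR/NCPR/kappa: phospho residues count as one
# negative charge (sign convention), not -2.
patterningSigns <- function(seq) {
  ch <- residueCharges(seq)
  sign(ch)
}

#' Charge composition of a sequence
#'
#' FCR is the fraction of residues carrying a nonzero charge and NCPR the net
#' charge per residue, both under the sign convention in which a
#' phosphorylated residue counts as one negatively charged residue.
#'
#' @param seq an [AnnotatedSequence-class].
#' @return Named numeric vector with elements `FCR` and `NCPR`.
#' @export
chargeFractions <- function(seq) {
  s <- patterningSigns(seq)
  c(FCR = mean(s != 0), NCPR = mean(s))
}

# sigma of a window or of the whole sequence: (f+ - f-)^2 / (f+ + f-),
# defined as 0 when the window carries no charge.
sigmaPattern <- function(fplus, fminus) {
  tot <- fplus + fminus
  ifelse(tot == 0, 0, (fplus - fminus)^2 / tot)
}

# delta for one blob size: mean over all stride-1 windows fully inside the
# sequence of (sigma_window - sigma_sequence)^2.
deltaBlob <- function(signs, g) {
  n <- length(signs)
  if (n < g) stop("sequence shorter than blob size ", g)
  cp <- cumsum(c(0, signs == 1))
  cm <- cumsum(c(0, signs == -1))
  i <- seq_len(n - g + 1)
  fp <- (cp[i + g] - cp[i]) / g
  fm <- (cm[i + g] - cm[i]) / g
  sseq <- sigmaPattern(sum(signs == 1) / n, sum(signs == -1) / n)
  mean((sigmaPattern(fp, fm) - sseq)^2)
}

chargeDelta <- function(signs, blobs = c(5, 6)) {
  mean(vapply(blobs, function(g) deltaBlob(signs, g), numeric(1)))
}

# Most-segregated (block) arrangements of a composition: a + block and a -
# block with the neutral residues split between front, middle and end in all
# possible ways. Returns the maximal delta over the family.
deltaMaxSegregated <- function(nPlus, nMinus, nZero, blobs = c(5, 6)) {
  best <- -Inf
  for (k1 in 0:nZero) {
    for (k2 in 0:(nZero - k1)) {
      s <- c(rep(0, k1), rep(1, nPlus), rep(0, k2), rep(-1, nMinus),
             rep(0, nZero - k1 - k2))
      best <- max(best, chargeDelta(s, blobs))
    }
  }
  best
}

#' Charge-patterning parameter kappa
#'
#' Das-Pappu style charge segregation: the blob-averaged variance `delta` of
#' the local charge asymmetry (blob sizes 5 and 6, stride 1, windows fully
#' inside the sequence), normalised by `delta_max` of the most segregated
#' block arrangement of the same composition (all splits of the neutral
#' residues around a positive and a negative block are considered). Values
#' are clipped to `[0, 1]`. Phosphorylated residues are equalized to
#' negatively charged residues (sign -1).
#'
#' @param seq an [AnnotatedSequence-class].
#' @param blobs blob (window) sizes, default `c(5, 6)`.
#' @return kappa in `[0, 1]`.
#' @export
kappaCharge <- function(seq, blobs = c(5, 6)) {
  s <- patterningSigns(seq)
  if (!any(s > 0) || !any(s < 0))
    stop("kappa undefined: sequence needs at least one positive and one negative residue")
  if (length(s) < max(blobs))
    stop("kappa undefined: sequence shorter than the largest blob")
  dmax <- deltaMaxSegregated(sum(s > 0), sum(s < 0), sum(s == 0), blobs)
  if (dmax <= 0) stop("kappa undefined: degenerate composition")
  min(1, max(0, chargeDelta(s, blobs) / dmax))
}

#' All charge-patterning metrics of a sequence
#'
#' @param seq an [AnnotatedSequence-class].
#' @param blobs blob sizes for kappa.
#' @return List with `FCR`, `NCPR`, `kappa` (NA when undefined) and `blobs`.
#' @export
chargePattern <- function(seq, blobs = c(5, 6)) {
  cf <- chargeFractions(seq)
  kap <- tryCatch(kappaCharge(seq, blobs), error = function(e) NA_real_)
  list(FCR = unname(cf["FCR"]), NCPR = unname(cf["NCPR"]),
       kappa = kap, blobs = blobs)
}
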
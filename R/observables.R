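# Global size observables and statistics for correlated per-frame series:
# radius of gyration, end-to-end distance, autocorrelation, Flyvbjerg-
# Petersen block-averaging errors, density histograms, and the percentage
# difference utility used for force-field comparison tables.

#' Radius of gyration per frame
#'
#' Mass-weighted Rg: `sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i )` with the
#' mass-weighted centroid `r_com`, evaluated per frame over the selected
#' atoms.
#'
#' @param ens an [Ensemble-class].
#' @param selection atom indices (default: all atoms).
#' @return Numeric vector, one value (nm) per frame.
#' @export
radiusOfGyration <- function(ens, selection = NULL) {
  X <- coords(ens)
  if (is.null(selection)) selection <- seq_len(dim(X)[2])
  if (!length(selection)) stop("selection is empty")
  m <- topology(ens)$mass[selection]
  M <- sum(m)
  if (M <= 0) stop("total mass must be positive")
  nf <- dim(X)[1]
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    P <- X[f, selection, , drop = TRUE]
    if (length(selection) == 1L) P <- matrix(P, 1L, 3L)
    com <- colSums(P * m) / M
    out[f] <- sqrt(sum(m * rowSums(sweep(P, 2, com)^2)) / M)
  }
  out
}

#' End-to-end distance per frame
#'
#' Distance between the chain's terminal anchor atoms. The default convention
#' is backbone N of the first residue to backbone C of the last; the
#' alternative is CA to CA. The convention in use is attached as attribute
#' `"convention"` since different trajectory tools differ here.
#'
#' @param ens an [Ensemble-class].
#' @param convention `"nc"` (N-first to C-last) or `"caca"`.
#' @return Numeric vector, one value (nm) per frame.
#' @export
endToEnd <- function(ens, convention = c("nc", "caca")) {
  convention <- match.arg(convention)
  topo <- topology(ens)
  res <- range(topo$resid)
  if (diff(res) < 1) stop("chain must have >= 2 residues")
  anchors <- if (convention == "nc") c("N", "C") else c("CA", "CA")
  i1 <- atomIndex(topo, res[1], anchors[1])
  i2 <- atomIndex(topo, res[2], anchors[2])
  if (is.na(i1) || is.na(i2))
    stop("anchor atom ", anchors[1], "/", anchors[2],
         " missing for convention '", convention, "'")
  X <- coords(ens)
  out <- sqrt((X[, i1, 1] - X[, i2, 1])^2 + (X[, i1, 2] - X[, i2, 2])^2 +
              (X[, i1, 3] - X[, i2, 3])^2)
  attr(out, "convention") <- convention
  out
}

#' Block-averaging error estimate
#'
#' Flyvbjerg-Petersen blocking: the series is repeatedly coarse-grained by
#' averaging pairs of neighbouring blocks; each level reports the naive
#' standard error of the block means. The plateau estimate is the first level
#' whose estimate has changed by less than 5% over two successive doublings;
#' if no such level exists the maximum-level estimate is returned with
#' `converged = FALSE`.
#'
#' @param x numeric series (length >= 16).
#' @return A [BlockErrorEstimate-class].
#' @export
blockError <- function(x) {
  n <- length(x)
  if (n < 16) stop("series too short for blocking analysis (need >= 16)")
  sizes <- integer(0)
  errs <- numeric(0)
  b <- 1L
  y <- x
  while (length(y) >= 4) {
    sizes <- c(sizes, b)
    errs <- c(errs, sd(y) / sqrt(length(y)))
    if (length(y) %% 2 == 1) y <- y[-length(y)]
    y <- (y[seq(1, length(y), by = 2)] + y[seq(2, length(y), by = 2)]) / 2
    b <- b * 2L
  }
  plateau <- NA_real_
  conv <- FALSE
  for (k in seq_along(errs)) {
    if (k < 3) next
    ref <- errs[k - 2:1]
    if (all(ref > 0) &&
        abs(errs[k - 1] - errs[k - 2]) / errs[k - 2] < 0.05 &&
        abs(errs[k] - errs[k - 1]) / errs[k - 1] < 0.05) {
      plateau <- errs[k]
      conv <- TRUE
      break
    }
    if (all(errs[(k - 2):k] == 0)) { plateau <- 0; conv <- TRUE; break }
  }
  if (!conv) plateau <- errs[length(errs)]
  new("BlockErrorEstimate", blockSizes = sizes, errors = errs,
      plateau = plateau, converged = conv)
}

#' Normalized autocorrelation and integrated correlation time
#'
#' ACF normalised to 1 at lag zero, plus the integrated correlation time
#' `spacing * (1 + 2 * sum ACF(t))` truncated at the first negative ACF
#' value.
#'
#' @param x numeric series (length >= 4).
#' @param spacing frame spacing (ps or frames), default 1.
#' @param lagMax maximum lag (default `length(x) - 1`, capped internally by
#'   `stats::acf`'s guidance when unset).
#' @return List with `lags`, `acf` and `tauInt`.
#' @export
seriesAutocorrelation <- function(x, spacing = 1, lagMax = NULL) {
  if (length(x) < 4) stop("series too short (need >= 4)")
  if (var(x) == 0) stop("autocorrelation undefined for zero-variance series")
  if (is.null(lagMax)) lagMax <- min(length(x) - 1, 10 * ceiling(sqrt(length(x))))
  a <- as.numeric(acf(x, lag.max = lagMax, plot = FALSE,
                      demean = TRUE)$acf)
  firstNeg <- which(a < 0)[1]
  upper <- if (is.na(firstNeg)) length(a) else firstNeg - 1L
  tau <- spacing * (1 + 2 * sum(a[seq_len(upper)][-1]))
  list(lags = spacing * (seq_along(a) - 1), acf = a, tauInt = tau)
}

#' Density-normalized histogram of a series
#'
#' Freedman-Diaconis bin widths by default; the returned densities integrate
#' to 1 over the binned range. A constant series yields a single occupied
#' bin.
#'
#' @param x numeric values.
#' @param breaks optional break points or count (passed to [graphics::hist]).
#' @return data.frame with `mid`, `density`, `width`; break points in
#'   attribute `"breaks"`.
#' @export
densityHistogram <- function(x, breaks = NULL) {
  if (!length(x)) stop("empty series")
  if (diff(range(x)) == 0) {
    w <- max(abs(x[1]) * 1e-3, 1e-6)
    out <- data.frame(mid = x[1], density = 1 / w, width = w)
    attr(out, "breaks") <- c(x[1] - w / 2, x[1] + w / 2)
    return(out)
  }
  if (is.null(breaks)) breaks <- "FD"
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  out <- data.frame(mid = h$mids, density = h$density,
                    width = diff(h$breaks))
  attr(out, "breaks") <- h$breaks
  out
}

#' Percentage difference relative to a reference value
#'
#' `100 * (reference - value) / reference`, rounded half-up to integers as in
#' published force-field comparison tables (e.g. the C36-vs-A99 size
#' reductions).
#'
#' @param reference reference value(s) (the denominator).
#' @param value compared value(s).
#' @param digits rounding digits; default 0 with half-up rounding.
#' @return Numeric percentage(s).
#' @export
percentDifference <- function(reference, value, digits = 0) {
  p <- 100 * (reference - value) / reference
  # round half away from zero, as printed tables do
  s <- 10^digits
  sign(p) * floor(abs(p) * s + 0.5) / s
}
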
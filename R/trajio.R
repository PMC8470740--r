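# Trajectory and curve I/O: multi-model PDB (always), DCD via bio3d when
# available, and whitespace-delimited 3-column scattering curves.
# Coordinates are stored in nm; PDB files are in Angstrom (converted on the
# fly); curve q units are declared in the header ('q_unit=nm^-1' or 'A^-1').

ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06)

#' Trajectory formats supported at runtime
#'
#' Multi-model PDB is always supported; DCD is available when the bio3d
#' package is installed.
#'
#' @return Character vector of format names.
#' @export
supportedTrajectoryFormats <- function() {
  c("pdb", if (requireNamespace("bio3d", quietly = TRUE)) "dcd")
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, standard fixed-width ATOM records,
#' coordinates converted from nm to Angstrom.
#'
#' @param ens an [Ensemble-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(ens, path) {
  topo <- topology(ens)
  X <- coords(ens)
  nf <- dim(X)[1]
  na <- dim(X)[2]
  nm <- topo$name
  # short names start in column 14, 4-character names fill 13-16
  nmfmt <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    A <- X[f, , , drop = TRUE] * 10
    if (na == 1L) A <- matrix(A, 1L, 3L)
    writeLines(sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(na) %% 100000L, nmfmt, "", topo$resname, "A", topo$resid, "",
      A[, 1], A[, 2], A[, 3], 1, 0, topo$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory into an Ensemble
#'
#' Multi-model PDB is parsed natively (fixed-width records, Angstrom to nm
#' conversion, atom order preserved). DCD files are read through bio3d when
#' installed and require `topologyPath` pointing to a PDB with the matching
#' atom list. Malformed records fail with the offending line number; frames
#' whose atom count differs from the first frame fail naming the frame, and
#' files truncated mid-frame are rejected.
#'
#' @param path trajectory file.
#' @param topologyPath optional PDB carrying the topology (required for DCD).
#' @param format `"auto"` (by extension), `"pdb"`, or `"dcd"`.
#' @return An [Ensemble-class].
#' @export
readTrajectory <- function(path, topologyPath = NULL,
                           format = c("auto", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  if (format == "dcd") {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("DCD support requires the bio3d package (see supportedTrajectoryFormats())")
    if (is.null(topologyPath))
      stop("DCD input requires topologyPath (a PDB with the atom list)")
    topo <- topology(readTrajectory(topologyPath, format = "pdb"))
    M <- bio3d::read.dcd(path, verbose = FALSE)
    nf <- nrow(M)
    na <- ncol(M) / 3
    if (na != nrow(topo))
      stop("DCD atom count does not match topology")
    X <- array(NA_real_, c(nf, na, 3))
    for (k in 1:3) X[, , k] <- M[, seq(k, by = 3, length.out = na)] / 10
    return(Ensemble(X, topo))
  }
  readPDBTrajectory(path)
}

readPDBTrajectory <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  isModel <- startsWith(rec, "MODEL")
  isEnd <- startsWith(rec, "ENDMDL")
  if (!any(isAtom)) stop("no ATOM records in ", path)

  # frame id per atom line: 1 if no MODEL records at all
  frameOf <- cumsum(isModel)
  if (!any(isModel)) frameOf <- rep(1L, length(lines))
  if (any(isModel)) {
    open <- cumsum(isModel) - cumsum(isEnd)
    if (any(isAtom & open == 0L))
      stop("ATOM record outside MODEL/ENDMDL block at line ",
           which(isAtom & open == 0L)[1])
    if (tail(cumsum(isModel), 1) != tail(cumsum(isEnd), 1))
      stop("truncated trajectory: MODEL block without ENDMDL")
  }

  al <- which(isAtom)
  txt <- lines[al]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(txt, from, to)))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("parse error (", what, ") at line ", al[bad[1]], " of ", path)
    v
  }
  name <- trimws(substr(txt, 13, 16))
  resname <- trimws(substr(txt, 18, 20))
  resid <- as.integer(num(23, 26, "residue number"))
  x <- num(31, 38, "x"); y <- num(39, 46, "y"); z <- num(47, 54, "z")
  element <- trimws(substr(txt, 77, 78))
  element[element == ""] <- substr(name[element == ""], 1, 1)

  fr <- frameOf[al]
  frIds <- unique(fr)
  counts <- tabulate(match(fr, frIds))
  if (length(unique(counts)) != 1)
    stop("structure error: frame ", frIds[which(counts != counts[1])[1]],
         " has ", counts[which(counts != counts[1])[1]],
         " atoms, expected ", counts[1])
  na <- counts[1]
  nf <- length(frIds)
  first <- fr == frIds[1]
  mass <- unname(ELEMENT_MASSES[element[first]])
  mass[is.na(mass)] <- 12.011
  topo <- data.frame(name = name[first], element = element[first],
                     mass = mass, resid = resid[first],
                     resname = resname[first], stringsAsFactors = FALSE)
  X <- array(NA_real_, c(nf, na, 3))
  X[, , 1] <- matrix(x, nf, na, byrow = TRUE) / 10
  X[, , 2] <- matrix(y, nf, na, byrow = TRUE) / 10
  X[, , 3] <- matrix(z, nf, na, byrow = TRUE) / 10
  Ensemble(X, topo)
}

#' Write a scattering curve as 3-column text
#'
#' Whitespace-delimited `q I sigma` (sigma column omitted when absent) with a
#' comment header declaring the q unit.
#'
#' @param curve a [ScatteringCurve-class].
#' @param path output file.
#' @param qUnit `"nm^-1"` (as stored) or `"A^-1"` (values divided by 10 on
#'   output).
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path, qUnit = c("nm^-1", "A^-1")) {
  qUnit <- match.arg(qUnit)
  q <- qValues(curve)
  if (qUnit == "A^-1") q <- q / 10
  sig <- intensityErrors(curve)
  M <- if (length(sig)) cbind(q, intensities(curve), sig)
       else cbind(q, intensities(curve))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# q I%s q_unit=%s", if (length(sig)) " sigma" else "",
                     qUnit), con)
  write.table(format(M, digits = 17, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scattering curve from 3-column text
#'
#' Accepts 2 or 3 whitespace-delimited columns (`q I [sigma]`) with `#`
#' comment lines; a header token `q_unit=nm^-1` or `q_unit=A^-1` declares the
#' unit (inverse Angstrom values are multiplied by 10 into nm^-1; nm^-1 is
#' assumed when no token is present). Non-monotone q or ragged rows are
#' rejected.
#'
#' @param path input file.
#' @return A [ScatteringCurve-class].
#' @export
readCurve <- function(path) {
  lines <- readLines(path)
  comments <- lines[startsWith(trimws(lines), "#")]
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  parts <- strsplit(trimws(body), "[[:space:]]+")
  ncols <- unique(lengths(parts))
  if (length(ncols) != 1)
    stop("format error: ragged rows in ", path)
  if (!ncols %in% 2:3)
    stop("format error: expected 2 or 3 columns, found ", ncols)
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) stop("format error: non-numeric field in ", path)
  M <- matrix(vals, ncol = ncols, byrow = TRUE)
  q <- M[, 1]
  unitTok <- regmatches(comments, regexpr("q_unit=[^[:space:]]+", comments))
  unitTok <- unlist(unitTok)
  if (length(unitTok) && grepl("A\\^-1", unitTok[1])) q <- q * 10
  if (any(diff(q) <= 0)) stop("format error: q must be strictly increasing")
  ScatteringCurve(q, M[, 2], if (ncols == 3) M[, 3] else numeric(0))
}
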
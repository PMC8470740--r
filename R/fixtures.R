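# Bundled peptide fixtures: the four phosphopeptides (two tau fragments, the
# beta-casein 1-25 phosphopeptide, statherin) with phosphosite configuration
# and published size-reference values.

#' Bundled peptide sequences with phosphosite annotations
#'
#' Reads the FASTA and phosphosite configuration shipped under `extdata` and
#' returns parsed, annotated sequences for Tau1, Tau2, bCPP and Stath.
#'
#' @return Named list of [AnnotatedSequence-class] objects.
#' @export
peptideFixtures <- function() {
  fa <- system.file("extdata", "peptides.fasta", package = "idpens",
                    mustWork = TRUE)
  ps <- system.file("extdata", "phosphosites.tsv", package = "idpens",
                    mustWork = TRUE)
  lines <- readLines(fa)
  hdr <- grep("^>", lines)
  names <- sub("^>([^ ]+).*", "\\1", lines[hdr])
  seqs <- vapply(seq_along(hdr), function(k) {
    to <- if (k < length(hdr)) hdr[k + 1] - 1 else length(lines)
    paste(lines[(hdr[k] + 1):to], collapse = "")
  }, character(1))
  sites <- read.table(ps, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
  out <- lapply(seq_along(names), function(k) {
    s <- sites$sites[sites$peptide == names[k]]
    pos <- if (length(s)) as.integer(strsplit(s, ",")[[1]]) else integer(0)
    parseSequence(seqs[k], phosphosites = pos)
  })
  names(out) <- names
  out
}

#' Published size-reference table for the bundled peptides
#'
#' Ensemble-average Rg and Ree (nm) for the four peptides under the A99
#' (Amber ff99SB-ILDN+TIP4P-D) and C36 (CHARMM36m) force fields, with
#' block-averaging errors and experimental references where available
#' (SAXS Rg for Stath, FRET Ree for Tau1). Used with [percentDifference()]
#' for force-field comparison worked examples.
#'
#' @return data.frame with columns `peptide`, `observable`, `a99_mean`,
#'   `a99_err`, `c36_mean`, `c36_err`, `exp_mean`, `exp_err`.
#' @export
sizeReferenceTable <- function() {
  f <- system.file("extdata", "size_reference.tsv", package = "idpens",
                   mustWork = TRUE)
  read.table(f, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}
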
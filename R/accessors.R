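# Accessor generics and show methods for the core classes.

#' @describeIn Ensemble-class coordinate array (`frames x atoms x 3`, nm)
#' @param object an object of the documented class
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @export
setMethod("coords", "Ensemble", function(object) object@coords)

#' @describeIn Ensemble-class per-atom topology data.frame
#' @export
setGeneric("topology", function(object) standardGeneric("topology"))
#' @export
setMethod("topology", "Ensemble", function(object) object@topology)

#' @describeIn Ensemble-class number of frames
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @export
setMethod("nFrames", "Ensemble", function(object) dim(object@coords)[1])

#' @describeIn Ensemble-class number of atoms
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))
#' @export
setMethod("nAtoms", "Ensemble", function(object) dim(object@coords)[2])

#' @describeIn Ensemble-class number of residues
#' @export
setGeneric("nResidues", function(object) standardGeneric("nResidues"))
#' @export
setMethod("nResidues", "Ensemble",
          function(object) length(unique(object@topology$resid)))
#' @export
setMethod("nResidues", "AnnotatedSequence",
          function(object) length(object@residues))

#' @describeIn Ensemble-class frame times (ps), possibly empty
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @export
setMethod("frameTimes", "Ensemble", function(object) object@times)

#' Extract frames from an ensemble
#'
#' @param x an [Ensemble-class]
#' @param i frame indices
#' @param j,...,drop ignored
#' @return An [Ensemble-class] with the selected frames.
#' @export
setMethod("[", "Ensemble", function(x, i, j, ..., drop = FALSE) {
  Ensemble(x@coords[i, , , drop = FALSE], x@topology,
           if (length(x@times)) x@times[i] else numeric(0))
})

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble:", dim(object@coords)[1], "frames,",
      dim(object@coords)[2], "atoms,",
      length(unique(object@topology$resid)), "residues\n")
})

#' @describeIn AnnotatedSequence-class one-letter residue codes
#' @param object an object of the documented class
#' @export
setGeneric("residues", function(object) standardGeneric("residues"))
#' @export
setMethod("residues", "AnnotatedSequence", function(object) object@residues)

#' @describeIn AnnotatedSequence-class phosphorylated positions (1-based)
#' @export
setGeneric("phosphosites", function(object) standardGeneric("phosphosites"))
#' @export
setMethod("phosphosites", "AnnotatedSequence",
          function(object) object@phosphosites)

#' @describeIn AnnotatedSequence-class per-residue charges (e) at the fixed
#'   pH state (phospho Ser/Thr carry -2)
#' @export
setGeneric("residueCharges", function(object) standardGeneric("residueCharges"))
#' @export
setMethod("residueCharges", "AnnotatedSequence", function(object) object@charges)

setMethod("show", "AnnotatedSequence", function(object) {
  s <- paste(object@residues, collapse = "")
  cat("AnnotatedSequence (", length(object@residues), " residues)\n", sep = "")
  cat(" ", s, "\n")
  if (length(object@phosphosites))
    cat("  phosphosites:", paste(object@phosphosites, collapse = ", "), "\n")
})

#' @describeIn ScatteringCurve-class momentum-transfer grid (nm^-1)
#' @param object an object of the documented class
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @export
setMethod("qValues", "ScatteringCurve", function(object) object@q)

#' @describeIn ScatteringCurve-class intensities
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @export
setMethod("intensities", "ScatteringCurve", function(object) object@I)

#' @describeIn ScatteringCurve-class per-point errors (may be empty)
#' @export
setGeneric("intensityErrors",
           function(object) standardGeneric("intensityErrors"))
#' @export
setMethod("intensityErrors", "ScatteringCurve", function(object) object@sigma)

setMethod("show", "ScatteringCurve", function(object) {
  cat("ScatteringCurve:", length(object@q), "points, q in [",
      signif(min(object@q), 4), ",", signif(max(object@q), 4), "] nm^-1,",
      if (length(object@sigma)) "with" else "without", "errors\n")
})

#' @describeIn SSMatrix-class per-frame, per-residue code matrix
#' @param object an object of the documented class
#' @export
setGeneric("ssCodes", function(object) standardGeneric("ssCodes"))
#' @export
setMethod("ssCodes", "SSMatrix", function(object) object@codes)

setMethod("show", "SSMatrix", function(object) {
  cat("SSMatrix:", nrow(object@codes), "frames x", ncol(object@codes),
      "residues\n")
  tab <- table(factor(object@codes, levels = SS_CODES))
  frac <- round(as.numeric(tab) / sum(tab), 3)
  cat(" ", paste(SS_CODES, frac, sep = ":", collapse = "  "), "\n")
})

#' @describeIn PCABasis-class per-component variance fractions
#' @param object an object of the documented class
#' @export
setGeneric("varianceFractions",
           function(object) standardGeneric("varianceFractions"))
#' @export
setMethod("varianceFractions", "PCABasis", function(object) object@varFractions)

setMethod("show", "PCABasis", function(object) {
  vf <- object@varFractions
  cat("PCABasis:", ncol(object@rotation), "components over",
      length(object@center), "coordinates\n")
  cat("  PC1/PC2 variance fractions:",
      paste(round(head(vf, 2), 3), collapse = ", "),
      sprintf("(first two: %.1f%%)", 100 * sum(head(vf, 2))), "\n")
})

#' @describeIn FreeEnergyLandscape-class free-energy grid (RT); `NA` = masked
#' @param object an object of the documented class
#' @export
setGeneric("energyGrid", function(object) standardGeneric("energyGrid"))
#' @export
setMethod("energyGrid", "FreeEnergyLandscape", function(object) object@energy)

#' @describeIn FreeEnergyLandscape-class basin label per cell
#' @export
setGeneric("basinLabels", function(object) standardGeneric("basinLabels"))
#' @export
setMethod("basinLabels", "FreeEnergyLandscape", function(object) object@basins)

#' @describeIn FreeEnergyLandscape-class data.frame of basin minima
#' @export
setGeneric("basinMinima", function(object) standardGeneric("basinMinima"))
#' @export
setMethod("basinMinima", "FreeEnergyLandscape", function(object) object@minima)

setMethod("show", "FreeEnergyLandscape", function(object) {
  nb <- if (nrow(object@minima)) nrow(object@minima) else NA_integer_
  cat("FreeEnergyLandscape:", length(object@pc1), "x", length(object@pc2),
      "grid, cap", object@capRT, "RT,",
      sum(!is.na(object@energy)), "unmasked cells")
  if (!is.na(nb)) cat(",", nb, "basins")
  cat("\n")
})

setMethod("show", "Chi2FitResult", function(object) {
  cat(sprintf("Chi2FitResult: f = %.6g, c = %.6g, chi2 = %.6g (%s, %d points)\n",
              object@f, object@c, object@chi2, object@norm, object@nPoints))
})

setMethod("show", "BlockErrorEstimate", function(object) {
  cat(sprintf("BlockErrorEstimate: plateau %.4g (%s), %d levels\n",
              object@plateau,
              if (object@converged) "converged" else "not converged",
              length(object@blockSizes)))
})

#' @describeIn ContactMap-class contact probability matrix
#' @param object an object of the documented class
#' @export
setGeneric("contactProbabilities",
           function(object) standardGeneric("contactProbabilities"))
#' @export
setMethod("contactProbabilities", "ContactMap",
          function(object) object@probabilities)

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap:", nrow(object@probabilities), "residues, cutoff",
      object@cutoff, "nm\n")
})
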
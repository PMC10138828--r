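#' Number of frames in a session
#' @param x an [MDSession-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "MDSession", function(x) x@nFrames)

#' Residue counts per molecule
#' @param x an [MDSession-class], [SystemFrame-class] or other object
#'   carrying per-molecule lengths.
#' @return integer vector.
#' @export
setGeneric("molLengths", function(x) standardGeneric("molLengths"))

#' @rdname molLengths
#' @export
setMethod("molLengths", "MDSession", function(x) x@molLengths)

#' @rdname molLengths
#' @export
setMethod("molLengths", "SystemFrame", function(x) x@molLengths)

#' @rdname molLengths
#' @export
setMethod("molLengths", "ContactMap", function(x) x@molLengths)

#' Per-molecule coordinates of a frame
#' @param x a [SystemFrame-class].
#' @return list of n x 3 coordinate matrices (Angstrom).
#' @export
setGeneric("frameCoords", function(x) standardGeneric("frameCoords"))

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "SystemFrame", function(x) x@coords)

#' Binary contact matrix of a contact map
#' @param x a [ContactMap-class].
#' @return binary matrix.
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))

#' @rdname contactMatrix
#' @export
setMethod("contactMatrix", "ContactMap", function(x) x@contacts)

#' Criterion that produced a contact map
#' @param x a [ContactMap-class].
#' @return the [ContactCriterion-class].
#' @export
setGeneric("criterion", function(x) standardGeneric("criterion"))

#' @rdname criterion
#' @export
setMethod("criterion", "ContactMap", function(x) x@criterion)

#' Kernel label table of a library
#' @param x a [KernelLibrary-class].
#' @return data.frame with columns `k`, `orientation`, `class`, `shift`,
#'   `nnz`.
#' @export
setGeneric("kernelLabels", function(x) standardGeneric("kernelLabels"))

#' @rdname kernelLabels
#' @export
setMethod("kernelLabels", "KernelLibrary", function(x) x@labels)

#' Edge table of a contact graph
#' @param x a [ContactGraph-class].
#' @return data.frame of edges.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname graphEdges
#' @export
setMethod("graphEdges", "ContactGraph", function(x) x@edges)

#' Connected components of a contact graph
#' @param x a [ContactGraph-class].
#' @return list of integer vectors of 1-based molecule indices.
#' @export
setGeneric("graphClusters", function(x) standardGeneric("graphClusters"))

#' @rdname graphClusters
#' @export
setMethod("graphClusters", "ContactGraph", function(x) x@clusters)

setMethod("show", "MDSession", function(object) {
  cat("MDSession:", basename(object@configPath),
      if (!is.na(object@trajPath)) paste0("+ ", basename(object@trajPath)),
      "\n")
  cat(" ", length(object@molLengths), "molecule(s),",
      sum(object@molLengths), "selected point(s),",
      object@nFrames, "frame(s)\n")
  cat("  selection:", paste(object@selection, collapse = ", "), "\n")
})

setMethod("show", "SystemSummary", function(object) {
  cat("SystemSummary:", length(object@peptideLengthList), "molecule(s)\n")
  for (len in names(object@lenDict))
    cat(sprintf("  %s molecule(s) of %s residue(s)\n",
                object@lenDict[[len]], len))
})

setMethod("show", "SystemFrame", function(object) {
  cat("SystemFrame", object@frameIndex, "-", length(object@coords),
      "molecule(s), lengths:", paste(object@molLengths, collapse = " "), "\n")
})

setMethod("show", "ContactCriterion", function(object) {
  if (object@kind == "beta")
    cat(sprintf("beta contact criterion: d <= %.2f A, minSep %d\n",
                object@dHigh, object@minSep))
  else
    cat(sprintf("alpha contact criterion: %.2f <= d <= %.2f A, minSep %d\n",
                object@dLow, object@dHigh, object@minSep))
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap over", nrow(object@contacts), "points (",
      length(object@molLengths), "molecules ):",
      sum(object@contacts) / 2, "contact pair(s)\n")
  show(object@criterion)
})

setMethod("show", "KernelLibrary", function(object) {
  cat(sprintf("KernelLibrary: RES = %d, %d kernels (P+/P-/A+/A- x shifts 0..%d)\n",
              object@res, dim(object@L)[3], object@res - 1L))
})

setMethod("show", "AlignmentMatrix", function(object) {
  n <- sum(object@P[upper.tri(object@P)] != 0L)
  cat(sprintf("AlignmentMatrix: %d molecules, %d classified pair(s) (minContact %d, %s NCC)\n",
              nrow(object@P), n, object@minContact, object@normalization))
})

setMethod("show", "ContactGraph", function(object) {
  cat(sprintf("ContactGraph: %d node(s), %d edge(s), %d cluster(s)\n",
              object@nMol, nrow(object@edges), length(object@clusters)))
})

setMethod("show", "BetaSheetDomains", function(object) {
  cat(sprintf("BetaSheetDomains: %d strand pair(s), %d triplet(s) over %d molecule(s)\n",
              nrow(object@pairs), nrow(object@triplets), object@nMol))
})

setMethod("show", "StructuralTimeSeries", function(object) {
  cat(sprintf("StructuralTimeSeries: %d frame(s) x %d molecule(s)\n",
              length(object@frames), ncol(object@alpha)))
  if (length(object@frames)) {
    cat(sprintf("  mean alpha-helix content: %.2f%%\n", mean(object@alpha)))
    cat(sprintf("  mean beta-turn content:   %.2f%%\n", mean(object@betaTurn)))
  }
})
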
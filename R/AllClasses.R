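#' @import methods
NULL

#' Distance criterion used to binarize a distance map
#'
#' A `ContactCriterion` holds the geometric rule that turns inter-residue
#' distances into binary contacts. Two kinds exist: `"beta"` marks a contact
#' when the distance falls at or below a single threshold (`dHigh`), the
#' cross-beta inter-strand spacing regime; `"alpha"` marks a contact when the
#' distance falls inside a closed band `[dLow, dHigh]`, the regime of
#' (i, i+4) backbone distances in an alpha-helix. Alpha contacts are only
#' evaluated within one molecule and only for residue pairs separated by at
#' least `minSep` positions along the chain.
#'
#' @slot kind character, `"beta"` or `"alpha"`.
#' @slot dLow numeric, lower edge of the band in Angstrom (0 for beta).
#' @slot dHigh numeric, threshold / upper band edge in Angstrom.
#' @slot minSep integer, minimum intra-molecular sequence separation.
#'
#' @seealso [betaCriterion()], [alphaCriterion()], [contactMap()]
#' @exportClass ContactCriterion
setClass("ContactCriterion",
  slots = c(kind = "character", dLow = "numeric", dHigh = "numeric",
            minSep = "integer"),
  validity = function(object) {
    if (!object@kind %in% c("beta", "alpha"))
      return("kind must be 'beta' or 'alpha'")
    if (object@dHigh <= 0) return("dHigh must be positive")
    if (object@kind == "alpha" &&
        !(object@dLow > 0 && object@dLow < object@dHigh))
      return("alpha band requires 0 < dLow < dHigh")
    if (object@minSep < 0L) return("minSep must be >= 0")
    TRUE
  })

#' Per-molecule backbone coordinates for one trajectory frame
#'
#' @slot frameIndex integer, 0-based index of the frame in the trajectory.
#' @slot coords list of numeric matrices, one per molecule; each matrix has
#'   one row per residue (ordered by residue index) and columns x, y, z in
#'   Angstrom.
#' @slot molLengths integer vector of residue counts per molecule.
#'
#' @exportClass SystemFrame
setClass("SystemFrame",
  slots = c(frameIndex = "integer", coords = "list", molLengths = "integer"),
  validity = function(object) {
    if (object@frameIndex < 0L) return("frameIndex must be >= 0")
    if (length(object@coords) != length(object@molLengths))
      return("coords and molLengths disagree on molecule count")
    for (m in seq_along(object@coords)) {
      xyz <- object@coords[[m]]
      if (!is.matrix(xyz) || ncol(xyz) != 3L)
        return(sprintf("molecule %d: coordinates must be an n x 3 matrix", m))
      if (nrow(xyz) != object@molLengths[m])
        return(sprintf("molecule %d: %d rows but molLengths says %d",
                       m, nrow(xyz), object@molLengths[m]))
      if (any(!is.finite(xyz)))
        return(sprintf("molecule %d has non-finite coordinates", m))
    }
    TRUE
  })

#' A loaded MD system plus optional trajectory
#'
#' Created by [loadSession()]. Coordinates are reduced to one point per
#' residue (the centroid of the selected atoms, a single bead under the
#' MARTINI "BB" selection) and stored per frame in Angstrom.
#'
#' @slot configPath path of the structure file the session was built from.
#' @slot trajPath path of the trajectory file, or `NA` for a static system.
#' @slot selection character vector of selected atom names.
#' @slot nFrames integer number of frames (1 for a static structure).
#' @slot frames list of per-frame coordinate lists (one n x 3 matrix per
#'   molecule).
#' @slot molLengths integer residue counts per molecule.
#' @slot sequences list of per-molecule residue-name vectors.
#'
#' @exportClass MDSession
setClass("MDSession",
  slots = c(configPath = "character", trajPath = "character",
            selection = "character", nFrames = "integer",
            frames = "list", molLengths = "integer", sequences = "list"),
  validity = function(object) {
    if (object@nFrames < 1L) return("nFrames must be >= 1")
    if (length(object@frames) != object@nFrames)
      return("frames list length must equal nFrames")
    if (sum(object@molLengths) < 1L)
      return("selection resolves to zero points")
    TRUE
  })

#' System composition summary
#'
#' @slot peptideLengthList integer residue counts, one entry per molecule.
#' @slot lenDict named integer vector mapping residue count to the number
#'   of molecules with that length.
#' @slot sequences list of per-molecule residue-name vectors.
#'
#' @exportClass SystemSummary
setClass("SystemSummary",
  slots = c(peptideLengthList = "integer", lenDict = "integer",
            sequences = "list"),
  validity = function(object) {
    if (sum(object@lenDict) != length(object@peptideLengthList))
      return("lenDict counts must sum to the number of molecules")
    if (!all(as.character(object@peptideLengthList) %in% names(object@lenDict)))
      return("every peptide length must appear as a lenDict key")
    TRUE
  })

#' Pairwise distance map over all selected points of a frame
#'
#' Flat symmetric matrix of Euclidean distances (Angstrom) over the points
#' of every molecule, concatenated in molecule order.
#'
#' @slot D numeric symmetric matrix of distances.
#' @slot offsets integer, 0-based start offset of each molecule's block.
#' @slot molLengths integer residue counts per molecule.
#'
#' @exportClass DistanceMap
setClass("DistanceMap",
  slots = c(D = "matrix", offsets = "integer", molLengths = "integer"),
  validity = function(object) {
    if (nrow(object@D) != ncol(object@D)) return("D must be square")
    if (nrow(object@D) != sum(object@molLengths))
      return("D dimension must equal the total point count")
    if (any(object@D < 0)) return("distances must be >= 0")
    if (any(abs(diag(object@D)) > 1e-9)) return("diagonal must be zero")
    TRUE
  })

#' Binary contact map
#'
#' Symmetric 0/1 matrix with the same indexing as the [DistanceMap-class]
#' it was derived from, together with the criterion that produced it. The
#' originating distances are retained so contact lists can be exported with
#' their distances.
#'
#' @slot contacts binary symmetric matrix.
#' @slot D the distance matrix the map was thresholded from.
#' @slot offsets integer 0-based molecule block offsets.
#' @slot molLengths integer residue counts per molecule.
#' @slot criterion the [ContactCriterion-class] applied.
#'
#' @exportClass ContactMap
setClass("ContactMap",
  slots = c(contacts = "matrix", D = "matrix", offsets = "integer",
            molLengths = "integer", criterion = "ContactCriterion"),
  validity = function(object) {
    if (!all(object@contacts %in% c(0, 1))) return("C must be binary")
    if (any(diag(object@contacts) != 0)) return("self-contacts are excluded")
    if (!isTRUE(all.equal(object@contacts, t(object@contacts)))) return("C must be symmetric")
    TRUE
  })

#' Library of binary shift matrices for strand-pair arrangements
#'
#' The stack of `4 * RES` binary `RES x RES` templates enumerating every
#' parallel-positive, parallel-negative, antiparallel-positive and
#' antiparallel-negative register shift between two equal-length strands.
#' Kernel indices `k` run 0-based over `[0, 4 RES)` in that family order.
#'
#' @slot res integer residue count the kernels are built for.
#' @slot L numeric array of dimension `RES x RES x 4 RES`.
#' @slot labels data.frame with columns `k`, `orientation` (one of
#'   `"P+", "P-", "A+", "A-"`), `class` (reporting class `"P"`, `"AP+"`,
#'   `"AP-"`), `shift`, `nnz`.
#'
#' @seealso [kernelLibrary()]
#' @exportClass KernelLibrary
setClass("KernelLibrary",
  slots = c(res = "integer", L = "array", labels = "data.frame"),
  validity = function(object) {
    d <- dim(object@L)
    if (length(d) != 3L || d[1] != object@res || d[2] != object@res ||
        d[3] != 4L * object@res)
      return("L must be RES x RES x 4*RES")
    if (nrow(object@labels) != 4L * object@res)
      return("labels must have one row per kernel")
    TRUE
  })

#' Molecular alignment matrix
#'
#' Square matrix over molecule pairs holding, for every pair whose
#' inter-molecular contact block carries at least `minContact` contacts, the
#' index of the kernel that maximizes the normalized cross-correlation with
#' the block. Entries are stored as `k + 1` with 0 meaning "no classified
#' interaction", so that the shift-0 parallel kernel (library index 0) is
#' not conflated with the absence of an interaction; [alignmentTable()]
#' reports the 0-based library indices.
#'
#' @slot P integer nmol x nmol matrix of winning kernel indices plus one
#'   (0 = none).
#' @slot res integer residue count.
#' @slot minContact integer contact-count threshold used.
#' @slot contactCounts integer nmol x nmol matrix of per-block contact
#'   counts.
#' @slot normalization character, `"geometric"` or `"product"` (see
#'   [alignmentMatrix()]).
#'
#' @exportClass AlignmentMatrix
setClass("AlignmentMatrix",
  slots = c(P = "matrix", res = "integer", minContact = "integer",
            contactCounts = "matrix", normalization = "character"),
  validity = function(object) {
    if (nrow(object@P) != ncol(object@P)) return("P must be square")
    if (any(diag(object@P) != 0L)) return("diagonal of P must be 0")
    if (any(object@P < 0L) || any(object@P > 4L * object@res))
      return("P entries must lie in [0, 4*RES]")
    TRUE
  })

#' Per-frame molecular interaction graph
#'
#' Undirected graph whose nodes are molecules and whose edges join pairs
#' classified by the alignment matrix, weighted by the number of contacts
#' in the pair's block. Clusters are the connected components.
#'
#' @slot nMol integer number of molecules (nodes).
#' @slot edges data.frame with columns `p`, `q` (1-based molecule indices,
#'   `p < q`), `nContacts`, `orientation` (`"P"`, `"AP+"`, `"AP-"`),
#'   `shift`.
#' @slot clusters list of integer vectors partitioning the nodes.
#'
#' @exportClass ContactGraph
setClass("ContactGraph",
  slots = c(nMol = "integer", edges = "data.frame", clusters = "list"),
  validity = function(object) {
    got <- sort(unlist(object@clusters))
    if (!identical(got, seq_len(object@nMol)))
      return("clusters must partition the molecule indices")
    TRUE
  })

#' Beta-sheet domains over strand pairs and triplets
#'
#' @slot pairs data.frame of classified strand pairs: `p`, `q` (1-based,
#'   `p < q`), `orientation`, `shift`, `nContacts`, `runLength` (longest
#'   run of consecutive sheet residues along the pair).
#' @slot triplets data.frame of confirmed three-strand sheets: `p`, `q`,
#'   `s`, `projection` (dot product coupling the two pairs through the
#'   shared strand `q`).
#' @slot nMol integer number of molecules in the system.
#'
#' @exportClass BetaSheetDomains
setClass("BetaSheetDomains",
  slots = c(pairs = "data.frame", triplets = "data.frame", nMol = "integer"))

#' Time series of structural content over sampled frames
#'
#' @slot frames integer 0-based indices of the sampled frames.
#' @slot alpha numeric frames x molecules matrix of alpha-helix content
#'   (percent of residues).
#' @slot betaTurn numeric frames x molecules matrix of beta-turn content
#'   (percent).
#' @slot paceHelix numeric frames x molecules matrix of mean helix pace
#'   (NA where no alpha contact was seen).
#' @slot sheetFraction numeric per-frame fraction of peptides in beta
#'   sheets (empty until a beta analysis is attached).
#' @slot tallies data.frame of per-frame contact counts by orientation
#'   class (`frame`, `P`, `APplus`, `APminus`).
#' @slot shiftTable data.frame `frame`, `class`, `shift`, `count`.
#'
#' @exportClass StructuralTimeSeries
setClass("StructuralTimeSeries",
  slots = c(frames = "integer", alpha = "matrix", betaTurn = "matrix",
            paceHelix = "matrix", sheetFraction = "numeric",
            tallies = "data.frame", shiftTable = "data.frame"),
  validity = function(object) {
    nf <- length(object@frames)
    if (nrow(object@alpha) != nf || nrow(object@betaTurn) != nf)
      return("content matrices must have one row per frame")
    if (any(object@alpha < 0 | object@alpha > 100, na.rm = TRUE))
      return("alpha content must lie in [0, 100]")
    if (length(object@sheetFraction) &&
        any(object@sheetFraction < 0 | object@sheetFraction > 1))
      return("sheetFraction must lie in [0, 1]")
    TRUE
  })
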
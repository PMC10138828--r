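#' Identify alpha-helix and beta-turn contacts of one molecule
#'
#' Scans the intra-molecular alpha-criterion contacts of molecule `mol`
#' in row order (`i < j`, sequence separation at least 2): a contact with
#' `j - i` of 4 or 5 residues (more than 3 and less than 6, the helix
#' pace window) counts as an alpha-helix contact, any other as a
#' beta-turn contact. The running means of `j - i` (the helix pace and
#' the turn length) are updated incrementally as
#' `mean <- ((j - i) * (count - 1) + mean) / count`, seeded with the
#' first observation; for non-constant separations this recency-weighted
#' update differs from the plain arithmetic mean (see the package
#' vignette).
#'
#' @param cm an alpha-criterion [ContactMap-class].
#' @param mol 1-based molecule index.
#' @return list with elements `countAlpha`, `countBetaTurn`, `paceHelix`
#'   and `lengthBetaTurn` (NA when the respective count is 0),
#'   `alphaContacts` and `turnContacts` (two-column matrices of 1-based
#'   residue pairs), `helixResidues` and `turnResidues` (sorted unions of
#'   the inclusive residue spans covered by the contacts).
#' @export
alphaTurnAssignment <- function(cm, mol = 1L) {
  stopifnot(is(cm, "ContactMap"))
  if (mol < 1L || mol > length(cm@molLengths))
    stop("mol must be a molecule index in 1..", length(cm@molLengths))
  B <- .intraBlock(cm, mol)
  res <- nrow(B)
  countA <- 0L; countB <- 0L
  pace <- NA_real_; lenB <- NA_real_
  aList <- NULL; bList <- NULL
  for (i in seq_len(res)) {
    js <- which(B[i, ] != 0)
    for (j in js[js >= i + 2L]) {
      gap <- j - i
      if (gap %in% c(4L, 5L)) {
        countA <- countA + 1L
        pace <- if (countA == 1L) gap else
          (gap * (countA - 1L) + pace) / countA
        aList <- rbind(aList, c(i, j))
      } else {
        countB <- countB + 1L
        lenB <- if (countB == 1L) gap else
          (gap * (countB - 1L) + lenB) / countB
        bList <- rbind(bList, c(i, j))
      }
    }
  }
  span <- function(pairs) {
    if (is.null(pairs)) return(integer())
    sort(unique(unlist(lapply(seq_len(nrow(pairs)),
                              function(r) pairs[r, 1]:pairs[r, 2]))))
  }
  list(countAlpha = countA, countBetaTurn = countB,
       paceHelix = pace, lengthBetaTurn = lenB,
       alphaContacts = if (is.null(aList))
         matrix(integer(), 0, 2) else unname(aList),
       turnContacts = if (is.null(bList))
         matrix(integer(), 0, 2) else unname(bList),
       helixResidues = span(aList), turnResidues = span(bList))
}

#' Helix / turn content of an assignment
#'
#' The alpha-helix content of a molecule is the percentage of its
#' residues covered by the union of the inclusive `[i, j]` spans of its
#' alpha contacts; a single (i, i+4) contact on an 8-residue peptide
#' covers 5 residues, i.e. 62.5 percent. `turnContent()` is the
#' analogous percentage over beta-turn contact spans.
#'
#' @param assignment result of [alphaTurnAssignment()].
#' @param res residue count of the molecule.
#' @return percentage in `[0, 100]`.
#' @export
helixContent <- function(assignment, res) {
  stopifnot(res >= 1L)
  100 * length(assignment$helixResidues) / res
}

#' @rdname helixContent
#' @export
turnContent <- function(assignment, res) {
  stopifnot(res >= 1L)
  100 * length(assignment$turnResidues) / res
}

#' Reduced strand-pair vectors
#'
#' `strandRowVector()` reduces the contact block of strand pair `(p, q)`
#' to its column sums (one entry per residue of `q`);
#' `strandColVector()` reduces the block of pair `(q, s)` to its row sums
#' (one entry per residue of `q`). The dot product of the two
#' ([tripletProjection()]) is nonzero exactly when the shared strand `q`
#' couples both pairs on overlapping residues, confirming a three-strand
#' sheet.
#'
#' @param cm a beta-criterion [ContactMap-class].
#' @param p,q,s 1-based molecule indices.
#' @return numeric vector of length `RES`.
#' @export
strandRowVector <- function(cm, p, q) {
  colSums(moleculeBlock(cm, p, q))
}

#' @rdname strandRowVector
#' @export
strandColVector <- function(cm, q, s) {
  rowSums(moleculeBlock(cm, q, s))
}

#' @rdname strandRowVector
#' @param vr,vc reduced vectors of equal length.
#' @export
tripletProjection <- function(vr, vc) {
  if (length(vr) != length(vc))
    stop("reduced vectors must have equal length (", length(vr),
         " vs ", length(vc), ")")
  sum(vr * vc)
}

#' Identify beta-sheet domains over strand pairs and triplets
#'
#' Every upper-triangle pair `(p, q)` classified in the alignment matrix
#' is a two-strand sheet; for every further strand `s > q` with `(q, s)`
#' classified, the pair of reduced vectors through the shared strand `q`
#' is projected ([tripletProjection()]) and a nonzero projection confirms
#' the triplet `(p, q, s)`. The run length of a pair is the longest run
#' of consecutive nonzero entries of its reduced row vector — the number
#' of consecutive residues structured along the strand direction.
#'
#' @param am an [AlignmentMatrix-class].
#' @param cm the beta-criterion [ContactMap-class] of the same frame.
#' @return a [BetaSheetDomains-class].
#' @export
betaSheetDomains <- function(am, cm) {
  stopifnot(is(am, "AlignmentMatrix"), is(cm, "ContactMap"))
  tab <- alignmentTable(am)
  trip <- NULL
  if (nrow(tab)) {
    runs <- integer(nrow(tab))
    for (e in seq_len(nrow(tab))) {
      vr <- strandRowVector(cm, tab$p[e], tab$q[e])
      runs[e] <- .maxRun(vr)
      q <- tab$q[e]
      partners <- tab$q[tab$p == q]          # s > q with P[q, s] != 0
      for (s in partners) {
        vc <- strandColVector(cm, q, s)
        vp <- tripletProjection(vr, vc)
        if (vp != 0) trip <- rbind(trip,
          data.frame(p = tab$p[e], q = q, s = s, projection = vp))
      }
    }
    pairs <- data.frame(p = tab$p, q = tab$q, orientation = tab$class,
                        shift = tab$shift, nContacts = tab$nContacts,
                        runLength = runs, stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(p = integer(), q = integer(),
                        orientation = character(), shift = integer(),
                        nContacts = integer(), runLength = integer(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(trip))
    trip <- data.frame(p = integer(), q = integer(), s = integer(),
                       projection = numeric())
  new("BetaSheetDomains", pairs = pairs, triplets = trip,
      nMol = length(cm@molLengths))
}

#' Fraction of peptides participating in beta-sheets
#'
#' @param domains a [BetaSheetDomains-class].
#' @param nmol total number of peptides (defaults to the system size
#'   recorded in `domains`).
#' @return fraction in `[0, 1]`.
#' @export
peptidesInBeta <- function(domains, nmol = domains@nMol) {
  stopifnot(is(domains, "BetaSheetDomains"), nmol >= 1L)
  members <- unique(c(domains@pairs$p, domains@pairs$q,
                      domains@triplets$p, domains@triplets$q,
                      domains@triplets$s))
  length(members) / nmol
}
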
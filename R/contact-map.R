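#' Contact criteria
#'
#' `betaCriterion()` builds the single-threshold criterion used for
#' beta-sheet detection: two residues are in contact when their
#' representative points lie at or below `d0` Angstrom apart, the
#' inter-strand spacing regime of cross-beta structures (about 4.7 to
#' 5.3 Angstrom; the default takes the upper end, 5.3).
#'
#' `alphaCriterion()` builds the band criterion used for alpha-helix /
#' beta-turn detection: a contact requires the distance to fall inside the
#' closed band `[dLow, dHigh]` (default 5.1 to 6.3 Angstrom, the (i, i+4)
#' backbone distance range of an alpha-helix). Alpha contacts are
#' intra-molecular only and require a sequence separation of at least
#' `minSep` residues; the default of 3 keeps the (i, i+2) backbone
#' distance of a helix (about 5.4 Angstrom, inside the band) from being
#' miscounted as a turn contact.
#'
#' @param d0 beta threshold distance in Angstrom.
#' @param dLow,dHigh alpha band edges in Angstrom.
#' @param minSep minimum intra-molecular sequence separation.
#' @return a [ContactCriterion-class].
#' @export
betaCriterion <- function(d0 = 5.3, minSep = 0L) {
  new("ContactCriterion", kind = "beta", dLow = 0, dHigh = d0,
      minSep = as.integer(minSep))
}

#' @rdname betaCriterion
#' @export
alphaCriterion <- function(dLow = 5.1, dHigh = 6.3, minSep = 3L) {
  new("ContactCriterion", kind = "alpha", dLow = dLow, dHigh = dHigh,
      minSep = as.integer(minSep))
}

#' Pairwise distance map of a frame
#'
#' Computes the full symmetric matrix of Euclidean distances between all
#' selected points of a frame, molecules concatenated in order. No
#' thresholding is applied. Distances are plain Euclidean (no periodic
#' minimum-image convention).
#'
#' @param frame a [SystemFrame-class].
#' @return a [DistanceMap-class].
#' @export
distanceMap <- function(frame) {
  stopifnot(is(frame, "SystemFrame"))
  xyz <- do.call(rbind, frame@coords)
  if (nrow(xyz) < 1L) stop("frame has no points")
  if (any(!is.finite(xyz))) {
    bad <- which(!is.finite(rowSums(xyz)))[1]
    mol <- findInterval(bad - 1L, cumsum(frame@molLengths), left.open = FALSE) + 1L
    stop("non-finite coordinate at molecule ", mol)
  }
  D <- as.matrix(stats::dist(xyz))
  dimnames(D) <- NULL
  offsets <- c(0L, cumsum(frame@molLengths))[seq_along(frame@molLengths)]
  new("DistanceMap", D = D, offsets = as.integer(offsets),
      molLengths = frame@molLengths)
}

#' Binarize a distance map into a contact map
#'
#' Applies a [ContactCriterion-class] to a [DistanceMap-class]. For the
#' beta criterion a contact is `D <= d0`; intra-molecular pairs closer
#' than `minSep` positions along the chain are excluded (default 0, i.e.
#' none). For the alpha criterion a contact is `dLow <= D <= dHigh`,
#' restricted to pairs within the same molecule separated by at least
#' `minSep` residues; inter-molecular pairs never count. The diagonal is
#' always zero.
#'
#' @param dm a [DistanceMap-class].
#' @param criterion a [ContactCriterion-class].
#' @return a [ContactMap-class].
#' @export
contactMap <- function(dm, criterion = betaCriterion()) {
  stopifnot(is(dm, "DistanceMap"), is(criterion, "ContactCriterion"))
  D <- dm@D
  n <- nrow(D)
  molOf <- rep.int(seq_along(dm@molLengths), dm@molLengths)
  resOf <- unlist(lapply(dm@molLengths, seq_len), use.names = FALSE)
  sameMol <- outer(molOf, molOf, "==")
  sep <- abs(outer(resOf, resOf, "-"))

  if (criterion@kind == "beta") {
    C <- (D <= criterion@dHigh)
    if (criterion@minSep > 0L)
      C[sameMol & sep < criterion@minSep] <- FALSE
  } else {
    C <- (D >= criterion@dLow & D <= criterion@dHigh) & sameMol &
      (sep >= criterion@minSep)
  }
  diag(C) <- FALSE
  C <- matrix(as.numeric(C), n, n)
  new("ContactMap", contacts = C, D = D, offsets = dm@offsets,
      molLengths = dm@molLengths, criterion = criterion)
}

#' Inter-molecular block of a contact map
#'
#' Extracts the `RES x RES` sub-matrix describing the contacts between two
#' equal-length molecules: rows index the residues of `p`, columns those
#' of `q`. This is the block that is scored against the kernel library.
#'
#' @param cm a [ContactMap-class].
#' @param p,q 1-based molecule indices, `p != q`.
#' @return binary `RES x RES` matrix.
#' @export
moleculeBlock <- function(cm, p, q) {
  stopifnot(is(cm, "ContactMap"))
  nmol <- length(cm@molLengths)
  if (p < 1L || p > nmol || q < 1L || q > nmol || p == q)
    stop("p and q must be distinct molecule indices in 1..", nmol)
  if (cm@molLengths[p] != cm@molLengths[q])
    stop("molecules ", p, " and ", q, " have different lengths (",
         cm@molLengths[p], " vs ", cm@molLengths[q],
         "); kernel matching requires square blocks")
  ri <- cm@offsets[p] + seq_len(cm@molLengths[p])
  ci <- cm@offsets[q] + seq_len(cm@molLengths[q])
  cm@contacts[ri, ci, drop = FALSE]
}

## intra-molecular block (square, symmetric) of molecule m
.intraBlock <- function(cm, m) {
  ri <- cm@offsets[m] + seq_len(cm@molLengths[m])
  cm@contacts[ri, ri, drop = FALSE]
}

#' Export a contact map as a TSV edge list
#'
#' Writes one row per contact pair (upper triangle) with 1-based flat
#' point indices, the molecule/residue decomposition of each endpoint and
#' the distance in Angstrom.
#'
#' @param cm a [ContactMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeContactsTSV <- function(cm, path) {
  stopifnot(is(cm, "ContactMap"))
  idx <- which(cm@contacts != 0 & upper.tri(cm@contacts), arr.ind = TRUE)
  molOf <- rep.int(seq_along(cm@molLengths), cm@molLengths)
  resOf <- unlist(lapply(cm@molLengths, seq_len), use.names = FALSE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   mol_i = molOf[idx[, 1]], res_i = resOf[idx[, 1]],
                   mol_j = molOf[idx[, 2]], res_j = resOf[idx[, 2]],
                   distance = .fmt(cm@D[idx]))
  df <- df[order(df$i, df$j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
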
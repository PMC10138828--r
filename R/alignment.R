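#' Normalized cross-correlation of a contact block with a kernel
#'
#' For binary matrices `B` (contact block) and `L` (kernel) the score is
#'
#' \deqn{NCC = \frac{\sum_{ij} B_{ij} L_{ij}}{\mathrm{den}(B, L)}}
#'
#' where the denominator is either the plain product of the two sums
#' (`normalization = "product"`, the method's printed form) or the
#' geometric mean `sqrt(sum(B) * sum(L))` (`"geometric"`, the standard
#' energy-normalized cross-correlation). The score is defined as 0 when
#' either matrix is all-zero.
#'
#' For a fixed block the two normalizations rank kernels identically
#' within a family of equal kernel size, but they differ across sizes:
#' the product form scores by the covered fraction of the kernel and so
#' prefers a small template nested inside the block whenever a contact of
#' the true arrangement is missing, while the geometric form balances
#' coverage against template size and degrades gracefully under missing
#' or spurious contacts. Classification therefore defaults to
#' `"geometric"` (see [alignmentMatrix()]); `"product"` is the
#' literal printed form.
#'
#' @param block binary `RES x RES` matrix.
#' @param kernel binary `RES x RES` matrix.
#' @param normalization `"product"` or `"geometric"`.
#' @return numeric score.
#' @examples
#' lib <- kernelLibrary(4)
#' K <- kernelMatrix(lib, 0)
#' nccScore(K, K)              # 1 / nnz under the product form
#' @export
nccScore <- function(block, kernel,
                     normalization = c("product", "geometric")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(block) || !is.matrix(kernel) ||
      !all(dim(block) == dim(kernel)))
    stop("block and kernel must be matrices of identical dimension")
  sb <- sum(block)
  sk <- sum(kernel)
  if (sb == 0 || sk == 0) return(0)
  num <- sum(block * kernel)
  den <- if (normalization == "product") sb * sk else sqrt(sb * sk)
  num / den
}

## score all kernels against a block at once; returns the numeric vector
## of scores in kernel order
.scoreAllKernels <- function(block, lib, normalization) {
  Lmat <- matrix(lib@L, nrow = lib@res^2)       # RES^2 x 4RES
  o <- as.vector(crossprod(Lmat, as.vector(block)))
  sb <- sum(block)
  sk <- lib@labels$nnz
  if (sb == 0) return(rep(0, length(o)))
  if (normalization == "product") o / (sb * sk) else o / sqrt(sb * sk)
}

## argmax with deterministic tie-breaking: highest score, then largest
## kernel support, then lowest kernel index. Returns the 0-based kernel
## index, or -1 when no kernel scores above zero.
.bestKernel <- function(scores, nnz) {
  best <- max(scores)
  if (best <= 0) return(-1L)
  cand <- which(scores == best)
  cand <- cand[nnz[cand] == max(nnz[cand])]
  cand[1] - 1L
}

#' Classify every molecule pair against the kernel library
#'
#' For each ordered pair of distinct molecules whose inter-molecular
#' contact block carries at least `minContact` contacts, scores the block
#' against all `4 * RES` kernels with [nccScore()] and stores the winning
#' kernel. Pairs below the contact threshold, or whose every score is
#' zero, are marked "no classified interaction". Ties are broken towards
#' the kernel with the largest support and then the lowest index, so an
#' exact-kernel block always recovers its generating arrangement (up to
#' the inherent shift-0 duplicates P+/P- and A+/A-).
#'
#' @param cm a beta-criterion [ContactMap-class] whose molecules all have
#'   length `res` of `lib`.
#' @param lib a [KernelLibrary-class].
#' @param minContact minimum number of contacts in a block for the pair
#'   to be classified (default 3).
#' @param normalization NCC normalization, `"geometric"` (default) or
#'   `"product"`; see [nccScore()].
#' @return an [AlignmentMatrix-class].
#' @export
alignmentMatrix <- function(cm, lib, minContact = 3L,
                            normalization = c("geometric", "product")) {
  normalization <- match.arg(normalization)
  stopifnot(is(cm, "ContactMap"), is(lib, "KernelLibrary"))
  if (!all(cm@molLengths == lib@res))
    stop("all molecules must have length ", lib@res,
         " to match the kernel library")
  minContact <- as.integer(minContact)
  if (minContact < 1L) stop("minContact must be >= 1")
  nmol <- length(cm@molLengths)
  P <- matrix(0L, nmol, nmol)
  counts <- matrix(0L, nmol, nmol)
  for (p in seq_len(nmol)) for (q in seq_len(nmol)) {
    if (p == q) next
    block <- moleculeBlock(cm, p, q)
    nc <- sum(block)
    counts[p, q] <- as.integer(nc)
    if (nc < minContact) next
    k <- .bestKernel(.scoreAllKernels(block, lib, normalization),
                     lib@labels$nnz)
    if (k >= 0L) P[p, q] <- k + 1L
  }
  new("AlignmentMatrix", P = P, res = lib@res, minContact = minContact,
      contactCounts = counts, normalization = normalization)
}

#' Classified-pair table of an alignment matrix
#'
#' One row per upper-triangle pair with a classified interaction,
#' reporting the 0-based winning kernel index, its orientation class and
#' register shift, and the block contact count.
#'
#' @param am an [AlignmentMatrix-class].
#' @return data.frame with columns `p`, `q`, `k`, `orientation`, `class`,
#'   `shift`, `nContacts`.
#' @export
alignmentTable <- function(am) {
  stopifnot(is(am, "AlignmentMatrix"))
  idx <- which(am@P != 0L & upper.tri(am@P), arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(p = integer(), q = integer(), k = integer(),
                      orientation = character(), class = character(),
                      shift = integer(), nContacts = integer(),
                      stringsAsFactors = FALSE))
  k <- am@P[idx] - 1L
  cls <- lapply(k, kernelClass, res = am@res)
  out <- data.frame(p = idx[, 1], q = idx[, 2], k = k,
                    orientation = vapply(cls, `[[`, "", "orientation"),
                    class = vapply(cls, `[[`, "", "class"),
                    shift = vapply(cls, function(x) x$shift, 0L),
                    nContacts = am@contactCounts[idx],
                    stringsAsFactors = FALSE)
  out[order(out$p, out$q), , drop = FALSE]
}

#' Export an alignment matrix as TSV
#'
#' Writes the nmol x nmol matrix of winning kernel indices in the
#' 0-doubles-as-none convention: classified pairs carry their 0-based
#' kernel index and unclassified pairs carry 0 (note the shift-0 parallel
#' kernel also has index 0; [alignmentTable()] is unambiguous).
#'
#' @param am an [AlignmentMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignmentTSV <- function(am, path) {
  stopifnot(is(am, "AlignmentMatrix"))
  M <- pmax(am@P - 1L, 0L)
  utils::write.table(M, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
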
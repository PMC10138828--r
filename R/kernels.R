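#' Build the library of strand-pair shift matrices
#'
#' Generates the ordered stack of `4 * RES` binary `RES x RES` templates
#' ("kernels") enumerating every idealized arrangement of two equal-length
#' strands: parallel with the second strand shifted forward (P+) or
#' backward (P-) by `s` residues, and antiparallel with the register
#' shifted positively (A+) or negatively (A-) by `s`, for every shift
#' `s` in `[0, RES)`. With 0-based residue indices `i, j` and
#' `n = RES - 1` the four families place ones where
#'
#' \itemize{
#'   \item P+ (`k` in `[0, RES)`, `s = k`): `j - i = s`
#'   \item P- (`k` in `[RES, 2 RES)`, `s = k - RES`): `i - j = s`
#'   \item A+ (`k` in `[2 RES, 3 RES)`, `s = k - 2 RES`): `i + j = n + s`
#'   \item A- (`k` in `[3 RES, 4 RES)`, `s = k - 3 RES`): `i + j = n - s`
#' }
#'
#' so the P family kernels are diagonals offset by the shift, and the A
#' family kernels are anti-diagonals: at shift 0 the A kernels are the
#' exact anti-diagonal, the in-register antiparallel ladder. Each kernel
#' has `RES - s` nonzero entries. The shift-0 members of P+ and P-
#' coincide (the identity), as do those of A+ and A-; both copies are kept
#' so the library always has `4 * RES` members.
#'
#' @param res residue count per strand (at least 2).
#' @return a [KernelLibrary-class].
#' @examples
#' lib <- kernelLibrary(4)
#' kernelMatrix(lib, 8)   # A+ shift 0: the anti-diagonal
#' @export
kernelLibrary <- function(res) {
  res <- as.integer(res)
  if (is.na(res) || res < 2L) stop("res must be an integer >= 2")
  nk <- 4L * res
  L <- array(0, dim = c(res, res, nk))
  i0 <- matrix(0:(res - 1L), res, res)        # 0-based row index
  j0 <- t(i0)                                 # 0-based column index
  n <- res - 1L
  for (k in 0:(nk - 1L)) {
    fam <- k %/% res
    s <- k %% res
    hit <- switch(fam + 1L,
                  j0 - i0 == s,
                  i0 - j0 == s,
                  i0 + j0 == n + s,
                  i0 + j0 == n - s)
    L[, , k + 1L][hit] <- 1
  }
  orient <- rep(c("P+", "P-", "A+", "A-"), each = res)
  cls <- rep(c("P", "P", "AP+", "AP-"), each = res)
  labels <- data.frame(k = 0:(nk - 1L), orientation = orient, class = cls,
                       shift = rep(0:(res - 1L), 4L),
                       nnz = apply(L, 3, sum),
                       stringsAsFactors = FALSE)
  new("KernelLibrary", res = res, L = L, labels = labels)
}

#' Retrieve one kernel matrix
#'
#' @param lib a [KernelLibrary-class].
#' @param k 0-based kernel index in `[0, 4 * RES)`.
#' @return binary `RES x RES` matrix.
#' @export
kernelMatrix <- function(lib, k) {
  stopifnot(is(lib, "KernelLibrary"))
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k >= 4L * lib@res)
    stop("kernel index must lie in [0, ", 4L * lib@res, ")")
  lib@L[, , k + 1L]
}

#' Orientation and shift of a kernel index
#'
#' Maps a 0-based kernel index to its family, reporting class and register
#' shift. The reporting classes collapse the two parallel families to
#' `"P"` and keep the antiparallel sign: `"AP+"` and `"AP-"`.
#'
#' @param k 0-based kernel index in `[0, 4 * RES)`.
#' @param res residue count of the library.
#' @return list with elements `orientation` (`"P+"`, `"P-"`, `"A+"`,
#'   `"A-"`), `class` (`"P"`, `"AP+"`, `"AP-"`) and `shift`.
#' @export
kernelClass <- function(k, res) {
  res <- as.integer(res)
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k >= 4L * res)
    stop("kernel index must lie in [0, ", 4L * res, ")")
  fam <- k %/% res
  list(orientation = c("P+", "P-", "A+", "A-")[fam + 1L],
       class = c("P", "P", "AP+", "AP-")[fam + 1L],
       shift = k %% res)
}

#' Export kernel labels as TSV
#'
#' @param lib a [KernelLibrary-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeKernelLabelsTSV <- function(lib, path) {
  stopifnot(is(lib, "KernelLibrary"))
  utils::write.table(lib@labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
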
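# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the kernel stack is built by a literal triple
# loop over the four family conditions, components by union-find, and NCC
# argmax by direct per-kernel evaluation against that brute stack.

# brute-force kernel stack: 0-based indices, half-open family intervals
bruteKernelStack <- function(res) {
  n <- res - 1L
  L <- array(0, c(res, res, 4L * res))
  for (k in 0:(4L * res - 1L)) for (i in 0:n) for (j in 0:n) {
    on <-
      (k < res               && j - i == k) ||
      (k >= res  && k < 2L * res && i - j == k - res) ||
      (k >= 2L * res && k < 3L * res && i + j == n + (k - 2L * res)) ||
      (k >= 3L * res             && i + j == n - (k - 3L * res))
    if (on) L[i + 1L, j + 1L, k + 1L] <- 1
  }
  L
}

# exhaustive NCC argmax with the tie rule (max score, then max support,
# then min index); returns 0-based kernel index or -1
bruteBestKernel <- function(block, res, normalization = "product") {
  L <- bruteKernelStack(res)
  bestScore <- 0; bestK <- -1L; bestNnz <- -1L
  for (k in 0:(4L * res - 1L)) {
    K <- L[, , k + 1L]
    sb <- sum(block); sk <- sum(K)
    sc <- if (sb == 0 || sk == 0) 0 else {
      den <- if (normalization == "product") sb * sk else sqrt(sb * sk)
      sum(block * K) / den
    }
    if (sc > bestScore || (sc == bestScore && sc > 0 && sk > bestNnz)) {
      bestScore <- sc; bestK <- k; bestNnz <- sk
    }
  }
  bestK
}

# union-find connected components; edges is a 2-column matrix of node pairs
ufComponents <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), match(roots, unique(roots))))
}

# wrap a list of per-molecule coordinate matrices as a frame
frameOf <- function(coords, index = 0L) {
  new("SystemFrame", frameIndex = as.integer(index), coords = coords,
      molLengths = vapply(coords, nrow, integer(1)))
}

# two-molecule beta contact map whose inter-molecular block is B
cmFromBlock <- function(B) {
  res <- nrow(B)
  Z <- matrix(0, res, res)
  C <- rbind(cbind(Z, B), cbind(t(B), Z))
  new("ContactMap", contacts = C, D = matrix(0, 2 * res, 2 * res),
      offsets = c(0L, res), molLengths = c(res, res),
      criterion = betaCriterion())
}

# single-molecule alpha contact map with contacts at the given 1-based pairs
cmIntra <- function(res, pairs) {
  C <- matrix(0, res, res)
  if (length(pairs)) for (p in pairs) { C[p[1], p[2]] <- 1; C[p[2], p[1]] <- 1 }
  new("ContactMap", contacts = C, D = matrix(0, res, res),
      offsets = 0L, molLengths = as.integer(res),
      criterion = alphaCriterion())
}

# orientation classes counted equivalent at the shift-0 antiparallel
# degeneracy (A+ and A- coincide there, as P+ and P- do)
classMatches <- function(gotClass, gotShift, wantClass, wantShift) {
  if (gotShift != wantShift) return(FALSE)
  if (gotClass == wantClass) return(TRUE)
  wantShift == 0 && all(c(gotClass, wantClass) %in% c("AP+", "AP-"))
}
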
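#' Per-frame alpha-helix / beta-turn content series
#'
#' Runs the helix/turn identification on every frame and assembles the
#' per-molecule content matrices (percent of residues, via
#' [helixContent()] and [turnContent()]) and the helix-pace matrix.
#'
#' @param frames list of [SystemFrame-class] objects (equal layout).
#' @param criterion an alpha [ContactCriterion-class].
#' @return a [StructuralTimeSeries-class].
#' @export
helixScoreSeries <- function(frames, criterion = alphaCriterion()) {
  stopifnot(length(frames) >= 1L, criterion@kind == "alpha")
  nmol <- length(frames[[1]]@coords)
  lens <- frames[[1]]@molLengths
  nf <- length(frames)
  alpha <- matrix(0, nf, nmol)
  turn <- matrix(0, nf, nmol)
  pace <- matrix(NA_real_, nf, nmol)
  for (f in seq_len(nf)) {
    cm <- contactMap(distanceMap(frames[[f]]), criterion)
    for (m in seq_len(nmol)) {
      a <- alphaTurnAssignment(cm, m)
      alpha[f, m] <- helixContent(a, lens[m])
      turn[f, m] <- turnContent(a, lens[m])
      pace[f, m] <- a$paceHelix
    }
  }
  new("StructuralTimeSeries",
      frames = vapply(frames, function(x) x@frameIndex, integer(1)),
      alpha = alpha, betaTurn = turn, paceHelix = pace,
      sheetFraction = numeric(0),
      tallies = data.frame(), shiftTable = data.frame())
}

#' Stability of a structural content series
#'
#' The percentage of frames whose content lies strictly above the series
#' mean. A constant series has stability 0.
#'
#' @param x numeric series of per-frame content values.
#' @return percentage in `[0, 100)`.
#' @examples
#' stabilityScore(c(10, 20, 30, 40))  # 50
#' @export
stabilityScore <- function(x) {
  stopifnot(length(x) >= 1L)
  100 * sum(x > mean(x)) / length(x)
}

#' Transition (relative) entropy between two content series
#'
#' The Kullback-Leibler divergence, in bits, of the beta-turn content
#' distribution from the alpha-helix content distribution over frames:
#' both series are first normalized to empirical distributions (sum 1)
#' and `RE = sum_t beta(t) * log2(beta(t) / alpha(t))` is accumulated
#' over frames with `beta(t) > 0`, flooring `alpha(t)` at `eps` where it
#' vanishes. Higher values mark less probable alpha-to-beta transitions.
#' An all-zero beta series gives 0. Set `normalize = FALSE` to evaluate
#' the sum on the raw series instead.
#'
#' @param beta,alpha equal-length non-negative series.
#' @param normalize normalize both series to sum 1 first (default TRUE).
#' @param eps floor applied to vanishing alpha terms.
#' @return relative entropy in bits (non-negative when normalized).
#' @export
transitionEntropy <- function(beta, alpha, normalize = TRUE,
                              eps = 1e-12) {
  if (length(beta) != length(alpha))
    stop("series must have equal length")
  if (any(beta < 0) || any(alpha < 0))
    stop("series must be non-negative")
  if (all(beta == 0)) return(0)
  if (normalize) {
    beta <- beta / sum(beta)
    if (sum(alpha) > 0) alpha <- alpha / sum(alpha)
  }
  sel <- beta > 0
  sum(beta[sel] * log2(beta[sel] / pmax(alpha[sel], eps)))
}

#' Mutual information between two series
#'
#' Each series is discretized into `nBins` equal-width bins over its own
#' observed range (a constant series occupies a single bin) and the
#' mutual information `MI = sum p(a,b) log2(p(a,b) / (p(a) p(b)))` is
#' computed from the joint empirical histogram, in bits.
#'
#' @param a,b equal-length numeric series (length at least 2).
#' @param nBins number of equal-width bins (default 10).
#' @return mutual information in bits (non-negative).
#' @export
mutualInformation <- function(a, b, nBins = 10L) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 2L) stop("series must have length >= 2")
  if (nBins < 2L) stop("nBins must be >= 2")
  bin <- function(x) {
    if (max(x) == min(x)) return(rep(1L, length(x)))
    br <- seq(min(x), max(x), length.out = nBins + 1L)
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  joint <- table(bin(a), bin(b)) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (pa[i] * pb[j]))
  }
  max(mi, 0)
}

#' Antiparallel/parallel organizational ratios per frame
#'
#' From per-frame contact tallies by orientation class, returns both the
#' organizational index AP / P (antiparallel over parallel contact
#' counts; NA where no parallel contacts exist) and the
#' antiparallel-to-total ratio AP / (AP + P) (0 where no contacts at
#' all). The organizational index is the quantity comparable to
#' ATR-FTIR-derived sheet organization measurements.
#'
#' @param tallies data.frame with columns `frame`, `P`, `APplus`,
#'   `APminus` (contact counts).
#' @return data.frame with columns `frame`, `orgIndex`, `apToTotal`.
#' @export
organizationalIndex <- function(tallies) {
  stopifnot(all(c("frame", "P", "APplus", "APminus") %in% names(tallies)))
  ap <- tallies$APplus + tallies$APminus
  p <- tallies$P
  data.frame(frame = tallies$frame,
             orgIndex = ifelse(p > 0, ap / p, NA_real_),
             apToTotal = ifelse(ap + p > 0, ap / (ap + p), 0))
}

#' Register-shift distribution over frames
#'
#' Histograms the register shifts of the classified pairs of each frame,
#' split by orientation class (P, AP+, AP-).
#'
#' @param amList list of per-frame [AlignmentMatrix-class] objects.
#' @param frames optional integer frame indices (defaults to
#'   `0, 1, ...`).
#' @return data.frame with columns `frame`, `class`, `shift`, `count`
#'   (only nonzero counts, in frame/class/shift order).
#' @export
shiftProfile <- function(amList, frames = seq_along(amList) - 1L) {
  stopifnot(length(amList) == length(frames))
  out <- NULL
  for (f in seq_along(amList)) {
    tab <- alignmentTable(amList[[f]])
    if (!nrow(tab)) next
    agg <- stats::aggregate(list(count = tab$k),
                            by = list(class = tab$class, shift = tab$shift),
                            FUN = length)
    agg$frame <- frames[f]
    out <- rbind(out, agg[, c("frame", "class", "shift", "count")])
  }
  if (is.null(out))
    out <- data.frame(frame = integer(), class = character(),
                      shift = integer(), count = integer())
  out[order(out$frame, out$class, out$shift), , drop = FALSE]
}

#' Summary table of a structural content series
#'
#' For each molecule: the maximum content, the number of frames attaining
#' that maximum (exact equality; contents are exact rationals `k/RES`),
#' the mean content and the stability ([stabilityScore()]).
#'
#' @param contents frames x molecules matrix of content percentages (or
#'   a numeric vector for one molecule).
#' @return data.frame with columns `molecule`, `max`, `framesAtMax`,
#'   `mean`, `stability`.
#' @export
summarizeSeries <- function(contents) {
  if (is.vector(contents)) contents <- matrix(contents, ncol = 1)
  stopifnot(nrow(contents) >= 1L)
  do.call(rbind, lapply(seq_len(ncol(contents)), function(m) {
    x <- contents[, m]
    data.frame(molecule = m, max = max(x),
               framesAtMax = sum(x == max(x)),
               mean = mean(x), stability = stabilityScore(x))
  }))
}
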
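## run expr with a temporarily seeded RNG, restoring the caller's state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.addNoise <- function(xyz, sigma) {
  if (sigma > 0)
    xyz + matrix(stats::rnorm(length(xyz), sd = sigma), nrow(xyz), 3)
  else xyz
}

#' Ideal helix backbone
#'
#' Places `n` points on a helical curve
#' `(radius cos(i twist), radius sin(i twist), i rise)`, optionally
#' perturbed by isotropic Gaussian noise. The defaults (radius 2.3 A,
#' rise 1.5 A per residue, twist 100 degrees per residue) reproduce
#' alpha-helix backbone geometry: the (i, i+4) distance is the chord
#' `sqrt((2 r sin(4 twist / 2))^2 + (4 rise)^2)`, about 6.20 A, inside
#' the alpha contact band, while (i, i+3) falls just below it.
#'
#' @param n number of residues (at least 5 for an (i, i+4) pair to
#'   exist; at least 2 required).
#' @param radius helix radius in Angstrom.
#' @param rise rise per residue in Angstrom.
#' @param twist twist per residue in degrees.
#' @param noiseSigma per-coordinate Gaussian noise sd in Angstrom.
#' @param seed RNG seed for the noise (the caller's RNG state is left
#'   untouched).
#' @return n x 3 coordinate matrix.
#' @export
makeHelix <- function(n, radius = 2.3, rise = 1.5, twist = 100,
                      noiseSigma = 0, seed = NULL) {
  if (n < 2L) stop("n must be >= 2")
  th <- .deg2rad((seq_len(n) - 1L) * twist)
  xyz <- cbind(radius * cos(th), radius * sin(th),
               (seq_len(n) - 1L) * rise)
  .withSeed(seed, .addNoise(xyz, noiseSigma))
}

#' Beta-sheet ladder of straight strands
#'
#' Builds `nStrands` straight strands of `strandLen` residues along x at
#' an intra-strand step of `step` Angstrom, stacked along y at an
#' inter-strand gap of `gap` Angstrom, so that matched residues of
#' adjacent strands lie at `gap` (inside the cross-beta contact
#' threshold) and off-register pairs at `sqrt(gap^2 + step^2)` (outside
#' it). Parallel ladders shift each successive strand by `shift`
#' residues, making every adjacent block the parallel shift-`shift`
#' template; antiparallel ladders reverse the residue order of every
#' other strand with the register offset by `shift`, making every
#' adjacent block the antiparallel-positive shift-`shift` template.
#'
#' @param nStrands number of strands (at least 1).
#' @param strandLen residues per strand.
#' @param step intra-strand spacing in Angstrom (default 3.5).
#' @param gap inter-strand spacing in Angstrom (default 4.8).
#' @param orientation `"A"` (antiparallel) or `"P"` (parallel).
#' @param shift register shift in `[0, strandLen)`.
#' @param noiseSigma per-coordinate Gaussian noise sd in Angstrom.
#' @param seed RNG seed for the noise.
#' @return list with `coords` (list of strand coordinate matrices) and
#'   `truth` (data.frame of adjacent pairs `p`, `q`, `orientation`
#'   reporting class `"P"` / `"AP+"`, and `shift`).
#' @export
makeSheet <- function(nStrands, strandLen, step = 3.5, gap = 4.8,
                      orientation = c("A", "P"), shift = 0L,
                      noiseSigma = 0, seed = NULL) {
  orientation <- match.arg(orientation)
  shift <- as.integer(shift)
  if (nStrands < 1L) stop("nStrands must be >= 1")
  if (gap <= 0) stop("gap must be positive (strands would overlap)")
  if (shift < 0L || shift >= strandLen)
    stop("shift must lie in [0, strandLen)")
  n0 <- strandLen - 1L
  i0 <- 0:n0
  coords <- vector("list", nStrands)
  for (t in 0:(nStrands - 1L)) {
    xIdx <- if (orientation == "P") i0 - t * shift
            else if (t %% 2L == 0L) i0 else (n0 + shift) - i0
    coords[[t + 1L]] <- cbind(xIdx * step, rep(t * gap, strandLen),
                              rep(0, strandLen))
  }
  coords <- .withSeed(seed,
                      lapply(coords, .addNoise, sigma = noiseSigma))
  truth <- if (nStrands > 1L)
    data.frame(p = 1:(nStrands - 1L), q = 2:nStrands,
               orientation = if (orientation == "P") "P" else "AP+",
               shift = shift, stringsAsFactors = FALSE)
  else
    data.frame(p = integer(), q = integer(), orientation = character(),
               shift = integer(), stringsAsFactors = FALSE)
  list(coords = coords, truth = truth)
}

#' Random-coil (or straight) chain
#'
#' A fixed-step random walk that resamples any step bringing the new
#' point within `minApproach` of a previous non-adjacent point, as a
#' negative control carrying no regular secondary-structure geometry.
#' With `straight = TRUE` the degenerate straight-line chain is returned
#' instead: at the default 3.8 A step all pairs separated by 2 or more
#' residues are at least 7.6 A apart, outside both contact regimes.
#'
#' @param n number of residues (at least 2).
#' @param step step length in Angstrom (default 3.8).
#' @param seed RNG seed.
#' @param minApproach minimum distance between non-adjacent points.
#' @param straight return a straight chain instead of a random walk.
#' @return n x 3 coordinate matrix.
#' @export
makeCoil <- function(n, step = 3.8, seed = NULL, minApproach = 4.0,
                     straight = FALSE) {
  if (n < 2L) stop("n must be >= 2")
  if (straight)
    return(cbind((seq_len(n) - 1L) * step, rep(0, n), rep(0, n)))
  .withSeed(seed, {
    for (attempt in 1:100) {
      xyz <- matrix(0, n, 3)
      ok <- TRUE
      for (i in 2:n) {
        placed <- FALSE
        for (try in 1:200) {
          u <- stats::rnorm(3)
          cand <- xyz[i - 1L, ] + step * u / sqrt(sum(u^2))
          if (i == 2L ||
              all(sqrt(colSums((t(xyz[1:(i - 2L), , drop = FALSE]) -
                                cand)^2)) >= minApproach)) {
            xyz[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(xyz)
    }
    stop("could not build a self-avoiding walk of length ", n)
  })
}

#' Specification of a synthetic multi-molecule system
#'
#' Describes a system for [makeSystem()]: one motif per molecule
#' (`"helix"`, `"strand"` or `"coil"`), a common residue count, the sheet
#' topology applied to the strand motifs (all consecutive strands form
#' one ladder), the helix and strand geometry, a noise level and a seed.
#' Defaults follow the package's canonical geometry: helix radius 2.3 A,
#' rise 1.5 A, twist 100 degrees; strand step 3.5 A, gap 4.8 A.
#'
#' @param motifs character vector of per-molecule motifs.
#' @param nRes residues per molecule.
#' @param orientation,shift sheet topology for the strand motifs.
#' @param helix named list overriding `radius`, `rise`, `twist`.
#' @param strand named list overriding `step`, `gap`.
#' @param coilStep step of coil molecules in Angstrom.
#' @param spacing placement gap between independent molecules (Angstrom,
#'   at least 20 so unrelated molecules share no contacts).
#' @param noiseSigma per-coordinate Gaussian noise sd in Angstrom.
#' @param seed RNG seed.
#' @return list of class `"synthSpec"`.
#' @export
synthSpec <- function(motifs, nRes, orientation = "A", shift = 0L,
                      helix = list(), strand = list(), coilStep = 3.8,
                      spacing = 25, noiseSigma = 0, seed = NULL) {
  if (!length(motifs) || !all(motifs %in% c("helix", "strand", "coil")))
    stop("motifs must be 'helix', 'strand' or 'coil'")
  if (as.integer(shift) >= nRes) stop("shift must be < nRes")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (spacing < 20) stop("spacing must be >= 20 Angstrom")
  h <- utils::modifyList(list(radius = 2.3, rise = 1.5, twist = 100), helix)
  s <- utils::modifyList(list(step = 3.5, gap = 4.8), strand)
  structure(list(motifs = motifs, nRes = as.integer(nRes),
                 orientation = orientation, shift = as.integer(shift),
                 helix = h, strand = s, coilStep = coilStep,
                 spacing = spacing, noiseSigma = noiseSigma, seed = seed),
            class = "synthSpec")
}

#' Assemble a synthetic system frame with ground truth
#'
#' Builds every molecule of the spec, groups the strand motifs into one
#' sheet ladder and displaces each independent unit (the ladder, every
#' helix, every coil) far enough apart (`spacing` beyond each unit's
#' extent) that no inter-unit contact can arise. Identical seeds give
#' identical output.
#'
#' @param spec a [synthSpec()].
#' @return list with `frame` (a [SystemFrame-class]), `truth`
#'   (data.frame of ground-truth sheet pairs with system molecule
#'   indices) and `motifs`.
#' @export
makeSystem <- function(spec) {
  stopifnot(inherits(spec, "synthSpec"))
  nmol <- length(spec$motifs)
  strandIdx <- which(spec$motifs == "strand")
  coords <- vector("list", nmol)
  truth <- data.frame(p = integer(), q = integer(),
                      orientation = character(), shift = integer(),
                      stringsAsFactors = FALSE)
  if (length(strandIdx)) {
    sh <- makeSheet(length(strandIdx), spec$nRes,
                    step = spec$strand$step, gap = spec$strand$gap,
                    orientation = spec$orientation, shift = spec$shift,
                    noiseSigma = spec$noiseSigma,
                    seed = if (is.null(spec$seed)) NULL else spec$seed)
    coords[strandIdx] <- sh$coords
    if (nrow(sh$truth)) {
      truth <- sh$truth
      truth$p <- strandIdx[truth$p]
      truth$q <- strandIdx[truth$q]
    }
  }
  other <- which(spec$motifs != "strand")
  for (u in seq_along(other)) {
    m <- other[u]
    seedM <- if (is.null(spec$seed)) NULL else spec$seed + m
    coords[[m]] <- switch(spec$motifs[m],
      helix = makeHelix(spec$nRes, spec$helix$radius, spec$helix$rise,
                        spec$helix$twist, spec$noiseSigma, seedM),
      coil = makeCoil(spec$nRes, spec$coilStep, seedM))
  }
  ## displace independent units along x so they cannot interact
  units <- c(if (length(strandIdx)) list(strandIdx),
             as.list(other))
  xShift <- 0
  for (u in units) {
    xs <- unlist(lapply(coords[u], function(m) m[, 1]))
    lo <- min(xs)
    for (m in u) coords[[m]][, 1] <- coords[[m]][, 1] - lo + xShift
    xShift <- xShift + (max(xs) - lo) + spec$spacing
  }
  frame <- new("SystemFrame", frameIndex = 0L, coords = coords,
               molLengths = rep(spec$nRes, nmol))
  list(frame = frame, truth = truth, motifs = spec$motifs)
}

#' Linear morph between two synthetic systems
#'
#' Interpolates coordinates linearly between two systems of identical
#' molecule layout over `nFrames` frames (frame 0 is the first system,
#' the last frame the second), producing a small synthetic "trajectory"
#' for time-series tests, e.g. a helix unfolding into a coil.
#'
#' @param systemA,systemB results of [makeSystem()] with equal layout.
#' @param nFrames number of frames (at least 2).
#' @return list of [SystemFrame-class] objects.
#' @export
morphTrajectory <- function(systemA, systemB, nFrames = 2L) {
  stopifnot(nFrames >= 2L)
  fa <- systemA$frame
  fb <- systemB$frame
  if (!identical(fa@molLengths, fb@molLengths))
    stop("systems must have identical molecule layout")
  lapply(seq_len(nFrames) - 1L, function(f) {
    w <- f / (nFrames - 1L)
    coords <- lapply(seq_along(fa@coords), function(m)
      (1 - w) * fa@coords[[m]] + w * fb@coords[[m]])
    new("SystemFrame", frameIndex = as.integer(f), coords = coords,
        molLengths = fa@molLengths)
  })
}
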
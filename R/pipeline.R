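#' Analysis run configuration
#'
#' Bundles the inputs and tunables of a full analysis run. The `device`
#' option exists for interface compatibility with GPU-accelerated
#' workflows; only the serial CPU backend is implemented, and `"gpu"` is
#' accepted with a warning.
#'
#' @param configPath structure file (PDB or GRO).
#' @param trajPath optional trajectory file (DCD or multi-model PDB).
#' @param outDir output directory (created if missing).
#' @param selection atom names to analyze (default MARTINI `"BB"`).
#' @param betaThreshold beta contact threshold in Angstrom.
#' @param alphaBand numeric length-2 alpha contact band in Angstrom.
#' @param alphaMinSep minimum sequence separation for alpha contacts.
#' @param minContact minimum block contacts for pair classification.
#' @param interval frame sampling stride.
#' @param device `"cpu"` (or `"gpu"`, mapped to cpu with a warning).
#' @param seed optional integer recorded in the output summary.
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(configPath, trajPath = NULL, outDir = tempfile("scan"),
                      selection = "BB", betaThreshold = 5.3,
                      alphaBand = c(5.1, 6.3), alphaMinSep = 3L,
                      minContact = 3L, interval = 1L,
                      device = c("cpu", "gpu"), seed = NULL) {
  device <- match.arg(device)
  if (device == "gpu") {
    warning("gpu backend not available; falling back to cpu")
    device <- "cpu"
  }
  stopifnot(betaThreshold > 0, length(alphaBand) == 2L,
            alphaBand[1] > 0, alphaBand[1] < alphaBand[2],
            interval >= 1L)
  structure(list(configPath = configPath, trajPath = trajPath,
                 outDir = outDir, selection = selection,
                 betaThreshold = betaThreshold, alphaBand = alphaBand,
                 alphaMinSep = as.integer(alphaMinSep),
                 minContact = as.integer(minContact),
                 interval = as.integer(interval), device = device,
                 seed = seed),
            class = "runConfig")
}

.writeCSV <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmt)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full per-frame analysis pipeline
#'
#' Loads the system, samples frames, and for every sampled frame computes
#' the distance map, the beta and alpha contact maps, the molecular
#' alignment matrix, the interaction graph with its clusters, the
#' beta-sheet domains and the helix/turn assignments. Results are written
#' to `outDir` as plain-text tables plus a JSON summary:
#'
#' \itemize{
#'   \item `summary.json` - system composition, parameters, headline means
#'   \item `frame_metrics.csv` - per-frame mean contents, peptides-in-beta
#'     fraction, organizational index and antiparallel-to-total ratio
#'   \item `secstruct.csv` - per-frame per-molecule helix/turn counts,
#'     pace, contents and sheet membership
#'   \item `edges.csv`, `clusters.csv` - per-frame graph edges and
#'     cluster memberships with majority orientation
#'   \item `shift_profile.tsv` - per-frame register-shift histograms by
#'     orientation class
#'   \item `alignment/frame_<f>.tsv` - per-frame alignment matrices
#' }
#'
#' Outputs are deterministically ordered and formatted (6 significant
#' digits), so re-running the same inputs reproduces them byte for byte.
#' Beta-sheet classification requires all molecules to share one length;
#' on mixed-length systems it is skipped with a warning and only the
#' helix/turn analysis is reported.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with the output directory, the per-frame
#'   objects and the summary list.
#' @export
analyzeTrajectory <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  session <- loadSession(config$configPath, config$trajPath,
                         config$selection)
  summaryS <- exploreSystem(session)
  interval <- config$interval
  if (interval > nFrames(session)) {
    warning("interval (", interval, ") exceeds the ", nFrames(session),
            "-frame trajectory; analyzing the first frame only")
    interval <- nFrames(session)
  }
  frames <- sampleFrames(session, interval)
  lens <- molLengths(session)
  nmol <- length(lens)
  doBeta <- length(unique(lens)) == 1L && nmol > 1L
  if (!doBeta && nmol > 1L)
    warning("molecules have mixed lengths; beta-sheet classification skipped")
  lib <- if (doBeta) kernelLibrary(lens[1]) else NULL
  critB <- betaCriterion(config$betaThreshold)
  critA <- alphaCriterion(config$alphaBand[1], config$alphaBand[2],
                          config$alphaMinSep)

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$outDir, "alignment"), showWarnings = FALSE)

  secRows <- list(); edgeRows <- list(); clustRows <- list()
  frameRows <- list(); amList <- list()
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    f <- fr@frameIndex
    dm <- distanceMap(fr)
    cmA <- contactMap(dm, critA)
    assigns <- lapply(seq_len(nmol), function(m)
      alphaTurnAssignment(cmA, m))
    alphaPct <- vapply(seq_len(nmol), function(m)
      helixContent(assigns[[m]], lens[m]), numeric(1))
    turnPct <- vapply(seq_len(nmol), function(m)
      turnContent(assigns[[m]], lens[m]), numeric(1))

    inBeta <- rep(FALSE, nmol)
    pj <- 0; oi <- NA_real_; apt <- 0
    if (doBeta) {
      cmB <- contactMap(dm, critB)
      am <- alignmentMatrix(cmB, lib, config$minContact)
      amList[[fi]] <- am
      writeAlignmentTSV(am, file.path(config$outDir, "alignment",
                                      sprintf("frame_%06d.tsv", f)))
      graph <- contactGraph(am, cmB)
      domains <- betaSheetDomains(am, cmB)
      pj <- peptidesInBeta(domains)
      inBeta[unique(c(domains@pairs$p, domains@pairs$q))] <- TRUE
      edges <- graph@edges
      if (nrow(edges)) {
        edges <- cbind(frame = f, edges)
        edgeRows[[length(edgeRows) + 1L]] <- edges
      }
      lab <- clusterOrientation(graph)
      clustRows[[length(clustRows) + 1L]] <- data.frame(
        frame = f, cluster = seq_along(graph@clusters),
        size = lengths(graph@clusters),
        members = vapply(graph@clusters, paste, "", collapse = " "),
        orientation = lab, stringsAsFactors = FALSE)
      tal <- .orientationTallies(am, f)
      ratios <- organizationalIndex(tal)
      oi <- ratios$orgIndex; apt <- ratios$apToTotal
    }
    secRows[[fi]] <- data.frame(
      frame = f, molecule = seq_len(nmol),
      countAlpha = vapply(assigns, `[[`, 0L, "countAlpha"),
      paceHelix = vapply(assigns, `[[`, NA_real_, "paceHelix"),
      helixContentPct = alphaPct,
      countBetaTurn = vapply(assigns, `[[`, 0L, "countBetaTurn"),
      lengthBetaTurn = vapply(assigns, `[[`, NA_real_, "lengthBetaTurn"),
      turnContentPct = turnPct,
      inBetaSheet = inBeta)
    frameRows[[fi]] <- data.frame(
      frame = f, alphaMean = mean(alphaPct), betaTurnMean = mean(turnPct),
      peptidesInBeta = pj, orgIndex = oi, apToTotal = apt)
  }

  frameDf <- do.call(rbind, frameRows)
  .writeCSV(frameDf, file.path(config$outDir, "frame_metrics.csv"))
  .writeCSV(do.call(rbind, secRows), file.path(config$outDir, "secstruct.csv"))
  edgeDf <- if (length(edgeRows)) do.call(rbind, edgeRows) else
    data.frame(frame = integer(), p = integer(), q = integer(),
               nContacts = integer(), orientation = character(),
               shift = integer())
  .writeCSV(edgeDf, file.path(config$outDir, "edges.csv"))
  if (length(clustRows))
    .writeCSV(do.call(rbind, clustRows),
              file.path(config$outDir, "clusters.csv"))
  shifts <- if (doBeta)
    shiftProfile(amList, vapply(frames, function(x) x@frameIndex,
                                integer(1)))
  else data.frame(frame = integer(), class = character(),
                  shift = integer(), count = integer())
  utils::write.table(shifts, file.path(config$outDir, "shift_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    nMolecules = nmol,
    lenDict = as.list(summaryS@lenDict),
    nFramesTotal = nFrames(session),
    nFramesAnalyzed = length(frames),
    interval = interval,
    betaThreshold = config$betaThreshold,
    alphaBand = config$alphaBand,
    minContact = config$minContact,
    seed = config$seed,
    meanAlphaContent = mean(frameDf$alphaMean),
    meanBetaTurnContent = mean(frameDf$betaTurnMean),
    meanPeptidesInBeta = mean(frameDf$peptidesInBeta),
    nBetaPairsLastFrame = if (doBeta) sum(amList[[length(amList)]]@P[
      upper.tri(amList[[length(amList)]]@P)] != 0L) else 0L)
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(outDir = config$outDir, summary = summary,
                 frames = frames, alignments = amList,
                 frameMetrics = frameDf))
}

## contact tallies by orientation class for one frame's alignment
.orientationTallies <- function(am, frame) {
  tab <- alignmentTable(am)
  data.frame(frame = frame,
             P = sum(tab$nContacts[tab$class == "P"]),
             APplus = sum(tab$nContacts[tab$class == "AP+"]),
             APminus = sum(tab$nContacts[tab$class == "AP-"]))
}

#' Track alpha-helix / beta-turn dynamics over a trajectory
#'
#' Runs the helix/turn identification on every sampled frame and writes
#' the per-frame series (`helix_series.csv`) plus a per-molecule summary
#' (`helix_summary.csv`) with, for each content type, the maximum, the
#' number of frames attaining it, the mean and the stability, and the
#' transition entropy from the alpha series to the beta-turn series.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with the output directory, the
#'   [StructuralTimeSeries-class] and the two summary data.frames.
#' @export
helixScore <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  session <- loadSession(config$configPath, config$trajPath,
                         config$selection)
  interval <- min(config$interval, nFrames(session))
  frames <- sampleFrames(session, interval)
  critA <- alphaCriterion(config$alphaBand[1], config$alphaBand[2],
                          config$alphaMinSep)
  series <- helixScoreSeries(frames, critA)

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  nmol <- ncol(series@alpha)
  long <- do.call(rbind, lapply(seq_len(nmol), function(m)
    data.frame(frame = series@frames, molecule = m,
               alphaContentPct = series@alpha[, m],
               betaTurnContentPct = series@betaTurn[, m],
               paceHelix = series@paceHelix[, m])))
  long <- long[order(long$frame, long$molecule), ]
  .writeCSV(long, file.path(config$outDir, "helix_series.csv"))

  sumA <- summarizeSeries(series@alpha)
  sumB <- summarizeSeries(series@betaTurn)
  names(sumA)[-1] <- paste0("alpha_", names(sumA)[-1])
  names(sumB)[-1] <- paste0("betaTurn_", names(sumB)[-1])
  summ <- cbind(sumA, sumB[-1])
  summ$transitionEntropy <- vapply(seq_len(nmol), function(m)
    transitionEntropy(series@betaTurn[, m], series@alpha[, m]),
    numeric(1))
  .writeCSV(summ, file.path(config$outDir, "helix_summary.csv"))
  invisible(list(outDir = config$outDir, series = series,
                 summary = summ, seriesTable = long))
}

#' Render result plots from a completed analysis
#'
#' Thin rendering of the tables an [analyzeTrajectory()] run wrote; no
#' quantity is computed here that is not already in a CSV. Available
#' plots: `"graph"` (interaction graph of one frame, edges green for
#' parallel and blue for antiparallel, width proportional to contact
#' count), `"frame_aggregates"` (cluster sizes of one frame colored by
#' majority orientation), `"contacts"` (antiparallel-to-total ratio over
#' frames), `"peptides_in_beta"` (sheet-forming peptide fraction over
#' frames) and `"shift3d"` (register-shift distributions over frames by
#' orientation class).
#'
#' @param bundle result of [analyzeTrajectory()], or the output
#'   directory path.
#' @param which plot name.
#' @param file output file (default `<which>.pdf` inside the bundle
#'   directory).
#' @param frame 0-based frame for the graph / aggregate plots (default:
#'   last analyzed).
#' @return the output file path, invisibly.
#' @export
plotResults <- function(bundle,
                        which = c("graph", "frame_aggregates", "contacts",
                                  "peptides_in_beta", "shift3d"),
                        file = NULL, frame = NULL) {
  which <- match.arg(which)
  outDir <- if (is.character(bundle)) bundle else bundle$outDir
  if (is.null(file)) file <- file.path(outDir, paste0(which, ".pdf"))
  fm <- utils::read.csv(file.path(outDir, "frame_metrics.csv"))
  edges <- utils::read.csv(file.path(outDir, "edges.csv"))
  grDevices::pdf(file, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  edgeCol <- function(orient) ifelse(orient == "P", "forestgreen", "blue")
  if (which == "contacts") {
    plot(fm$frame, fm$apToTotal, type = "b", pch = 16, ylim = c(0, 1),
         xlab = "frame", ylab = "antiparallel / total contacts")
  } else if (which == "peptides_in_beta") {
    plot(fm$frame, fm$peptidesInBeta, type = "b", pch = 16, ylim = c(0, 1),
         xlab = "frame", ylab = "fraction of peptides in beta-sheets")
  } else if (which == "graph") {
    if (is.null(frame)) frame <- max(fm$frame)
    sec <- utils::read.csv(file.path(outDir, "secstruct.csv"))
    nmol <- max(sec$molecule)
    th <- 2 * pi * (seq_len(nmol) - 1L) / nmol
    x <- cos(th); y <- sin(th)
    plot(x, y, pch = 21, bg = "grey80", cex = 2.2, axes = FALSE,
         xlab = "", ylab = "", xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3),
         main = paste("interaction graph, frame", frame))
    e <- edges[edges$frame == frame, , drop = FALSE]
    if (nrow(e))
      segments(x[e$p], y[e$p], x[e$q], y[e$q],
               col = edgeCol(e$orientation),
               lwd = 0.5 + 2 * e$nContacts / max(e$nContacts))
    graphics::text(1.15 * x, 1.15 * y, labels = seq_len(nmol), cex = 0.8)
  } else if (which == "frame_aggregates") {
    if (is.null(frame)) frame <- max(fm$frame)
    cl <- utils::read.csv(file.path(outDir, "clusters.csv"))
    cl <- cl[cl$frame == frame, , drop = FALSE]
    cols <- c(P = "forestgreen", AP = "blue", mixed = "purple",
              none = "grey70")
    graphics::barplot(cl$size, names.arg = cl$cluster,
                      col = cols[cl$orientation],
                      xlab = "cluster", ylab = "molecules",
                      main = paste("aggregates, frame", frame))
  } else {  # shift3d
    sp <- utils::read.table(file.path(outDir, "shift_profile.tsv"),
                            header = TRUE, sep = "\t")
    graphics::par(mfrow = c(1, 3))
    for (cls in c("P", "AP+", "AP-")) {
      s <- sp[sp$class == cls, , drop = FALSE]
      if (nrow(s))
        plot(s$frame, s$shift, cex = 0.5 + s$count / max(s$count) * 2,
             pch = 16, xlab = "frame", ylab = "shift", main = cls)
      else
        plot(0, 0, type = "n", xlab = "frame", ylab = "shift", main = cls)
    }
  }
  invisible(file)
}
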
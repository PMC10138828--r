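ANGSTROM_PER_NM <- 10

## chain identifier pool for the PDB writer
.chainPool <- c(LETTERS, letters, as.character(0:9))

#' Load an MD system and optional trajectory
#'
#' Reads a structure file (PDB or GRO) and, optionally, a trajectory (DCD
#' or multi-model PDB), selects atoms by name and reduces every residue to
#' a single point: the centroid of its selected atoms. Under the default
#' MARTINI backbone selection `"BB"` (one bead per residue) or the
#' atomistic `"CA"` selection this point is the bead / C-alpha position
#' itself. All coordinates are carried in Angstrom; GRO files (nm) are
#' converted on read.
#'
#' One molecule corresponds to one chain: a new molecule starts whenever
#' the chain identifier changes or the residue numbering restarts
#' (decreases), the convention used by MD packages that write consecutive
#' molecules with restarting residue numbers. Within a molecule the point
#' order follows the residue order in the file.
#'
#' A multi-model PDB given as `configPath` contributes all of its models
#' as frames. XTC/TRR trajectories are not readable by this package;
#' convert them to DCD or multi-model PDB first (e.g. with
#' `gmx trjconv` or `mdconvert`).
#'
#' @param configPath path of the structure file (.pdb or .gro).
#' @param trajPath optional path of the trajectory (.dcd or multi-model
#'   .pdb) with the same atom count as the structure.
#' @param selection character vector of atom names to keep
#'   (default `"BB"`).
#' @return an [MDSession-class].
#' @examples
#' sys <- makeSystem(synthSpec(motifs = rep("helix", 2), nRes = 8))
#' pdb <- tempfile(fileext = ".pdb")
#' writeFramesPDB(list(sys$frame), pdb)
#' sess <- loadSession(pdb)
#' nFrames(sess)
#' @export
loadSession <- function(configPath, trajPath = NULL, selection = "BB") {
  if (!file.exists(configPath))
    stop("structure file not found: ", configPath)
  ext <- tolower(tools::file_ext(configPath))
  topo <- switch(ext,
    pdb = .readPDBTopology(configPath),
    gro = .readGROTopology(configPath),
    stop("unrecognized structure format '", ext, "' for: ", configPath))

  sel <- topo$atoms$name %in% selection
  if (!any(sel))
    stop("selection {", paste(selection, collapse = ", "),
         "} matches zero atoms in ", configPath)

  atoms <- topo$atoms[sel, , drop = FALSE]
  ## molecule break: chain change or residue numbering restart
  molId <- integer(nrow(atoms))
  cur <- 1L
  molId[1] <- 1L
  if (nrow(atoms) > 1L) for (a in 2:nrow(atoms)) {
    newChain <- !identical(atoms$chain[a], atoms$chain[a - 1L])
    restart  <- atoms$resno[a] < atoms$resno[a - 1L]
    if (newChain || restart) cur <- cur + 1L
    molId[a] <- cur
  }
  ## residue groups: consecutive runs of equal resno within a molecule
  resKey <- cumsum(c(1L, as.integer(
    diff(atoms$resno) != 0L | diff(molId) != 0L)))

  frames <- topo$xyz
  if (!is.null(trajPath)) {
    if (!file.exists(trajPath))
      stop("trajectory file not found: ", trajPath)
    text <- tolower(tools::file_ext(trajPath))
    traj <- switch(text,
      dcd = .readDCDFrames(trajPath),
      pdb = .readPDBTopology(trajPath)$xyz,
      xtc = ,
      trr = stop("no reader for .", text, " trajectories is available; ",
                 "convert to DCD or multi-model PDB"),
      stop("unrecognized trajectory format '", text, "' for: ", trajPath))
    nat <- nrow(traj[[1]])
    if (nat != nrow(topo$atoms))
      stop("trajectory atom count (", nat, ") does not match topology (",
           nrow(topo$atoms), ")")
    frames <- traj
  }

  selRows <- which(sel)
  molLens <- vapply(split(resKey, molId),
                    function(r) length(unique(r)), integer(1))
  names(molLens) <- NULL
  seqs <- lapply(split(seq_len(nrow(atoms)), molId), function(rows) {
    first <- rows[!duplicated(resKey[rows])]
    atoms$resname[first]
  })
  names(seqs) <- NULL

  frameList <- lapply(frames, function(xyz) {
    xyzSel <- xyz[selRows, , drop = FALSE]
    if (any(!is.finite(xyzSel)))
      stop("non-finite coordinates among selected atoms")
    com <- rowsum(xyzSel, group = resKey) /
      as.vector(table(resKey)[as.character(sort(unique(resKey)))])
    molOfRes <- molId[!duplicated(resKey)]
    lapply(split(seq_len(nrow(com)), molOfRes),
           function(rows) unname(com[rows, , drop = FALSE]))
  })
  frameList <- lapply(frameList, function(fl) { names(fl) <- NULL; fl })

  new("MDSession",
      configPath = configPath,
      trajPath = if (is.null(trajPath)) NA_character_ else trajPath,
      selection = selection,
      nFrames = length(frameList),
      frames = frameList,
      molLengths = unname(as.integer(molLens)),
      sequences = seqs)
}

## parse a PDB (possibly multi-model) through bio3d
.readPDBTopology <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB file ", path, ": ",
                         conditionMessage(e)))
  atoms <- data.frame(name = pdb$atom$elety,
                      resname = pdb$atom$resid,
                      chain = ifelse(is.na(pdb$atom$chain), "",
                                     pdb$atom$chain),
                      resno = pdb$atom$resno,
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(f)
    matrix(xyz[f, ], ncol = 3, byrow = TRUE))
  list(atoms = atoms, xyz = frames)
}

## minimal fixed-width GRO parser (no reader for this format ships with
## the R toolchain); coordinates converted nm -> Angstrom
.readGROTopology <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("cannot parse GRO file ", path, ": too short")
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat) || length(lines) < nat + 3L)
    stop("cannot parse GRO file ", path, ": bad atom count line")
  body <- lines[3:(2 + nat)]
  resno <- as.integer(substr(body, 1, 5))
  resname <- trimws(substr(body, 6, 10))
  name <- trimws(substr(body, 11, 15))
  x <- as.numeric(substr(body, 21, 28))
  y <- as.numeric(substr(body, 29, 36))
  z <- as.numeric(substr(body, 37, 44))
  if (any(is.na(resno)) || any(is.na(x + y + z)))
    stop("cannot parse GRO file ", path, ": malformed atom record")
  atoms <- data.frame(name = name, resname = resname, chain = "",
                      resno = resno, stringsAsFactors = FALSE)
  xyz <- cbind(x, y, z) * ANGSTROM_PER_NM
  list(atoms = atoms, xyz = list(unname(xyz)))
}

.readDCDFrames <- function(path) {
  xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse DCD file ", path, ": ",
                         conditionMessage(e)))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(f)
    matrix(xyz[f, ], ncol = 3, byrow = TRUE))
}

#' Summarize system composition
#'
#' Reports how many molecules the session contains, their residue counts
#' and the per-length molecule tally, mirroring the exploratory step that
#' precedes any per-frame analysis.
#'
#' @param session an [MDSession-class].
#' @return a [SystemSummary-class].
#' @export
exploreSystem <- function(session) {
  stopifnot(is(session, "MDSession"))
  lens <- molLengths(session)
  keep <- lens > 0L
  if (!all(keep)) {
    warning(sum(!keep), " molecule(s) with zero selected points excluded")
    lens <- lens[keep]
  }
  tab <- table(lens)
  lenDict <- as.integer(tab)
  names(lenDict) <- names(tab)
  new("SystemSummary",
      peptideLengthList = as.integer(lens),
      lenDict = lenDict,
      sequences = session@sequences[keep])
}

#' Sample trajectory frames at a fixed interval
#'
#' Returns frames `0, interval, 2*interval, ...` (0-based); frame 0 is
#' always included. An interval larger than the trajectory yields the
#' first frame only.
#'
#' @param session an [MDSession-class].
#' @param interval positive integer stride.
#' @return list of [SystemFrame-class] objects in frame order.
#' @export
sampleFrames <- function(session, interval = 1L) {
  stopifnot(is(session, "MDSession"))
  interval <- as.integer(interval)
  if (is.na(interval) || interval <= 0L)
    stop("interval must be a positive integer")
  idx <- seq.int(1L, session@nFrames, by = interval)
  lapply(idx, function(i)
    new("SystemFrame", frameIndex = i - 1L,
        coords = session@frames[[i]],
        molLengths = session@molLengths))
}

#' Write frames as a (multi-model) PDB file
#'
#' Writes one MODEL block per frame, one chain per molecule and one
#' `"BB"` pseudo-atom per residue, so that a synthetic or reduced system
#' round-trips through [loadSession()]. Coordinates are written at the
#' 0.001 Angstrom precision of the PDB format.
#'
#' @param frames a [SystemFrame-class] or a list of them (equal molecule
#'   layout).
#' @param path output file path.
#' @param resname residue name to write (default `"ALA"`).
#' @param atomName atom name to write (default `"BB"`).
#' @return `path`, invisibly.
#' @export
writeFramesPDB <- function(frames, path, resname = "ALA", atomName = "BB") {
  if (is(frames, "SystemFrame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L, all(vapply(frames, is, logical(1),
                                             "SystemFrame")))
  nmol <- length(frames[[1]]@coords)
  if (nmol > length(.chainPool))
    stop("PDB writer supports at most ", length(.chainPool), " molecules")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    fr <- frames[[f]]
    for (m in seq_len(nmol)) {
      xyz <- fr@coords[[m]]
      for (r in seq_len(nrow(xyz))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, atomName, resname, .chainPool[m], r,
          xyz[r, 1], xyz[r, 2], xyz[r, 3], 1, 0), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
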
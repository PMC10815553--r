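#' @include AllClasses.R
NULL

## Multi-model PDB is the one required trajectory format: text, portable,
## and exactly what structure viewers export. bio3d does the parsing; a
## cheap pre-scan of the MODEL/ENDMDL blocks produces the structured
## per-model errors the contract requires (bio3d takes atom records from
## the first model only, so it cannot notice a later model going short).

.scanModels <- function(lines) {
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L) {
    atoms <- grep("^(ATOM|HETATM)", lines)
    return(list(nModels = if (length(atoms)) 1L else 0L,
                sig = list(lines[atoms])))
  }
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed trajectory PDB: unpaired MODEL/ENDMDL records")
  sig <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    blk <- lines[seq(starts[k] + 1L, ends[k] - 1L)]
    sig[[k]] <- blk[grepl("^(ATOM|HETATM)", blk)]
  }
  list(nModels = length(starts), sig = sig)
}

#' Read a multi-model PDB trajectory
#'
#' Reads MODEL/ENDMDL frames of one receptor-ligand complex into a
#' [Trajectory-class]. Every model must contain the same atoms in the same
#' order; a model that deviates is reported by model number. A file without
#' MODEL records is read as a single frame.
#'
#' @param path PDB file path.
#' @param frameInterval time per frame in ns (PDB carries no time axis).
#' @return A [Trajectory-class]; frame order follows MODEL order,
#'   coordinates in Angstrom.
#' @examples
#' tr <- makeToyGpcr(state = "inactive", nFrames = 2)$trajectory
#' f <- tempfile(fileext = ".pdb")
#' writeTrajectory(tr, f)
#' tr2 <- readTrajectory(f, frameInterval = frameInterval(tr))
#' nFrames(tr2)
#' @export
readTrajectory <- function(path, frameInterval = 0.1) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  scan <- .scanModels(lines)
  if (scan$nModels == 0L)
    stop("empty trajectory: no ATOM/HETATM records in ", path)
  counts <- lengths(scan$sig)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf(
      "inconsistent atom count across models: model %d has %d atoms, model 1 has %d",
      bad, counts[bad], counts[1]))
  }
  # atom identity (name + residue number columns) must agree across models
  key <- function(s) paste(substr(s, 13, 16), substr(s, 23, 26))
  if (scan$nModels > 1L) {
    k1 <- key(scan$sig[[1]])
    for (m in 2:scan$nModels)
      if (!identical(key(scan$sig[[m]]), k1))
        stop(sprintf("model %d lists different atoms than model 1", m))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nA <- nrow(pdb$atom)
  arr <- array(NA_real_, c(nrow(xyz), nA, 3))
  arr[, , 1] <- xyz[, seq(1, 3 * nA, by = 3), drop = FALSE]
  arr[, , 2] <- xyz[, seq(2, 3 * nA, by = 3), drop = FALSE]
  arr[, , 3] <- xyz[, seq(3, 3 * nA, by = 3), drop = FALSE]
  element <- pdb$atom$elesy
  blank <- is.na(element) | element == ""
  # fall back to the first letter of the atom name when the element column
  # is absent (common in minimised/converted PDBs)
  element[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", pdb$atom$elety[blank])
  atoms <- data.frame(
    name = pdb$atom$elety, element = toupper(element),
    resid = pdb$atom$resno, resname = pdb$atom$resid,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    stringsAsFactors = FALSE)
  Trajectory(arr, atoms, frameInterval)
}

#' Write a trajectory as a multi-model PDB
#'
#' Inverse of [readTrajectory()]: coordinates at PDB precision (3 decimals).
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  at <- traj@atoms
  nF <- nFrames(traj); nA <- nAtoms(traj)
  xyz <- matrix(NA_real_, nF, 3 * nA)
  xyz[, seq(1, 3 * nA, by = 3)] <- traj@coords[, , 1]
  xyz[, seq(2, 3 * nA, by = 3)] <- traj@coords[, , 2]
  xyz[, seq(3, 3 * nA, by = 3)] <- traj@coords[, , 3]
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                   resno = at$resid, resid = at$resname, eleno = seq_len(nA),
                   elety = at$name, chain = at$chain, elesy = at$element)
  invisible(path)
}
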
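#' @include AllGenerics.R
NULL

## Central containers. Validity methods enforce the structural contracts the
## downstream analyses rely on; all construction goes through the exported
## constructor functions, all access through accessor generics.

#' Trajectory: frames x atoms Cartesian coordinates with atom metadata
#'
#' Holds a molecular-dynamics trajectory of one receptor-ligand complex:
#' an \code{n_frames x n_atoms x 3} coordinate array in Angstrom, a per-atom
#' metadata table and the time per frame in nanoseconds.
#'
#' @slot coords numeric array \code{(n_frames, n_atoms, 3)}, Angstrom.
#' @slot atoms data.frame with columns \code{name} (PDB atom name),
#'   \code{element}, \code{resid} (author residue number, 1-based, verbatim
#'   from the PDB), \code{resname}, \code{chain}, \code{heavy} (logical).
#' @slot frameInterval time per frame in ns (> 0).
#'
#' @seealso [readTrajectory()], [writeTrajectory()], [Trajectory()]
#' @exportClass Trajectory
setClass("Trajectory",
  representation(coords = "array", atoms = "data.frame",
                 frameInterval = "numeric"))

setValidity("Trajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be an (n_frames, n_atoms, 3) array")
  else {
    if (d[1] < 1L) msg <- c(msg, "need at least one frame")
    if (d[2] < 1L) msg <- c(msg, "need at least one atom")
    if (nrow(object@atoms) != d[2])
      msg <- c(msg, "atom metadata rows must match n_atoms")
  }
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite")
  need <- c("name", "element", "resid", "resname", "chain", "heavy")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atom metadata must have columns:",
                        paste(need, collapse = ", ")))
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number (ns)")
  if (length(msg)) msg else TRUE
})

#' Construct a Trajectory
#'
#' @param coords numeric array \code{(n_frames, n_atoms, 3)} in Angstrom.
#' @param atoms per-atom data.frame (see [Trajectory-class]); a \code{heavy}
#'   column is derived from \code{element} when absent.
#' @param frameInterval time per frame in ns.
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(coords, atoms, frameInterval = 0.1) {
  if (is.null(atoms$heavy))
    atoms$heavy <- !(toupper(atoms$element) %in% c("H", "D"))
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  new("Trajectory", coords = coords, atoms = atoms,
      frameInterval = as.numeric(frameInterval))
}

#' BWMapping: Ballesteros-Weinstein generic-number table
#'
#' Bidirectional map between generic numbers (\code{"helix.position"}
#' strings, e.g. \code{"3.32"}) and sequence residue identifiers. Generic
#' numbers are kept as strings throughout: \code{"6.48"} and \code{"6.480"}
#' are distinct labels, never floats.
#'
#' @slot table data.frame with columns \code{generic} (character),
#'   \code{helix} (integer 1-7), \code{resid} (integer), \code{resname}
#'   (expected one-letter code, may be \code{NA}).
#'
#' @seealso [readBWMapping()], [resolveBW()], [helixOf()]
#' @exportClass BWMapping
setClass("BWMapping", representation(table = "data.frame"))

setValidity("BWMapping", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("generic", "helix", "resid", "resname")
  if (!all(need %in% names(tb)))
    return(paste("mapping table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$generic))
    msg <- c(msg, "generic numbers must be unique")
  if (anyDuplicated(tb$resid))
    msg <- c(msg, "residue ids must be unique")
  pre <- suppressWarnings(as.integer(sub("\\..*$", "", tb$generic)))
  if (any(is.na(pre)) || !all(pre == tb$helix))
    msg <- c(msg, "helix index must equal the integer part of the generic number")
  if (length(msg)) msg else TRUE
})

#' Construct a BWMapping
#'
#' @param generic character vector of \code{"helix.position"} labels.
#' @param resid integer residue sequence ids.
#' @param resname optional expected one-letter residue codes.
#' @param helix optional helix indices; derived from \code{generic} if missing.
#' @return A [BWMapping-class] object.
#' @export
BWMapping <- function(generic, resid, resname = NA_character_, helix = NULL) {
  generic <- as.character(generic)
  if (is.null(helix)) helix <- as.integer(sub("\\..*$", "", generic))
  tb <- data.frame(generic = generic, helix = as.integer(helix),
                   resid = as.integer(resid),
                   resname = as.character(resname),
                   stringsAsFactors = FALSE)
  new("BWMapping", table = tb)
}

#' DescriptorSeries: one per-frame scalar descriptor
#'
#' @slot name descriptor identifier (e.g. \code{"edry_ionic"}, \code{"rmsd"}).
#' @slot values per-frame values in Angstrom, all finite.
#' @slot frameInterval ns per frame.
#' @exportClass DescriptorSeries
setClass("DescriptorSeries",
  representation(name = "character", values = "numeric",
                 frameInterval = "numeric"))

setValidity("DescriptorSeries", function(object) {
  msg <- character()
  if (length(object@values) < 1L || !all(is.finite(object@values)))
    msg <- c(msg, "values must be non-empty and finite")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number")
  if (length(msg)) msg else TRUE
})

DescriptorSeries <- function(name, values, frameInterval) {
  new("DescriptorSeries", name = name, values = as.numeric(values),
      frameInterval = as.numeric(frameInterval))
}

#' CorrelationNetwork: residue-ligand dynamical network
#'
#' Nodes are protein residues (anchored at their Calpha) plus one ligand
#' node (anchored at its basic nitrogen). \code{C} holds motion
#' correlations, \code{mask} the persistent-contact criterion, and \code{W}
#' edge weights \eqn{w_{ij} = -\log|C_{ij}|} for admitted edges (\code{NA}
#' where there is no edge).
#'
#' @slot nodes data.frame with columns \code{id} (character), \code{kind}
#'   (\code{"residue"} or \code{"ligand"}), \code{resid}, \code{anchor}
#'   (atom index of Calpha / basic nitrogen).
#' @slot cor symmetric correlation matrix, unit diagonal, entries in [-1, 1].
#' @slot mask symmetric logical contact matrix.
#' @slot W symmetric edge-weight matrix, non-negative, NA off-edges.
#' @exportClass CorrelationNetwork
setClass("CorrelationNetwork",
  representation(nodes = "data.frame", cor = "matrix", mask = "matrix",
                 W = "matrix"))

setValidity("CorrelationNetwork", function(object) {
  n <- nrow(object@nodes)
  msg <- character()
  if (anyDuplicated(object@nodes$id)) msg <- c(msg, "node ids must be unique")
  for (nm in c("cor", "mask", "W")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n)))
      msg <- c(msg, sprintf("%s must be %d x %d", nm, n, n))
  }
  if (length(msg)) return(msg)
  if (max(abs(object@cor - t(object@cor))) > 1e-9)
    msg <- c(msg, "C must be symmetric")
  if (any(abs(object@cor) > 1 + 1e-9))
    msg <- c(msg, "|C| entries must be <= 1")
  if (max(abs(diag(object@cor) - 1)) > 1e-9)
    msg <- c(msg, "C must have unit diagonal")
  if (!isTRUE(all(object@mask == t(object@mask))))
    msg <- c(msg, "contact mask must be symmetric")
  w <- object@W[!is.na(object@W)]
  if (length(w) && any(w < -1e-12))
    msg <- c(msg, "all edge weights must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PathSet: optimal and suboptimal communication pathways
#'
#' @slot source,sink node ids.
#' @slot paths list of node-id character vectors, sorted by distance then
#'   node order; optimal path(s) first.
#' @slot distances total edge weight per path (dimensionless).
#' @slot optimalDistance weight of the optimal path (\code{Inf} when the
#'   sink is unreachable).
#' @slot offset the suboptimal-path offset used.
#' @slot nOptimal \code{n}: residue/node count of the optimal pathway.
#' @slot nPaths \code{N}: number of (sub)optimal paths found.
#' @slot disconnected TRUE when no path exists.
#' @exportClass PathSet
setClass("PathSet",
  representation(source = "character", sink = "character", paths = "list",
                 distances = "numeric", optimalDistance = "numeric",
                 offset = "numeric", nOptimal = "integer",
                 nPaths = "integer", disconnected = "logical"))

setValidity("PathSet", function(object) {
  msg <- character()
  if (length(object@paths) != length(object@distances))
    msg <- c(msg, "one distance per path required")
  if (object@nPaths != length(object@paths))
    msg <- c(msg, "nPaths must equal the number of listed paths")
  for (p in object@paths) {
    if (length(p) && (p[1] != object@source || p[length(p)] != object@sink))
      msg <- c(msg, "every path must start at source and end at sink")
    if (anyDuplicated(p)) msg <- c(msg, "paths must be simple")
  }
  if (!object@disconnected && length(object@distances)) {
    if (any(object@distances < object@optimalDistance - 1e-9))
      msg <- c(msg, "no path may be shorter than the optimal distance")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' PIEDATable: per-residue pair interaction energy decomposition
#'
#' One record per receptor residue of one complex: total pair interaction
#' energy (PIE) and its electrostatic (\code{e_es}), exchange-repulsion
#' (\code{e_ex}), charge-transfer (\code{e_ct}) and dispersion
#' (\code{e_disp}) components, the Gibbs solvation term (\code{dg_solv}),
#' all kcal/mol, plus the minimum ligand-residue contact distance in
#' Angstrom (\code{NA} = not determined).
#'
#' @slot complexId complex identifier.
#' @slot ligandId ligand identifier.
#' @slot classLabel \code{"agonist"}, \code{"antagonist"} or \code{"unknown"}.
#' @slot records data.frame with columns \code{residue_id},
#'   \code{residue_name}, \code{pie}, \code{e_es}, \code{e_ex}, \code{e_ct},
#'   \code{e_disp}, \code{dg_solv}, \code{min_dist}.
#' @seealso [readPiedaTable()], [polarityShare()], [classifyInteraction()]
#' @exportClass PIEDATable
setClass("PIEDATable",
  representation(complexId = "character", ligandId = "character",
                 classLabel = "character", records = "data.frame"))

setValidity("PIEDATable", function(object) {
  msg <- character()
  rec <- object@records
  need <- c("residue_id", "residue_name", "pie", "e_es", "e_ex", "e_ct",
            "e_disp", "dg_solv", "min_dist")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$residue_id))
    msg <- c(msg, "residue ids must be unique within a table")
  en <- as.matrix(rec[c("pie", "e_es", "e_ex", "e_ct", "e_disp", "dg_solv")])
  if (!all(is.finite(en)))
    msg <- c(msg, "all energy fields must be finite")
  md <- rec$min_dist
  if (any(!is.na(md) & md <= 0))
    msg <- c(msg, "min_dist must be > 0 or missing (NA)")
  if (!object@classLabel %in% c("agonist", "antagonist", "unknown"))
    msg <- c(msg, "classLabel must be agonist, antagonist or unknown")
  if (length(msg)) msg else TRUE
})

#' Construct a PIEDATable
#'
#' @param records data.frame of per-residue records (see
#'   [PIEDATable-class]).
#' @param complexId,ligandId identifiers.
#' @param classLabel functional class of the ligand.
#' @return A [PIEDATable-class] object.
#' @export
PIEDATable <- function(records, complexId = "complex", ligandId = "ligand",
                       classLabel = "unknown") {
  records$residue_id <- as.integer(records$residue_id)
  rownames(records) <- NULL
  new("PIEDATable", complexId = complexId, ligandId = ligandId,
      classLabel = classLabel, records = records)
}
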
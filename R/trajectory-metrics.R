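#' @include AllClasses.R bw-mapping.R
NULL

## internal: coords array -> bio3d-style frames x 3N matrix for `sel` atoms
.xyzMatrix <- function(traj, sel) {
  nF <- nFrames(traj)
  nS <- length(sel)
  m <- matrix(NA_real_, nF, 3 * nS)
  m[, seq(1, 3 * nS, by = 3)] <- traj@coords[, sel, 1, drop = FALSE]
  m[, seq(2, 3 * nS, by = 3)] <- traj@coords[, sel, 2, drop = FALSE]
  m[, seq(3, 3 * nS, by = 3)] <- traj@coords[, sel, 3, drop = FALSE]
  m
}

.resolveSelection <- function(traj, selection) {
  at <- traj@atoms
  sel <- if (is.null(selection)) which(at$name == "CA")
         else if (is.logical(selection)) which(selection)
         else as.integer(selection)
  if (length(sel) == 0L)
    stop("atom selection is empty")
  sel
}

#' Per-frame RMSD after optimal rigid superposition
#'
#' Root-mean-square deviation of selected atoms of every frame from a
#' reference frame, after Kabsch superposition of the selection onto the
#' reference (so the series is invariant under rigid-body motion of whole
#' frames).
#'
#' @param traj a [Trajectory-class].
#' @param reference reference frame index (default 1).
#' @param selection atom indices or logical vector; default all Calpha.
#' @return A [DescriptorSeries-class] named \code{"rmsd"}, Angstrom.
#' @export
rmsdSeries <- function(traj, reference = 1L, selection = NULL) {
  stopifnot(is(traj, "Trajectory"))
  sel <- .resolveSelection(traj, selection)
  m <- .xyzMatrix(traj, sel)
  v <- bio3d::rmsd(m[reference, ], m, fit = TRUE)
  DescriptorSeries("rmsd", v, traj@frameInterval)
}

#' Per-atom RMSF about the mean structure
#'
#' Each frame's selection is first superposed (Kabsch) onto the reference
#' frame, the mean structure of the fitted ensemble is computed, the
#' ensemble is re-fitted onto that mean, and the root-mean-square
#' fluctuation of each selected atom about its mean position is returned
#' (population formula, i.e. dividing by the number of frames).
#'
#' @param traj a [Trajectory-class] with at least two frames.
#' @param selection atom indices or logical vector; default all Calpha.
#' @param fit superpose frames before measuring fluctuations? Set
#'   \code{FALSE} for trajectories that are already aligned, in which case
#'   the RMSF of an atom is exactly the population standard deviation of
#'   its positions about their mean.
#' @return data.frame with columns \code{atom} (index into the trajectory),
#'   \code{resid}, \code{name}, \code{rmsf} (Angstrom).
#' @export
rmsfSeries <- function(traj, selection = NULL, fit = TRUE) {
  stopifnot(is(traj, "Trajectory"))
  if (nFrames(traj) < 2L)
    stop("RMSF requires at least two frames")
  sel <- .resolveSelection(traj, selection)
  m <- .xyzMatrix(traj, sel)
  idx <- seq_len(ncol(m))
  fitted <- if (fit) {
    f1 <- suppressWarnings(bio3d::fit.xyz(m[1, ], m,
                                          fixed.inds = idx, mobile.inds = idx))
    mu <- colMeans(f1)
    suppressWarnings(bio3d::fit.xyz(mu, f1,
                                    fixed.inds = idx, mobile.inds = idx))
  } else m
  dev2 <- sweep(fitted, 2, colMeans(fitted))^2
  perAtom <- dev2[, seq(1, ncol(m), 3), drop = FALSE] +
             dev2[, seq(2, ncol(m), 3), drop = FALSE] +
             dev2[, seq(3, ncol(m), 3), drop = FALSE]
  data.frame(atom = sel, resid = traj@atoms$resid[sel],
             name = traj@atoms$name[sel],
             rmsf = sqrt(colMeans(perAtom)))
}

.descriptorNames <- c("lbs_tightening", "npxxy_hbond", "npxxy_ca",
                      "pif_36", "pif_56", "edry_ionic")

## atom indices of residue `resid` whose names are in `names`
.atomsOf <- function(traj, resid, names) {
  which(traj@atoms$resid == resid & traj@atoms$name %in% names)
}

.oneAtom <- function(traj, resid, name, what) {
  i <- .atomsOf(traj, resid, name)
  if (length(i) != 1L)
    stop(sprintf("residue %d: expected one '%s' atom for %s, found %d",
                 resid, paste(name, collapse = "/"), what, length(i)))
  i
}

## per-frame distance between single atoms i, j
.atomDist <- function(traj, i, j) {
  d <- traj@coords[, i, , drop = FALSE] - traj@coords[, j, , drop = FALSE]
  sqrt(rowSums(matrix(d, nrow = nFrames(traj))^2))
}

## per-frame minimum distance between two atom groups
.minGroupDist <- function(traj, gi, gj) {
  best <- rep(Inf, nFrames(traj))
  for (i in gi) for (j in gj) best <- pmin(best, .atomDist(traj, i, j))
  best
}

#' Activation-motif distance descriptors
#'
#' Per-frame geometric descriptors of the class-A GPCR activation
#' microswitches, addressed through Ballesteros-Weinstein generic numbers:
#' \describe{
#'   \item{lbs_tightening}{Calpha(5.46)-Calpha(7.42): tightening of the
#'     ligand-binding site upon activation.}
#'   \item{npxxy_hbond}{side-chain hydroxyl O of 3.39 to the nearest
#'     side-chain amide hydrogen of 7.49 (donor-acceptor distance of the
#'     potential S-N hydrogen bond); falls back to the O...N distance with
#'     a warning when the structure carries no hydrogens.}
#'   \item{npxxy_ca}{Calpha(3.44)-Calpha(7.53).}
#'   \item{pif_36, pif_56}{Calpha(3.40)-Calpha(6.44) and
#'     Calpha(5.50)-Calpha(6.44): the P-I-F switch triangle.}
#'   \item{edry_ionic}{minimum distance between the guanidinium heavy atoms
#'     (NH1, NH2, NE, CZ) of R3.50 and the carboxylate heavy atoms
#'     (OE1, OE2, CD) of E6.30: the ionic-lock of the E/DRY motif.}
#' }
#'
#' @param traj a [Trajectory-class].
#' @param mapping a [BWMapping-class] resolving the generic numbers.
#' @param descriptor one of \code{"lbs_tightening"}, \code{"npxxy_hbond"},
#'   \code{"npxxy_ca"}, \code{"pif_36"}, \code{"pif_56"},
#'   \code{"edry_ionic"}.
#' @return A [DescriptorSeries-class] in Angstrom.
#' @export
motifDistance <- function(traj, mapping, descriptor) {
  stopifnot(is(traj, "Trajectory"), is(mapping, "BWMapping"))
  descriptor <- match.arg(descriptor, .descriptorNames)
  ca <- function(bw) .oneAtom(traj, resolveBW(mapping, bw), "CA", descriptor)
  v <- switch(descriptor,
    lbs_tightening = .atomDist(traj, ca("5.46"), ca("7.42")),
    npxxy_ca = .atomDist(traj, ca("3.44"), ca("7.53")),
    pif_36 = .atomDist(traj, ca("3.40"), ca("6.44")),
    pif_56 = .atomDist(traj, ca("5.50"), ca("6.44")),
    npxxy_hbond = {
      rSer <- resolveBW(mapping, "3.39")
      rAsn <- resolveBW(mapping, "7.49")
      og <- .oneAtom(traj, rSer, "OG", descriptor)
      hs <- .atomsOf(traj, rAsn, c("HD21", "HD22", "1HD2", "2HD2"))
      if (length(hs)) {
        .minGroupDist(traj, og, hs)
      } else {
        nd2 <- .oneAtom(traj, rAsn, "ND2", descriptor)
        warning("npxxy_hbond: no side-chain amide hydrogens on residue ",
                rAsn, "; falling back to the O...N distance")
        .atomDist(traj, og, nd2)
      }
    },
    edry_ionic = {
      rArg <- resolveBW(mapping, "3.50")
      rGlu <- resolveBW(mapping, "6.30")
      gi <- .atomsOf(traj, rArg, c("NH1", "NH2", "NE", "CZ"))
      gj <- .atomsOf(traj, rGlu, c("OE1", "OE2", "CD"))
      if (!length(gi))
        stop(sprintf("residue %d: no guanidinium atoms (NH1/NH2/NE/CZ) for edry_ionic", rArg))
      if (!length(gj))
        stop(sprintf("residue %d: no carboxylate atoms (OE1/OE2/CD) for edry_ionic", rGlu))
      .minGroupDist(traj, gi, gj)
    })
  DescriptorSeries(descriptor, v, traj@frameInterval)
}

#' Reduce a descriptor series to fixed-length block medians
#'
#' Splits the series into contiguous, non-overlapping blocks of
#' \code{blockLength} ns anchored at t = 0 and takes the median of each
#' full block (even counts: midpoint of the two central values). A trailing
#' partial block is dropped with a message.
#'
#' @param series a [DescriptorSeries-class].
#' @param blockLength block length in ns (default 10).
#' @return data.frame with columns \code{block}, \code{start_ns},
#'   \code{end_ns}, \code{median}.
#' @export
blockMedians <- function(series, blockLength = 10) {
  stopifnot(is(series, "DescriptorSeries"), blockLength > 0)
  v <- series@values
  dt <- series@frameInterval
  total <- length(v) * dt
  nBlocks <- floor(total / blockLength + 1e-9)
  if (nBlocks < 1L)
    stop(sprintf("series spans %.4g ns, shorter than one %.4g ns block",
                 total, blockLength))
  # frame i (1-based) is sampled at t = (i-1)*dt and belongs to block
  # floor(t / blockLength) + 1
  blk <- floor((seq_along(v) - 1) * dt / blockLength + 1e-9) + 1L
  keep <- blk <= nBlocks
  if (any(!keep))
    message(sum(!keep), " trailing frame(s) beyond the last full block dropped")
  med <- vapply(seq_len(nBlocks), function(b) median(v[keep & blk == b]), 0)
  data.frame(block = seq_len(nBlocks),
             start_ns = (seq_len(nBlocks) - 1) * blockLength,
             end_ns = seq_len(nBlocks) * blockLength,
             median = med)
}

#' Read activation-state region rectangles from YAML
#'
#' The config lists, per descriptor pair, closed rectangles in Angstrom for
#' the \code{active} and \code{inactive} states. These reference regions
#' are user configuration: the shipped example
#' (\code{inst/extdata/regions.yaml}) is illustrative, not canonical.
#'
#' @param path YAML file path.
#' @return List of pair entries (\code{x}, \code{y}, \code{regions}).
#' @export
readRegions <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pairs)) stop("regions config must have a 'pairs' list")
  lapply(cfg$pairs, function(p) {
    # YAML 1.1 reads a bare `y:` key as the boolean TRUE; undo that
    names(p)[names(p) == "TRUE"] <- "y"
    p
  })
}

#' Look up the region rectangles for a descriptor pair
#'
#' @param regions list returned by [readRegions()].
#' @param x,y descriptor names.
#' @return Named list of rectangles \code{(xmin, xmax, ymin, ymax)} per
#'   state label, or an error when the pair is not configured.
#' @export
regionsFor <- function(regions, x, y) {
  for (p in regions)
    if (identical(p$x, x) && identical(p$y, y))
      return(lapply(p$regions, function(r)
        unlist(r)[c("xmin", "xmax", "ymin", "ymax")]))
  stop(sprintf("no region rectangles configured for pair (%s, %s)", x, y))
}

.rectanglesOverlap <- function(a, b) {
  a["xmin"] <= b["xmax"] && b["xmin"] <= a["xmax"] &&
  a["ymin"] <= b["ymax"] && b["ymin"] <= a["ymax"]
}

#' Classify block medians against activation-state regions
#'
#' Each block's \code{(median_x, median_y)} point is labelled by the
#' (closed) rectangle containing it — \code{"active"} or
#' \code{"inactive"} — and \code{"intermediate"} when it lies in neither.
#' Points on a rectangle edge belong to that region.
#'
#' @param x,y block-median data.frames from [blockMedians()] (equal block
#'   counts).
#' @param regions named list of rectangles per state label, each
#'   \code{c(xmin, xmax, ymin, ymax)}; rectangles of different labels must
#'   not overlap.
#' @return List with \code{labels} (per block) and \code{fractions}
#'   (named: active, inactive, intermediate; summing to 1).
#' @export
classifyBlocks <- function(x, y, regions) {
  if (nrow(x) != nrow(y))
    stop(sprintf("block count mismatch: x has %d blocks, y has %d",
                 nrow(x), nrow(y)))
  stopifnot(all(c("active", "inactive") %in% names(regions)))
  if (.rectanglesOverlap(regions$active, regions$inactive))
    stop("active and inactive rectangles overlap")
  lab <- vapply(seq_len(nrow(x)), function(i) {
    px <- x$median[i]; py <- y$median[i]
    for (state in c("active", "inactive")) {
      r <- regions[[state]]
      if (px >= r["xmin"] && px <= r["xmax"] &&
          py >= r["ymin"] && py <= r["ymax"]) return(state)
    }
    "intermediate"
  }, "")
  frac <- vapply(c(active = "active", inactive = "inactive",
                   intermediate = "intermediate"),
                 function(s) mean(lab == s), 0)
  list(labels = lab, fractions = frac)
}
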
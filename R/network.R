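#' @include AllClasses.R
NULL

#' Assign dynamical-network nodes
#'
#' One node per protein residue, anchored at its Calpha atom, plus one
#' ligand node anchored at the ligand's basic nitrogen. Node ids are the
#' residue sequence numbers as strings; the ligand node id is the ligand
#' residue name.
#'
#' @param traj a [Trajectory-class].
#' @param ligandResname residue name of the ligand (e.g. \code{"LIG"}).
#' @param ligandNitrogen atom name of the ligand's basic nitrogen
#'   (default \code{"N1"}). Ligands with several basic nitrogens must name
#'   the one to use; only a single ligand node is created.
#' @return data.frame of nodes with columns \code{id}, \code{kind},
#'   \code{resid}, \code{anchor} (atom index).
#' @export
assignNodes <- function(traj, ligandResname, ligandNitrogen = "N1") {
  stopifnot(is(traj, "Trajectory"))
  at <- traj@atoms
  isLig <- at$resname == ligandResname
  if (!any(isLig))
    stop("no ligand residue named '", ligandResname, "' in trajectory")
  prot <- sort(unique(at$resid[!isLig]))
  anchor <- vapply(prot, function(r) {
    i <- which(at$resid == r & !isLig & at$name == "CA")
    if (length(i) != 1L)
      stop("residue ", r, " has no unique Calpha atom")
    i
  }, 0L)
  ligN <- which(isLig & at$name == ligandNitrogen)
  if (length(ligN) != 1L)
    stop("ligand '", ligandResname, "' has no unique atom named '",
         ligandNitrogen, "'")
  data.frame(
    id = c(as.character(prot), ligandResname),
    kind = c(rep("residue", length(prot)), "ligand"),
    resid = c(prot, unique(at$resid[isLig])[1]),
    anchor = c(anchor, ligN),
    stringsAsFactors = FALSE)
}

#' Motion-correlation matrix between network nodes
#'
#' Normalised covariance of anchor-atom displacements about their
#' trajectory-mean positions:
#' \deqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#'   \sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}}
#' The trajectory is assumed already aligned (no internal superposition is
#' applied); synthetic trajectories from this package satisfy that by
#' construction.
#'
#' @param traj a [Trajectory-class] with at least two frames.
#' @param nodes node table from [assignNodes()].
#' @return Symmetric correlation matrix with unit diagonal, dimnames =
#'   node ids.
#' @export
correlationMatrix <- function(traj, nodes) {
  stopifnot(is(traj, "Trajectory"))
  if (nFrames(traj) < 2L)
    stop("correlation requires at least two frames")
  n <- nrow(nodes)
  xs <- traj@coords[, nodes$anchor, 1, drop = FALSE][, , 1]
  ys <- traj@coords[, nodes$anchor, 2, drop = FALSE][, , 1]
  zs <- traj@coords[, nodes$anchor, 3, drop = FALSE][, , 1]
  dim(xs) <- dim(ys) <- dim(zs) <- c(nFrames(traj), n)
  xs <- sweep(xs, 2, colMeans(xs)); ys <- sweep(ys, 2, colMeans(ys))
  zs <- sweep(zs, 2, colMeans(zs))
  num <- (crossprod(xs) + crossprod(ys) + crossprod(zs)) / nFrames(traj)
  fluct <- diag(num)
  frozen <- fluct <= 0
  if (any(frozen))
    stop("nodes with zero total fluctuation (correlations undefined): ",
         paste(nodes$id[frozen], collapse = ", "))
  C <- num / sqrt(outer(fluct, fluct))
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  dimnames(C) <- list(nodes$id, nodes$id)
  C
}

#' Persistent-contact mask between network nodes
#'
#' Two nodes are in contact when the minimum heavy-atom distance between
#' their residues is at most \code{cutoff} in at least
#' \code{frameFraction} of the frames. The 4.5 Angstrom / 75 per cent
#' defaults follow the package's contact convention (the same 4.5 A cutoff
#' the interaction-energy module uses).
#'
#' @param traj a [Trajectory-class].
#' @param nodes node table from [assignNodes()].
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param frameFraction required fraction of frames in (0, 1].
#' @return Symmetric logical matrix (FALSE diagonal), dimnames = node ids.
#' @export
contactMask <- function(traj, nodes, cutoff = 4.5, frameFraction = 0.75) {
  stopifnot(is(traj, "Trajectory"), cutoff > 0,
            frameFraction > 0, frameFraction <= 1)
  at <- traj@atoms
  n <- nrow(nodes)
  heavy <- which(at$heavy)
  # atoms -> node indicator (heavy atoms of each node's residue; the ligand
  # node owns every heavy atom of the ligand residue)
  Z <- matrix(0, length(heavy), n)
  ligName <- nodes$id[nodes$kind == "ligand"]
  for (k in seq_len(n)) {
    if (nodes$kind[k] == "ligand")
      Z[at$resname[heavy] %in% ligName, k] <- 1
    else
      Z[at$resid[heavy] == nodes$resid[k] &
        !(at$resname[heavy] %in% ligName), k] <- 1
  }
  counts <- matrix(0, n, n)
  cut2 <- cutoff^2
  for (f in seq_len(nFrames(traj))) {
    xyz <- traj@coords[f, heavy, ]
    d2 <- as.matrix(stats::dist(xyz))^2
    B <- (d2 <= cut2) * 1
    counts <- counts + ((t(Z) %*% B %*% Z) > 0)
  }
  mask <- counts / nFrames(traj) >= frameFraction
  diag(mask) <- FALSE
  mask <- mask & t(mask)
  dimnames(mask) <- list(nodes$id, nodes$id)
  mask
}

#' Build the dynamical network
#'
#' Admits an edge between two nodes when (i) they satisfy the persistent
#' contact mask, (ii) they are not the same residue nor sequence nearest
#' neighbours (protein-protein pairs with \code{|resid_i - resid_j| <=
#' neighborExclusion} are excluded; ligand edges are exempt), and (iii)
#' \eqn{|C_{ij}| > 0}. Admitted edges carry the weight
#' \eqn{w_{ij} = -\log|C_{ij}|} (natural log), so strongly correlated or
#' anti-correlated motion gives short, "well communicating" edges.
#'
#' @param C correlation matrix from [correlationMatrix()].
#' @param mask logical contact matrix from [contactMask()].
#' @param nodes node table from [assignNodes()].
#' @param neighborExclusion exclude protein pairs within this sequence
#'   separation (default 1 = self and nearest neighbours; 0 disables).
#' @return A [CorrelationNetwork-class].
#' @export
buildNetwork <- function(C, mask, nodes, neighborExclusion = 1) {
  n <- nrow(nodes)
  stopifnot(all(dim(C) == n), all(dim(mask) == n))
  prot <- nodes$kind == "residue"
  sep <- abs(outer(nodes$resid, nodes$resid, "-"))
  neighbor <- outer(prot, prot, "&") & sep <= neighborExclusion
  admit <- mask & !neighbor & abs(C) > 0
  diag(admit) <- FALSE
  W <- matrix(NA_real_, n, n, dimnames = list(nodes$id, nodes$id))
  W[admit] <- -log(pmin(abs(C[admit]), 1))
  new("CorrelationNetwork", nodes = nodes, cor = C,
      mask = mask & !neighbor, W = W)
}

#' Construct a network directly from an edge-weight matrix
#'
#' Convenience constructor for path-search work on an arbitrary weighted
#' graph: correlations are back-filled as \eqn{|C| = e^{-w}} so the usual
#' invariants hold.
#'
#' @param W symmetric non-negative weight matrix, \code{NA} = no edge.
#' @param ids optional node ids (default \code{"1"..."n"}).
#' @return A [CorrelationNetwork-class] whose nodes are all of kind
#'   \code{"residue"}.
#' @export
networkFromWeights <- function(W, ids = NULL) {
  n <- nrow(W)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  nodes <- data.frame(id = ids, kind = "residue",
                      resid = seq_len(n) * 10L, anchor = seq_len(n),
                      stringsAsFactors = FALSE)
  C <- exp(-W)
  C[is.na(W)] <- 0
  diag(C) <- 1
  mask <- !is.na(W)
  diag(mask) <- FALSE
  dimnames(W) <- dimnames(C) <- dimnames(mask) <- list(ids, ids)
  new("CorrelationNetwork", nodes = nodes, cor = C, mask = mask, W = W)
}
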
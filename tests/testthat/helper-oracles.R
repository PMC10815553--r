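## Independent oracles and shared fixture builders. Everything here is
## deliberately naive (exhaustive enumeration, grid search, explicit loops)
## and never calls the package code paths it is used to check.

## --- exhaustive simple-path enumeration ------------------------------------

enumerateAllPathsOracle <- function(W, src, sink) {
  paths <- list()
  dists <- numeric()
  rec <- function(u, visited, path, acc) {
    if (u == sink) {
      paths[[length(paths) + 1L]] <<- path
      dists[[length(dists) + 1L]] <<- acc
      return(invisible())
    }
    for (v in seq_len(nrow(W))) {
      if (!visited[v] && !is.na(W[u, v])) {
        visited2 <- visited
        visited2[v] <- TRUE
        rec(v, visited2, c(path, v), acc + W[u, v])
      }
    }
  }
  v0 <- rep(FALSE, nrow(W))
  v0[src] <- TRUE
  rec(src, v0, src, 0)
  list(paths = paths, dists = dists)
}

## the same keep/sort rule the contract states: optimal ties always kept,
## otherwise strictly below optimal + offset
bruteForcePathSet <- function(W, src, sink, offset, tol = 1e-9) {
  e <- enumerateAllPathsOracle(W, src, sink)
  if (!length(e$paths))
    return(list(paths = list(), dists = numeric(), opt = Inf))
  opt <- min(e$dists)
  keep <- e$dists <= opt + tol | e$dists < opt + offset - tol
  paths <- e$paths[keep]
  dists <- e$dists[keep]
  key <- vapply(paths, function(p) paste(sprintf("%05d", p), collapse = " "), "")
  o <- order(round(dists / tol) * tol, key)
  list(paths = paths[o], dists = dists[o], opt = opt)
}

randomWeightGraph <- function(n, p = 0.45, wmin = 0.05, wmax = 5) {
  W <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) W[i, j] <- W[j, i] <- runif(1, wmin, wmax)
  }
  W
}

## --- rigid-superposition RMSD by grid search over SO(3) --------------------

rotZYZ <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

rmsdOracle <- function(ref, x) {
  A <- sweep(x, 2, colMeans(x))
  B <- sweep(ref, 2, colMeans(ref))
  f <- function(p) {
    R <- rotZYZ(p[1], p[2], p[3])
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- Inf; bp <- c(0, 0, 0)
  for (a in seq(0, 2 * pi, length.out = 13))
    for (b in seq(0, pi, length.out = 7))
      for (cc in seq(0, 2 * pi, length.out = 13)) {
        v <- f(c(a, b, cc))
        if (v < best) { best <- v; bp <- c(a, b, cc) }
      }
  o <- stats::optim(bp, f, control = list(reltol = 1e-14, maxit = 5000))
  o$value
}

## --- hand-built trajectories ------------------------------------------------

## trajectory from an explicit coordinate array, one CA atom per residue
## (plus an optional single-nitrogen ligand as the last "residue")
trajFromCoords <- function(coordArr, frameInterval = 0.1, ligandLast = FALSE) {
  nA <- dim(coordArr)[2]
  atoms <- data.frame(
    name = c(rep("CA", nA - ligandLast), if (ligandLast) "N1"),
    element = c(rep("C", nA - ligandLast), if (ligandLast) "N"),
    resid = seq_len(nA),
    resname = c(rep("GLY", nA - ligandLast), if (ligandLast) "LIG"),
    chain = "A", stringsAsFactors = FALSE)
  Trajectory(coordArr, atoms, frameInterval)
}

## --- planted anchor + relay-chain scenario ---------------------------------

## Strong communication chain LIG-4-6-8-10 (planted correlation 0.8 per
## edge) against a weak alternative LIG-3-5-9-12-10 (0.4 per edge), on a
## triangular contact lattice 2.6 A apart. The designated anchor is
## residue 4 and the optimal path the strong chain.
plantedScenarioTruth <- list(anchor = "4",
                             chain = c("LIG", "4", "6", "8", "10"),
                             sink = "10")

makePlantedScenario <- function(seed, nFrames = 400) {
  sdN <- 0.4
  aS <- amplitudeForCorrelation(0.8, sdN)
  aW <- amplitudeForCorrelation(0.4, sdN)
  g <- function(m, a) list(members = m, amplitude = a)
  step <- c(2.6, 0, 0)
  diag60 <- c(1.3, 2.6 * sin(pi / 3), 0)
  makeCorrelatedTrajectory(
    nResidues = 12, nFrames = nFrames, noiseSd = sdN, seed = seed,
    groups = list(
      g(c("LIG", "4"), aS), g(c("4", "6"), aS), g(c("6", "8"), aS),
      g(c("8", "10"), aS),
      g(c("LIG", "3"), aW), g(c("3", "5"), aW), g(c("5", "9"), aW),
      g(c("9", "12"), aW), g(c("12", "10"), aW)),
    plantedContacts = list(
      list(pair = c("LIG", "4"), offset = step),
      list(pair = c("4", "6"), offset = step),
      list(pair = c("6", "8"), offset = step),
      list(pair = c("8", "10"), offset = step),
      list(pair = c("LIG", "3"), offset = diag60),
      list(pair = c("3", "5"), offset = step),
      list(pair = c("5", "9"), offset = step),
      list(pair = c("9", "12"), offset = step),
      list(pair = c("12", "10"), distance = 2.6)))
}

plantedScenarioNetwork <- function(seed, nFrames = 400) {
  tr <- makePlantedScenario(seed, nFrames)
  nd <- assignNodes(tr, "LIG", "N1")
  C <- correlationMatrix(tr, nd)
  mk <- contactMask(tr, nd)
  buildNetwork(C, mk, nd)
}
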
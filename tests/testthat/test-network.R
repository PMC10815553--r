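test_that("node assignment follows the Calpha / basic-nitrogen rule", {
  tr <- makeCorrelatedTrajectory(nResidues = 5, nFrames = 3, seed = 1)
  nd <- assignNodes(tr, "LIG", "N1")
  expect_equal(nrow(nd), 6L)                    # 5 residues + ligand
  expect_equal(sum(nd$kind == "ligand"), 1L)
  expect_identical(nd$id, c("1", "2", "3", "4", "5", "LIG"))
  expect_error(assignNodes(tr, "LIG", "N9"), "N9")
  expect_error(assignNodes(tr, "XYZ"), "XYZ")
})

test_that("correlation equals a hand-evaluated oracle on a tiny trajectory", {
  set.seed(42)
  co <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  tr <- trajFromCoords(co)
  nd <- data.frame(id = c("1", "2", "3"), kind = "residue",
                   resid = 1:3, anchor = 1:3, stringsAsFactors = FALSE)
  C <- correlationMatrix(tr, nd)
  # explicit-loop evaluation of <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)
  oracle <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    di <- sweep(co[, i, ], 2, colMeans(co[, i, ]))
    dj <- sweep(co[, j, ], 2, colMeans(co[, j, ]))
    num <- mean(rowSums(di * dj))
    oracle[i, j] <- num / sqrt(mean(rowSums(di^2)) * mean(rowSums(dj^2)))
  }
  expect_equal(unname(C), oracle, tolerance = 1e-12)
  # structural invariants
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 3))
  expect_true(all(abs(C) <= 1))
})

test_that("perfectly shared and mirrored motion give correlations +1 / -1", {
  s <- c(0.5, -1, 0.25, 0.25)
  co <- array(0, c(4, 3, 3))
  co[, 1, 1] <- s
  co[, 2, 1] <- s + 10
  co[, 3, 1] <- -s
  tr <- trajFromCoords(co)
  nd <- data.frame(id = as.character(1:3), kind = "residue",
                   resid = 1:3, anchor = 1:3, stringsAsFactors = FALSE)
  C <- correlationMatrix(tr, nd)
  expect_equal(C["1", "2"], 1)
  expect_equal(C["1", "3"], -1)
})

test_that("frozen nodes are reported as an error", {
  co <- array(0, c(3, 2, 3))
  co[, 1, 1] <- c(1, 2, 3)     # node 2 never moves
  tr <- trajFromCoords(co)
  nd <- data.frame(id = c("1", "2"), kind = "residue", resid = 1:2,
                   anchor = 1:2, stringsAsFactors = FALSE)
  expect_error(correlationMatrix(tr, nd), "zero total fluctuation.*2")
})

test_that("correlation agrees with an independent cross-correlation routine", {
  tr <- makeCorrelatedTrajectory(
    nResidues = 5, nFrames = 80, seed = 9,
    groups = list(list(members = c("1", "3"), amplitude = 1)))
  nd <- assignNodes(tr, "LIG", "N1")
  C <- correlationMatrix(tr, nd)
  xyz <- matrix(NA_real_, 80, 3 * nrow(nd))
  for (k in seq_len(nrow(nd)))
    xyz[, 3 * k - 2:0] <- coords(tr)[, nd$anchor[k], ]
  ref <- unclass(bio3d::dccm.xyz(xyz))
  expect_equal(unname(C), unname(ref), tolerance = 1e-8)
})

test_that("contact mask applies cutoff, persistence and symmetry", {
  # residues 1-2 always 3 A apart; 2-3 within reach in half the frames only
  co <- array(0, c(4, 3, 3))
  co[, 2, 1] <- 3
  co[, 3, 1] <- c(6, 6, 40, 40)
  tr <- trajFromCoords(co)
  nd <- data.frame(id = as.character(1:3), kind = "residue", resid = 1:3,
                   anchor = 1:3, stringsAsFactors = FALSE)
  mk <- contactMask(tr, nd, cutoff = 4.5, frameFraction = 0.75)
  expect_true(mk["1", "2"])
  expect_false(mk["2", "3"])
  expect_identical(mk, t(mk))
  expect_false(any(diag(mk)))
  # at 50% persistence requirement the intermittent pair qualifies
  expect_true(contactMask(tr, nd, frameFraction = 0.5)["2", "3"])
  # closed boundary: exactly 4.5 A counts as contact
  co2 <- array(0, c(2, 2, 3))
  co2[, 2, 1] <- 4.5
  nd2 <- nd[1:2, ]
  expect_true(contactMask(trajFromCoords(co2), nd2)["1", "2"])
  co2[, 2, 1] <- 4.5 + 1e-6
  expect_false(contactMask(trajFromCoords(co2), nd2)["1", "2"])
})

test_that("edge admission excludes sequence neighbours and maps weights", {
  # residues 1 and 2 are sequence neighbours; residue 10 is remote
  nd <- data.frame(id = as.character(1:3), kind = "residue",
                   resid = c(1L, 2L, 10L),
                   anchor = 1:3, stringsAsFactors = FALSE)
  C <- rbind(c(1, 1, 0.5), c(1, 1, -0.8), c(0.5, -0.8, 1))
  mask <- matrix(TRUE, 3, 3); diag(mask) <- FALSE
  net <- buildNetwork(C, mask, nd)
  W <- edgeWeights(net)
  expect_true(is.na(W["1", "2"]))               # adjacent residues: no edge
  expect_equal(W["1", "3"], -log(0.5))          # 0.693147...
  expect_equal(W["2", "3"], -log(0.8))          # anti-correlation by magnitude
  # |C| = 1 gives weight exactly 0
  C2 <- C; C2[1, 3] <- C2[3, 1] <- 1
  expect_equal(buildNetwork(C2, mask, nd)@W["1", "3"], 0)
  # disabling the exclusion admits the neighbour edge
  expect_false(is.na(buildNetwork(C, mask, nd, neighborExclusion = 0)@W["1", "2"]))
})

test_that("optimal path search handles the degenerate and tied cases", {
  W <- rbind(c(NA, 1, 4), c(1, NA, 1), c(4, 1, NA))
  net <- networkFromWeights(W)
  # source equals sink
  p0 <- optimalPaths(net, "2", "2")
  expect_identical(pathList(p0), list("2"))
  expect_equal(p0@optimalDistance, 0)
  # two-node graph: the single edge
  p1 <- optimalPaths(net, "1", "2")
  expect_identical(pathList(p1)[[1]], c("1", "2"))
  expect_equal(pathDistances(p1)[1], 1)
  # tie: 1-3 direct (4) vs 1-2-3 (2): unique optimum
  p2 <- optimalPaths(net, "1", "3")
  expect_identical(pathList(p2), list(c("1", "2", "3")))
  # exact tie reported in full
  Wt <- rbind(c(NA, 1, 1, NA), c(1, NA, NA, 1), c(1, NA, NA, 1),
              c(NA, 1, 1, NA))
  pt <- optimalPaths(networkFromWeights(Wt), "1", "4")
  expect_equal(length(pathList(pt)), 2L)
  expect_equal(pt@nOptimal, 3L)
  # unreachable sink: explicit disconnected result, not an exception
  Wd <- matrix(NA_real_, 3, 3); Wd[1, 2] <- Wd[2, 1] <- 1
  pd <- optimalPaths(networkFromWeights(Wd), "1", "3")
  expect_true(pd@disconnected)
  expect_equal(pd@nPaths, 0L)
})

test_that("optimal distances agree with an independent graph library", {
  set.seed(7)
  for (rep in 1:10) {
    W <- randomWeightGraph(8)
    net <- networkFromWeights(W)
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(is.na(W), 0, W), mode = "undirected", weighted = TRUE)
    ref <- igraph::distances(g, v = 1, to = 8)[1, 1]
    got <- suboptimalPaths(net, "1", "8", offset = 0)@optimalDistance
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("suboptimal enumeration matches brute force on a small graph", {
  set.seed(123)
  W <- randomWeightGraph(5, p = 0.8)
  net <- networkFromWeights(W)
  for (offset in c(0, 1, 5)) {
    got <- suboptimalPaths(net, "1", "5", offset = offset)
    ref <- bruteForcePathSet(W, 1, 5, offset)
    expect_equal(length(pathList(got)), length(ref$paths))
    expect_identical(pathList(got),
                     lapply(ref$paths, function(p) as.character(p)))
    expect_equal(pathDistances(got), ref$dists)
    # postcondition: all distances within [opt, opt + offset)
    if (length(ref$dists))
      expect_true(all(pathDistances(got) <= got@optimalDistance + offset + 1e-9))
  }
  # the suboptimal set shrinks monotonically as the offset decreases
  sizes <- vapply(c(10, 5, 2, 0),
                  function(o) suboptimalPaths(net, "1", "5", o)@nPaths, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("the offset bound is strict but keeps tied optima", {
  # opt = 2 direct; detour = 2 + offset exactly -> excluded
  off <- 1
  W <- matrix(NA_real_, 3, 3)
  W[1, 3] <- W[3, 1] <- 2
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1 + off
  ps <- suboptimalPaths(networkFromWeights(W), "1", "3", offset = off)
  expect_identical(pathList(ps), list(c("1", "3")))
  # a hair under the bound -> included
  W[2, 3] <- W[3, 2] <- 1 + off - 1e-3
  ps2 <- suboptimalPaths(networkFromWeights(W), "1", "3", offset = off)
  expect_equal(ps2@nPaths, 2L)
  # offset 0 still returns (all) optimal paths
  W[2, 3] <- W[3, 2] <- 1
  ps3 <- suboptimalPaths(networkFromWeights(W), "1", "3", offset = 0)
  expect_equal(ps3@nPaths, 2L)   # both distance-2 routes are optimal ties
})

test_that("the ligand anchor is the smallest-weight ligand edge", {
  nd <- data.frame(id = c("10", "20", "30", "LIG"),
                   kind = c("residue", "residue", "residue", "ligand"),
                   resid = c(10L, 20L, 30L, 99L), anchor = 1:4,
                   stringsAsFactors = FALSE)
  W <- matrix(NA_real_, 4, 4, dimnames = list(nd$id, nd$id))
  W[4, 1] <- W[1, 4] <- 0.9
  W[4, 2] <- W[2, 4] <- 0.3
  W[4, 3] <- W[3, 4] <- 1.2
  C <- exp(-ifelse(is.na(W), Inf, W)); diag(C) <- 1
  net <- new("CorrelationNetwork", nodes = nd, cor = C,
             mask = !is.na(W), W = W)
  expect_identical(ligandAnchor(net), "20")
  # tie -> lower residue id, with a message
  W[4, 1] <- W[1, 4] <- 0.3
  C <- exp(-ifelse(is.na(W), Inf, W)); diag(C) <- 1
  net2 <- new("CorrelationNetwork", nodes = nd, cor = C,
              mask = !is.na(W), W = W)
  expect_message(a <- ligandAnchor(net2), "tie")
  expect_identical(a, "10")
  # isolated ligand node
  W[] <- NA_real_
  C <- diag(4); dimnames(C) <- dimnames(W)
  net3 <- new("CorrelationNetwork", nodes = nd, cor = C,
              mask = !is.na(W), W = W)
  expect_error(ligandAnchor(net3), "no edges")
})

test_that("helix hop segmentation reproduces the path", {
  bw <- BWMapping(c("3.36", "3.40", "6.44", "6.29"),
                  c(119, 123, 256, 241))
  path <- c("LIG", "119", "123", "256", "241")
  h <- helixHops(path, bw)
  expect_identical(h$segments$label, c("ligand", "TMH3", "TMH6"))
  expect_equal(h$transfers, 2L)
  # concatenated segments reproduce the path exactly
  expect_identical(unlist(mapply(function(f, t) path[match(f, path):match(t, path)],
                                 h$segments$from, h$segments$to,
                                 SIMPLIFY = FALSE), use.names = FALSE), path)
  # path entirely within one helix: a single segment, no transfers
  h2 <- helixHops(c("119", "123"), bw)
  expect_identical(h2$segments$label, "TMH3")
  expect_equal(h2$transfers, 0L)
  # unmapped residues become loop segments
  h3 <- helixHops(c("119", "500"), bw)
  expect_identical(h3$labels, c("TMH3", "loop"))
})
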
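rigidTransform <- function(xyz, angle = pi / 2, shift = c(5, -3, 2)) {
  R <- rotZYZ(angle, 0, 0)   # rotation about z
  sweep(xyz %*% t(R), 2, shift, `+`)
}

test_that("RMSD is zero for identical and rigidly transformed frames", {
  tg <- makeToyGpcr(state = "inactive", jitterSd = 0, nFrames = 3)
  tr <- tg$trajectory
  co <- coords(tr)
  co[2, , ] <- rigidTransform(co[2, , ])       # frame 2 = rigid copy of 1
  tr2 <- Trajectory(co, atomMeta(tr), frameInterval(tr))
  v <- descriptorValues(rmsdSeries(tr2))
  expect_equal(v[1], 0, tolerance = 1e-6)
  expect_equal(v[2], 0, tolerance = 1e-6)
})

test_that("RMSD equals a grid-search superposition oracle on a toy", {
  # 4 atoms, one displaced by 2 A relative to the reference
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  moved <- ref
  moved[4, ] <- moved[4, ] + c(0, 2, 0)
  # present the mobile frame in a scrambled rigid pose
  co <- array(NA_real_, c(2, 4, 3))
  co[1, , ] <- ref
  co[2, , ] <- rigidTransform(moved, angle = 1.1, shift = c(-4, 7, 1))
  tr <- trajFromCoords(co)
  got <- descriptorValues(rmsdSeries(tr))[2]
  expect_equal(got, rmsdOracle(ref, moved), tolerance = 1e-3)
})

test_that("RMSD series is invariant under rigid transforms of every frame", {
  tg <- makeToyGpcr(jitterSd = 0.3, nFrames = 5, seed = 2)
  tr <- tg$trajectory
  v0 <- descriptorValues(rmsdSeries(tr))
  co <- coords(tr)
  for (f in seq_len(dim(co)[1]))
    co[f, , ] <- rigidTransform(co[f, , ], angle = f, shift = c(f, -f, 2 * f))
  v1 <- descriptorValues(rmsdSeries(Trajectory(co, atomMeta(tr),
                                               frameInterval(tr))))
  expect_equal(v1, v0, tolerance = 1e-6)
})

test_that("RMSF matches the population standard deviation on aligned toys", {
  # static trajectory: all fluctuations zero
  tg <- makeToyGpcr(jitterSd = 0, nFrames = 4)
  expect_equal(rmsfSeries(tg$trajectory)$rmsf,
               rep(0, sum(atomMeta(tg$trajectory)$name == "CA")),
               tolerance = 1e-8)
  # one atom oscillating +/- 1 A along x in a pre-aligned frame set
  co <- array(0, c(4, 3, 3))
  co[, 2, 1] <- 10; co[, 3, 2] <- 10        # two static far-away atoms
  co[, 1, 1] <- c(1, -1, 1, -1)             # oscillator
  tr <- trajFromCoords(co)
  r <- rmsfSeries(tr, fit = FALSE)
  expect_equal(r$rmsf, c(1, 0, 0))
  # frame order does not matter
  perm <- c(3, 1, 4, 2)
  r2 <- rmsfSeries(trajFromCoords(co[perm, , , drop = FALSE]), fit = FALSE)
  expect_equal(r2$rmsf, r$rmsf)
  # single frame is rejected
  expect_error(rmsfSeries(trajFromCoords(co[1, , , drop = FALSE])),
               "two frames")
})

test_that("motif distances follow their atom definitions", {
  # 3-4-5 triangle between two Calpha atoms
  co <- array(NA_real_, c(1, 2, 3))
  co[1, 1, ] <- c(0, 0, 0)
  co[1, 2, ] <- c(3, 4, 0)
  tr <- trajFromCoords(co)
  bw <- BWMapping(c("5.46", "7.42"), c(1, 2))
  expect_equal(descriptorValues(motifDistance(tr, bw, "lbs_tightening")), 5)

  # all six planted targets, exact at zero jitter
  for (state in c("active", "inactive")) {
    tg <- makeToyGpcr(state = state, jitterSd = 0, nFrames = 2)
    targets <- if (state == "active")
      c(lbs_tightening = 11, npxxy_hbond = 2, npxxy_ca = 9,
        pif_36 = 9, pif_56 = 13, edry_ionic = 20)
    else
      c(lbs_tightening = 13, npxxy_hbond = 5, npxxy_ca = 11.5,
        pif_36 = 11.5, pif_56 = 12, edry_ionic = 3.5)
    for (d in names(targets)) {
      v <- descriptorValues(motifDistance(tg$trajectory, tg$mapping, d))
      expect_equal(v, rep(targets[[d]], 2), tolerance = 1e-6,
                   label = paste(state, d))
    }
  }
})

test_that("hydrogen-free structures fall back to the O...N distance", {
  tg <- makeToyGpcr(state = "inactive", jitterSd = 0, nFrames = 1,
                    hydrogens = FALSE)
  expect_warning(
    s <- motifDistance(tg$trajectory, tg$mapping, "npxxy_hbond"),
    "falling back")
  # ND2 placed 1.01 A beyond the (absent) amide hydrogen
  expect_equal(descriptorValues(s), 5 + 1.01, tolerance = 1e-6)
})

test_that("missing atoms and unmapped numbers are reported by name", {
  tg <- makeToyGpcr(nFrames = 1)
  bw <- BWMapping(c("5.46"), c(546))
  expect_error(motifDistance(tg$trajectory, bw, "lbs_tightening"),
               "unknown generic number '7.42'")
  at <- atomMeta(tg$trajectory)
  drop <- which(at$resid == 742 & at$name == "CA")
  tr2 <- Trajectory(coords(tg$trajectory)[, -drop, , drop = FALSE],
                    at[-drop, ], 1)
  expect_error(motifDistance(tr2, tg$mapping, "lbs_tightening"), "742")
})

test_that("block medians follow the 10 ns anchored-block rule", {
  # constant series over 100 ns -> ten medians, all equal
  s <- DescriptorSeries("d", rep(7, 100), frameInterval = 1)
  b <- blockMedians(s, 10)
  expect_equal(nrow(b), 10L)
  expect_equal(b$median, rep(7, 10))
  expect_equal(b$start_ns, seq(0, 90, 10))
  # even count: midpoint of the central values
  s2 <- DescriptorSeries("d", 1:10, frameInterval = 1)
  expect_equal(blockMedians(s2, 10)$median, 5.5)
  # trailing partial block dropped with a message
  s3 <- DescriptorSeries("d", seq_len(1050), frameInterval = 0.1)
  expect_message(b3 <- blockMedians(s3, 10), "50 trailing")
  expect_equal(nrow(b3), 10L)
  expect_true(all(b3$median <= 1000))
  # shorter than one block is an error
  expect_error(blockMedians(DescriptorSeries("d", 1:5, 1), 10), "shorter")
  # medians lie within their block's range
  set.seed(1)
  s4 <- DescriptorSeries("d", runif(60, 2, 9), frameInterval = 0.5)
  b4 <- blockMedians(s4, 10)
  for (k in seq_len(nrow(b4))) {
    vals <- descriptorValues(s4)[((k - 1) * 20 + 1):(k * 20)]
    expect_gte(b4$median[k], min(vals))
    expect_lte(b4$median[k], max(vals))
  }
})

test_that("block classification respects closed rectangles and counts", {
  rects <- list(active = c(xmin = 15, xmax = 25, ymin = 7, ymax = 10),
                inactive = c(xmin = 2, xmax = 6, ymin = 10.5, ymax = 13))
  mk <- function(v) data.frame(block = seq_along(v), start_ns = 0,
                               end_ns = 1, median = v)
  # inside, boundary (closed), and outside points
  cl <- classifyBlocks(mk(c(20, 15, 10, 3.5)), mk(c(8, 7, 8, 11)), rects)
  expect_identical(cl$labels,
                   c("active", "active", "intermediate", "inactive"))
  expect_equal(sum(cl$fractions), 1)
  # 7 active / 3 intermediate -> fractions (0.7, 0, 0.3)
  cl2 <- classifyBlocks(mk(c(rep(20, 7), rep(10, 3))),
                        mk(c(rep(8, 7), rep(1, 3))), rects)
  expect_equal(unname(cl2$fractions), c(0.7, 0, 0.3))
  expect_error(classifyBlocks(mk(1:3), mk(1:4), rects), "mismatch")
  bad <- rects; bad$inactive <- c(xmin = 14, xmax = 26, ymin = 6, ymax = 11)
  expect_error(classifyBlocks(mk(1), mk(1), bad), "overlap")
})

test_that("region configuration round trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "pairs:",
    "  - x: edry_ionic",
    "    y: npxxy_ca",
    "    regions:",
    "      active: {xmin: 17.0, xmax: 23.0, ymin: 7.5, ymax: 10.5}",
    "      inactive: {xmin: 2.0, xmax: 6.0, ymin: 10.6, ymax: 13.0}"), f)
  reg <- readRegions(f)
  r <- regionsFor(reg, "edry_ionic", "npxxy_ca")
  expect_equal(r$active[["xmin"]], 17)
  expect_error(regionsFor(reg, "pif_36", "pif_56"), "no region")
})
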
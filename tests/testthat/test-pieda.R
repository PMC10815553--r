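test_that("polarity share reproduces its analytic limits and midpoint", {
  expect_equal(polarityShare(-5, -2, 0)$value, 100)   # purely polar
  expect_equal(polarityShare(0, 0, -3)$value, 0)      # purely dispersive
  expect_equal(polarityShare(-4, -1, -5)$value, 50)   # (4+1)/(4+1+5)
  # all-zero components: flagged undefined, not an error
  u <- polarityShare(0, 0, 0)
  expect_false(u$defined)
  expect_true(is.na(u$value))
})

test_that("polarity share is scale- and sign-invariant and bounded", {
  set.seed(5)
  for (i in 1:50) {
    es <- rnorm(1, 0, 5); ct <- rnorm(1, 0, 2); dp <- rnorm(1, 0, 4)
    v <- polarityShare(es, ct, dp)$value
    expect_gte(v, 0); expect_lte(v, 100)
    k <- runif(1, 0.1, 10)
    expect_equal(polarityShare(k * es, k * ct, k * dp)$value, v)
    expect_equal(polarityShare(-es, ct, -dp)$value, v)
  }
  # boundary characterisations
  expect_equal(polarityShare(2, 3, 0)$value, 100)
  expect_equal(polarityShare(0, 0, 0.1)$value, 0)
})

test_that("interaction classification follows sign and closed contact cutoff", {
  r <- classifyInteraction(c(-3.2, 1.4, -8.0), c(3.1, 3.9, 5.0))
  expect_identical(as.character(r$category),
                   c("attractive", "repulsive", "no_contact"))
  # the boundary belongs to the contact side
  expect_identical(as.character(classifyInteraction(-1, 4.5)$category),
                   "attractive")
  expect_identical(as.character(classifyInteraction(-1, 4.5 + 1e-9)$category),
                   "no_contact")
  # missing distance is no contact even for huge energies
  expect_identical(as.character(classifyInteraction(-50, NA)$category),
                   "no_contact")
  # PIE exactly zero -> attractive branch, with a message
  expect_message(z <- classifyInteraction(0, 3), "exactly 0")
  expect_identical(as.character(z$category), "attractive")
})

test_that("classification on a table keeps residue ids", {
  tb <- makePiedaTables(nPerClass = c(agonist = 1), seed = 2)[[1]]
  cl <- classifyInteraction(tb)
  expect_identical(cl$residue_id, records(tb)$residue_id)
  contacted <- !is.na(records(tb)$min_dist) & records(tb)$min_dist <= 4.5
  expect_identical(cl$category == "no_contact", !contacted)
})

.toyTables <- function() {
  bw <- bindingSiteMapping()
  mk <- function(id, class, resids, pies, dists) {
    n <- length(resids)
    PIEDATable(data.frame(
      residue_id = resids, residue_name = "X", pie = pies,
      e_es = -1, e_ex = 1, e_ct = -0.5, e_disp = -1, dg_solv = 0.5,
      min_dist = dists), complexId = id, classLabel = class)
  }
  list(bw = bw,
       tabs = list(
         mk("AG1", "agonist", c(332, 336, 548), c(-90, -2.5, -1), c(2.8, 3.1, 6)),
         mk("AN1", "antagonist", c(332, 546, 651), c(-95, 3.1, -4), c(2.7, 4.5, 3))))
}

test_that("heat map assembles the union of contacted residues", {
  x <- .toyTables()
  hm <- buildHeatmap(x$tabs, x$bw)
  # 3.32 excluded by default and recorded
  expect_identical(hm$excluded, "3.32")
  expect_false("3.32" %in% colnames(hm$matrix))
  # union of remaining contacted residues; no-contact cells are NA
  expect_setequal(colnames(hm$matrix), c("3.36", "5.46", "6.51"))
  expect_equal(hm$matrix["AG1", "3.36"], -2.5)    # copied, not transformed
  expect_true(is.na(hm$matrix["AN1", "3.36"]))
  expect_equal(hm$matrix["AN1", "5.46"], 3.1)     # boundary 4.5 A contact
  # residue beyond the cutoff never enters (AG1 residue 548 at 6 A)
  expect_false("5.43" %in% colnames(hm$matrix))
  # agonist rows come first
  expect_identical(rownames(hm$matrix), c("AG1", "AN1"))
  expect_identical(hm$classes, c("agonist", "antagonist"))
  # empty exclusion keeps every contacted column
  hm2 <- buildHeatmap(x$tabs, x$bw, exclude = character())
  expect_true("3.32" %in% colnames(hm2$matrix))
  expect_identical(hm2$excluded, character())
})

test_that("heat map warns on unmapped residues and keeps raw ids", {
  x <- .toyTables()
  extra <- PIEDATable(data.frame(
    residue_id = 777, residue_name = "Z", pie = -1.5, e_es = -1, e_ex = 1,
    e_ct = 0, e_disp = -1, dg_solv = 0, min_dist = 3),
    complexId = "AN2", classLabel = "antagonist")
  expect_warning(hm <- buildHeatmap(c(x$tabs, list(extra)), x$bw), "777")
  expect_true("777" %in% colnames(hm$matrix))
  expect_equal(hm$matrix["AN2", "777"], -1.5)
})

test_that("occupancy statistics aggregate and compare classes", {
  mk <- function(id, class, nContact) {
    n <- 14
    PIEDATable(data.frame(
      residue_id = seq_len(n), residue_name = "X", pie = -1,
      e_es = -1, e_ex = 1, e_ct = 0, e_disp = -1, dg_solv = 0,
      min_dist = c(rep(3, nContact), rep(6, n - nContact))),
      complexId = id, classLabel = class)
  }
  tabs <- list(mk("AG1", "agonist", 5), mk("AG2", "agonist", 5),
               mk("AN1", "antagonist", 8), mk("AN2", "antagonist", 10))
  occ <- occupancyStats(tabs, seed = 1)
  expect_equal(occ$perComplex$count, c(5, 5, 8, 10))
  expect_equal(occ$comparison$estimate, 4)       # mean 9 vs mean 5
  expect_equal(occ$byClass$median[occ$byClass$class == "antagonist"], 9)
  # contact frequency: residue 1 touched by everyone, residue 10 only by AN2
  expect_equal(unname(occ$contactFrequency["1", ]), c(1, 1))
  expect_equal(unname(occ$contactFrequency["10", c("agonist", "antagonist")]),
               c(0, 0.5))
  # identical classes: permutation p near 1
  tabs0 <- list(mk("AG1", "agonist", 7), mk("AG2", "agonist", 7),
                mk("AN1", "antagonist", 7), mk("AN2", "antagonist", 7))
  occ0 <- occupancyStats(tabs0, seed = 1)
  expect_gt(occ0$comparison$p.value, 0.5)
  # a single class: comparison marked unavailable, per-class stats intact
  occ1 <- occupancyStats(tabs[1:2])
  expect_type(occ1$comparison, "character")
  expect_equal(occ1$byClass$mean, 5)
  # seeded permutation draw is reproducible
  expect_equal(occupancyStats(tabs, seed = 7)$comparison$p.value,
               occupancyStats(tabs, seed = 7)$comparison$p.value)
})
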
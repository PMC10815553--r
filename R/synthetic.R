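#' @include AllClasses.R
NULL

## run `expr` under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.unitVec <- function(v) v / sqrt(sum(v^2))

.randUnit <- function() .unitVec(rnorm(3))

#' Shared-mode amplitude for a target planted correlation
#'
#' The correlated-trajectory generator moves each node of a group along a
#' fixed unit vector with a shared standard-normal mode of amplitude
#' \code{a} plus node-local noise of standard deviation \code{sigma} along
#' the same vector, so two nodes sharing exactly one group (and no other)
#' have motion correlation \eqn{\rho = a^2 / (a^2 + \sigma^2)}. This
#' inverts the closed form.
#'
#' @param rho target correlation in (0, 1).
#' @param sigma node-local noise standard deviation in Angstrom.
#' @return Amplitude \code{a} in Angstrom.
#' @export
amplitudeForCorrelation <- function(rho, sigma) {
  stopifnot(rho > 0, rho < 1, sigma > 0)
  sigma * sqrt(rho / (1 - rho))
}

#' Synthetic trajectory with planted correlation structure
#'
#' Generates a Calpha-resolution pseudo-protein (one atom per residue)
#' plus an optional single-atom ligand pseudo-residue, with node motions
#' built as \code{base + a_g s_g(t) u_g + eps(t) u}: \code{s_g} a shared
#' standard-normal mode per group and frame, \code{u_g} a fixed unit
#' vector per group, and \code{eps} node-local normal noise along the same
#' vector (so the planted within-group correlation has the closed form
#' of [amplitudeForCorrelation()]). Residue base positions are spread far
#' apart (20 Angstrom) so that only planted contact pairs are in contact.
#'
#' @param nResidues number of protein residues.
#' @param nFrames number of frames (>= 2 for any correlation work).
#' @param frameInterval ns per frame.
#' @param groups list of \code{list(members, amplitude)}: members are node
#'   labels (residue numbers, or \code{"LIG"} for the ligand), amplitude
#'   the shared-mode amplitude in Angstrom. Groups may overlap; the
#'   closed-form correlation applies to node pairs sharing exactly one
#'   group and belonging to no other.
#' @param noiseSd node-local noise standard deviation in Angstrom (> 0,
#'   all nodes).
#' @param plantedContacts list of \code{list(pair, distance, offset)}:
#'   node pairs whose base positions are placed at the given distance
#'   (default 3 Angstrom) so the contact criterion holds in every frame.
#'   Unpinned partners are placed in the xy-plane at successive angles
#'   around the first node; an explicit 3-vector \code{offset} overrides
#'   the placement direction (useful to close contact cycles). Jointly
#'   infeasible placements (both nodes already pinned at a distance more
#'   than 1 Angstrom from the target) raise an error.
#' @param ligand include the ligand pseudo-residue (resname \code{"LIG"},
#'   basic nitrogen \code{"N1"})? Default TRUE.
#' @param seed integer seed; the generator is bit-deterministic given it.
#' @return A [Trajectory-class].
#' @export
makeCorrelatedTrajectory <- function(nResidues, nFrames,
                                     frameInterval = 0.02,
                                     groups = list(), noiseSd = 0.3,
                                     plantedContacts = list(),
                                     ligand = TRUE, seed = 1) {
  stopifnot(nResidues >= 1, nFrames >= 1, noiseSd > 0)
  labels <- c(as.character(seq_len(nResidues)), if (ligand) "LIG")
  nNodes <- length(labels)
  labIdx <- function(x) {
    i <- match(as.character(x), labels)
    if (any(is.na(i)))
      stop("unknown node label(s): ",
           paste(as.character(x)[is.na(i)], collapse = ", "))
    i
  }
  ## base positions: default 20 A ladder; planted contacts pulled together
  base <- cbind(0, 0, 20 * seq_len(nNodes))
  partnerCount <- integer(nNodes)
  pinned <- logical(nNodes)
  for (pc in plantedContacts) {
    off <- pc$offset
    d <- if (!is.null(off)) sqrt(sum(off^2))
         else if (is.null(pc$distance)) 3 else pc$distance
    ij <- labIdx(pc$pair)
    a <- ij[1]; b <- ij[2]
    if (pinned[a] && pinned[b]) {
      have <- sqrt(sum((base[a, ] - base[b, ])^2))
      if (abs(have - d) > 1)
        stop(sprintf(
          "planted contacts jointly infeasible: %s-%s already %.2f A apart, target %.2f",
          pc$pair[1], pc$pair[2], have, d))
      next
    }
    if (pinned[b] && !pinned[a]) {
      tmp <- a; a <- b; b <- tmp
      if (!is.null(off)) off <- -off
    }
    if (is.null(off)) {
      ang <- 2 * pi * partnerCount[a] / 3
      off <- d * c(cos(ang), sin(ang), 0)
    }
    base[b, ] <- base[a, ] + off
    partnerCount[a] <- partnerCount[a] + 1L
    pinned[a] <- pinned[b] <- TRUE
  }
  .withSeed(seed, {
    ## fixed directions: one per group, one per node (noise)
    gU <- lapply(groups, function(g) {
      if (!is.null(g$direction)) .unitVec(g$direction) else .randUnit()
    })
    memb <- lapply(groups, function(g) labIdx(g$members))
    amp <- vapply(groups, function(g) g$amplitude, 0)
    nodeU <- matrix(NA_real_, nNodes, 3)
    for (k in seq_len(nNodes)) {
      inG <- which(vapply(memb, function(m) k %in% m, TRUE))
      nodeU[k, ] <- if (length(inG)) gU[[inG[1]]] else .randUnit()
    }
    S <- matrix(rnorm(nFrames * length(groups)), nFrames)
    E <- matrix(rnorm(nFrames * nNodes, sd = noiseSd), nFrames)
    coords <- array(NA_real_, c(nFrames, nNodes, 3))
    for (k in seq_len(nNodes)) {
      disp <- E[, k, drop = FALSE] %*% nodeU[k, , drop = FALSE]
      inG <- which(vapply(memb, function(m) k %in% m, TRUE))
      for (g in inG)
        disp <- disp + (amp[g] * S[, g, drop = FALSE]) %*%
                       matrix(gU[[g]], 1)
      coords[, k, ] <- rep(base[k, ], each = nFrames) + disp
    }
    atoms <- data.frame(
      name = c(rep("CA", nResidues), if (ligand) "N1"),
      element = c(rep("C", nResidues), if (ligand) "N"),
      resid = seq_len(nNodes),
      resname = c(rep("GLY", nResidues), if (ligand) "LIG"),
      chain = "A", stringsAsFactors = FALSE)
    Trajectory(coords, atoms, frameInterval)
  })
}

.toyTargets <- list(
  active = c(lbs_tightening = 11.0, npxxy_hbond = 2.0, npxxy_ca = 9.0,
             pif_36 = 9.0, pif_56 = 13.0, edry_ionic = 20.0),
  inactive = c(lbs_tightening = 13.0, npxxy_hbond = 5.0, npxxy_ca = 11.5,
               pif_36 = 11.5, pif_56 = 12.0, edry_ionic = 3.5))

#' Minimal seven-helix toy receptor with planted motif geometry
#'
#' Builds a small structure carrying exactly the atoms the six microswitch
#' descriptors need (Calpha atoms, the Ser 3.39 hydroxyl, the Asn 7.49
#' side-chain amide with hydrogens, the Arg 3.50 guanidinium and the Glu
#' 6.30 carboxylate), placed so every descriptor equals its target
#' distance exactly at zero jitter, plus a matching Ballesteros-Weinstein
#' mapping. Targets default to illustrative active/inactive geometries
#' (e.g. the E/DRY ionic-lock distance near 20 Angstrom when active,
#' salt-bridge range when inactive; the NPxxY donor-acceptor distance near
#' 5 Angstrom — no hydrogen bond — when inactive).
#'
#' @param state \code{"active"} or \code{"inactive"}: selects the default
#'   targets.
#' @param targets optional named vector overriding any of the six
#'   descriptor targets (Angstrom).
#' @param jitterSd isotropic per-atom, per-frame Gaussian jitter
#'   (Angstrom); 0 = exact geometry in every frame.
#' @param nFrames number of frames.
#' @param frameInterval ns per frame (defaults give a 100 ns series).
#' @param hydrogens include the Asn 7.49 amide hydrogens?
#' @param ligand include a two-atom ligand pseudo-residue (resname
#'   \code{"LIG"}, resid 900) next to the binding-pocket region?
#' @param seed integer seed for the jitter.
#' @return List with \code{trajectory} ([Trajectory-class]) and
#'   \code{mapping} ([BWMapping-class]).
#' @export
makeToyGpcr <- function(state = c("inactive", "active"), targets = NULL,
                        jitterSd = 0, nFrames = 100, frameInterval = 1,
                        hydrogens = TRUE, ligand = TRUE, seed = 1) {
  state <- match.arg(state)
  tg <- .toyTargets[[state]]
  if (!is.null(targets)) {
    bad <- setdiff(names(targets), names(tg))
    if (length(bad)) stop("unknown descriptor target(s): ",
                          paste(bad, collapse = ", "))
    tg[names(targets)] <- targets
    if (any(tg <= 0)) stop("descriptor targets must be positive")
  }
  lbs <- tg[["lbs_tightening"]]; hb <- tg[["npxxy_hbond"]]
  nca <- tg[["npxxy_ca"]]; p36 <- tg[["pif_36"]]; p56 <- tg[["pif_56"]]
  edry <- tg[["edry_ionic"]]
  A <- function(resid, resname, name, element, x, y, z)
    data.frame(resid = resid, resname = resname, name = name,
               element = element, x = x, y = y, z = z,
               stringsAsFactors = FALSE)
  at <- rbind(
    A(332, "ASP", "CA", "C", 5, 5, -40),
    A(339, "SER", "CA", "C", -2.5, 1.0, 180),
    A(339, "SER", "CB", "C", -1.5, 0.3, 180),
    A(339, "SER", "OG", "O", 0, 0, 180),
    A(340, "ILE", "CA", "C", p36, 0, 0),
    A(344, "CYS", "CA", "C", 0, 0, 120),
    A(350, "ARG", "CA", "C", -4.5, 0.5, 240),
    A(350, "ARG", "NE", "N", -2.2, 0.9, 240),
    A(350, "ARG", "CZ", "C", -1.3, 0, 240),
    A(350, "ARG", "NH1", "N", 0, 0, 240),
    A(350, "ARG", "NH2", "N", -1.9, -1.0, 240),
    A(546, "SER", "CA", "C", 0, 0, 60),
    A(550, "PRO", "CA", "C", 0, p56, 0),
    A(630, "GLU", "CA", "C", edry + 4.5, 0.5, 240),
    A(630, "GLU", "CD", "C", edry + 1.25, 0, 240),
    A(630, "GLU", "OE1", "O", edry, 0, 240),
    A(630, "GLU", "OE2", "O", edry + 1.9, 1.0, 240),
    A(644, "PHE", "CA", "C", 0, 0, 0),
    A(742, "ALA", "CA", "C", lbs, 0, 60),
    A(749, "ASN", "CA", "C", hb + 3.5, 1.2, 180),
    A(749, "ASN", "CB", "C", hb + 2.6, 0.6, 180),
    A(749, "ASN", "ND2", "N", hb + 1.01, 0, 180),
    if (hydrogens) A(749, "ASN", "HD21", "H", hb, 0, 180),
    if (hydrogens) A(749, "ASN", "HD22", "H", hb + 1.4, 0.85, 180),
    A(753, "TYR", "CA", "C", nca, 0, 120),
    if (ligand) A(900, "LIG", "N1", "N", 0.8, -2.9, 0),
    if (ligand) A(900, "LIG", "C1", "C", 1.6, -2.2, 0))
  xyz0 <- as.matrix(at[, c("x", "y", "z")])
  nA <- nrow(at)
  coords <- .withSeed(seed, {
    out <- array(0, c(nFrames, nA, 3))
    for (d in 1:3) out[, , d] <- matrix(xyz0[, d], nFrames, nA, byrow = TRUE)
    if (jitterSd > 0)
      out <- out + array(rnorm(nFrames * nA * 3, sd = jitterSd),
                         c(nFrames, nA, 3))
    out
  })
  atoms <- at[, c("name", "element", "resid", "resname")]
  atoms$chain <- "A"
  mapping <- BWMapping(
    generic = c("3.32", "3.39", "3.40", "3.44", "3.50", "5.46", "5.50",
                "6.30", "6.44", "7.42", "7.49", "7.53"),
    resid = c(332, 339, 340, 344, 350, 546, 550, 630, 644, 742, 749, 753),
    resname = c("D", "S", "I", "C", "R", "S", "P", "E", "F", "A", "N", "Y"))
  list(trajectory = Trajectory(coords, atoms, frameInterval),
       mapping = mapping)
}

#' Default binding-site mapping for synthetic PIEDA tables
#'
#' A Ballesteros-Weinstein mapping covering a conserved aminergic
#' binding-site residue set (helices 2-7), with residue ids encoded as
#' \code{helix * 100 + position}.
#'
#' @return A [BWMapping-class].
#' @export
bindingSiteMapping <- function() {
  gen <- c("2.50", "3.32", "3.33", "3.36", "5.39", "5.42", "5.43", "5.46",
           "6.48", "6.51", "6.52", "6.55", "7.39", "7.43")
  resid <- vapply(strsplit(gen, ".", fixed = TRUE), function(p)
    as.integer(p[1]) * 100L + as.integer(p[2]), 0L)
  nm <- c("D", "D", "V", "C", "V", "S", "S", "S", "W", "F", "F", "H",
          "T", "Y")
  BWMapping(gen, resid, nm)
}

.drawComponents <- function(n, repulsive) {
  draw <- function(mu, sdv) rnorm(n, mu, sdv)
  if (repulsive) {
    e_es <- draw(1.0, 1.0); e_ex <- draw(7.0, 1.5); e_ct <- draw(-0.8, 0.4)
    e_disp <- draw(-2.0, 0.8); dg <- draw(1.0, 1.0)
  } else {
    e_es <- draw(-4.0, 2.0); e_ex <- draw(3.0, 1.0); e_ct <- draw(-1.5, 0.8)
    e_disp <- draw(-3.0, 1.0); dg <- draw(1.5, 1.0)
  }
  data.frame(e_es = e_es, e_ex = e_ex, e_ct = e_ct, e_disp = e_disp,
             dg_solv = dg, pie = e_es + e_ex + e_ct + e_disp + dg)
}

## components conditioned on the sign of the total: redraw until every
## record's PIE sign matches its attractive/repulsive designation
.drawSigned <- function(n, repulsive) {
  out <- .drawComponents(n, repulsive)
  want <- if (repulsive) 1 else -1
  for (iter in 1:1000) {
    bad <- sign(out$pie) != want
    if (!any(bad)) return(out)
    out[bad, ] <- .drawComponents(sum(bad), repulsive)
  }
  stop("could not realise the requested interaction signs")
}

#' Synthetic per-residue PIEDA tables with controlled structure
#'
#' Emulates the structure of real interaction-energy tables: per class, a
#' contact probability controls how many binding-site residues each
#' complex engages (the planted occupancy effect), and a repulsive
#' fraction controls how many contacted residues get a positive total
#' PIE. Component energies are drawn from Gaussian mixtures conditioned
#' on the designated sign; non-contacted residues carry near-zero
#' energies and a contact distance above the cutoff. Deterministic under
#' the seed.
#'
#' @param nPerClass named integer vector: complexes per class, e.g.
#'   \code{c(agonist = 7, antagonist = 10)}.
#' @param contactProb named vector of per-residue contact probabilities
#'   per class.
#' @param repulsiveFraction named vector: probability that a contacted
#'   residue is repulsive, per class.
#' @param mapping a [BWMapping-class] giving the residue universe
#'   (default [bindingSiteMapping()]).
#' @param seed integer seed.
#' @return List of [PIEDATable-class], agonists first.
#' @export
makePiedaTables <- function(nPerClass = c(agonist = 7, antagonist = 10),
                            contactProb = c(agonist = 0.55, antagonist = 0.8),
                            repulsiveFraction = c(agonist = 0.1,
                                                  antagonist = 0.15),
                            mapping = bindingSiteMapping(), seed = 1) {
  stopifnot(all(names(nPerClass) %in% c("agonist", "antagonist", "unknown")),
            all(contactProb[names(nPerClass)] >= 0),
            all(contactProb[names(nPerClass)] <= 1))
  tb <- mapping@table
  prefix <- c(agonist = "AG", antagonist = "AN", unknown = "UN")
  .withSeed(seed, {
    out <- list()
    for (cl in names(nPerClass)) {
      for (k in seq_len(nPerClass[[cl]])) {
        n <- nrow(tb)
        contact <- runif(n) < contactProb[[cl]]
        repul <- contact & runif(n) < repulsiveFraction[[cl]]
        rec <- .drawComponents(n, FALSE)
        rec[contact & !repul, ] <- .drawSigned(sum(contact & !repul), FALSE)
        if (any(repul)) rec[repul, ] <- .drawSigned(sum(repul), TRUE)
        # non-contacted residues: near-zero energies, distance beyond cutoff
        far <- !contact
        if (any(far)) {
          z <- matrix(rnorm(sum(far) * 5, sd = 0.1), sum(far))
          rec[far, c("e_es", "e_ex", "e_ct", "e_disp", "dg_solv")] <- z
          rec$pie[far] <- rowSums(z)
        }
        rec$min_dist <- ifelse(contact, runif(n, 2.6, 4.4),
                               runif(n, 4.6, 9.0))
        id <- sprintf("%s%d", prefix[[cl]], k)
        out[[id]] <- PIEDATable(
          data.frame(residue_id = tb$resid, residue_name = tb$resname,
                     rec[, c("pie", "e_es", "e_ex", "e_ct", "e_disp",
                             "dg_solv", "min_dist")],
                     stringsAsFactors = FALSE),
          complexId = id, ligandId = paste0("lig_", id), classLabel = cl)
      }
    }
    out
  })
}
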
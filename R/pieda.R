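#' @include AllClasses.R bw-mapping.R
NULL

#' Polarity share of a pair interaction energy
#'
#' Percentage share of the electrostatic plus charge-transfer components
#' in the three-component decomposition, on absolute values:
#' \deqn{\%E_{es+ct} = \frac{|E_{es}| + |E_{ct}|}
#'   {|E_{es}| + |E_{ct}| + |E_{disp}|} \cdot 100}
#' 100 means a purely polar interaction; 0 means a purely dispersive
#' (hydrophobic) one. When all three components are zero the share is
#' undefined and flagged rather than raised as an error.
#'
#' @param eEs,eCt,eDisp electrostatic, charge-transfer and dispersion
#'   components in kcal/mol (vectorised).
#' @return data.frame with columns \code{value} (percentage in [0, 100],
#'   \code{NA} when undefined) and \code{defined} (logical).
#' @examples
#' polarityShare(-5, -2, 0)$value    # 100: purely polar
#' polarityShare(0, 0, -3)$value     # 0: purely dispersive
#' @export
polarityShare <- function(eEs, eCt, eDisp) {
  stopifnot(all(is.finite(eEs)), all(is.finite(eCt)), all(is.finite(eDisp)))
  num <- abs(eEs) + abs(eCt)
  den <- num + abs(eDisp)
  defined <- den > 0
  value <- ifelse(defined, num / den * 100, NA_real_)
  data.frame(value = value, defined = defined)
}

#' Polarity shares for every residue of a PIEDA table
#'
#' @param table a [PIEDATable-class].
#' @return data.frame with columns \code{residue_id}, \code{value},
#'   \code{defined}.
#' @export
polarityTable <- function(table) {
  stopifnot(is(table, "PIEDATable"))
  rec <- table@records
  cbind(data.frame(residue_id = rec$residue_id),
        polarityShare(rec$e_es, rec$e_ct, rec$e_disp))
}

#' Classify ligand-residue interactions
#'
#' Three-way call per residue: \code{"no_contact"} when the minimum
#' contact distance exceeds the cutoff or is missing (the boundary is
#' closed: a distance exactly at the cutoff still counts as contact);
#' otherwise \code{"attractive"} for negative total pair interaction
#' energy and \code{"repulsive"} for positive. A PIE of exactly zero is
#' classified with the attractive branch and reported with a message
#' (the two-colour scheme has no neutral class).
#'
#' @param pie total pair interaction energies in kcal/mol, or a
#'   [PIEDATable-class] (then \code{minDist} is taken from the table).
#' @param minDist minimum contact distances in Angstrom (\code{NA} =
#'   missing).
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @return data.frame with columns \code{residue_id} (when a table was
#'   given), \code{category} (factor: attractive, repulsive, no_contact).
#' @export
classifyInteraction <- function(pie, minDist = NULL, cutoff = 4.5) {
  if (is(pie, "PIEDATable")) {
    rec <- pie@records
    out <- classifyInteraction(rec$pie, rec$min_dist, cutoff)
    return(cbind(data.frame(residue_id = rec$residue_id), out))
  }
  stopifnot(length(pie) == length(minDist), cutoff > 0)
  noContact <- is.na(minDist) | minDist > cutoff
  if (any(pie == 0 & !noContact))
    message(sum(pie == 0 & !noContact),
            " contact(s) with PIE exactly 0 classified as attractive")
  category <- ifelse(noContact, "no_contact",
                     ifelse(pie > 0, "repulsive", "attractive"))
  data.frame(category = factor(category,
             levels = c("attractive", "repulsive", "no_contact")))
}

.sortGenericCols <- function(cols) {
  isGeneric <- grepl("^[0-9]+\\.[0-9]+$", cols)
  g <- cols[isGeneric]
  helix <- as.integer(sub("\\..*", "", g))
  pos <- as.integer(sub(".*\\.", "", g))
  c(g[order(helix, pos)], sort(cols[!isGeneric]))
}

#' Assemble a cross-complex interaction-energy heat map
#'
#' One row per complex (agonists first, then antagonists, then unknown;
#' alphabetical within class), one column per contacted residue labelled
#' by its generic number, cells holding the total PIE in kcal/mol and
#' \code{NA} marking no contact (minimum distance above the cutoff or
#' missing). Residues whose generic numbers are listed in \code{exclude}
#' are dropped from the matrix and reported in \code{excluded}; the
#' conserved salt-bridge aspartate 3.32 is excluded by default because its
#' PIE (about -100 kcal/mol) would dwarf every other cell. Residues absent
#' from the mapping keep their raw residue id as the column label, with a
#' warning.
#'
#' @param tables list of [PIEDATable-class] objects sharing one mapping.
#' @param mapping a [BWMapping-class].
#' @param exclude character vector of generic numbers to omit
#'   (default \code{"3.32"}).
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @return List with \code{matrix} (complexes x residues), \code{classes}
#'   (per-row class labels) and \code{excluded}.
#' @export
buildHeatmap <- function(tables, mapping, exclude = "3.32", cutoff = 4.5) {
  stopifnot(length(tables) >= 1L, is(mapping, "BWMapping"))
  info <- lapply(tables, function(tb) {
    stopifnot(is(tb, "PIEDATable"))
    rec <- tb@records
    contacted <- !is.na(rec$min_dist) & rec$min_dist <= cutoff
    gen <- genericOf(mapping, rec$residue_id)
    if (any(is.na(gen) & contacted))
      warning("complex ", tb@complexId, ": residue id(s) ",
              paste(rec$residue_id[is.na(gen) & contacted], collapse = ", "),
              " not in the BW mapping; keeping raw residue id")
    gen[is.na(gen)] <- as.character(rec$residue_id[is.na(gen)])
    list(id = tb@complexId, class = tb@classLabel,
         gen = gen[contacted], pie = rec$pie[contacted])
  })
  classes <- vapply(info, `[[`, "", "class")
  ids <- vapply(info, `[[`, "", "id")
  rowOrder <- order(match(classes, c("agonist", "antagonist", "unknown")), ids)
  allCols <- .sortGenericCols(unique(unlist(lapply(info, `[[`, "gen"))))
  excluded <- intersect(exclude, allCols)
  cols <- setdiff(allCols, exclude)
  m <- matrix(NA_real_, length(info), length(cols),
              dimnames = list(ids[rowOrder], cols))
  for (r in seq_along(rowOrder)) {
    x <- info[[rowOrder[r]]]
    keep <- x$gen %in% cols
    m[r, x$gen[keep]] <- x$pie[keep]
  }
  list(matrix = m, classes = classes[rowOrder], excluded = excluded)
}

## permutation test on a difference of group means; two-sided, add-one
## correction, seeded and restoring the caller's RNG state
.permTestMeanDiff <- function(x, y, nPerm, seed = NULL) {
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  nx <- length(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  perm <- replicate(nPerm, {
    i <- sample.int(length(pool), nx)
    mean(pool[i]) - mean(pool[-i])
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (nPerm + 1)
  list(estimate = obs, p.value = p)
}

#' Binding-site occupancy statistics by ligand class
#'
#' Counts, per complex, the residues in contact with the ligand (minimum
#' distance at most \code{cutoff}), aggregates the counts by functional
#' class, and — when both an agonist and an antagonist group are present —
#' tests the difference of class means with a seeded label-permutation
#' test (distribution-free, suited to the small per-class sample sizes
#' typical of these studies). Also reports how often each residue is
#' contacted within each class.
#'
#' @param tables list of [PIEDATable-class] objects.
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @param nPerm number of label permutations (default 999).
#' @param seed optional integer seed for the permutation draw.
#' @return List with \code{perComplex} (data.frame: complex, class, count),
#'   \code{byClass} (data.frame: class, n, mean, median),
#'   \code{contactFrequency} (residue x class matrix of contact
#'   frequencies) and \code{comparison} (list: estimate = antagonist mean
#'   minus agonist mean, p.value; or a character note when one class is
#'   absent).
#' @export
occupancyStats <- function(tables, cutoff = 4.5, nPerm = 999, seed = NULL) {
  stopifnot(length(tables) >= 1L)
  per <- do.call(rbind, lapply(tables, function(tb) {
    stopifnot(is(tb, "PIEDATable"))
    rec <- tb@records
    data.frame(complex = tb@complexId, class = tb@classLabel,
               count = sum(!is.na(rec$min_dist) & rec$min_dist <= cutoff),
               stringsAsFactors = FALSE)
  }))
  byClass <- do.call(rbind, lapply(split(per, per$class), function(d)
    data.frame(class = d$class[1], n = nrow(d), mean = mean(d$count),
               median = median(d$count), stringsAsFactors = FALSE)))
  rownames(byClass) <- NULL
  # residue contact frequency by class
  contacts <- lapply(tables, function(tb) {
    rec <- tb@records
    rec$residue_id[!is.na(rec$min_dist) & rec$min_dist <= cutoff]
  })
  resids <- sort(unique(unlist(lapply(tables, function(tb)
    tb@records$residue_id))))
  classes <- sort(unique(per$class))
  freq <- matrix(0, length(resids), length(classes),
                 dimnames = list(as.character(resids), classes))
  for (k in seq_along(tables)) {
    cl <- per$class[k]
    hit <- as.character(contacts[[k]])
    freq[hit, cl] <- freq[hit, cl] + 1
  }
  for (cl in classes) freq[, cl] <- freq[, cl] / sum(per$class == cl)
  comparison <- if (all(c("agonist", "antagonist") %in% per$class)) {
    .permTestMeanDiff(per$count[per$class == "antagonist"],
                      per$count[per$class == "agonist"], nPerm, seed)
  } else "comparison unavailable: need at least one agonist and one antagonist"
  list(perComplex = per, byClass = byClass, contactFrequency = freq,
       comparison = comparison)
}
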
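#' @include AllClasses.R
NULL

#' Resolve a Ballesteros-Weinstein generic number to a residue id
#'
#' Looks a generic number (e.g. \code{"3.32"}) up in a mapping. When the
#' mapping carries an expected one-letter residue name and the caller
#' supplies the structure's actual residue name, a mismatch raises a
#' warning (the lookup still succeeds): the numbering is taken as given,
#' but disagreements with the structure are worth surfacing.
#'
#' @param mapping a [BWMapping-class].
#' @param generic generic number as a string, \code{"helix.position"}.
#' @param resname optional observed one-letter residue name to check
#'   against the mapping's expectation.
#' @return Integer residue sequence id.
#' @examples
#' bw <- BWMapping(c("3.32", "6.48"), c(115, 256), c("D", "W"))
#' resolveBW(bw, "3.32")
#' @export
resolveBW <- function(mapping, generic, resname = NULL) {
  stopifnot(is(mapping, "BWMapping"))
  tb <- mapping@table
  i <- match(generic, tb$generic)
  if (is.na(i)) {
    near <- tb$generic[agrepl(generic, tb$generic, max.distance = 1)]
    hint <- if (length(near))
      paste0("; near misses: ", paste(head(near, 5), collapse = ", "))
    else ""
    stop("unknown generic number '", generic, "'", hint)
  }
  expect <- tb$resname[i]
  if (!is.null(resname) && !is.na(expect) && !identical(resname, expect))
    warning(sprintf(
      "mapping expects residue '%s' at %s (id %d) but structure has '%s'",
      expect, generic, tb$resid[i], resname))
  tb$resid[i]
}

#' Helix index of a residue
#'
#' @param mapping a [BWMapping-class].
#' @param resid residue sequence id(s).
#' @return Integer helix index (1-7) per residue, \code{NA} for residues
#'   not in the mapping (loops, ligand pseudo-residues).
#' @export
helixOf <- function(mapping, resid) {
  stopifnot(is(mapping, "BWMapping"))
  tb <- mapping@table
  tb$helix[match(as.integer(resid), tb$resid)]
}

#' Generic number of a residue (reverse lookup)
#'
#' @param mapping a [BWMapping-class].
#' @param resid residue sequence id(s).
#' @return Character generic number per residue, \code{NA} when unmapped.
#' @export
genericOf <- function(mapping, resid) {
  stopifnot(is(mapping, "BWMapping"))
  tb <- mapping@table
  tb$generic[match(as.integer(resid), tb$resid)]
}
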
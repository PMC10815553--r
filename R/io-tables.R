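#' @include AllClasses.R
NULL

.piedaCols <- c("complex_id", "ligand_id", "class", "residue_id",
                "residue_name", "pie", "e_es", "e_ex", "e_ct", "e_disp",
                "dg_solv", "min_dist")

#' Read a per-residue PIEDA energy table
#'
#' Canonical CSV schema (one complex per file):
#' \code{complex_id,ligand_id,class,residue_id,residue_name,pie,e_es,e_ex,
#' e_ct,e_disp,dg_solv,min_dist}. Energies in kcal/mol, \code{min_dist} in
#' Angstrom; an empty \code{min_dist} cell means the contact distance was
#' not determined and is kept as missing, never coerced to zero.
#'
#' @param path CSV file path.
#' @return A [PIEDATable-class].
#' @examples
#' f <- system.file("extdata", "example_pieda.csv", package = "gpcrdyn")
#' readPiedaTable(f)
#' @export
readPiedaTable <- function(path) {
  if (!file.exists(path)) stop("PIEDA table not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  missing <- setdiff(.piedaCols, names(raw))
  if (length(missing))
    stop("PIEDA CSV is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) stop("PIEDA CSV has no records: ", path)
  num <- function(col, required = TRUE) {
    x <- raw[[col]]
    empty <- is.na(x) | x == ""
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!empty & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                   x[bad[1]], col, bad[1]))
    if (required && any(empty))
      stop(sprintf("missing value in required column '%s' at data row %d",
                   col, which(empty)[1]))
    v
  }
  rid <- num("residue_id")
  dup <- rid[duplicated(rid)]
  if (length(dup))
    stop("duplicated residue id in PIEDA table: ", paste(unique(dup), collapse = ", "))
  for (col in c("complex_id", "ligand_id", "class"))
    if (length(unique(raw[[col]])) != 1L)
      stop("PIEDA CSV must describe a single complex; column '", col,
           "' is not constant")
  rec <- data.frame(
    residue_id = as.integer(rid), residue_name = raw$residue_name,
    pie = num("pie"), e_es = num("e_es"), e_ex = num("e_ex"),
    e_ct = num("e_ct"), e_disp = num("e_disp"), dg_solv = num("dg_solv"),
    min_dist = num("min_dist", required = FALSE),
    stringsAsFactors = FALSE)
  PIEDATable(rec, complexId = raw$complex_id[1], ligandId = raw$ligand_id[1],
             classLabel = raw$class[1])
}

#' Write a PIEDA table to the canonical CSV schema
#'
#' @param table a [PIEDATable-class].
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writePiedaTable <- function(table, path) {
  stopifnot(is(table, "PIEDATable"))
  rec <- table@records
  out <- data.frame(complex_id = table@complexId, ligand_id = table@ligandId,
                    class = table@classLabel, rec, stringsAsFactors = FALSE)
  write.csv(out[, .piedaCols], path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Read a Ballesteros-Weinstein mapping table
#'
#' CSV schema: \code{generic_number,helix,residue_id,residue_name}.
#'
#' @param path CSV file path.
#' @return A [BWMapping-class].
#' @export
readBWMapping <- function(path) {
  if (!file.exists(path)) stop("BW mapping file not found: ", path)
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("generic_number", "helix", "residue_id", "residue_name")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("BW mapping CSV is missing columns: ", paste(missing, collapse = ", "))
  BWMapping(generic = raw$generic_number,
            resid = as.integer(raw$residue_id),
            resname = ifelse(raw$residue_name == "", NA, raw$residue_name),
            helix = as.integer(raw$helix))
}

#' Write a BW mapping table
#'
#' @param mapping a [BWMapping-class].
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeBWMapping <- function(mapping, path) {
  stopifnot(is(mapping, "BWMapping"))
  tb <- mapping@table
  out <- data.frame(generic_number = tb$generic, helix = tb$helix,
                    residue_id = tb$resid, residue_name = tb$resname)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Export analysis results
#'
#' Writes result objects with deterministic column/key ordering so that
#' re-reading yields an equal object. Supported: [PathSet-class] to JSON
#' (re-read with [readPathSet()]), [DescriptorSeries-class] to CSV (one row
#' per frame), and plain matrices (e.g. heat maps) to CSV with residues as
#' columns and complexes as rows.
#'
#' @param obj the result object.
#' @param path output file path.
#' @param format \code{"json"} or \code{"csv"}; default chosen by type.
#' @return Invisibly, \code{path}.
#' @export
writeResults <- function(obj, path, format = NULL) {
  if (is(obj, "PathSet")) {
    if (!is.null(format) && format != "json")
      stop("PathSet results are written as JSON")
    od <- obj@optimalDistance
    if (!is.finite(od)) od <- "Inf"   # JSON has no Inf literal
    x <- list(source = obj@source, sink = obj@sink,
              optimal_distance = od, offset = obj@offset,
              n = if (is.na(obj@nOptimal)) NULL else obj@nOptimal,
              N = obj@nPaths,
              disconnected = obj@disconnected,
              paths = lapply(seq_along(obj@paths), function(i)
                list(nodes = as.list(obj@paths[[i]]),
                     distance = obj@distances[[i]])))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (is(obj, "DescriptorSeries")) {
    v <- obj@values
    df <- data.frame(frame = seq_along(v),
                     time_ns = (seq_along(v) - 1) * obj@frameInterval,
                     value = v)
    names(df)[3] <- obj@name
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (is.matrix(obj)) {
    df <- data.frame(complex = rownames(obj), obj, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, na = "")
  } else {
    stop("unsupported result type: ", paste(class(obj), collapse = "/"))
  }
  invisible(path)
}

#' Read a PathSet written by [writeResults()]
#'
#' @param path JSON file path.
#' @return A [PathSet-class] equal to the one written.
#' @export
readPathSet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  paths <- lapply(x$paths, function(p) vapply(p$nodes, as.character, ""))
  new("PathSet", source = x$source, sink = x$sink, paths = paths,
      distances = vapply(x$paths, function(p) as.numeric(p$distance), 0),
      optimalDistance = as.numeric(x$optimal_distance),
      offset = as.numeric(x$offset),
      nOptimal = if (is.null(x$n)) NA_integer_ else as.integer(x$n),
      nPaths = as.integer(x$N), disconnected = isTRUE(x$disconnected))
}
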
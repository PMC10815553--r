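#' @include AllClasses.R trajectory-metrics.R network.R paths.R pieda.R
NULL

.stageResult <- function(complex, stage, status, file = NA_character_,
                         note = "") {
  data.frame(complex = complex, stage = stage, status = status,
             file = file, md5 = if (!is.na(file) && file.exists(file))
               unname(tools::md5sum(file)) else NA_character_,
             note = note, stringsAsFactors = FALSE)
}

#' Run the full per-complex analysis pipeline
#'
#' Orchestrates, for each configured complex, the descriptor analysis
#' (RMSD plus the six microswitch descriptors, block medians, state
#' classification against configured regions), the dynamical-network path
#' analysis (ligand to sink node), and, across complexes, the PIEDA heat
#' map and occupancy comparison. Complexes are isolated: a failing stage
#' is recorded in the manifest and the run continues. Identical config
#' and seed give an identical manifest (checksums included).
#'
#' @param config either a YAML file path or a list with entries:
#' \describe{
#'   \item{complexes}{list of \code{list(name, trajectory, pieda, class,
#'     ligandResname, ligandNitrogen, frameInterval)}; \code{pieda} may be
#'     omitted or missing on disk (that stage is then skipped with a
#'     note).}
#'   \item{bwMap}{path to the BW mapping CSV.}
#'   \item{regions}{path to the regions YAML (optional; classification is
#'     skipped without it).}
#'   \item{network}{list: \code{cutoff} (4.5), \code{frameFraction}
#'     (0.75), \code{offset} (20), \code{sink} (generic number, default
#'     \code{"6.29"}, falling back to \code{"6.30"} when unmapped).}
#'   \item{pieda}{list: \code{cutoff} (4.5), \code{exclude}
#'     (\code{"3.32"}).}
#'   \item{blockNs}{block length in ns (10).}
#'   \item{outDir}{output directory (created).}
#'   \item{seed}{integer seed for the permutation test.}
#' }
#' @return Invisibly, the manifest data.frame (also written as
#'   \code{manifest.json} in \code{outDir}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$complexes), !is.null(config$bwMap),
            !is.null(config$outDir))
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  mapping <- readBWMapping(config$bwMap)
  regions <- if (!is.null(config$regions)) readRegions(config$regions)
  netCfg <- config$network
  cutoff <- netCfg$cutoff %||% 4.5
  frameFraction <- netCfg$frameFraction %||% 0.75
  offset <- netCfg$offset %||% 20
  sinkBW <- netCfg$sink %||% "6.29"
  piedaCfg <- config$pieda
  pCut <- piedaCfg$cutoff %||% 4.5
  pExcl <- piedaCfg$exclude %||% "3.32"
  blockNs <- config$blockNs %||% 10
  manifest <- list()
  add <- function(x) manifest[[length(manifest) + 1L]] <<- x
  tables <- list()

  for (cx in config$complexes) {
    name <- cx$name
    traj <- tryCatch(
      readTrajectory(cx$trajectory, frameInterval = cx$frameInterval %||% 0.1),
      error = function(e) e)
    if (inherits(traj, "error")) {
      add(.stageResult(name, "read", "failed", note = conditionMessage(traj)))
      next
    }
    ## descriptors -----------------------------------------------------
    blocks <- list()
    for (d in c("rmsd", .descriptorNames)) {
      res <- tryCatch({
        s <- if (d == "rmsd") rmsdSeries(traj)
             else motifDistance(traj, mapping, d)
        f <- file.path(outDir, sprintf("%s_%s.csv", name, d))
        writeResults(s, f)
        if (d != "rmsd")
          blocks[[d]] <- blockMedians(s, blockNs)
        f
      }, error = function(e) e)
      if (inherits(res, "error"))
        add(.stageResult(name, paste0("descriptor:", d), "failed",
                         note = conditionMessage(res)))
      else
        add(.stageResult(name, paste0("descriptor:", d), "ok", res))
    }
    ## state classification -------------------------------------------
    if (!is.null(regions)) {
      res <- tryCatch({
        calls <- list()
        for (p in regions) {
          if (is.null(blocks[[p$x]]) || is.null(blocks[[p$y]])) next
          rects <- regionsFor(regions, p$x, p$y)
          cl <- classifyBlocks(blocks[[p$x]], blocks[[p$y]], rects)
          calls[[paste(p$x, p$y, sep = "|")]] <- cl
        }
        f <- file.path(outDir, sprintf("%s_states.json", name))
        jsonlite::write_json(calls, f, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        f
      }, error = function(e) e)
      if (inherits(res, "error"))
        add(.stageResult(name, "states", "failed",
                         note = conditionMessage(res)))
      else add(.stageResult(name, "states", "ok", res))
    }
    ## network paths ---------------------------------------------------
    res <- tryCatch({
      nd <- assignNodes(traj, cx$ligandResname %||% "LIG",
                        cx$ligandNitrogen %||% "N1")
      C <- correlationMatrix(traj, nd)
      mk <- contactMask(traj, nd, cutoff = cutoff,
                        frameFraction = frameFraction)
      net <- buildNetwork(C, mk, nd)
      sinkRes <- tryCatch(resolveBW(mapping, sinkBW),
                          error = function(e) resolveBW(mapping, "6.30"))
      ps <- suboptimalPaths(net, cx$ligandResname %||% "LIG",
                            as.character(sinkRes), offset = offset)
      f <- file.path(outDir, sprintf("%s_paths.json", name))
      writeResults(ps, f)
      f
    }, error = function(e) e)
    if (inherits(res, "error"))
      add(.stageResult(name, "network", "failed",
                       note = conditionMessage(res)))
    else add(.stageResult(name, "network", "ok", res))
    ## pieda table -----------------------------------------------------
    if (!is.null(cx$pieda)) {
      if (file.exists(cx$pieda)) {
        res <- tryCatch(readPiedaTable(cx$pieda), error = function(e) e)
        if (inherits(res, "error"))
          add(.stageResult(name, "pieda", "failed",
                           note = conditionMessage(res)))
        else {
          tables[[name]] <- res
          add(.stageResult(name, "pieda", "ok", cx$pieda))
        }
      } else {
        add(.stageResult(name, "pieda", "skipped",
                         note = paste("missing file:", cx$pieda)))
      }
    }
  }
  ## cross-complex PIEDA summary ---------------------------------------
  if (length(tables)) {
    res <- tryCatch({
      hm <- buildHeatmap(tables, mapping, exclude = pExcl, cutoff = pCut)
      f1 <- file.path(outDir, "heatmap.csv")
      writeResults(hm$matrix, f1)
      occ <- occupancyStats(tables, cutoff = pCut,
                            seed = config$seed %||% 1)
      f2 <- file.path(outDir, "occupancy.json")
      occOut <- occ
      occOut$contactFrequency <- as.data.frame(occ$contactFrequency)
      jsonlite::write_json(occOut, f2, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "rows")
      pol <- do.call(rbind, lapply(names(tables), function(nm)
        cbind(complex = nm, polarityTable(tables[[nm]]))))
      f3 <- file.path(outDir, "polarity.csv")
      write.csv(pol, f3, row.names = FALSE, quote = FALSE)
      c(f1, f2, f3)
    }, error = function(e) e)
    if (inherits(res, "error"))
      add(.stageResult("ALL", "pieda_summary", "failed",
                       note = conditionMessage(res)))
    else for (f in res)
      add(.stageResult("ALL", "pieda_summary", "ok", f))
  }
  manifest <- do.call(rbind, manifest)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "string")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
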
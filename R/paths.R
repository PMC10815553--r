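#' @include AllClasses.R network.R bw-mapping.R
NULL

## Numerical tolerance for "equal distance" decisions (tied optimal paths,
## the strict offset bound). Weights are O(1) so an absolute tolerance is
## appropriate.
.pathTol <- 1e-9

## O(n^2) Dijkstra over the weight matrix; returns distances from `src`
## to every node (Inf = unreachable). W is symmetric, NA = no edge.
.dijkstra <- function(W, src) {
  n <- nrow(W)
  dist <- rep(Inf, n)
  dist[src] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- which(!is.na(W[u, ]) & !done)
    if (length(nb)) {
      cand <- dist[u] + W[u, nb]
      improve <- cand < dist[nb]
      dist[nb[improve]] <- cand[improve]
    }
  }
  dist
}

## Depth-first enumeration of all simple source->sink paths whose total
## weight stays within `bound` (inclusive, up to tolerance). `h` is the
## exact distance-to-sink from a reverse Dijkstra, used for admissible
## branch-and-bound pruning, so the enumeration is exact, never sampled.
.enumeratePaths <- function(W, src, sink, bound, h, maxPaths) {
  n <- nrow(W)
  paths <- list()
  dists <- numeric()
  visited <- rep(FALSE, n)
  stack <- integer(n)
  recurse <- function(u, depth, acc) {
    if (u == sink) {
      if (length(paths) >= maxPaths)
        stop("more than ", maxPaths,
             " paths within the offset; raise maxPaths explicitly")
      paths[[length(paths) + 1L]] <<- stack[seq_len(depth)]
      dists[[length(dists) + 1L]] <<- acc
      return(invisible())
    }
    nb <- which(!is.na(W[u, ]) & !visited)
    for (v in nb) {
      accv <- acc + W[u, v]
      if (accv + h[v] <= bound + .pathTol) {
        visited[v] <<- TRUE
        stack[depth + 1L] <<- v
        recurse(v, depth + 1L, accv)
        visited[v] <<- FALSE
      }
    }
  }
  visited[src] <- TRUE
  stack[1L] <- src
  recurse(src, 1L, 0)
  list(paths = paths, dists = dists)
}

## order paths by distance, then by node-index sequence (shorter prefix
## first on ties); deterministic tie-breaking
.orderPaths <- function(paths, dists) {
  if (length(paths) <= 1L) return(seq_along(paths))
  keys <- vapply(paths, function(p)
    paste(sprintf("%05d", p), collapse = " "), "")
  order(round(dists / .pathTol) * .pathTol, keys)
}

.makePathSet <- function(nodes, srcId, sinkId, paths, dists, opt, offset) {
  ids <- nodes$id
  o <- .orderPaths(paths, dists)
  paths <- lapply(paths[o], function(p) ids[p])
  dists <- dists[o]
  nOpt <- if (length(paths)) length(paths[[1]]) else NA_integer_
  new("PathSet", source = srcId, sink = sinkId, paths = paths,
      distances = as.numeric(dists), optimalDistance = opt,
      offset = as.numeric(offset), nOptimal = as.integer(nOpt),
      nPaths = length(paths), disconnected = !is.finite(opt))
}

.nodeIndex <- function(net, id) {
  i <- match(as.character(id), net@nodes$id)
  if (is.na(i))
    stop("node '", id, "' is not part of the network")
  i
}

#' Optimal communication pathways
#'
#' All minimum-total-weight simple paths between two nodes (ties are all
#' reported). Distance is the sum of the \eqn{-\log|C|} edge weights along
#' the path. An unreachable sink yields a PathSet flagged
#' \code{disconnected}, not an error.
#'
#' @param net a [CorrelationNetwork-class].
#' @param source,sink node ids (e.g. the ligand node and a residue id).
#' @param maxPaths safety cap on the number of enumerated paths; exceeding
#'   it is an error, never a silent truncation.
#' @return A [PathSet-class] with the optimal path(s) only.
#' @export
optimalPaths <- function(net, source, sink, maxPaths = 1e5) {
  suboptimalPaths(net, source, sink, offset = 0, maxPaths = maxPaths)
}

#' Suboptimal communication pathways within an offset
#'
#' Enumerates, exactly, every simple path from \code{source} to
#' \code{sink} whose distance is either equal to the optimal distance or
#' strictly less than optimal + \code{offset} (the offset bound is strict:
#' a path exactly \code{offset} longer than the optimal one is excluded).
#' Paths are sorted by distance, then by node order. In the returned set,
#' \code{n} is the node count of the optimal pathway and \code{N} the
#' number of paths found.
#'
#' @param net a [CorrelationNetwork-class].
#' @param source,sink node ids.
#' @param offset non-negative distance offset (default 20).
#' @param maxPaths safety cap; exceeding it raises an error.
#' @return A [PathSet-class].
#' @export
suboptimalPaths <- function(net, source, sink, offset = 20, maxPaths = 1e5) {
  stopifnot(is(net, "CorrelationNetwork"), offset >= 0)
  W <- net@W
  s <- .nodeIndex(net, source)
  t <- .nodeIndex(net, sink)
  if (s == t) {
    return(.makePathSet(net@nodes, as.character(source), as.character(sink),
                        list(s), 0, 0, offset))
  }
  h <- .dijkstra(W, t)          # symmetric W: distance-to-sink
  opt <- h[s]
  if (!is.finite(opt)) {
    return(.makePathSet(net@nodes, as.character(source), as.character(sink),
                        list(), numeric(), Inf, offset))
  }
  enum <- .enumeratePaths(W, s, t, opt + offset, h, maxPaths)
  # strict bound: keep optimal ties plus paths strictly below opt + offset
  keep <- enum$dists <= opt + .pathTol |
          enum$dists < opt + offset - .pathTol
  .makePathSet(net@nodes, as.character(source), as.character(sink),
               enum$paths[keep], enum$dists[keep], opt, offset)
}

#' Ligand anchor residue
#'
#' The residue through which communication out of the ligand is strongest:
#' among the ligand node's edges, the one with the smallest weight
#' (largest \eqn{|C|}). Ties are broken towards the lower residue id and
#' reported with a message.
#'
#' @param net a [CorrelationNetwork-class].
#' @param ligand ligand node id; default the network's unique ligand node.
#' @return Node id (character) of the anchor residue.
#' @export
ligandAnchor <- function(net, ligand = NULL) {
  stopifnot(is(net, "CorrelationNetwork"))
  if (is.null(ligand)) {
    ligand <- net@nodes$id[net@nodes$kind == "ligand"]
    if (length(ligand) != 1L)
      stop("network does not have a unique ligand node; pass `ligand`")
  }
  li <- .nodeIndex(net, ligand)
  w <- net@W[li, ]
  if (all(is.na(w)))
    stop("ligand node '", ligand, "' has no edges")
  best <- min(w, na.rm = TRUE)
  cand <- which(!is.na(w) & w <= best + .pathTol)
  if (length(cand) > 1L) {
    cand <- cand[order(net@nodes$resid[cand])]
    message("ligand anchor tie between ",
            paste(net@nodes$id[cand], collapse = ", "),
            "; choosing lowest residue id")
  }
  net@nodes$id[cand[1]]
}

#' Segment a pathway into helix runs and inter-helix transfers
#'
#' Maps every node of a path to its transmembrane helix (via the BW
#' mapping), labels the ligand node \code{"ligand"} and unmapped residues
#' \code{"loop"}, and splits the path into maximal runs of equal labels.
#' Transitions between consecutive runs are the inter-helix signal
#' transfers; concatenating the segments reproduces the path exactly.
#'
#' @param path character vector of node ids (as in [pathList()]).
#' @param mapping a [BWMapping-class].
#' @param ligandId node id(s) to label \code{"ligand"} (default: any
#'   non-integer id).
#' @return List with \code{segments} (data.frame: label, from, to, length),
#'   \code{labels} (per node) and \code{transfers} (count of inter-segment
#'   transitions).
#' @export
helixHops <- function(path, mapping, ligandId = NULL) {
  stopifnot(length(path) >= 1L, is(mapping, "BWMapping"))
  isLig <- if (is.null(ligandId))
    is.na(suppressWarnings(as.integer(path)))
  else path %in% ligandId
  lab <- character(length(path))
  lab[isLig] <- "ligand"
  if (any(!isLig)) {
    hx <- helixOf(mapping, as.integer(path[!isLig]))
    lab[!isLig] <- ifelse(is.na(hx), "loop", paste0("TMH", hx))
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segments <- data.frame(label = r$values,
                         from = path[starts], to = path[ends],
                         length = r$lengths, stringsAsFactors = FALSE)
  list(segments = segments, labels = lab,
       transfers = length(r$values) - 1L)
}
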
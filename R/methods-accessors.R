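#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname nFrames
#' @aliases nFrames,Trajectory-method
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname nAtoms
#' @aliases nAtoms,Trajectory-method
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])

#' @rdname frameInterval
#' @aliases frameInterval,Trajectory-method
setMethod("frameInterval", "Trajectory", function(x) x@frameInterval)

#' @rdname frameInterval
#' @aliases frameInterval,DescriptorSeries-method
setMethod("frameInterval", "DescriptorSeries", function(x) x@frameInterval)

#' @rdname atomMeta
#' @aliases atomMeta,Trajectory-method
setMethod("atomMeta", "Trajectory", function(x) x@atoms)

#' @rdname coords
#' @aliases coords,Trajectory-method
setMethod("coords", "Trajectory", function(x) x@coords)

#' @rdname nodes
#' @aliases nodes,CorrelationNetwork-method
setMethod("nodes", "CorrelationNetwork", function(x) x@nodes)

#' @rdname edgeWeights
#' @aliases edgeWeights,CorrelationNetwork-method
setMethod("edgeWeights", "CorrelationNetwork", function(x) x@W)

#' @rdname correlations
#' @aliases correlations,CorrelationNetwork-method
setMethod("correlations", "CorrelationNetwork", function(x) x@cor)

#' @rdname contactMaskOf
#' @aliases contactMaskOf,CorrelationNetwork-method
setMethod("contactMaskOf", "CorrelationNetwork", function(x) x@mask)

#' @rdname pathList
#' @aliases pathList,PathSet-method
setMethod("pathList", "PathSet", function(x) x@paths)

#' @rdname pathDistances
#' @aliases pathDistances,PathSet-method
setMethod("pathDistances", "PathSet", function(x) x@distances)

#' @rdname records
#' @aliases records,PIEDATable-method
setMethod("records", "PIEDATable", function(x) x@records)

#' @rdname classLabel
#' @aliases classLabel,PIEDATable-method
setMethod("classLabel", "PIEDATable", function(x) x@classLabel)

#' @rdname complexId
#' @aliases complexId,PIEDATable-method
setMethod("complexId", "PIEDATable", function(x) x@complexId)

#' @rdname bwTable
#' @aliases bwTable,BWMapping-method
setMethod("bwTable", "BWMapping", function(x) x@table)

#' @rdname descriptorValues
#' @aliases descriptorValues,DescriptorSeries-method
setMethod("descriptorValues", "DescriptorSeries", function(x) x@values)

#' @rdname descriptorName
#' @aliases descriptorName,DescriptorSeries-method
setMethod("descriptorName", "DescriptorSeries", function(x) x@name)

## show methods --------------------------------------------------------------

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms (%d residues), %.4g ns/frame\n",
              nFrames(object), nAtoms(object),
              length(unique(object@atoms$resid)), object@frameInterval))
})

setMethod("show", "BWMapping", function(object) {
  tb <- object@table
  cat(sprintf("BWMapping: %d generic numbers over helices %s\n",
              nrow(tb), paste(sort(unique(tb$helix)), collapse = ",")))
})

setMethod("show", "DescriptorSeries", function(object) {
  v <- object@values
  cat(sprintf("DescriptorSeries '%s': %d frames, range [%.3f, %.3f] A\n",
              object@name, length(v), min(v), max(v)))
})

setMethod("show", "CorrelationNetwork", function(object) {
  nE <- sum(!is.na(object@W[upper.tri(object@W)]))
  cat(sprintf("CorrelationNetwork: %d nodes (%d residue, %d ligand), %d edges\n",
              nrow(object@nodes), sum(object@nodes$kind == "residue"),
              sum(object@nodes$kind == "ligand"), nE))
})

setMethod("show", "PathSet", function(object) {
  if (object@disconnected) {
    cat(sprintf("PathSet: %s -> %s DISCONNECTED\n", object@source, object@sink))
  } else {
    cat(sprintf(
      "PathSet: %s -> %s, optimal distance %.4f, n = %d nodes, N = %d paths (offset %.3g)\n",
      object@source, object@sink, object@optimalDistance, object@nOptimal,
      object@nPaths, object@offset))
  }
})

setMethod("show", "PIEDATable", function(object) {
  cat(sprintf("PIEDATable '%s' (ligand %s, %s): %d residues\n",
              object@complexId, object@ligandId, object@classLabel,
              nrow(object@records)))
})
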
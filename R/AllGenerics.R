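## Accessor generics for the package's containers.

#' Number of frames in a trajectory
#' @param x a [Trajectory-class]
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms in a trajectory
#' @param x a [Trajectory-class]
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Time per frame in nanoseconds
#' @param x a [Trajectory-class] or [DescriptorSeries-class]
#' @return numeric scalar (ns)
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Per-atom metadata table
#' @param x a [Trajectory-class]
#' @return data.frame with one row per atom
#' @export
setGeneric("atomMeta", function(x) standardGeneric("atomMeta"))

#' Coordinate array
#' @param x a [Trajectory-class]
#' @return numeric array \code{(n_frames, n_atoms, 3)} in Angstrom
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Node table of a dynamical network
#' @param x a [CorrelationNetwork-class]
#' @return data.frame of nodes (id, kind, resid, anchor)
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Edge-weight matrix of a dynamical network
#' @param x a [CorrelationNetwork-class]
#' @return numeric matrix, \code{NA} where no edge is admitted
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' Motion-correlation matrix of a dynamical network
#' @param x a [CorrelationNetwork-class]
#' @return symmetric numeric matrix with unit diagonal
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))

#' Contact mask of a dynamical network
#' @param x a [CorrelationNetwork-class]
#' @return symmetric logical matrix
#' @export
setGeneric("contactMaskOf", function(x) standardGeneric("contactMaskOf"))

#' Paths of a PathSet
#' @param x a [PathSet-class]
#' @return list of node-id character vectors
#' @export
setGeneric("pathList", function(x) standardGeneric("pathList"))

#' Path distances of a PathSet
#' @param x a [PathSet-class]
#' @return numeric vector of summed edge weights
#' @export
setGeneric("pathDistances", function(x) standardGeneric("pathDistances"))

#' Per-residue record table of a PIEDA table
#' @param x a [PIEDATable-class]
#' @return data.frame of records
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Functional class label of a PIEDA table
#' @param x a [PIEDATable-class]
#' @return \code{"agonist"}, \code{"antagonist"} or \code{"unknown"}
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' Complex identifier of a PIEDA table
#' @param x a [PIEDATable-class]
#' @return character scalar
#' @export
setGeneric("complexId", function(x) standardGeneric("complexId"))

#' Mapping table of a BWMapping
#' @param x a [BWMapping-class]
#' @return data.frame (generic, helix, resid, resname)
#' @export
setGeneric("bwTable", function(x) standardGeneric("bwTable"))

#' Descriptor values (per frame)
#' @param x a [DescriptorSeries-class]
#' @return numeric vector in Angstrom
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' Descriptor name
#' @param x a [DescriptorSeries-class]
#' @return character scalar
#' @export
setGeneric("descriptorName", function(x) standardGeneric("descriptorName"))
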
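# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname AtomModel-class
#' @param object,x an object.
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname AtomModel-class
#' @export
setMethod("atoms", "AtomModel", function(object) object@atoms)

#' @rdname AtomModel-class
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname AtomModel-class
#' @export
setMethod("modelId", "AtomModel", function(object) object@modelId)

#' @rdname AtomModel-class
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))
#' @rdname AtomModel-class
#' @export
setMethod("nAtoms", "AtomModel", function(object) nrow(object@atoms))

#' @rdname AtomModel-class
#' @export
setGeneric("chains", function(object) standardGeneric("chains"))
#' @rdname AtomModel-class
#' @export
setMethod("chains", "AtomModel", function(object) unique(object@atoms$chain))

#' Atom coordinates as an n x 3 matrix
#' @param object an [AtomModel-class].
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname coords
#' @export
setMethod("coords", "AtomModel", function(object) {
  as.matrix(object@atoms[, c("x", "y", "z"), drop = FALSE])
})

#' @rdname DensityMap-class
#' @param object an object.
#' @export
setGeneric("mapGrid", function(object) standardGeneric("mapGrid"))
#' @rdname DensityMap-class
#' @export
setMethod("mapGrid", "DensityMap", function(object) object@grid)

#' @rdname DensityMap-class
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname DensityMap-class
#' @export
setMethod("voxelSize", "DensityMap", function(object) object@voxel)

#' @rdname DensityMap-class
#' @export
setGeneric("mapOrigin", function(object) standardGeneric("mapOrigin"))
#' @rdname DensityMap-class
#' @export
setMethod("mapOrigin", "DensityMap", function(object) object@origin)

#' Recomputed map statistics (min, max, mean, rms)
#' @param object a [DensityMap-class].
#' @return named numeric vector.
#' @export
setGeneric("mapStatistics", function(object) standardGeneric("mapStatistics"))
#' @rdname mapStatistics
#' @export
setMethod("mapStatistics", "DensityMap", function(object) {
  g <- as.vector(object@grid)
  m <- mean(g)
  c(min = min(g), max = max(g), mean = m, rms = sqrt(mean((g - m)^2)))
})

#' @rdname EnclosureProfile-class
#' @param object an object.
#' @export
setGeneric("subunitIds", function(object) standardGeneric("subunitIds"))
#' @rdname EnclosureProfile-class
#' @export
setMethod("subunitIds", "EnclosureProfile", function(object) object@subunitIds)
#' @rdname EnclosureProfile-class
#' @export
setMethod("subunitIds", "EnclosureStats", function(object) object@subunitIds)

#' @rdname EnclosureProfile-class
#' @export
setGeneric("uncoveredCounts", function(object) standardGeneric("uncoveredCounts"))
#' @rdname EnclosureProfile-class
#' @export
setMethod("uncoveredCounts", "EnclosureProfile", function(object) {
  m <- object@counts
  dimnames(m) <- list(object@subunitIds, NULL)
  m
})

#' @rdname EnclosureProfile-class
#' @export
setGeneric("profileLevels", function(object) standardGeneric("profileLevels"))
#' @rdname EnclosureProfile-class
#' @export
setMethod("profileLevels", "EnclosureProfile", function(object) object@levels)
#' @rdname EnclosureProfile-class
#' @export
setMethod("profileLevels", "EnclosureStats", function(object) object@levels)

#' Per-subunit enclosure probabilities
#' @param object an [EnclosureStats-class] after [enclosureProbability()].
#' @return named numeric vector of p = n/N per subunit.
#' @export
setGeneric("enclosureP", function(object) standardGeneric("enclosureP"))
#' @rdname enclosureP
#' @export
setMethod("enclosureP", "EnclosureStats", function(object) {
  stats::setNames(object@p, object@subunitIds)
})

#' Confidence band of an EnclosureStats as a data.frame
#' @param object an [EnclosureStats-class].
#' @return data.frame with level, mu, sigma, ciLower, ciUpper.
#' @export
setGeneric("confidenceBandTable", function(object) standardGeneric("confidenceBandTable"))
#' @rdname confidenceBandTable
#' @export
setMethod("confidenceBandTable", "EnclosureStats", function(object) {
  data.frame(level = object@levels, mu = object@mu, sigma = object@sigma,
             ciLower = object@ciLower, ciUpper = object@ciUpper)
})
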
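# Central S4 containers: AtomModel (hierarchical atom table), DensityMap
# (3-D scalar grid in a physical frame), Selection, EnclosureProfile and
# EnclosureStats (contour-sweep enclosure analysis results).

.ATOM_COLS <- c("chain", "resno", "inscode", "resname", "atom", "element",
                "x", "y", "z", "occ", "b")

#' AtomModel: hierarchical atom table
#'
#' Flat atom table (chains -> residues -> atoms) with coordinates in Angstrom,
#' element symbols, occupancies and B-factors; the unit of all geometry in the
#' package. Row order is preserved by all operations.
#'
#' @slot atoms data.frame with columns `chain`, `resno` (integer, author
#'   numbering), `inscode`, `resname`, `atom`, `element`, `x`, `y`, `z`
#'   (Angstrom), `occ`, `b`.
#' @slot modelId single character identifier.
#' @export
setClass("AtomModel",
  representation(atoms = "data.frame", modelId = "character"),
  prototype(atoms = data.frame(), modelId = "model")
)

setValidity("AtomModel", function(object) {
  at <- object@atoms
  msgs <- character()
  if (nrow(at) > 0) {
    missing <- setdiff(.ATOM_COLS, names(at))
    if (length(missing))
      return(paste("atom table lacks columns:", paste(missing, collapse = ", ")))
    if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
      msgs <- c(msgs, "non-finite atom positions")
    key <- paste(at$chain, at$resno, at$inscode, at$atom)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate (chain, residue, insertion code, atom name) keys")
  }
  if (length(object@modelId) != 1)
    msgs <- c(msgs, "modelId must be a single string")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct an AtomModel
#'
#' @param atoms data.frame of atoms; missing `inscode`, `occ`, `b` columns are
#'   filled with defaults ("", 1, 0).
#' @param modelId model identifier.
#' @return an [AtomModel-class] object.
#' @examples
#' m <- atomModel(data.frame(chain = "A", resno = 1L, resname = "ALA",
#'                           atom = "CA", element = "C", x = 0, y = 0, z = 0))
#' nAtoms(m)
#' @export
atomModel <- function(atoms, modelId = "model") {
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) > 0) {
    if (is.null(atoms$inscode)) atoms$inscode <- ""
    if (is.null(atoms$occ)) atoms$occ <- 1
    if (is.null(atoms$b)) atoms$b <- 0
    atoms$resno <- as.integer(atoms$resno)
    atoms <- atoms[, .ATOM_COLS]
    rownames(atoms) <- NULL
  }
  new("AtomModel", atoms = atoms, modelId = as.character(modelId))
}

#' DensityMap: 3-D scalar grid
#'
#' A density map on a regular orthogonal grid. The grid array is indexed
#' `[x, y, z]` (x fastest, R's natural column-major layout); maps read from
#' MRC/CCP4 files with a different stored axis order are permuted to this
#' canonical order on read.
#'
#' @slot grid 3-D numeric array indexed `[x, y, z]`.
#' @slot voxel numeric(3), voxel spacing along x, y, z in Angstrom.
#' @slot origin numeric(3), physical position (Angstrom) of grid index (1,1,1).
#' @slot originRule how the origin was determined on read: "origin-field",
#'   "start-indices" or "constructed".
#' @export
setClass("DensityMap",
  representation(grid = "array", voxel = "numeric", origin = "numeric",
                 originRule = "character"),
  prototype(voxel = c(1, 1, 1), origin = c(0, 0, 0), originRule = "constructed")
)

setValidity("DensityMap", function(object) {
  msgs <- character()
  if (length(dim(object@grid)) != 3) msgs <- c(msgs, "grid must be a 3-D array")
  if (length(object@voxel) != 3 || any(!is.finite(object@voxel)) ||
      any(object@voxel <= 0))
    msgs <- c(msgs, "voxel sizes must be three strictly positive numbers")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be three finite numbers")
  if (length(dim(object@grid)) == 3 && any(dim(object@grid) < 1))
    msgs <- c(msgs, "grid must be non-empty")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a DensityMap
#'
#' @param grid 3-D numeric array indexed `[x, y, z]`.
#' @param voxel voxel spacing (scalar or numeric(3)), Angstrom.
#' @param origin physical position of grid index (1,1,1), Angstrom.
#' @param originRule provenance tag for the origin convention.
#' @return a [DensityMap-class] object.
#' @export
densityMap <- function(grid, voxel = 1, origin = c(0, 0, 0),
                       originRule = "constructed") {
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  new("DensityMap", grid = grid, voxel = as.numeric(voxel),
      origin = as.numeric(origin), originRule = originRule)
}

#' Selection of atoms by chain, residue range and atom name
#'
#' Empty criteria mean select-all; residue ranges are inclusive on both ends.
#'
#' @slot chains character vector of chain ids (empty = all).
#' @slot residues integer(2) inclusive residue-number range (empty = all).
#' @slot atomNames character vector of atom names (empty = all).
#' @slot resnames character vector of residue names (empty = all).
#' @slot heavyOnly drop hydrogens when TRUE.
#' @export
setClass("Selection",
  representation(chains = "character", residues = "integer",
                 atomNames = "character", resnames = "character",
                 heavyOnly = "logical"),
  prototype(chains = character(), residues = integer(),
            atomNames = character(), resnames = character(), heavyOnly = FALSE)
)

#' Build a Selection
#'
#' @param chains,residues,atomNames,resnames selection criteria; `NULL` (the
#'   default) selects everything for that criterion. `residues` may be a
#'   length-2 inclusive range or a single residue number.
#' @param heavyOnly if TRUE, hydrogens are excluded.
#' @return a [Selection-class] object.
#' @examples
#' atomSelection(chains = "A", residues = c(10, 20), heavyOnly = TRUE)
#' @export
atomSelection <- function(chains = NULL, residues = NULL, atomNames = NULL,
                          resnames = NULL, heavyOnly = FALSE) {
  if (!is.null(residues)) {
    residues <- as.integer(residues)
    if (length(residues) == 1) residues <- c(residues, residues)
    stopifnot(length(residues) == 2, residues[1] <= residues[2])
  }
  new("Selection",
      chains = as.character(chains %||% character()),
      residues = residues %||% integer(),
      atomNames = as.character(atomNames %||% character()),
      resnames = as.character(resnames %||% character()),
      heavyOnly = isTRUE(heavyOnly))
}

#' EnclosureProfile: uncovered-atom counts per subunit and contour level
#'
#' @slot subunitIds character, subunit identifiers (M rows of the matrix).
#' @slot levels numeric, probed contour levels (N columns).
#' @slot counts matrix (subunit x level) of uncovered-atom counts, or
#'   fractions when `normalized`.
#' @slot atomsPerSubunit integer, element atom count common to all subunits.
#' @slot normalized logical, TRUE when counts were divided by atom counts.
#' @export
setClass("EnclosureProfile",
  representation(subunitIds = "character", levels = "numeric",
                 counts = "matrix", atomsPerSubunit = "integer",
                 normalized = "logical"),
  prototype(normalized = FALSE)
)

setValidity("EnclosureProfile", function(object) {
  msgs <- character()
  if (nrow(object@counts) != length(object@subunitIds))
    msgs <- c(msgs, "counts rows must match subunit ids")
  if (ncol(object@counts) != length(object@levels))
    msgs <- c(msgs, "counts columns must match levels")
  if (!object@normalized && length(object@atomsPerSubunit) == 1 &&
      nrow(object@counts) > 0) {
    if (any(object@counts < 0 | object@counts > object@atomsPerSubunit))
      msgs <- c(msgs, "counts must lie in [0, atoms per subunit]")
  }
  if (nrow(object@counts) > 0 && ncol(object@counts) > 1) {
    mono <- apply(object@counts, 1, function(r) all(diff(r) >= 0))
    if (!all(mono))
      msgs <- c(msgs, "uncovered counts must be non-decreasing in contour level")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' EnclosureStats: confidence band and per-subunit enclosure probability
#'
#' Holds the per-level mean/sd and confidence band `mu +/- z * sigma / sqrt(M)`
#' across the M symmetry-related subunits, and (once
#' [enclosureProbability()] has run) the per-subunit count `n` of levels below
#' the band and the probability `p = n / N`.
#'
#' @slot levels,mu,sigma,ciLower,ciUpper per-level numerics.
#' @slot z normal quantile used for the band (default 3.291).
#' @slot M number of subunits.
#' @slot subunitIds,n,p per-subunit id, level count below the band, and
#'   probability (empty until [enclosureProbability()]).
#' @slot nLevels total number of contour levels N.
#' @slot mode "below" (strictly below the lower bound) or "outside" (outside
#'   the whole band).
#' @export
setClass("EnclosureStats",
  representation(levels = "numeric", mu = "numeric", sigma = "numeric",
                 ciLower = "numeric", ciUpper = "numeric", z = "numeric",
                 M = "integer", subunitIds = "character", n = "integer",
                 p = "numeric", nLevels = "integer", mode = "character"),
  prototype(mode = "below")
)

setMethod("show", "AtomModel", function(object) {
  at <- object@atoms
  cat("AtomModel '", object@modelId, "': ", nrow(at), " atoms",
      sep = "")
  if (nrow(at) > 0) {
    ch <- unique(at$chain)
    cat(", ", length(ch), " chain(s) [",
        paste(utils::head(ch, 8), collapse = " "),
        if (length(ch) > 8) " ..." else "", "]", sep = "")
  }
  cat("\n")
})

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@grid)
  cat(sprintf("DensityMap %d x %d x %d, voxel (%.3g, %.3g, %.3g) A, origin (%.3g, %.3g, %.3g) [%s]\n",
              d[1], d[2], d[3], object@voxel[1], object@voxel[2], object@voxel[3],
              object@origin[1], object@origin[2], object@origin[3],
              object@originRule))
  g <- object@grid
  cat(sprintf("  min %.4g  max %.4g  mean %.4g  rms %.4g\n",
              min(g), max(g), mean(g), stats::sd(as.vector(g)) * 0 + sqrt(mean((g - mean(g))^2))))
})

setMethod("show", "EnclosureProfile", function(object) {
  cat(sprintf("EnclosureProfile: %d subunit(s) x %d level(s), %d atoms/subunit%s\n",
              length(object@subunitIds), length(object@levels),
              object@atomsPerSubunit,
              if (object@normalized) " (normalized)" else ""))
})

setMethod("show", "EnclosureStats", function(object) {
  cat(sprintf("EnclosureStats: %d level(s), M = %d subunits, z = %.3f, mode = '%s'\n",
              length(object@levels), object@M, object@z, object@mode))
  if (length(object@p))
    cat(sprintf("  p: min %.3f  median %.3f  max %.3f (N = %d levels)\n",
                min(object@p), stats::median(object@p), max(object@p),
                object@nLevels))
})
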
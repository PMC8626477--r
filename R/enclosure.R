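# Contour-sweep enclosure analysis: for each symmetry-related subunit, count
# the flexible-element atoms whose interpolated map value falls below each
# contour level of a sweep; form the confidence band mu +/- z*sigma/sqrt(M)
# across subunits; report per subunit the fraction p = n/N of levels at which
# that subunit lies below the band (its element enclosed by density). Also a
# masked map-model cross-correlation re-implementing the usual validation CC.

#' Define a contour-level sweep
#'
#' Level count is `floor((max - min) / step) + 1`; the defaults are the sweep
#' used for the native core scaffold analysis and probe 75 levels.
#'
#' @param min,max,step sweep bounds and step in map units; `min < max`,
#'   `step > 0`.
#' @return list of class `ContourSweep`.
#' @examples
#' length(contourLevels(contourSweep()))  # 75
#' @export
contourSweep <- function(min = 0.015, max = 0.052, step = 0.0005) {
  stopifnot(min < max, step > 0)
  structure(list(min = min, max = max, step = step), class = "ContourSweep")
}

#' Contour levels of a sweep
#' @param sweep a [contourSweep()].
#' @return numeric vector of levels.
#' @export
contourLevels <- function(sweep) {
  stopifnot(inherits(sweep, "ContourSweep"))
  n <- floor((sweep$max - sweep$min) / sweep$step + 1e-9) + 1
  sweep$min + (seq_len(n) - 1) * sweep$step
}

#' Trilinear interpolation of a map at physical positions
#'
#' Positions outside the grid's bounding box yield `-Inf` and are reported in
#' the `"outside"` attribute of the result.
#'
#' @param map a [DensityMap-class].
#' @param positions n x 3 matrix of physical positions (Angstrom).
#' @return numeric vector of interpolated map values, with attribute
#'   `outside` (logical vector flagging out-of-box positions).
#' @export
mapValuesAt <- function(map, positions) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  g <- mapGrid(map)
  d <- dim(g)
  t <- sweep(sweep(positions, 2, mapOrigin(map), "-"), 2, voxelSize(map), "/")
  outside <- t[, 1] < 0 | t[, 1] > d[1] - 1 |
             t[, 2] < 0 | t[, 2] > d[2] - 1 |
             t[, 3] < 0 | t[, 3] > d[3] - 1
  vals <- rep(-Inf, nrow(positions))
  if (any(!outside)) {
    tt <- t[!outside, , drop = FALSE]
    i0 <- pmin(floor(tt), matrix(rep(d - 2L, each = nrow(tt)), ncol = 3))
    i0 <- pmax(i0, 0)
    f <- tt - i0
    acc <- numeric(nrow(tt))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[, 1] else 1 - f[, 1]) *
           (if (dy) f[, 2] else 1 - f[, 2]) *
           (if (dz) f[, 3] else 1 - f[, 3])
      acc <- acc + w * g[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1,
                               i0[, 3] + dz + 1)]
    }
    vals[!outside] <- acc
  }
  attr(vals, "outside") <- outside
  vals
}

#' Count atoms not covered by map density at a contour level
#'
#' An atom is uncovered when the trilinearly interpolated map value at its
#' centre is strictly below the level (value equal to the level counts as
#' covered). Atoms outside the map box count as uncovered.
#'
#' @param map a [DensityMap-class].
#' @param model a non-empty [AtomModel-class] (the element selection).
#' @param level contour level in map units.
#' @return integer count.
#' @export
countUncoveredAtoms <- function(map, model, level) {
  if (nAtoms(model) == 0)
    stop("empty atom selection: cannot distinguish 'no element modeled' from 'fully covered'")
  vals <- mapValuesAt(map, coords(model))
  sum(vals < level)
}

#' Contour-sweep enclosure profile over subunits
#'
#' Computes the full (subunit x level) matrix of uncovered-atom counts. All
#' subunits must present the same element atom count (the same element model
#' is evaluated once per symmetry-related copy); with `normalize = TRUE`,
#' unequal counts are tolerated and counts are reported as fractions.
#'
#' @param map a [DensityMap-class].
#' @param elements named list of [AtomModel-class], one element selection per
#'   subunit.
#' @param sweep a [contourSweep()].
#' @param normalize divide counts by the per-subunit atom count.
#' @return an [EnclosureProfile-class].
#' @export
contourSweepProfile <- function(map, elements, sweep = contourSweep(),
                                normalize = FALSE) {
  stopifnot(length(elements) >= 1)
  ids <- names(elements) %||% as.character(seq_along(elements))
  sizes <- vapply(elements, nAtoms, integer(1))
  if (any(sizes == 0)) stop("empty element selection for subunit(s): ",
                            paste(ids[sizes == 0], collapse = ", "))
  if (!normalize && length(unique(sizes)) > 1)
    stop("subunits have unequal element atom counts (",
         paste(range(sizes), collapse = "-"),
         "); use normalize = TRUE to compare fractions instead")
  levels <- contourLevels(sweep)
  counts <- matrix(0, nrow = length(elements), ncol = length(levels))
  for (i in seq_along(elements)) {
    vals <- mapValuesAt(map, coords(elements[[i]]))
    # counts are non-decreasing in level by construction
    counts[i, ] <- vapply(levels, function(L) sum(vals < L), numeric(1))
    if (normalize) counts[i, ] <- counts[i, ] / sizes[i]
  }
  new("EnclosureProfile", subunitIds = ids, levels = levels, counts = counts,
      atomsPerSubunit = if (normalize) sizes[1] else unique(sizes),
      normalized = normalize)
}

#' Confidence band across subunits
#'
#' Per contour level, the mean and sample standard deviation (denominator
#' M - 1) of the uncovered counts over the M subunits, and the band
#' `CI = mu +/- z * sigma / sqrt(M)`. The default `z = 3.291` is the
#' two-sided 99.9% normal quantile (such bands are sometimes loosely called
#' 99% intervals; the formula is what counts, and `z` is configurable).
#'
#' @param profile an [EnclosureProfile-class] with at least 2 subunits.
#' @param z normal quantile for the band half-width.
#' @return an [EnclosureStats-class] carrying the band (no probabilities yet).
#' @export
confidenceBand <- function(profile, z = 3.291) {
  stopifnot(is(profile, "EnclosureProfile"))
  M <- length(profile@subunitIds)
  if (M < 2) stop("confidence band needs at least 2 subunits (got ", M, ")")
  mu <- colMeans(profile@counts)
  sigma <- apply(profile@counts, 2, stats::sd)
  half <- z * sigma / sqrt(M)
  new("EnclosureStats", levels = profile@levels, mu = mu, sigma = sigma,
      ciLower = mu - half, ciUpper = mu + half, z = z, M = as.integer(M),
      subunitIds = character(), n = integer(), p = numeric(),
      nLevels = length(profile@levels), mode = "below")
}

#' Per-subunit enclosure probability
#'
#' For each subunit, `n` is the number of levels at which its uncovered count
#' is strictly below the band's lower bound (default mode `"below"`: fewer
#' uncovered atoms than expected means the element is enclosed by density), and
#' `p = n / N` with N the sweep's level count. Mode `"outside"` instead counts
#' levels outside the whole band.
#'
#' @param profile the [EnclosureProfile-class] the band was computed on.
#' @param band the matching [EnclosureStats-class] from [confidenceBand()].
#' @param mode `"below"` or `"outside"`.
#' @return the [EnclosureStats-class] completed with per-subunit `n` and `p`
#'   (see [enclosureP()]).
#' @export
enclosureProbability <- function(profile, band, mode = c("below", "outside")) {
  mode <- match.arg(mode)
  stopifnot(is(profile, "EnclosureProfile"), is(band, "EnclosureStats"))
  if (!identical(profile@levels, band@levels))
    stop("band was not computed on this profile (levels differ)")
  below <- sweep(profile@counts, 2, band@ciLower, "<")
  hits <- if (mode == "below") below
          else below | sweep(profile@counts, 2, band@ciUpper, ">")
  n <- as.integer(rowSums(hits))
  band@subunitIds <- profile@subunitIds
  band@n <- n
  band@p <- n / band@nLevels
  band@mode <- mode
  band
}

#' Masked map-model cross-correlation
#'
#' Pearson correlation between the experimental map and a map simulated from
#' the model (same Gaussian convention as [simulateMap()]) over the voxels
#' within `maskRadius` of any model atom.
#'
#' @param map the experimental [DensityMap-class].
#' @param model an [AtomModel-class] inside the map box.
#' @param resolution resolution (Angstrom) for the simulated map.
#' @param maskRadius mask radius around atoms (Angstrom).
#' @return list of class `CCResult`: `cc`, `maskRadius`, `nVoxels`.
#' @export
mapModelCC <- function(map, model, resolution, maskRadius = 3) {
  sim <- .simulateOnGrid(map, model, resolution)
  g <- mapGrid(map)
  d <- dim(g)
  vox <- voxelSize(map)
  org <- mapOrigin(map)
  mask <- array(FALSE, dim = d)
  pos <- coords(model)
  for (a in seq_len(nrow(pos))) {
    i1 <- pmax(1L, ceiling((pos[a, ] - maskRadius - org) / vox) + 1L)
    i2 <- pmin(d, floor((pos[a, ] + maskRadius - org) / vox) + 1L)
    if (any(i1 > i2)) next
    xs <- org[1] + (i1[1]:i2[1] - 1) * vox[1]
    ys <- org[2] + (i1[2]:i2[2] - 1) * vox[2]
    zs <- org[3] + (i1[3]:i2[3] - 1) * vox[3]
    dx2 <- (xs - pos[a, 1])^2
    dy2 <- (ys - pos[a, 2])^2
    dz2 <- (zs - pos[a, 3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= maskRadius^2
    blk <- mask[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]]
    mask[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <- blk | inside
  }
  nv <- sum(mask)
  if (nv < 2) stop("empty mask: no map voxels within ", maskRadius,
                   " A of the model")
  cc <- stats::cor(g[mask], mapGrid(sim)[mask])
  structure(list(cc = cc, maskRadius = maskRadius, nVoxels = nv),
            class = "CCResult")
}
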
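# Toy-assembly and simulated-map generators. The toy assembly emulates, at
# reduced scale, a hollow symmetric shell of rigid subunits (the 60-meric E2
# core in the real system) with an optional set of four interior trimers
# placed with tetrahedral spacing (the 12 interior E3BP copies), and a
# per-subunit "flexible element" cluster displaced outward from each shell
# subunit whose density weight is controllable (the N-terminal backfolded
# element whose map density varies between symmetry-related copies).

#' Describe a toy-assembly scenario
#'
#' Defaults state a 12-subunit shell of 100 A radius with four interior trimers
#' at 50 A: a 1:5 scale stand-in for the 60-subunit icosahedral core with 12
#' interior copies. All randomness is fixed by `seed`.
#'
#' @param nCore number of shell subunits.
#' @param coreAtoms pseudo-atoms per rigid subunit cluster.
#' @param shellRadius shell radius in Angstrom.
#' @param interiorTrimers place four interior trimers when TRUE.
#' @param trimerRadius radial distance of the four trimer centres (Angstrom).
#' @param elementAtoms atoms in each subunit's flexible-element cluster.
#' @param elementWeights numeric in `[0, 1]`, one per shell subunit: the map
#'   density weight of that subunit's flexible element.
#' @param elementOffset outward displacement of the element cluster (Angstrom).
#' @param elementSpread radius of the element cluster (Angstrom). The default
#'   2.5 sizes the cluster so a full-weight element's densities clear the
#'   default contour sweep window while partial occupancies land inside it,
#'   so the sweep actually probes the element.
#' @param seed integer random seed fixing all coordinates.
#' @return a list of class `AssemblyScenario`.
#' @export
assemblyScenario <- function(nCore = 12, coreAtoms = 30, shellRadius = 100,
                             interiorTrimers = TRUE, trimerRadius = 50,
                             elementAtoms = 20,
                             elementWeights = rep(1, nCore),
                             elementOffset = 12, elementSpread = 2.5, seed = 1) {
  stopifnot(nCore >= 1, coreAtoms >= 1, shellRadius > 0, trimerRadius > 0,
            elementAtoms >= 1, elementOffset >= 0, elementSpread > 0)
  if (length(elementWeights) != nCore)
    stop("elementWeights must have length nCore (", nCore, ")")
  if (any(elementWeights < 0 | elementWeights > 1))
    stop("elementWeights must lie in [0, 1]")
  structure(list(nCore = as.integer(nCore), coreAtoms = as.integer(coreAtoms),
                 shellRadius = shellRadius,
                 interiorTrimers = isTRUE(interiorTrimers),
                 trimerRadius = trimerRadius,
                 elementAtoms = as.integer(elementAtoms),
                 elementWeights = as.numeric(elementWeights),
                 elementOffset = elementOffset, elementSpread = elementSpread,
                 seed = as.integer(seed)),
            class = "AssemblyScenario")
}

.coreChainIds <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)]
  else sprintf("S%02d", seq_len(n))
}

# compact deterministic pseudo-atom blob around a centre
.atomBlob <- function(n, centre, radius) {
  pts <- matrix(stats::rnorm(3 * n), ncol = 3)
  nr <- sqrt(rowSums(pts^2)); nr[nr < 1e-9] <- 1
  r <- radius * stats::runif(n)^(1 / 3)
  sweep(pts / nr * r, 2, centre, "+")
}

#' Build a toy hollow assembly
#'
#' Shell subunits are placed on a sphere via a deterministic golden-spiral
#' layout, each carrying a rigid pseudo-atom cluster (residue name "COR",
#' residues 1..coreAtoms) and a flexible-element cluster displaced outward
#' (residue name "ELM", residues 1001..1000+elementAtoms). When requested and
#' `nCore >= 12`, four interior trimers (chains "1".."4", residue name
#' "TRI") are placed at the vertices of a regular tetrahedron, so their
#' pairwise centre-of-mass distances are equal.
#'
#' @param scenario an [assemblyScenario()].
#' @return an [AtomModel-class]; coordinates are bitwise-reproducible for a
#'   given seed.
#' @examples
#' m <- buildToyAssembly(assemblyScenario(nCore = 12, seed = 7))
#' length(chains(m))
#' @export
buildToyAssembly <- function(scenario) {
  stopifnot(inherits(scenario, "AssemblyScenario"))
  set.seed(scenario$seed)
  dirs <- fibonacciSphere(scenario$nCore)
  centres <- dirs * scenario$shellRadius
  # packing feasibility: shell subunits must not overlap (cluster radius 4 A)
  if (scenario$nCore > 1) {
    dmin <- min(crossDist(centres, centres)[upper.tri(diag(scenario$nCore))])
    if (dmin < 10)
      stop("packing error: shell subunits overlap (closest centres ",
           sprintf("%.1f", dmin), " A apart; increase shellRadius)")
  }
  ids <- .coreChainIds(scenario$nCore)
  rows <- vector("list", scenario$nCore + 4L)
  for (i in seq_len(scenario$nCore)) {
    core <- .atomBlob(scenario$coreAtoms, centres[i, ], 4)
    elemCentre <- dirs[i, ] * (scenario$shellRadius + scenario$elementOffset)
    elem <- .atomBlob(scenario$elementAtoms, elemCentre, scenario$elementSpread)
    rows[[i]] <- data.frame(
      chain = ids[i],
      resno = c(seq_len(scenario$coreAtoms), 1000L + seq_len(scenario$elementAtoms)),
      resname = rep(c("COR", "ELM"), c(scenario$coreAtoms, scenario$elementAtoms)),
      atom = "CA", element = "C",
      x = c(core[, 1], elem[, 1]), y = c(core[, 2], elem[, 2]),
      z = c(core[, 3], elem[, 3]),
      stringsAsFactors = FALSE)
  }
  if (scenario$interiorTrimers && scenario$nCore >= 12) {
    tdirs <- tetrahedronDirections()
    for (k in 1:4) {
      centre <- tdirs[k, ] * scenario$trimerRadius
      # three subunit blobs at 120 degrees in the plane normal to the radial
      # direction; offsets sum to zero so the trimer COM is exactly the centre
      nrm <- tdirs[k, ]
      ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * nrm) * nrm; u <- u / vecNorm(u)
      v <- c(nrm[2] * u[3] - nrm[3] * u[2],
             nrm[3] * u[1] - nrm[1] * u[3],
             nrm[1] * u[2] - nrm[2] * u[1])
      sub <- lapply(0:2, function(j) {
        ang <- 2 * pi * j / 3
        .atomBlob(scenario$coreAtoms, centre + 6 * (cos(ang) * u + sin(ang) * v), 3)
      })
      pts <- do.call(rbind, sub)
      rows[[scenario$nCore + k]] <- data.frame(
        chain = as.character(k),
        resno = seq_len(nrow(pts)),
        resname = "TRI", atom = "CA", element = "C",
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        stringsAsFactors = FALSE)
    }
  }
  atomModel(do.call(rbind, rows),
            modelId = sprintf("toy-assembly-seed%d", scenario$seed))
}

#' Map simulation configuration
#'
#' @param resolution nominal resolution in Angstrom; per-atom Gaussian width
#'   is `sigma = resolution / (pi * sqrt(2))`.
#' @param voxel voxel size in Angstrom; must satisfy `resolution >= 2 * voxel`.
#' @param noiseSd standard deviation of additive Gaussian noise (map units).
#' @param padding box padding around the model (Angstrom); must be at least
#'   `3 * sigma`.
#' @param seed integer seed for the noise stream.
#' @return a list of class `MapSimulationConfig`.
#' @export
mapSimulationConfig <- function(resolution = 6, voxel = 2, noiseSd = 0,
                                padding = 8, seed = 1) {
  sigma <- resolution / (pi * sqrt(2))
  stopifnot(resolution > 0, voxel > 0, noiseSd >= 0)
  if (resolution < 2 * voxel)
    stop("resolution must be at least 2 x voxel size (Nyquist)")
  if (padding < 3 * sigma)
    stop("padding must be at least 3 x the atom sigma (", sprintf("%.2f", 3 * sigma), " A)")
  structure(list(resolution = resolution, voxel = voxel, noiseSd = noiseSd,
                 padding = padding, seed = as.integer(seed), sigma = sigma),
            class = "MapSimulationConfig")
}

# Add w * G(sigma) for each atom onto an existing grid (no noise). The
# Gaussian is separable, so each atom splats an outer product of 1-D factors.
.splatAtoms <- function(grid, origin, voxel, pos, amp, sigma, cutoff = 6) {
  d <- dim(grid)
  norm <- (2 * pi * sigma^2)^(-1.5)
  reach <- cutoff * sigma
  ax <- origin[1] + (seq_len(d[1]) - 1) * voxel[1]
  ay <- origin[2] + (seq_len(d[2]) - 1) * voxel[2]
  az <- origin[3] + (seq_len(d[3]) - 1) * voxel[3]
  for (a in seq_len(nrow(pos))) {
    if (amp[a] == 0) next
    i1 <- max(1L, ceiling((pos[a, 1] - reach - origin[1]) / voxel[1]) + 1L)
    i2 <- min(d[1], floor((pos[a, 1] + reach - origin[1]) / voxel[1]) + 1L)
    j1 <- max(1L, ceiling((pos[a, 2] - reach - origin[2]) / voxel[2]) + 1L)
    j2 <- min(d[2], floor((pos[a, 2] + reach - origin[2]) / voxel[2]) + 1L)
    k1 <- max(1L, ceiling((pos[a, 3] - reach - origin[3]) / voxel[3]) + 1L)
    k2 <- min(d[3], floor((pos[a, 3] + reach - origin[3]) / voxel[3]) + 1L)
    if (i1 > i2 || j1 > j2 || k1 > k2) next
    gx <- exp(-((ax[i1:i2] - pos[a, 1])^2) / (2 * sigma^2))
    gy <- exp(-((ay[j1:j2] - pos[a, 2])^2) / (2 * sigma^2))
    gz <- exp(-((az[k1:k2] - pos[a, 3])^2) / (2 * sigma^2))
    blk <- (amp[a] * norm) * (gx %o% gy %o% gz)
    grid[i1:i2, j1:j2, k1:k2] <- grid[i1:i2, j1:j2, k1:k2] + blk
  }
  grid
}

.atomAmplitudes <- function(at, elementWeights, elementResname = "ELM") {
  amp <- rep(1, nrow(at))
  if (!is.null(elementWeights) && length(elementWeights)) {
    isElem <- at$resname == elementResname
    w <- elementWeights[at$chain[isElem]]
    w[is.na(w)] <- 1
    amp[isElem] <- w
  }
  amp
}

#' Simulate a density map from an atomic model
#'
#' The map is a sum over atoms of normalised 3-D Gaussians,
#' `sigma = resolution / (pi * sqrt(2))`; the peak value of an isolated atom
#' equals the normalisation constant `(2 pi sigma^2)^(-3/2)`. Atoms whose
#' residue name is `elementResname` are scaled by their chain's entry in
#' `elementWeights` (the planted flexible-element occupancy). Optional white
#' Gaussian noise is added, deterministic in `cfg$seed`.
#'
#' @param model an [AtomModel-class].
#' @param cfg a [mapSimulationConfig()].
#' @param elementWeights named numeric, chain id -> weight in `[0, 1]`;
#'   `NULL` leaves all atoms at weight 1.
#' @param elementResname residue-name tag of flexible-element atoms.
#' @return a [DensityMap-class] whose box covers the model plus padding.
#' @export
simulateMap <- function(model, cfg, elementWeights = NULL,
                        elementResname = "ELM") {
  stopifnot(inherits(cfg, "MapSimulationConfig"))
  if (!is.null(elementWeights) &&
      any(elementWeights < 0 | elementWeights > 1))
    stop("element weights must lie in [0, 1]")
  at <- atoms(model)
  if (!nrow(at)) stop("cannot simulate a map from an empty model")
  pos <- as.matrix(at[, c("x", "y", "z")])
  lo <- apply(pos, 2, min) - cfg$padding
  hi <- apply(pos, 2, max) + cfg$padding
  d <- pmax(2L, as.integer(ceiling((hi - lo) / cfg$voxel)) + 1L)
  grid <- array(0, dim = d)
  amp <- .atomAmplitudes(at, elementWeights, elementResname)
  grid <- .splatAtoms(grid, lo, rep(cfg$voxel, 3), pos, amp, cfg$sigma)
  if (cfg$noiseSd > 0) {
    set.seed(cfg$seed)
    grid <- grid + stats::rnorm(length(grid), sd = cfg$noiseSd)
  }
  densityMap(grid, voxel = cfg$voxel, origin = lo, originRule = "constructed")
}

# simulate (noise-free) onto the grid of an existing map; used by mapModelCC
.simulateOnGrid <- function(refMap, model, resolution,
                            elementWeights = NULL, elementResname = "ELM") {
  at <- atoms(model)
  sigma <- resolution / (pi * sqrt(2))
  grid <- array(0, dim = dim(mapGrid(refMap)))
  amp <- .atomAmplitudes(at, elementWeights, elementResname)
  grid <- .splatAtoms(grid, mapOrigin(refMap), voxelSize(refMap),
                      as.matrix(at[, c("x", "y", "z")]), amp, sigma)
  densityMap(grid, voxel = voxelSize(refMap), origin = mapOrigin(refMap),
             originRule = "constructed")
}

#' Random planted-occupancy scenario
#'
#' Draws a scenario for occupancy-recovery exercises: a random half of the
#' shell subunits carry no flexible element (weight 0, the element disordered
#' away from its site) and the other half carry it at a partial occupancy
#' drawn uniformly from 0.4-1. Both classes are always represented because
#' the enclosure band is cohort-relative: a cohort with no absent (or no
#' present) elements carries no contrast for the statistic to find.
#'
#' @param seed integer seed (drives the weights and the geometry).
#' @param nCore number of shell subunits (even).
#' @param ... passed to [assemblyScenario()].
#' @return an [assemblyScenario()] with the drawn `elementWeights`.
#' @export
randomOccupancyScenario <- function(seed, nCore = 12, ...) {
  stopifnot(nCore %% 2 == 0)
  set.seed(seed)
  w <- sample(c(rep(0, nCore / 2), stats::runif(nCore / 2, 0.4, 1)))
  assemblyScenario(nCore = nCore, elementWeights = w, seed = seed, ...)
}
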
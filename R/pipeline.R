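# Orchestration of the three headline analyses on a scenario (or on real
# inputs loaded through the readers): enclosure-by-proximity, interior
# occupancy, and restraint-based pose screening. All stage parameters default
# to field-standard constants.

#' Pipeline run configuration
#'
#' Bundles every stage parameter with analysis defaults: contour sweep
#' 0.015-0.052 step 0.0005 (75 levels), band quantile z = 3.291, interior
#' sphere radius 80 A, probe 1.4 A, proximity bounds 55/70/75 A, restraint
#' bounds 10-25 A.
#'
#' @param sweep a [contourSweep()].
#' @param z band quantile.
#' @param bounds a [groupBounds()].
#' @param mask a [sphereMask()].
#' @param radii a [defaultRadiusTable()].
#' @param restraintBounds numeric(2) restraint distance bounds (Angstrom).
#' @param seed global seed.
#' @param outDir optional output directory; when set, runs write their
#'   resolved config and result tables there.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(sweep = contourSweep(), z = 3.291,
                      bounds = groupBounds(), mask = sphereMask(),
                      radii = defaultRadiusTable(),
                      restraintBounds = c(10, 25), seed = 1, outDir = NULL) {
  structure(list(sweep = sweep, z = z, bounds = bounds, mask = mask,
                 radii = radii, restraintBounds = restraintBounds,
                 seed = as.integer(seed), outDir = outDir),
            class = "RunConfig")
}

.writeResolvedConfig <- function(cfg, stage) {
  if (is.null(cfg$outDir)) return(invisible(NULL))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  lines <- c(
    sprintf("stage=%s", stage),
    sprintf("sweep.min=%g", cfg$sweep$min),
    sprintf("sweep.max=%g", cfg$sweep$max),
    sprintf("sweep.step=%g", cfg$sweep$step),
    sprintf("z=%g", cfg$z),
    sprintf("bounds.group1=%g,%g", cfg$bounds$group1[1], cfg$bounds$group1[2]),
    sprintf("bounds.group2_threshold=%g", cfg$bounds$group2Threshold),
    sprintf("mask.radius=%g", cfg$mask$radius),
    sprintf("mask.spacing=%g", cfg$mask$spacing),
    sprintf("probe=%g", cfg$radii$probe),
    sprintf("restraint.lower=%g", cfg$restraintBounds[1]),
    sprintf("restraint.upper=%g", cfg$restraintBounds[2]),
    sprintf("seed=%d", cfg$seed))
  writeLines(lines, file.path(cfg$outDir, sprintf("%s-config.txt", stage)))
  invisible(NULL)
}

# per-subunit element selections and anchors of a toy assembly; shell chains
# are recognised by their "COR" residues, interior partners by "TRI"
.scenarioSubunits <- function(model) {
  at <- atoms(model)
  coreChains <- unique(at$chain[at$resname == "COR"])
  elements <- stats::setNames(lapply(coreChains, function(ch)
    selectAtoms(model, atomSelection(chains = ch, resnames = "ELM"))),
    coreChains)
  anchors <- stats::setNames(lapply(coreChains, function(ch)
    centerOfMass(selectAtoms(model, atomSelection(chains = ch, resnames = "COR")))),
    coreChains)
  trimerChains <- unique(at$chain[at$resname == "TRI"])
  partners <- if (length(trimerChains))
    stats::setNames(lapply(trimerChains, function(ch)
      centerOfMass(selectAtoms(model, atomSelection(chains = ch)))), trimerChains)
  else list()
  list(elements = elements, anchors = anchors, partners = partners)
}

#' Enclosure-by-proximity analysis
#'
#' Joins the proximity grouping of shell subunits (distance of each subunit's
#' anchor to the closest interior-partner anchor) with the per-subunit
#' enclosure probability from the contour sweep, and compares the two groups'
#' probabilities with the rank-sum test.
#'
#' @param model the assembly [AtomModel-class] (a [buildToyAssembly()] output
#'   or a real scaffold prepared the same way: element atoms tagged "ELM",
#'   interior partner chains tagged "TRI").
#' @param map the [DensityMap-class] to sweep.
#' @param cfg a [runConfig()].
#' @return list: `table` (per-subunit distance, group, n, N, p), `groups`
#'   (output of [compareGroupProbabilities()]), `band`.
#' @export
runEnclosureByProximity <- function(model, map, cfg = runConfig()) {
  parts <- .scenarioSubunits(model)
  if (!length(parts$partners))
    stop("missing stage input: no interior partner chains (residue tag 'TRI') for the proximity stage")
  if (!length(parts$elements))
    stop("missing stage input: no element selections for the enclosure stage")
  dist <- nearestPartnerDistances(parts$anchors, parts$partners)
  dist <- classifyGroups(dist, cfg$bounds)
  profile <- contourSweepProfile(map, parts$elements, cfg$sweep)
  band <- confidenceBand(profile, cfg$z)
  stats <- enclosureProbability(profile, band)
  p <- enclosureP(stats)
  tab <- data.frame(subunit = dist$subunit, distance = dist$distance,
                    partner = dist$partner, group = dist$group,
                    n = stats@n[match(dist$subunit, stats@subunitIds)],
                    N = stats@nLevels,
                    p = p[dist$subunit],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  groups <- tryCatch(compareGroupProbabilities(p, stats::setNames(tab$group, tab$subunit)),
                     error = function(e) NULL)
  .writeResolvedConfig(cfg, "enclosure")
  if (!is.null(cfg$outDir))
    utils::write.csv(tab, file.path(cfg$outDir, "enclosure-by-proximity.csv"),
                     row.names = FALSE)
  list(table = tab, groups = groups, band = stats)
}

#' Interior occupancy analysis
#'
#' Occupancy of the interior sphere by the declared components, optionally
#' adding a disordered-chain ensemble as its own component (its mean volume
#' realised by the per-model union accounting of [occupancyReport()]).
#'
#' @param components named list of models (see [occupancyReport()]).
#' @param cfg a [runConfig()]; the mask centre should be the assembly centre.
#' @param ensemble optional list of C-alpha chains added as component
#'   "disordered" with a 3 A per-residue radius.
#' @return the [occupancyReport()] plus an `ensembleVolume` entry when an
#'   ensemble was supplied.
#' @export
runOccupancy <- function(components, cfg = runConfig(), ensemble = NULL) {
  overrides <- list()
  if (!is.null(ensemble)) {
    components <- c(components, list(disordered = ensemble))
    overrides <- list(disordered = 3.0)
  }
  report <- occupancyReport(components, cfg$radii, cfg$mask,
                         radiusOverrides = overrides)
  if (!is.null(ensemble))
    report$ensembleVolume <- ensembleVolume(ensemble, cfg$radii, cfg$mask)
  .writeResolvedConfig(cfg, "occupancy")
  if (!is.null(cfg$outDir)) {
    tab <- data.frame(component = c(names(report$componentFraction), "empty"),
                      fraction = c(report$componentFraction, report$emptyFraction))
    utils::write.csv(tab, file.path(cfg$outDir, "occupancy.csv"),
                     row.names = FALSE)
  }
  report
}

#' Restraint-based pose screening
#'
#' Ranks candidate poses by restraint satisfaction, clash count and buried
#' surface area, and attaches the per-pose interface residues.
#'
#' @param poses list of [AtomModel-class] poses.
#' @param spec a [restraintSpec()] (defaults take their bounds from `cfg`).
#' @param split named list, partner name -> chain ids.
#' @param cfg a [runConfig()].
#' @return list: `ranking` (the [rankPoses()] table), `interfaces` (list of
#'   [interfaceResidues()] per pose, in input order).
#' @export
runPoseScreen <- function(poses, spec, split, cfg = runConfig()) {
  if (!length(poses)) stop("empty pose set")
  ranking <- rankPoses(poses, spec, split, cfg$radii)
  interfaces <- lapply(poses, interfaceResidues, split = split)
  .writeResolvedConfig(cfg, "poses")
  if (!is.null(cfg$outDir))
    utils::write.csv(ranking, file.path(cfg$outDir, "pose-ranking.csv"),
                     row.names = FALSE)
  list(ranking = ranking, interfaces = interfaces)
}
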
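# Shared fixture builders. Everything is generated in code; no data files.

# quick atom-table model; fills element C and resname UNK when omitted
mkModel <- function(..., modelId = "fix") {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$resname)) df$resname <- "UNK"
  if (is.null(df$element)) df$element <- "C"
  if (is.null(df$atom)) df$atom <- paste0("C", seq_len(nrow(df)))
  if (is.null(df$chain)) df$chain <- "A"
  if (is.null(df$resno)) df$resno <- seq_len(nrow(df))
  atomModel(df, modelId = modelId)
}

# single-atom model at a position
oneAtom <- function(x = 0, y = 0, z = 0, element = "C", chain = "A",
                    resno = 1L, resname = "UNK", atom = "C1") {
  mkModel(chain = chain, resno = resno, resname = resname, atom = atom,
          element = element, x = x, y = y, z = z)
}

# the headline 12-subunit scenario: six subunits with the flexible element at
# full density weight, six with it absent
plantedHalfScenario <- function(seed = 42) {
  assemblyScenario(nCore = 12, elementWeights = rep(c(1, 0), each = 6),
                   seed = seed)
}

scenarioWeights <- function(scenario) {
  stats::setNames(scenario$elementWeights, LETTERS[seq_len(scenario$nCore)])
}

elementSelections <- function(model) {
  coreChains <- unique(atoms(model)$chain[atoms(model)$resname == "COR"])
  stats::setNames(lapply(coreChains, function(ch)
    selectAtoms(model, atomSelection(chains = ch, resnames = "ELM"))),
    coreChains)
}

# standard simulated map for a scenario (stated noise level 0.002 map units)
scenarioMap <- function(model, weights, seed, noiseSd = 0.002) {
  simulateMap(model, mapSimulationConfig(resolution = 6, voxel = 2,
                                         noiseSd = noiseSd, padding = 8,
                                         seed = seed),
              elementWeights = weights)
}

# enclosure probabilities for a scenario model + map
scenarioEnclosureP <- function(model, map, sweep = contourSweep()) {
  prof <- contourSweepProfile(map, elementSelections(model), sweep)
  enclosureP(enclosureProbability(prof, confidenceBand(prof)))
}
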
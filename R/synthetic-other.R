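# Generators for disordered-chain ensembles, Michaelis-Menten rate tables and
# alignments with planted per-column conservation, plus a scenario writer that
# emits each piece with its planted truth so downstream recovery is testable.

#' Disordered-chain ensemble configuration
#'
#' @param nModels number of chains to generate (>= 1).
#' @param nResidues residues per chain.
#' @param step consecutive C-alpha step length in Angstrom (default 3.8, the
#'   trans C-alpha..C-alpha virtual bond).
#' @param start 3-vector start anchor (Angstrom).
#' @param end optional 3-vector end anchor; chains finish within one step of it.
#' @param exclRadius self-avoidance radius in Angstrom.
#' @param seed integer seed.
#' @return list of class `EnsembleConfig`.
#' @export
ensembleConfig <- function(nModels = 100, nResidues = 50, step = 3.8,
                           start = c(0, 0, 0), end = NULL, exclRadius = 2.0,
                           seed = 1) {
  stopifnot(nModels >= 1, nResidues >= 2, step > 0, exclRadius >= 0)
  if (!is.null(end)) {
    if (vecNorm(end - start) > (nResidues - 1) * step)
      stop("anchors are further apart than the chain can span (",
           sprintf("%.1f A > %d x %.1f A", vecNorm(end - start),
                   nResidues - 1, step), ")")
  }
  structure(list(nModels = as.integer(nModels),
                 nResidues = as.integer(nResidues), step = step,
                 start = as.numeric(start), end = if (is.null(end)) NULL else as.numeric(end),
                 exclRadius = exclRadius, seed = as.integer(seed)),
            class = "EnsembleConfig")
}

.growChain <- function(cfg, maxStepTries = 60) {
  n <- cfg$nResidues
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- cfg$start
  for (i in 2:n) {
    placed <- FALSE
    for (try in seq_len(maxStepTries)) {
      cand <- pos[i - 1, ] + cfg$step * randomUnitVector()
      # self-avoidance against all earlier residues except the bonded neighbour
      if (i > 2 && cfg$exclRadius > 0) {
        d2 <- rowSums(sweep(pos[1:(i - 2), , drop = FALSE], 2, cand, "-")^2)
        if (any(d2 < cfg$exclRadius^2)) next
      }
      # end-anchoring: remaining steps must still be able to reach the anchor
      if (!is.null(cfg$end)) {
        remaining <- (n - i) * cfg$step + cfg$step
        if (vecNorm(cfg$end - cand) > remaining) next
      }
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  pos
}

#' Generate a self-avoiding disordered-chain ensemble
#'
#' Each model is a C-alpha-only chain with exact consecutive step length,
#' self-avoiding at `exclRadius`, grown from the start anchor by uniform
#' random directions with rejection. With an end anchor, steps that would
#' leave the anchor unreachable are rejected, so every chain ends within one
#' step length of the anchor. A stand-in for de novo disordered-segment
#' ensembles from dedicated modelling programs.
#'
#' @param cfg an [ensembleConfig()].
#' @param maxChainRetries restarts allowed per chain before failing.
#' @return list of [AtomModel-class] chains (chain "A", atom "CA").
#' @export
generateDisorderedEnsemble <- function(cfg, maxChainRetries = 500) {
  stopifnot(inherits(cfg, "EnsembleConfig"))
  set.seed(cfg$seed)
  out <- vector("list", cfg$nModels)
  for (m in seq_len(cfg$nModels)) {
    pos <- NULL
    tries <- 0
    while (is.null(pos)) {
      tries <- tries + 1
      if (tries > maxChainRetries)
        stop("ensemble generation failed: chain ", m, " not completed after ",
             maxChainRetries, " attempts")
      pos <- .growChain(cfg)
    }
    out[[m]] <- atomModel(data.frame(
      chain = "A", resno = seq_len(cfg$nResidues), resname = "GLY",
      atom = "CA", element = "C",
      x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE),
      modelId = sprintf("ensemble-%04d", m))
  }
  out
}

#' Simulate Michaelis-Menten rate data
#'
#' `v = Vmax * S / (Km + S)` plus i.i.d. Gaussian noise per replicate.
#'
#' @param km Michaelis constant (uM), > 0.
#' @param vmax limiting rate (caller's rate units), > 0.
#' @param substrate substrate concentration grid (uM).
#' @param noiseSd rate-units noise standard deviation.
#' @param replicates replicates per substrate concentration.
#' @param seed integer seed.
#' @return data.frame with columns `substrate_uM`, `rate`, `replicate`.
#' @examples
#' simulateKineticsData(148, 5, c(50, 148, 500), noiseSd = 0, replicates = 1)
#' @export
simulateKineticsData <- function(km, vmax, substrate, noiseSd = 0,
                                 replicates = 3, seed = 1) {
  stopifnot(km > 0, vmax > 0, all(substrate >= 0), replicates >= 1)
  set.seed(seed)
  S <- rep(substrate, each = replicates)
  v <- vmax * S / (km + S)
  if (noiseSd > 0) v <- v + stats::rnorm(length(v), sd = noiseSd)
  data.frame(substrate_uM = S, rate = v,
             replicate = rep(seq_len(replicates), times = length(substrate)))
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a multiple sequence alignment with planted conservation
#'
#' Each sampled sequence matches the reference residue at column j with
#' probability `profile[j]`; substitutions are uniform over the other 19
#' amino acids. The reference itself is included as the first sequence.
#'
#' @param reference ungapped reference sequence (character string).
#' @param n number of sequences to sample.
#' @param profile per-column match probabilities, same length as `reference`.
#' @param seed integer seed.
#' @param referenceId id of the reference sequence in the output.
#' @return an `MSA` object (see [msa()]).
#' @export
simulateAlignment <- function(reference, n, profile, seed = 1,
                              referenceId = "reference") {
  refChars <- strsplit(toupper(reference), "")[[1]]
  L <- length(refChars)
  if (length(profile) != L)
    stop("profile length (", length(profile), ") must equal reference length (", L, ")")
  stopifnot(all(profile >= 0 & profile <= 1), n >= 1)
  set.seed(seed)
  seqs <- character(n)
  for (s in seq_len(n)) {
    match <- stats::runif(L) < profile
    out <- refChars
    if (any(!match)) {
      out[!match] <- vapply(refChars[!match], function(r) {
        sample(setdiff(.AA20, r), 1)
      }, character(1))
    }
    seqs[s] <- paste(out, collapse = "")
  }
  names(seqs) <- sprintf("seq%04d", seq_len(n))
  msa(c(stats::setNames(reference, referenceId), seqs), referenceId)
}

#' Write a full synthetic scenario to disk with its planted truth
#'
#' Emits the toy assembly (PDB), its simulated map (MRC), the planted element
#' weights and generator parameters (key=value text), a kinetics table (CSV)
#' and a simulated alignment (FASTA), all derived deterministically from the
#' scenario seed.
#'
#' @param dir output directory (created if missing).
#' @param scenario an [assemblyScenario()].
#' @param mapCfg a [mapSimulationConfig()].
#' @param km,vmax,substrate,kinNoiseSd,replicates kinetics truth and grid.
#' @param reference,profile,nSeq alignment truth.
#' @return invisibly, a named list of the file paths written.
#' @export
writeScenario <- function(dir, scenario, mapCfg = mapSimulationConfig(),
                          km = 148, vmax = 5,
                          substrate = c(5, 10, 25, 50, 100, 250, 500, 1000),
                          kinNoiseSd = 0.25, replicates = 3,
                          reference = "MKRAVLPDHC", profile = rep(0.9, 10),
                          nSeq = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- buildToyAssembly(scenario)
  weights <- stats::setNames(scenario$elementWeights,
                             .coreChainIds(scenario$nCore))
  map <- simulateMap(model, mapCfg, elementWeights = weights)
  kin <- simulateKineticsData(km, vmax, substrate, kinNoiseSd, replicates,
                              seed = scenario$seed)
  aln <- simulateAlignment(reference, nSeq, profile, seed = scenario$seed)
  paths <- list(
    structure = file.path(dir, "assembly.pdb"),
    map = file.path(dir, "map.mrc"),
    truth = file.path(dir, "truth.txt"),
    kinetics = file.path(dir, "kinetics.csv"),
    alignment = file.path(dir, "alignment.fasta"))
  writeStructure(model, paths$structure)
  writeDensityMap(map, paths$map)
  utils::write.csv(kin, paths$kinetics, row.names = FALSE)
  writeLines(paste0(">", names(msaSequences(aln)), "\n", msaSequences(aln)),
             paths$alignment)
  writeLines(c(
    sprintf("seed=%d", scenario$seed),
    sprintf("element_weight.%s=%g", names(weights), weights),
    sprintf("km_uM=%g", km), sprintf("vmax=%g", vmax),
    sprintf("kinetics_noise_sd=%g", kinNoiseSd),
    sprintf("conservation_profile=%s", paste(profile, collapse = ","))),
    paths$truth)
  invisible(paths)
}
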
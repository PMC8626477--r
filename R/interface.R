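# Interface characterisation and docking-pose screening: buried surface area
# for a declared partner split, interface residues by heavy-atom contact, a
# clearly simplified three-component energy decomposition (Lennard-Jones,
# Coulomb with distance-dependent dielectric, ASP x delta-SASA desolvation),
# the lipoyllysine-style distance restraint check, steric clash counting with
# spatial binning, and a stable composite pose ranking.

.splitModels <- function(model, split) {
  stopifnot(is.list(split), length(split) >= 2)
  nms <- names(split)
  if (is.null(nms) || any(nms == "")) stop("partners must be named")
  declared <- unlist(split, use.names = FALSE)
  if (anyDuplicated(declared)) stop("partners must be disjoint chain sets")
  lapply(split, function(ch) selectAtoms(model, atomSelection(chains = ch)))
}

#' Buried surface area of a partner split
#'
#' `BSA = sum over partners of SASA(partner alone) - SASA(complex)`; for more
#' than two partners this is the multi-body total.
#'
#' @param model an [AtomModel-class] holding the complex.
#' @param split named list, partner name -> chain ids (disjoint).
#' @param radii a [defaultRadiusTable()].
#' @param spherePoints Shrake-Rupley sample points per atom.
#' @return BSA in A^2 (>= 0 up to sampling tolerance).
#' @export
buriedSurfaceArea <- function(model, split, radii = defaultRadiusTable(),
                              spherePoints = 960) {
  parts <- .splitModels(model, split)
  sizes <- vapply(parts, nAtoms, integer(1))
  if (any(sizes == 0))
    stop("partner(s) with zero atoms: ",
         paste(names(parts)[sizes == 0], collapse = ", "))
  complexModel <- selectAtoms(model,
                              atomSelection(chains = unlist(split, use.names = FALSE)))
  sasaParts <- vapply(parts, function(p) attr(sasa(p, radii, spherePoints), "total"),
                      numeric(1))
  sum(sasaParts) - attr(sasa(complexModel, radii, spherePoints), "total")
}

#' Interface residues by cross-partner heavy-atom contact
#'
#' A residue is at the interface when at least one of its heavy atoms lies
#' within `cutoff` (inclusive) of a heavy atom of another partner.
#'
#' @param model an [AtomModel-class].
#' @param split named list, partner name -> chain ids.
#' @param cutoff contact distance cutoff in Angstrom (default 5.0).
#' @return named list, partner -> character vector "chain:resno(:inscode)".
#' @export
interfaceResidues <- function(model, split, cutoff = 5.0) {
  parts <- lapply(.splitModels(model, split), function(p)
    selectAtoms(p, atomSelection(heavyOnly = TRUE)))
  nms <- names(parts)
  out <- stats::setNames(vector("list", length(parts)), nms)
  for (i in seq_along(parts)) out[[i]] <- character(0)
  resid <- function(at, idx) {
    key <- paste0(at$chain[idx], ":", at$resno[idx],
                  ifelse(at$inscode[idx] == "", "", paste0(":", at$inscode[idx])))
    unique(key)
  }
  for (i in seq_along(parts)) for (j in seq_along(parts)) {
    if (i >= j) next
    ai <- atoms(parts[[i]]); aj <- atoms(parts[[j]])
    if (!nrow(ai) || !nrow(aj)) next
    D <- crossDist(ai[, c("x", "y", "z")], aj[, c("x", "y", "z")])
    hit <- which(D <= cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[i]] <- union(out[[i]], resid(ai, hit[, 1]))
      out[[j]] <- union(out[[j]], resid(aj, hit[, 2]))
    }
  }
  lapply(out, sort)
}

#' Simplified interface energy decomposition
#'
#' A deliberately simplified stand-in for docking-refinement energetics, for
#' relative comparisons only: Lennard-Jones 12-6 with generic per-element
#' parameters (`vdw`), Coulomb with distance-dependent dielectric
#' `eps(r) = r` and coarse template charges (`elec`), and desolvation as
#' atomic-solvation-parameter times SASA change on binding (`desolv`).
#' Favourable contributions are negative. Absolute values are not comparable
#' to any full force field.
#'
#' @param model an [AtomModel-class].
#' @param split named list, partner name -> chain ids.
#' @param radii a [defaultRadiusTable()].
#' @param spherePoints SASA sampling for the desolvation term.
#' @return list: `vdw`, `elec`, `desolv` (kcal/mol-scale scores) and
#'   `parameterSet`.
#' @export
energyDecomposition <- function(model, split, radii = defaultRadiusTable(),
                                spherePoints = 480) {
  parts <- .splitModels(model, split)
  heavy <- lapply(parts, function(p) selectAtoms(p, atomSelection(heavyOnly = TRUE)))
  vdw <- 0; elec <- 0
  for (i in seq_along(heavy)) for (j in seq_along(heavy)) {
    if (i >= j) next
    ai <- atoms(heavy[[i]]); aj <- atoms(heavy[[j]])
    if (!nrow(ai) || !nrow(aj)) next
    ri <- vdwRadii(ai$element, radii); rj <- vdwRadii(aj$element, radii)
    ei <- .LJ_EPSILON[toupper(ai$element)]; ej <- .LJ_EPSILON[toupper(aj$element)]
    if (anyNA(ei) || anyNA(ej)) stop("missing Lennard-Jones parameters")
    qi <- coarseCharges(ai); qj <- coarseCharges(aj)
    D <- crossDist(ai[, c("x", "y", "z")], aj[, c("x", "y", "z")])
    D[D < 0.1] <- 0.1
    rmin <- outer(ri, rj, "+")
    epsij <- sqrt(outer(ei, ej))
    sr6 <- (rmin / D)^6
    vdw <- vdw + sum(epsij * (sr6^2 - 2 * sr6))
    # eps(r) = r  =>  E = k q1 q2 / r^2
    elec <- elec + .COULOMB_K * sum(outer(qi, qj) / D^2)
  }
  # desolvation: ASP-weighted SASA change on complexation; the complex is
  # rebuilt partner-blocked so per-atom orders line up with the free forms
  complexModel <- atomModel(do.call(rbind, lapply(parts, atoms)),
                            modelId = modelId(model))
  aC <- atoms(complexModel)
  aspC <- .ASP_PARAMS[toupper(aC$element)]
  if (anyNA(aspC)) stop("missing atomic solvation parameters")
  sasaComplex <- sasa(complexModel, radii, spherePoints)
  sasaFree <- unlist(lapply(parts, function(p) sasa(p, radii, spherePoints)),
                     use.names = FALSE)
  # parts concatenated in split order match the complex selection order
  desolv <- sum(aspC * (as.numeric(sasaComplex) - sasaFree))
  list(vdw = vdw, elec = elec, desolv = desolv,
       parameterSet = "corescaffold-simplified-1")
}

#' Distance restraint specification
#'
#' Default bounds 10-25 A reproduce the lipoyllysine reach restraint between
#' the lipoylated lysine C-alpha and the active-site alanine C-beta.
#'
#' @param atomA,atomB lists `list(chain=, resno=, atom=)` naming the two atoms.
#' @param lower,upper inclusive distance bounds in Angstrom.
#' @return list of class `RestraintSpec`.
#' @export
restraintSpec <- function(atomA, atomB, lower = 10, upper = 25) {
  stopifnot(lower >= 0, lower < upper)
  need <- c("chain", "resno", "atom")
  stopifnot(all(need %in% names(atomA)), all(need %in% names(atomB)))
  structure(list(atomA = atomA, atomB = atomB, lower = lower, upper = upper),
            class = "RestraintSpec")
}

.findAtom <- function(model, spec1) {
  at <- atoms(model)
  idx <- which(at$chain == spec1$chain & at$resno == spec1$resno &
               at$atom == spec1$atom)
  if (!length(idx))
    stop("restraint atom not found: ", spec1$chain, ":", spec1$resno, ":",
         spec1$atom)
  as.numeric(at[idx[1], c("x", "y", "z")])
}

#' Check a distance restraint on a model
#'
#' @param model an [AtomModel-class].
#' @param spec a [restraintSpec()].
#' @return list: `distance` (Angstrom) and `satisfied` (inclusive bounds).
#' @export
checkRestraint <- function(model, spec) {
  stopifnot(inherits(spec, "RestraintSpec"))
  d <- vecNorm(.findAtom(model, spec$atomA) - .findAtom(model, spec$atomB))
  list(distance = d, satisfied = d >= spec$lower && d <= spec$upper)
}

#' Count steric clashes across a partner split
#'
#' Cross-partner heavy-atom pairs with van der Waals overlap
#' `r_i + r_j - d` strictly greater than `tolerance` (default 0.4 A). Uses
#' spatial binning; results are identical to the all-pairs scan.
#'
#' @param model an [AtomModel-class].
#' @param split named list, partner name -> chain ids.
#' @param radii a [defaultRadiusTable()].
#' @param tolerance overlap tolerance in Angstrom.
#' @return list of class `ClashReport`: `nClashes`, `worstOverlap`, `pairs`
#'   (data.frame of atom pair, distance, overlap).
#' @export
countClashes <- function(model, split, radii = defaultRadiusTable(),
                         tolerance = 0.4) {
  parts <- lapply(.splitModels(model, split), function(p)
    selectAtoms(p, atomSelection(heavyOnly = TRUE)))
  at <- do.call(rbind, lapply(seq_along(parts), function(i) {
    a <- atoms(parts[[i]])
    if (nrow(a)) a$partner <- names(parts)[i]
    a
  }))
  empty <- data.frame(atomA = character(), atomB = character(),
                      distance = numeric(), overlap = numeric())
  if (is.null(at) || nrow(at) < 2)
    return(structure(list(nClashes = 0L, worstOverlap = 0, pairs = empty),
                     class = "ClashReport"))
  r <- vdwRadii(at$element, radii)
  cutoff <- 2 * max(r)  # max possible clashing distance
  cell <- pmax(cutoff, 1e-6)
  ijk <- floor(as.matrix(at[, c("x", "y", "z")]) / cell)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  cells <- split(seq_len(nrow(at)), key)
  cellIjk <- do.call(rbind, lapply(strsplit(names(cells), " "), as.numeric))
  rows <- list()
  for (ci in seq_along(cells)) {
    # neighbours with index >= this cell (visit each cell pair once)
    for (cj in seq_along(cells)) {
      if (cj < ci) next
      if (any(abs(cellIjk[ci, ] - cellIjk[cj, ]) > 1)) next
      ii <- cells[[ci]]; jj <- cells[[cj]]
      pair <- if (ci == cj) {
        if (length(ii) < 2) next
        t(utils::combn(ii, 2))
      } else as.matrix(expand.grid(ii, jj))
      keep <- at$partner[pair[, 1]] != at$partner[pair[, 2]]
      pair <- pair[keep, , drop = FALSE]
      if (!nrow(pair)) next
      d <- sqrt(rowSums((as.matrix(at[pair[, 1], c("x", "y", "z")]) -
                         as.matrix(at[pair[, 2], c("x", "y", "z")]))^2))
      ov <- r[pair[, 1]] + r[pair[, 2]] - d
      cl <- which(ov > tolerance)
      if (length(cl)) {
        lbl <- function(k) paste0(at$chain[k], ":", at$resno[k], ":", at$atom[k])
        rows[[length(rows) + 1]] <- data.frame(
          atomA = lbl(pair[cl, 1]), atomB = lbl(pair[cl, 2]),
          distance = d[cl], overlap = ov[cl], stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else empty
  structure(list(nClashes = nrow(pairs),
                 worstOverlap = if (nrow(pairs)) max(pairs$overlap) else 0,
                 pairs = pairs), class = "ClashReport")
}

#' Rank docking poses by restraint, clashes and buried surface
#'
#' Stable sort: restraint-satisfying poses first, then fewer clashes, then
#' larger BSA; full ties preserve input order.
#'
#' @param poses list of [AtomModel-class] poses.
#' @param spec a [restraintSpec()].
#' @param split named list, partner name -> chain ids.
#' @param radii a [defaultRadiusTable()].
#' @param spherePoints SASA sampling for the BSA key.
#' @return data.frame ordered by rank: pose, restraintDistance, satisfied,
#'   nClashes, bsa.
#' @export
rankPoses <- function(poses, spec, split, radii = defaultRadiusTable(),
                      spherePoints = 480) {
  stopifnot(length(poses) >= 1)
  nms <- names(poses) %||% sprintf("pose%03d", seq_along(poses))
  tab <- do.call(rbind, lapply(seq_along(poses), function(i) {
    rc <- checkRestraint(poses[[i]], spec)
    cl <- countClashes(poses[[i]], split, radii)
    data.frame(pose = nms[i], restraintDistance = rc$distance,
               satisfied = rc$satisfied, nClashes = cl$nClashes,
               bsa = buriedSurfaceArea(poses[[i]], split, radii, spherePoints),
               stringsAsFactors = FALSE)
  }))
  ord <- order(!tab$satisfied, tab$nClashes, -tab$bsa)  # stable radix sort
  out <- tab[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
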
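# Scaffold geometry: centres of mass, nearest-partner anchor distances,
# proximity-group classification and the group-wise comparison of enclosure
# probabilities.

#' Centre of mass of an atom set
#'
#' @param model a non-empty [AtomModel-class].
#' @param weighting "uniform" (plain mean) or "atomic-mass" (standard atomic
#'   weights).
#' @return numeric(3) position in Angstrom.
#' @examples
#' m <- atomModel(data.frame(chain = "A", resno = 1:2, resname = "GLY",
#'   atom = c("C1", "C2"), element = "C", x = c(0, 2), y = 0, z = 0))
#' centerOfMass(m)
#' @export
centerOfMass <- function(model, weighting = c("uniform", "atomic-mass")) {
  weighting <- match.arg(weighting)
  if (nAtoms(model) == 0) stop("cannot take the centre of mass of an empty model")
  xyz <- coords(model)
  w <- if (weighting == "uniform") rep(1, nrow(xyz))
       else atomicMasses(atoms(model)$element)
  colSums(xyz * w) / sum(w)
}

#' Nearest-partner distances between two anchor sets
#'
#' For each query anchor, the minimum Euclidean distance over all partner
#' anchors and the arg-min partner id; distance ties resolve to the
#' lexicographically smallest partner id.
#'
#' @param query named list (or n x 3 matrix with rownames) of query anchor
#'   positions.
#' @param partners named list (or matrix with rownames) of partner anchors.
#' @return data.frame with columns `subunit`, `partner`, `distance`, plus a
#'   `group` column of NA (filled by [classifyGroups()]).
#' @export
nearestPartnerDistances <- function(query, partners) {
  toMat <- function(x) {
    if (is.list(x)) {
      m <- do.call(rbind, x)
      rownames(m) <- names(x)
      m
    } else as.matrix(x)
  }
  q <- toMat(query); p <- toMat(partners)
  if (!nrow(q) || !nrow(p)) stop("both anchor sets must be non-empty")
  if (is.null(rownames(q))) rownames(q) <- as.character(seq_len(nrow(q)))
  if (is.null(rownames(p))) rownames(p) <- as.character(seq_len(nrow(p)))
  # lexicographic tie-break: scan partners in sorted-id order and keep strict
  # improvements only
  ord <- order(rownames(p))
  p <- p[ord, , drop = FALSE]
  # direct-difference distances (bit-identical to a naive double loop)
  D <- vapply(seq_len(nrow(p)), function(j)
    sqrt(rowSums(sweep(q, 2, p[j, ], "-")^2)), numeric(nrow(q)))
  D <- matrix(D, nrow = nrow(q))
  best <- apply(D, 1, which.min)  # first minimum = smallest sorted id on ties
  data.frame(subunit = rownames(q),
             partner = rownames(p)[best],
             distance = D[cbind(seq_len(nrow(q)), best)],
             group = NA_character_,
             stringsAsFactors = FALSE)
}

#' Proximity group bounds
#'
#' Defaults follow the conventional grouping of shell subunits by distance to the
#' closest interior copy: group 1 covers 55-70 A, group 2 is open above 75 A,
#' and the (70, 75] gap is deliberately left unassigned.
#'
#' @param group1 numeric(2) inclusive interval for group 1 (Angstrom).
#' @param group2Threshold open lower threshold for group 2 (Angstrom).
#' @return list of class `GroupBounds`.
#' @export
groupBounds <- function(group1 = c(55, 70), group2Threshold = 75) {
  stopifnot(length(group1) == 2, group1[1] < group1[2],
            group1[2] <= group2Threshold)
  structure(list(group1 = as.numeric(group1),
                 group2Threshold = group2Threshold), class = "GroupBounds")
}

#' Classify nearest-partner distances into proximity groups
#'
#' Distance within the group-1 interval (inclusive) -> "group1"; distance
#' strictly greater than the group-2 threshold -> "group2"; anything else ->
#' "unassigned" (kept and counted, not dropped).
#'
#' @param assignments data.frame from [nearestPartnerDistances()].
#' @param bounds a [groupBounds()].
#' @return the data.frame with the `group` column filled.
#' @examples
#' d <- data.frame(subunit = c("a", "b", "c"), partner = "p",
#'                 distance = c(60, 80, 72), group = NA)
#' classifyGroups(d, groupBounds())$group
#' @export
classifyGroups <- function(assignments, bounds = groupBounds()) {
  stopifnot(inherits(bounds, "GroupBounds"))
  d <- assignments$distance
  g <- ifelse(d >= bounds$group1[1] & d <= bounds$group1[2], "group1",
       ifelse(d > bounds$group2Threshold, "group2", "unassigned"))
  assignments$group <- g
  assignments
}

#' Compare enclosure probabilities between proximity groups
#'
#' Per-group summaries (n, median, quartiles) and a two-sided Mann-Whitney
#' rank-sum test (normal approximation with tie correction) between group 1
#' and group 2.
#'
#' @param p named numeric vector of per-subunit probabilities (names are
#'   subunit ids).
#' @param labels character vector of group labels aligned with `p` (or named
#'   by subunit id).
#' @return list with `summary` (data.frame), `U` (group-1 statistic) and
#'   `pValue`.
#' @export
compareGroupProbabilities <- function(p, labels) {
  if (!is.null(names(labels)) && !is.null(names(p)))
    labels <- labels[names(p)]
  stopifnot(length(p) == length(labels))
  keep <- labels %in% c("group1", "group2")
  groups <- split(p[keep], labels[keep])
  if (length(groups) < 2 || any(lengths(groups) < 1))
    stop("both groups must be non-empty for a comparison")
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v), median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
  g1 <- groups[["group1"]]; g2 <- groups[["group2"]]
  if (length(g1) < 3 || length(g2) < 3) {
    U <- sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
    return(list(summary = summ, U = U, pValue = NA_real_))
  }
  if (stats::sd(c(g1, g2)) == 0) {
    # all observations tied: no evidence of a difference
    U <- length(g1) * length(g2) / 2
    return(list(summary = summ, U = U, pValue = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE,
                                            correct = TRUE))
  list(summary = summ, U = unname(wt$statistic), pValue = wt$p.value)
}
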
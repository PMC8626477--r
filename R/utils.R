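# shared internal helpers

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif sd quantile cor
NULL

# deterministic, roughly uniform points on the unit sphere (golden-spiral)
fibonacciSphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

# unit vectors of a regular tetrahedron
tetrahedronDirections <- function() {
  d <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  d / sqrt(3)
}

randomUnitVector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

vecNorm <- function(v) sqrt(sum(v^2))

# pairwise Euclidean distances between rows of a and rows of b
crossDist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# encode integer voxel triplets as collision-free keys for set operations;
# base 2^17 keeps keys below 2^53 (exact in doubles) for indices in
# [-2^16, 2^16), i.e. lattices out to ~32000 A at 0.5 A spacing
voxelKeys <- function(ijk) {
  if (!nrow(ijk)) return(numeric(0))
  if (any(abs(ijk) >= 2^16)) stop("voxel index out of key range")
  base <- 2^17
  (as.numeric(ijk[, 1]) + 2^16) + base * ((as.numeric(ijk[, 2]) + 2^16) +
    base * (as.numeric(ijk[, 3]) + 2^16))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
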
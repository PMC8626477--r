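# Embedded parameter tables: van der Waals radii, atomic masses, and the
# coarse scoring parameters used by the simplified interface energetics.

.BONDI_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  ZN = 1.39, MG = 1.73, FE = 1.40, MN = 1.40, CU = 1.40, `NA` = 2.27,
  K = 2.75, CA = 2.31, B = 1.92, SI = 2.10
)

.ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971,
  ZN = 65.38, MG = 24.305, FE = 55.845, MN = 54.938, CU = 63.546,
  `NA` = 22.990, K = 39.098, CA = 40.078, B = 10.81, SI = 28.085
)

# Lennard-Jones well depths (kcal/mol), CHARMM-like generic per-element values
.LJ_EPSILON <- c(
  H = 0.03, C = 0.10, N = 0.17, O = 0.21, S = 0.25, P = 0.20,
  F = 0.12, CL = 0.30, BR = 0.32, I = 0.35, SE = 0.30,
  ZN = 0.25, MG = 0.02, FE = 0.02, MN = 0.02, CU = 0.02, `NA` = 0.03,
  K = 0.03, CA = 0.12, B = 0.05, SI = 0.31
)

# Atomic solvation parameters (kcal mol^-1 A^-2), Eisenberg-McLachlan style:
# positive for apolar atoms (burial favourable), negative for polar atoms.
.ASP_PARAMS <- c(
  C = 0.016, S = 0.021, H = 0.0, N = -0.006, O = -0.006, P = 0.016,
  F = -0.006, CL = 0.016, BR = 0.016, I = 0.016, SE = 0.021,
  ZN = -0.050, MG = -0.050, FE = -0.050, MN = -0.050, CU = -0.050,
  `NA` = -0.050, K = -0.050, CA = -0.050, B = 0.016, SI = 0.016
)

.COULOMB_K <- 332.06  # kcal mol^-1 A e^-2

#' Bundled van der Waals radius table
#'
#' Bondi-style van der Waals radii with a solvent probe radius, used by all
#' surface-area and excluded-volume computations. Unknown elements are a hard
#' error in the consumers rather than silently defaulted.
#'
#' @param probe solvent probe radius in Angstrom (default 1.4, a water probe).
#' @return object of class `RadiusTable`: list with `radii` (named numeric,
#'   Angstrom) and `probe`.
#' @examples
#' rt <- defaultRadiusTable()
#' rt$radii[["C"]]
#' @export
defaultRadiusTable <- function(probe = 1.4) {
  stopifnot(probe >= 0)
  structure(list(radii = .BONDI_RADII, probe = probe), class = "RadiusTable")
}

vdwRadii <- function(elements, radii) {
  el <- toupper(elements)
  r <- radii$radii[el]
  if (anyNA(r)) {
    bad <- sort(unique(el[is.na(r)]))
    stop("unknown element(s) in radius table: ", paste(bad, collapse = ", "))
  }
  unname(r)
}

atomicMasses <- function(elements) {
  el <- toupper(elements)
  m <- .ATOMIC_MASSES[el]
  if (anyNA(m)) {
    bad <- sort(unique(el[is.na(m)]))
    stop("unknown element(s) in mass table: ", paste(bad, collapse = ", "))
  }
  unname(m)
}

# Coarse side-chain charge template: Asp/Glu carboxylate -1 (split over the two
# oxygens), Lys +1 on NZ, Arg +1 split over NH1/NH2, His neutral, backbone
# dipoles ignored. Returns per-atom charges for an atom table.
coarseCharges <- function(at) {
  q <- numeric(nrow(at))
  res <- toupper(at$resname)
  nm <- toupper(at$atom)
  q[res == "ASP" & nm %in% c("OD1", "OD2")] <- -0.5
  q[res == "GLU" & nm %in% c("OE1", "OE2")] <- -0.5
  q[res == "LYS" & nm == "NZ"] <- 1.0
  q[res == "ARG" & nm %in% c("NH1", "NH2")] <- 0.5
  q
}
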
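# Enzyme kinetics: Lambert-Beer absorbance-to-concentration conversion and
# Michaelis-Menten nonlinear least-squares fitting.

#' Kinetics configuration
#'
#' @param epsilon molar extinction coefficient (L mol^-1 cm^-1); the default
#'   3.07e4 is the formazan product read-out used in the activity assay.
#' @param pathLength cuvette path length in cm.
#' @return list of class `KineticsConfig`.
#' @export
kineticsConfig <- function(epsilon = 3.07e4, pathLength = 1.0) {
  stopifnot(epsilon > 0, pathLength > 0)
  structure(list(epsilon = epsilon, pathLength = pathLength),
            class = "KineticsConfig")
}

#' Lambert-Beer: absorbance to molar concentration
#'
#' `c = A / (epsilon * l)`.
#'
#' @param A absorbance (>= 0, vectorised).
#' @param cfg a [kineticsConfig()].
#' @return concentration in mol/L.
#' @examples
#' absorbanceToConcentration(0.307)  # 1e-5 M = 10 uM
#' @export
absorbanceToConcentration <- function(A, cfg = kineticsConfig()) {
  stopifnot(all(A >= 0))
  A / (cfg$epsilon * cfg$pathLength)
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)`. Starting values are
#' `Vmax = max(v)` and `Km` = the substrate concentration at half-maximal rate
#' (linearly interpolated). Standard errors come from the Jacobian at the
#' optimum. With replicated substrate concentrations, `aggregate = "means"`
#' (the default) fits the per-concentration mean rates; `"pooled"` fits every
#' point.
#'
#' @param S substrate concentrations (uM), at least 3 distinct values.
#' @param v rates (>= 0), same length as `S`.
#' @param weights optional per-point weights for weighted least squares.
#' @param aggregate "means" or "pooled" (only differs with replicates).
#' @return list of class `MMFit`: `km`, `vmax`, `kmSE`, `vmaxSE`, `rss`, `n`,
#'   `fitted` function.
#' @examples
#' d <- simulateKineticsData(148, 5, c(10, 50, 100, 250, 500, 1000),
#'                           noiseSd = 0, replicates = 1)
#' fitMichaelisMenten(d$substrate_uM, d$rate)$km
#' @export
fitMichaelisMenten <- function(S, v, weights = NULL,
                               aggregate = c("means", "pooled")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(S) == length(v), all(is.finite(S)), all(is.finite(v)))
  if (length(unique(S)) < 3)
    stop("need at least 3 distinct substrate concentrations (got ",
         length(unique(S)), ")")
  if (aggregate == "means" && anyDuplicated(S)) {
    if (!is.null(weights)) stop("weights are not supported with aggregate = 'means'")
    agg <- tapply(v, S, mean)
    S <- as.numeric(names(agg))
    v <- as.numeric(agg)
  }
  ord <- order(S)
  Ss <- S[ord]; vs <- v[ord]
  vmax0 <- max(v)
  half <- vmax0 / 2
  km0 <- if (all(vs < half)) max(Ss) else {
    i <- which(vs >= half)[1]
    if (i == 1) Ss[1] else {
      f <- (half - vs[i - 1]) / (vs[i] - vs[i - 1])
      Ss[i - 1] + f * (Ss[i] - Ss[i - 1])
    }
  }
  km0 <- max(km0, min(Ss[Ss > 0], na.rm = TRUE) * 0.1, 1e-6)
  df <- data.frame(S = S, v = v)
  fit <- tryCatch(
    stats::nls(v ~ Vmax * S / (Km + S), data = df,
               start = list(Vmax = vmax0, Km = km0),
               weights = weights,
               algorithm = "port", lower = c(Vmax = 1e-12, Km = 1e-12),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("Michaelis-Menten fit did not converge: ",
                             conditionMessage(e)))
  co <- summary(fit)$coefficients
  km <- co["Km", "Estimate"]; vmax <- co["Vmax", "Estimate"]
  structure(list(km = km, vmax = vmax,
                 kmSE = co["Km", "Std. Error"],
                 vmaxSE = co["Vmax", "Std. Error"],
                 rss = sum(stats::residuals(fit)^2),
                 n = length(v),
                 fitted = function(s) vmax * s / (km + s)),
            class = "MMFit")
}
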
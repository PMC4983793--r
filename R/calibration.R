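#' Fit a recombinant-YFP standard curve
#'
#' Ordinary least-squares fit of plate-reader fluorescence against known
#' recombinant-YFP masses, `fluorescence = slope * mass + intercept`. A
#' typical curve spans 0-500 ng, with the mass-0 (blank) point included in
#' the fit rather than subtracted. Because plate readers may autogain,
#' samples and standards must share a plate/gain context: points from
#' mixed `plateId`s are refused, and the fitted curve carries its plate
#' identifier so [quantifyLysate()] can check it.
#'
#' @param massNg Numeric vector of YFP masses (ng), or a data.frame with
#'   columns `massNg`, `fluorescence` and optionally `plateId`.
#' @param fluorescence Numeric vector of fluorescence readings (ignored
#'   when `massNg` is a data.frame).
#' @param plateId Optional plate/gain context identifier.
#' @return A [StandardCurve-class].
#' @examples
#' sc <- fitStandardCurve(c(0, 100, 500), c(0, 200, 1000))
#' curveSlope(sc)       # 2 fluorescence units per ng
#' @export
fitStandardCurve <- function(massNg, fluorescence = NULL, plateId = NULL) {
  if (is.data.frame(massNg)) {
    df <- massNg
    stopifnot(all(c("massNg", "fluorescence") %in% names(df)))
    if (is.null(plateId) && "plateId" %in% names(df)) {
      plateId <- unique(as.character(df$plateId))
    }
    massNg <- df$massNg; fluorescence <- df$fluorescence
  }
  if (length(plateId) > 1L) {
    stop("standard-curve points span multiple plate/gain contexts (",
         paste(plateId, collapse = ", "),
         "); standards and samples must be read on the same plate")
  }
  stopifnot(length(massNg) == length(fluorescence),
            all(is.finite(massNg)), all(is.finite(fluorescence)))
  if (length(unique(massNg)) < 2L) {
    stop("degenerate fit: at least 2 distinct YFP masses are required")
  }
  fit <- stats::lm(fluorescence ~ massNg)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- if (stats::var(fluorescence) == 0) 1 else {
    1 - sum(stats::resid(fit)^2) / sum((fluorescence - mean(fluorescence))^2)
  }
  if (slope <= 0) {
    warning("fitted standard-curve slope is not positive; ",
            "the curve is not usable for quantification")
  }
  new("StandardCurve",
      points = data.frame(massNg = massNg, fluorescence = fluorescence),
      slope = slope, intercept = intercept, rSquared = r2,
      massRange = range(massNg),
      plateId = if (is.null(plateId)) "" else as.character(plateId))
}

#' Quantify YFP in a lysate from its fluorescence
#'
#' Inverts the standard curve: `mass = (fluorescence - intercept) / slope`,
#' then divides by the measured volume (default 10 ul, the standard aliquot
#' read in the plate) to give ng YFP per ul of lysate. Masses outside the
#' fitted range are flagged as extrapolated; a negative implied mass is
#' floored at 0 and flagged.
#'
#' @param fluorescence Numeric vector of well readings.
#' @param curve A [StandardCurve-class] with positive slope.
#' @param measuredVolume Volume of lysate measured, in ul (default 10).
#' @param plateId Optional plate context of the readings; refused if it
#'   differs from the curve's.
#' @return data.frame: `fluorescence`, `massNg`, `concentration` (ng/ul),
#'   `extrapolated`, `floored`.
#' @examples
#' sc <- fitStandardCurve(c(0, 100, 500), c(0, 2000, 10000))  # slope 20
#' quantifyLysate(268, sc)$concentration                      # 1.34 ng/ul
#' @export
quantifyLysate <- function(fluorescence, curve, measuredVolume = 10,
                           plateId = NULL) {
  stopifnot(is(curve, "StandardCurve"), measuredVolume > 0)
  if (curve@slope == 0) stop("standard curve has zero slope")
  if (curve@slope < 0) stop("standard curve has negative slope; refit")
  if (!is.null(plateId) && nzchar(curve@plateId) &&
      !identical(as.character(plateId), curve@plateId)) {
    stop(sprintf("plate/gain context mismatch: samples '%s' vs curve '%s'",
                 plateId, curve@plateId))
  }
  mass <- (fluorescence - curve@intercept) / curve@slope
  extrap <- mass < curve@massRange[1] | mass > curve@massRange[2]
  floored <- mass < 0
  mass <- pmax(mass, 0)
  data.frame(fluorescence = fluorescence, massNg = mass,
             concentration = mass / measuredVolume,
             extrapolated = extrap, floored = floored)
}

#' Plan a FLIP assay from the lysate YFP concentration
#'
#' Applies the assay-format rules: a large-volume FLIP uses 700 ul of
#' lysate and needs at least 0.5 ng/ul of YFP (at least 350 ng total per
#' IP); a mini-FLIP uses 100-120 ul and needs at least 0.3 ng/ul. The
#' total YFP is concentration x volume. Exceeding the minimum is
#' recommended, especially for antibodies of weak affinity, so the verdict
#' distinguishes "minimum met" from a comfortable margin.
#'
#' @param concentration YFP concentration of the lysate, ng/ul (>= 0).
#' @param format "large" (1.5-ml tube) or "mini" (PCR tube).
#' @param volume Lysate volume in ul; defaults to 700 (large) or 120 (mini).
#'   An explicit smaller aliquot may be given (e.g. 5 ul).
#' @return List: `format`, `volume`, `concentration`, `totalNg`,
#'   `minConcentration`, `feasible`, `verdict`, `note`.
#' @examples
#' planAssay(0.5, "large")$totalNg            # 350 ng, minimum met
#' planAssay(1.34, "mini", volume = 5)$totalNg  # 6.7 ng
#' @export
planAssay <- function(concentration, format = c("large", "mini"),
                      volume = NULL) {
  format <- match.arg(format)
  stopifnot(is.numeric(concentration), concentration >= 0)
  defaults <- list(large = list(volume = 700, minConc = 0.5),
                   mini = list(volume = 120, minConc = 0.3))
  fd <- defaults[[format]]
  if (is.null(volume)) volume <- fd$volume
  stopifnot(volume > 0)
  totalNg <- concentration * volume
  feasible <- concentration >= fd$minConc
  verdict <- if (!feasible) {
    "infeasible"
  } else if (concentration > fd$minConc) {
    "minimum exceeded"
  } else "minimum met"
  list(format = format, volume = volume, concentration = concentration,
       totalNg = totalNg, minConcentration = fd$minConc,
       feasible = feasible, verdict = verdict,
       note = paste("using more YFP-protein than the format minimum is",
                    "recommended, especially for weak-affinity antibodies"))
}
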
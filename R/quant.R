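#' @include AllClasses.R
NULL

#' Fit an external-standard calibration curve
#'
#' Ordinary least squares of peak area on concentration:
#' `area = slope * concentration + intercept`. At least three distinct
#' concentration levels with non-zero spread are required.
#'
#' @param concentration concentrations (ug/mL).
#' @param area corresponding peak areas.
#' @param analyte standard name.
#' @param wavelength detection wavelength (nm).
#' @return a [CalibrationCurve-class] (LOD/LOQ unset; see [lodLoq()]).
#' @examples
#' conc <- c(0.5, 5, 25, 50)
#' fitCalibration(conc, 18817 * conc - 10155, "gallic acid", 280)
#' @export
fitCalibration <- function(concentration, area, analyte = "",
                           wavelength = NA_real_) {
  if (length(concentration) != length(area))
    stop("concentration and area must have equal length")
  if (length(unique(concentration)) < 3L)
    stop("insufficient calibration: need >= 3 distinct concentrations")
  if (stats::sd(concentration) == 0)
    stop("insufficient calibration: zero concentration spread")
  if (stats::sd(area) == 0)
    stop("insufficient calibration: constant areas carry no response")
  fit <- stats::lm(area ~ concentration)
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((area - mean(area))^2)
  new("CalibrationCurve", analyte = as.character(analyte),
      wavelength = as.numeric(wavelength),
      slope = unname(cf[2]), intercept = unname(cf[1]),
      rSquared = r2, lod = NA_real_, loq = NA_real_)
}

#' Construct a calibration curve from known coefficients
#'
#' Used when the line parameters come from a validation report rather
#' than raw points.
#'
#' @param analyte standard name.
#' @param slope response per ug/mL (non-zero).
#' @param intercept area at zero concentration.
#' @param wavelength detection wavelength (nm).
#' @param rSquared reported coefficient of determination.
#' @param lod,loq reported sensitivity limits (ug/mL).
#' @return a [CalibrationCurve-class].
#' @export
calibrationCurve <- function(analyte, slope, intercept,
                             wavelength = NA_real_, rSquared = NA_real_,
                             lod = NA_real_, loq = NA_real_) {
  new("CalibrationCurve", analyte = as.character(analyte),
      wavelength = as.numeric(wavelength), slope = as.numeric(slope),
      intercept = as.numeric(intercept), rSquared = as.numeric(rSquared),
      lod = as.numeric(lod), loq = as.numeric(loq))
}

#' Limits of detection and quantification
#'
#' Computed from a baseline noise estimate at signal-to-noise ratios of
#' 3 (LOD) and 10 (LOQ): `lod = 3 * noiseSd / slope`,
#' `loq = 10 * noiseSd / slope`.
#'
#' @param noiseSd baseline noise standard deviation (area units), >= 0.
#' @param curve a [CalibrationCurve-class] with positive slope.
#' @return the curve with `lod`/`loq` slots filled (retrieve via
#'   [lodLoqValues()]).
#' @examples
#' cv <- calibrationCurve("gallic acid", 18817, -10155)
#' lodLoqValues(lodLoq(87.8, cv))
#' @export
lodLoq <- function(noiseSd, curve) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (!is.numeric(noiseSd) || noiseSd < 0)
    stop("'noiseSd' must be non-negative")
  if (curve@slope <= 0)
    stop("invalid curve: LOD/LOQ require a positive slope")
  curve@lod <- 3 * noiseSd / curve@slope
  curve@loq <- 10 * noiseSd / curve@slope
  validObject(curve)
  curve
}

#' @rdname lodLoq
#' @export
lodLoqValues <- function(curve) {
  stopifnot(is(curve, "CalibrationCurve"))
  c(lod = curve@lod, loq = curve@loq)
}

#' Back-calculate a concentration from a calibration curve
#'
#' Inverts the calibration line: `(area - intercept) / slope`.
#' Negative back-calculated values — routine for blank-level areas
#' below the intercept — are clamped to zero with a warning rather
#' than raising an error.
#'
#' @param area observed peak area.
#' @param curve a [CalibrationCurve-class].
#' @return concentration (ug/mL), >= 0.
#' @export
concentrationFromCurve <- function(area, curve) {
  stopifnot(is(curve, "CalibrationCurve"))
  conc <- (area - curve@intercept) / curve@slope
  if (any(conc < 0)) {
    warning("negative back-calculated concentration clamped to 0")
    conc <- pmax(conc, 0)
  }
  conc
}

#' Relative response factor
#'
#' Detector response of a known compound relative to an internal
#' standard: `RRF = (A_k / A_i) / (C_k / C_i)` with areas `A` and
#' concentrations `C`.
#'
#' @param areaKnown peak area of the known compound (A_k).
#' @param areaIS peak area of the internal standard (A_i).
#' @param concKnown concentration of the known compound (C_k, ug/mL).
#' @param concIS concentration of the internal standard (C_i, ug/mL).
#' @return the RRF (dimensionless, > 0).
#' @examples
#' relativeResponseFactor(1000, 500, 25, 20)  # 1.6
#' @export
relativeResponseFactor <- function(areaKnown, areaIS, concKnown, concIS) {
  vals <- c(areaKnown, areaIS, concKnown, concIS)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid measurement: all areas and concentrations must be > 0")
  (areaKnown / areaIS) / (concKnown / concIS)
}

#' Quantify a compound lacking an authentic standard
#'
#' Internal-standard quantification through the relative response
#' factor: `concentration = (A / A_i) * C_i / RRF / R`, where A is the
#' unknown's peak area, `A_i`/`C_i` the internal standard's area and
#' concentration, and R the recovery fraction.
#'
#' @param area peak area of the unknown compound (>= 0).
#' @param isSpec an [InternalStandardSpec-class].
#' @param rrf relative response factor (> 0).
#' @param recovery recovery fraction in (0, 1.2]; defaults to 1 when no
#'   compound-specific recovery is available.
#' @return concentration in solution (ug/mL).
#' @examples
#' is <- internalStandard("ferulic acid", 20, 4e5)
#' quantifyUnknown(4e5, is, rrf = 1)  # 20 ug/mL
#' @export
quantifyUnknown <- function(area, isSpec, rrf, recovery = 1) {
  stopifnot(is(isSpec, "InternalStandardSpec"))
  if (!is.numeric(area) || any(area < 0)) stop("'area' must be >= 0")
  if (!is.numeric(rrf) || rrf <= 0) stop("'rrf' must be > 0")
  if (!is.numeric(recovery) || recovery <= 0 || recovery > 1.2)
    stop("invalid recovery: must lie in (0, 1.2]")
  (area / isSpec@area) * isSpec@concentration / rrf / recovery
}

#' Spike recovery rate
#'
#' `[(measured after spiking - measured before spiking) / amount
#' spiked] * 100`, the accuracy statistic of standard-addition
#' validation.
#'
#' @param before measured amount before spiking.
#' @param after measured amount after spiking.
#' @param spiked actual amount spiked (> 0).
#' @return recovery in percent.
#' @examples
#' recoveryRate(10, 40, 30)  # 100
#' @export
recoveryRate <- function(before, after, spiked) {
  if (!is.numeric(spiked) || spiked <= 0)
    stop("invalid spike: spiked amount must be > 0")
  (after - before) / spiked * 100
}

#' Relative standard deviation
#'
#' Sample (n-1) standard deviation over the mean, in percent; the
#' precision statistic of replicate injections.
#'
#' @param values numeric vector of >= 2 replicate measurements.
#' @return RSD in percent.
#' @examples
#' rsd(c(1, 2, 3))  # 50
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values for an RSD")
  m <- mean(values)
  if (m == 0) stop("undefined RSD: mean is zero")
  stats::sd(values) / m * 100
}

#' Content per gram dry weight
#'
#' Converts a solution concentration to a dry-weight content:
#' `concentration * dilution * extractVolume / dryMass / 1000` gives
#' mg per g dry weight. Defaults describe 0.5 g of material extracted
#' in 15 mL (the optimal 1:30 g/mL solid/liquid ratio).
#'
#' @param concentration solution concentration (ug/mL).
#' @param extractVolume extract volume (mL).
#' @param dryMass dry material mass (g).
#' @param dilution dilution factor applied before measurement.
#' @return content in mg/g DW.
#' @examples
#' contentPerDw(30.67, 15, 0.5)  # ~0.92 mg/g DW
#' @export
contentPerDw <- function(concentration, extractVolume = 15, dryMass = 0.5,
                         dilution = 1) {
  stopifnot(extractVolume > 0, dryMass > 0, dilution > 0)
  concentration * dilution * extractVolume / dryMass / 1000
}

#' Folin-Ciocalteu total phenolics as gallic acid equivalents
#'
#' Back-calculates the gallic-acid-equivalent concentration from the
#' colorimetric absorbance via the gallic acid calibration curve, then
#' scales to g GAE per 100 g dry weight.
#'
#' @param absorbance measured absorbance (760 nm).
#' @param gallicCurve gallic acid [CalibrationCurve-class] fitted on
#'   absorbance vs concentration.
#' @param dilution dilution factor of the extract in the assay.
#' @param extractVolume extract volume (mL).
#' @param dryMass dry material mass (g).
#' @return total phenolic content in g GAE/100 g DW.
#' @export
folinTp <- function(absorbance, gallicCurve, dilution = 1,
                    extractVolume = 15, dryMass = 0.5) {
  stopifnot(extractVolume > 0, dryMass > 0, dilution > 0)
  conc <- concentrationFromCurve(absorbance, gallicCurve)
  # ug/mL -> ug per g DW -> g per 100 g DW
  conc * dilution * extractVolume / dryMass * 1e-6 * 100
}

#' Quantify a peak table
#'
#' Applies external-standard or RRF quantification to each compound of
#' a peak table, then converts to dry-weight content. The
#' quantification map assigns each compound its method:
#' `external_standard` rows use the named calibration curve; `rrf`
#' rows use the named internal standard with the supplied RRF and
#' recovery.
#'
#' @param peaks data.frame with columns `compound` and `area`.
#' @param map data.frame with columns `compound`, `class`, `method`,
#'   `standard`, `rrf`, `recovery` (see [defaultQuantMap()]).
#' @param curves named list of [CalibrationCurve-class] keyed by
#'   standard name.
#' @param isSpecs named list of [InternalStandardSpec-class] keyed by
#'   internal standard name.
#' @param extractVolume,dryMass,dilution passed to [contentPerDw()].
#' @return data.frame of quantification records: compound, class,
#'   method, concentration (ug/mL) and content (mg/g DW).
#' @export
quantifyBatch <- function(peaks, map, curves, isSpecs,
                          extractVolume = 15, dryMass = 0.5, dilution = 1) {
  stopifnot(all(c("compound", "area") %in% names(peaks)),
            all(c("compound", "class", "method", "standard", "rrf",
                  "recovery") %in% names(map)))
  idx <- match(peaks$compound, map$compound)
  if (anyNA(idx))
    stop("no quantification mapping for: ",
         paste(peaks$compound[is.na(idx)], collapse = ", "))
  m <- map[idx, , drop = FALSE]
  conc <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (m$method[i] == "external_standard") {
      cur <- curves[[m$standard[i]]]
      if (is.null(cur)) stop("missing calibration curve: ", m$standard[i])
      conc[i] <- concentrationFromCurve(peaks$area[i], cur)
    } else if (m$method[i] == "rrf") {
      is_spec <- isSpecs[[m$standard[i]]]
      if (is.null(is_spec)) stop("missing internal standard: ", m$standard[i])
      conc[i] <- quantifyUnknown(peaks$area[i], is_spec, m$rrf[i],
                                 m$recovery[i])
    } else stop("unknown quantification method: ", m$method[i])
  }
  data.frame(compound = peaks$compound, class = m$class,
             method = m$method, concentration = conc,
             content = contentPerDw(conc, extractVolume, dryMass, dilution))
}

#' Default internal-standard assignment map
#'
#' The structural-similarity assignment used for compounds lacking
#' authentic standards: protocatechuic acid anchors the simple
#' phenolic acids, ferulic acid the hydroxycinnamoyl esters, and
#' hesperidin the flavone glycosides/methoxyflavones; luteolin,
#' apigenin and acacetin carry their own curves. RRF and recovery
#' columns default to NA/1 and are filled from measurements.
#'
#' @return data.frame with columns compound, class, method, standard,
#'   rrf, recovery.
#' @export
defaultQuantMap <- function() {
  ext <- data.frame(
    compound = c("luteolin", "apigenin", "acacetin"),
    class = "flavonoid", method = "external_standard",
    standard = c("luteolin", "apigenin", "acacetin"))
  rrf <- data.frame(
    compound = c("3-O-caffeoyl-5-O-p-coumaroylquinic acid",
                 "gallic acid monohydrate", "shikimic acid isomer",
                 "coumaroyloleuropein",
                 "3,5-dicaffeoylquinic acid monohydrate",
                 "3,5-dicaffeoylquinic acid", "methoxyoleuropein isomer",
                 "prenyl-dimethoxy-caffeoyl-p-coumaric acid",
                 "tricin", "luteolin-O-glucoside", "chrysoeriol"),
    class = c("hydroxycinnamic_acid", "hydroxybenzoic_acid",
              "hydroxybenzoic_acid", rep("hydroxycinnamic_acid", 5),
              rep("flavonoid", 3)),
    method = "rrf",
    standard = c("protocatechuic acid", "protocatechuic acid",
                 "protocatechuic acid", rep("ferulic acid", 5),
                 rep("hesperidin", 3)))
  out <- rbind(ext, rrf)
  out$rrf <- NA_real_
  out$recovery <- 1
  out
}

#' Aggregate contents by compound class
#'
#' Per-class content sums, the grand total over the phenolic classes
#' (hydroxybenzoic + hydroxycinnamic + flavonoid), and the single most
#' abundant compound. Order of the input records does not matter.
#'
#' @param records data.frame with columns `compound`, `class` and
#'   `content` (mg/g DW), e.g. from [quantifyBatch()].
#' @return list with `class_totals` (named numeric), `phenolic_acid`
#'   (hydroxybenzoic + hydroxycinnamic), `total` (all phenolic
#'   classes), `top_compound` and `top_content`.
#' @examples
#' recs <- data.frame(compound = c("a", "b"),
#'                    class = c("flavonoid", "hydroxycinnamic_acid"),
#'                    content = c(1.5, 0.5))
#' aggregateByClass(recs)
#' @export
aggregateByClass <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0)
    return(list(class_totals = stats::setNames(numeric(0), character(0)),
                phenolic_acid = 0, total = 0,
                top_compound = NA_character_, top_content = NA_real_))
  stopifnot(all(c("compound", "class", "content") %in% names(records)))
  totals <- tapply(records$content, records$class, sum)
  totals <- stats::setNames(as.numeric(totals), names(totals))
  g <- function(cl) if (cl %in% names(totals)) totals[[cl]] else 0
  i <- which.max(records$content)
  list(class_totals = totals,
       phenolic_acid = g("hydroxybenzoic_acid") + g("hydroxycinnamic_acid"),
       total = g("hydroxybenzoic_acid") + g("hydroxycinnamic_acid") +
         g("flavonoid"),
       top_compound = records$compound[i],
       top_content = records$content[i])
}
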
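#' @include AllGenerics.R
NULL

# ---- FactorSpec --------------------------------------------------------

#' Extraction factor specification
#'
#' Describes one continuous extraction factor and its coded-unit mapping:
#' `uncoded = center + step * coded`, so the two-level factorial settings
#' sit at one `step` either side of `center`. The solid/liquid ratio is
#' parameterized through its continuous denominator D in "1:D g/mL"
#' (mL solvent per g material).
#'
#' @slot name factor name.
#' @slot center uncoded value at coded 0.
#' @slot step uncoded units per coded unit; must be positive.
#' @slot unit display unit (e.g. "min", "mL/g", "degC").
#'
#' @seealso [factorSpec()], [codeValue()], [buildCCCDesign()]
#' @exportClass FactorSpec
setClass("FactorSpec",
  representation(name = "character", center = "numeric", step = "numeric",
                 unit = "character"))

setValidity("FactorSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@center) != 1L || !is.finite(object@center))
    msg <- c(msg, "'center' must be a single finite number")
  if (length(object@step) != 1L || !is.finite(object@step) || object@step <= 0)
    msg <- c(msg, "'step' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Create a factor specification
#'
#' @param name factor name.
#' @param center uncoded value at coded level 0.
#' @param step uncoded units per coded unit (> 0).
#' @param unit display unit.
#' @return a [FactorSpec-class] object.
#' @examples
#' factorSpec("time", center = 30, step = 10, unit = "min")
#' @export
factorSpec <- function(name, center, step, unit = "") {
  new("FactorSpec", name = as.character(name), center = as.numeric(center),
      step = as.numeric(step), unit = as.character(unit))
}

setMethod("show", "FactorSpec", function(object) {
  cat(sprintf("FactorSpec '%s': center %g, step %g %s\n",
              object@name, object@center, object@step, object@unit))
})

# ---- CCCDesign ---------------------------------------------------------

#' Central composite circumscribed design
#'
#' A CCC design in k factors: the 2^k factorial block at coded levels
#' +/-1, 2k axial (star) points at +/-alpha on one axis, and replicated
#' center points. Responses (total-phenolic yield, g GAE/100 g DW) may be
#' attached after the experiment.
#'
#' @slot factors list of [FactorSpec-class], one per factor.
#' @slot alpha axial distance in coded units (> 1).
#' @slot coded numeric matrix of coded settings, one row per run.
#' @slot uncoded numeric matrix of uncoded settings (center + step * coded).
#' @slot role character vector: "factorial", "axial" or "center".
#' @slot response numeric vector of responses (NA when not yet measured).
#'
#' @seealso [buildCCCDesign()], [fitQuadratic()]
#' @exportClass CCCDesign
setClass("CCCDesign",
  representation(factors = "list", alpha = "numeric", coded = "matrix",
                 uncoded = "matrix", role = "character",
                 response = "numeric"))

setValidity("CCCDesign", function(object) {
  msg <- character()
  k <- length(object@factors)
  if (k < 2L) msg <- c(msg, "need at least two factors")
  if (!all(vapply(object@factors, is, logical(1), "FactorSpec")))
    msg <- c(msg, "'factors' must all be FactorSpec objects")
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 0)
    msg <- c(msg, "'alpha' must be a single positive number")
  n <- nrow(object@coded)
  if (ncol(object@coded) != k || !identical(dim(object@coded),
                                            dim(object@uncoded)))
    msg <- c(msg, "coded/uncoded dimensions inconsistent with factors")
  if (length(object@role) != n || length(object@response) != n)
    msg <- c(msg, "role/response length must equal the number of runs")
  if (!all(object@role %in% c("factorial", "axial", "center")))
    msg <- c(msg, "roles must be factorial, axial or center")
  if (n > 0 && max(abs(object@coded)) > object@alpha + 1e-9)
    msg <- c(msg, "coded settings exceed alpha in magnitude")
  if (n > 0 && any(abs(colSums(object@coded)) > 1e-8))
    msg <- c(msg, "coded linear columns must each sum to zero")
  fac <- object@role == "factorial"
  if (any(fac) && !all(abs(abs(object@coded[fac, , drop = FALSE]) - 1) < 1e-9))
    msg <- c(msg, "factorial points must have coded levels +/-1")
  ctr <- object@role == "center"
  if (any(ctr) && !all(abs(object@coded[ctr, , drop = FALSE]) < 1e-9))
    msg <- c(msg, "center points must have all-zero coded levels")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CCCDesign", function(object) {
  k <- length(object@factors)
  cat(sprintf("CCCDesign: %d factors, alpha = %g, %d runs (%d factorial, %d axial, %d center)\n",
              k, object@alpha, nrow(object@coded),
              sum(object@role == "factorial"), sum(object@role == "axial"),
              sum(object@role == "center")))
  cat(sprintf("  responses: %d of %d observed\n",
              sum(!is.na(object@response)), length(object@response)))
})

#' @rdname accessors
#' @export
setMethod("codedValues", "CCCDesign", function(x) x@coded)

#' @rdname accessors
#' @export
setMethod("uncodedValues", "CCCDesign", function(x) x@uncoded)

#' @rdname accessors
#' @export
setMethod("responses", "CCCDesign", function(x) x@response)

#' @rdname accessors
#' @export
setReplaceMethod("responses", "CCCDesign", function(x, value) {
  stopifnot(length(value) == nrow(x@coded))
  x@response <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("designRoles", "CCCDesign", function(x) x@role)

#' @rdname accessors
#' @export
setMethod("factorSpecs", "CCCDesign", function(x) x@factors)

# ---- QuadraticSurfaceModel --------------------------------------------

#' Fitted second-order response surface
#'
#' Full quadratic polynomial in the coded factors, fitted by ordinary
#' least squares: intercept, k linear, k pure-quadratic and k(k-1)/2
#' two-way interaction terms (df_model = 9 for k = 3).
#'
#' @slot coefficients named coefficient vector in the coded basis.
#' @slot factors list of [FactorSpec-class] carried from the design.
#' @slot rSquared coefficient of determination.
#' @slot fStatistic overall model F statistic.
#' @slot pValue p-value of the overall F test.
#' @slot dfModel model degrees of freedom.
#' @slot dfResidual residual degrees of freedom.
#' @slot sigma residual standard error.
#'
#' @seealso [fitQuadratic()], [anovaTable()], [optimizeSurface()]
#' @exportClass QuadraticSurfaceModel
setClass("QuadraticSurfaceModel",
  representation(coefficients = "numeric", factors = "list",
                 rSquared = "numeric", fStatistic = "numeric",
                 pValue = "numeric", dfModel = "integer",
                 dfResidual = "integer", sigma = "numeric"))

setValidity("QuadraticSurfaceModel", function(object) {
  msg <- character()
  k <- length(object@factors)
  if (k >= 1 && length(object@coefficients) != 1 + 2 * k + k * (k - 1) / 2)
    msg <- c(msg, "coefficient length does not match a full quadratic")
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QuadraticSurfaceModel", function(object) {
  cat(sprintf("QuadraticSurfaceModel: %d factors, R^2 = %.4f, F(%d, %d) = %.2f, p = %.3g\n",
              length(object@factors), object@rSquared, object@dfModel,
              object@dfResidual, object@fStatistic, object@pValue))
  print(round(object@coefficients, 5))
})

#' @rdname accessors
#' @export
setMethod("rSquared", "QuadraticSurfaceModel", function(x) x@rSquared)

#' @rdname accessors
#' @export
setMethod("factorSpecs", "QuadraticSurfaceModel", function(x) x@factors)

#' Model coefficients in the coded basis
#' @param object a [QuadraticSurfaceModel-class].
#' @param ... ignored.
#' @return named numeric vector.
#' @export
setMethod("coef", "QuadraticSurfaceModel", function(object, ...)
  object@coefficients)

# ---- OptimizationResult ------------------------------------------------

#' Constrained optimum of a fitted surface
#'
#' @slot codedOpt maximizer in coded units.
#' @slot uncodedOpt maximizer in uncoded units.
#' @slot predictedResponse fitted response at the maximizer.
#' @slot region 2 x k matrix of box bounds (rows lower/upper) in coded units.
#'
#' @seealso [optimizeSurface()]
#' @exportClass OptimizationResult
setClass("OptimizationResult",
  representation(codedOpt = "numeric", uncodedOpt = "numeric",
                 predictedResponse = "numeric", region = "matrix"))

setMethod("show", "OptimizationResult", function(object) {
  cat("OptimizationResult\n")
  cat("  coded optimum:   ", paste(sprintf("%.4f", object@codedOpt),
                                   collapse = ", "), "\n")
  cat("  uncoded optimum: ", paste(sprintf("%.2f", object@uncodedOpt),
                                   collapse = ", "), "\n")
  cat(sprintf("  predicted response: %.4f\n", object@predictedResponse))
})

# ---- SpectralTree ------------------------------------------------------

#' MSn spectral tree
#'
#' One chromatographic peak with its deprotonated molecular ion [M-H]-,
#' UV absorbance maxima, and the hierarchy of MSn fragments. Fragments
#' are stored flat: `parent = 0` denotes the precursor; `level` is the
#' MS stage (2 for MS2, ...). Relative intensities are percent of the
#' level base peak, in (0, 100], with at most one ion at exactly 100
#' per level (printed spectra occasionally omit the base peak, so a
#' level without a 100 is tolerated).
#'
#' @slot peakId peak identifier.
#' @slot precursorMz [M-H]- m/z (NA allowed only for peaks without MS data).
#' @slot uvLambdaMax UV absorbance maxima (nm); may be empty.
#' @slot rtMin retention time (min).
#' @slot fragments data.frame with columns node, parent, level, mz,
#'   rel_intensity.
#'
#' @seealso [spectralTree()], [neutralLosses()], [annotate()]
#' @exportClass SpectralTree
setClass("SpectralTree",
  representation(peakId = "character", precursorMz = "numeric",
                 uvLambdaMax = "numeric", rtMin = "numeric",
                 fragments = "data.frame"))

setValidity("SpectralTree", function(object) {
  msg <- character()
  fr <- object@fragments
  need <- c("node", "parent", "level", "mz", "rel_intensity")
  if (!all(need %in% names(fr)))
    return("fragments must have columns node, parent, level, mz, rel_intensity")
  if (nrow(fr) > 0 && is.na(object@precursorMz))
    msg <- c(msg, "precursorMz required when fragments are present")
  if (nrow(fr) > 0) {
    parent_mz <- ifelse(fr$parent == 0, object@precursorMz,
                        fr$mz[match(fr$parent, fr$node)])
    if (anyNA(parent_mz))
      msg <- c(msg, "fragment parent reference not found")
    else if (any(fr$mz >= parent_mz))
      msg <- c(msg, "each fragment m/z must be below its parent m/z")
    if (any(fr$rel_intensity <= 0 | fr$rel_intensity > 100))
      msg <- c(msg, "relative intensities must lie in (0, 100]")
    for (lv in unique(fr$level)) {
      if (sum(fr$rel_intensity[fr$level == lv] == 100) > 1)
        msg <- c(msg, sprintf("level %d has more than one base peak at 100%%", lv))
    }
    lvs <- sort(unique(fr$level))
    if (lvs[1] != 2L || any(diff(lvs) != 1L))
      msg <- c(msg, "fragment levels must be consecutive starting at 2")
    lv_parent <- ifelse(fr$parent == 0, 1L, fr$level[match(fr$parent, fr$node)])
    if (!anyNA(lv_parent) && any(fr$level != lv_parent + 1L))
      msg <- c(msg, "each fragment level must be its parent's level + 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpectralTree", function(object) {
  cat(sprintf("SpectralTree '%s': [M-H]- %s, Rt %.2f min, UV %s nm, %d fragments (levels %s)\n",
              object@peakId,
              ifelse(is.na(object@precursorMz), "n/a",
                     format(object@precursorMz)),
              object@rtMin,
              if (length(object@uvLambdaMax))
                paste(object@uvLambdaMax, collapse = "/") else "n/a",
              nrow(object@fragments),
              if (nrow(object@fragments))
                paste(range(object@fragments$level), collapse = "-") else "-"))
})

#' @rdname accessors
#' @export
setMethod("peakId", "SpectralTree", function(x) x@peakId)

#' @rdname accessors
#' @export
setMethod("precursorMz", "SpectralTree", function(x) x@precursorMz)

#' @rdname accessors
#' @export
setMethod("uvLambdaMax", "SpectralTree", function(x) x@uvLambdaMax)

#' @rdname accessors
#' @export
setMethod("retentionTime", "SpectralTree", function(x) x@rtMin)

#' @rdname accessors
#' @export
setMethod("fragments", "SpectralTree", function(x) x@fragments)

# ---- Annotation --------------------------------------------------------

#' Compound annotation
#'
#' Result of the rule cascade for one spectral tree: compound name,
#' class, confidence level and the ordered chain of matched evidence
#' (neutral losses, marker ions, UV windows).
#'
#' @slot peakId peak identifier of the annotated tree.
#' @slot name compound name, or "unknown".
#' @slot compoundClass one of hydroxybenzoic_acid, hydroxycinnamic_acid,
#'   flavonoid, hydroxy_fatty_acid, unknown.
#' @slot confidence one of standard_matched, deduced, tentative_isomer,
#'   unknown.
#' @slot evidence character vector of matched-rule descriptors.
#' @slot notes character vector of caveats attached by the rules.
#'
#' @seealso [annotate()], [annotateBatch()]
#' @exportClass Annotation
setClass("Annotation",
  representation(peakId = "character", name = "character",
                 compoundClass = "character", confidence = "character",
                 evidence = "character", notes = "character"))

.compoundClasses <- c("hydroxybenzoic_acid", "hydroxycinnamic_acid",
                      "flavonoid", "hydroxy_fatty_acid", "unknown")
.confidenceLevels <- c("standard_matched", "deduced", "tentative_isomer",
                       "unknown")

setValidity("Annotation", function(object) {
  msg <- character()
  if (!object@compoundClass %in% .compoundClasses)
    msg <- c(msg, "invalid compound class")
  if (!object@confidence %in% .confidenceLevels)
    msg <- c(msg, "invalid confidence level")
  unk <- identical(object@compoundClass, "unknown")
  if (unk != identical(tolower(object@name), "unknown"))
    msg <- c(msg, "class is 'unknown' if and only if name is 'unknown'")
  if (!unk && length(object@evidence) == 0)
    msg <- c(msg, "non-unknown annotations must carry evidence")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Annotation", function(object) {
  cat(sprintf("Annotation '%s': %s [%s, %s]\n", object@peakId, object@name,
              object@compoundClass, object@confidence))
  if (length(object@evidence))
    cat("  evidence:", paste(object@evidence, collapse = "; "), "\n")
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' @rdname accessors
#' @export
setMethod("peakId", "Annotation", function(x) x@peakId)

#' @rdname accessors
#' @export
setMethod("compoundName", "Annotation", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("compoundClass", "Annotation", function(x) x@compoundClass)

#' @rdname accessors
#' @export
setMethod("confidence", "Annotation", function(x) x@confidence)

#' @rdname accessors
#' @export
setMethod("evidence", "Annotation", function(x) x@evidence)

# ---- CalibrationCurve --------------------------------------------------

#' External-standard calibration curve
#'
#' Linear detector response `area = slope * concentration + intercept`
#' at a fixed detection wavelength, with sensitivity limits attached
#' once a baseline noise estimate is available (LOD at S/N = 3, LOQ at
#' S/N = 10).
#'
#' @slot analyte standard compound name.
#' @slot wavelength detection wavelength (nm).
#' @slot slope response per ug/mL.
#' @slot intercept area at zero concentration.
#' @slot rSquared coefficient of determination of the fit.
#' @slot lod limit of detection (ug/mL), NA until computed.
#' @slot loq limit of quantification (ug/mL), NA until computed.
#'
#' @seealso [fitCalibration()], [lodLoq()], [concentrationFromCurve()]
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(analyte = "character", wavelength = "numeric",
                 slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", lod = "numeric", loq = "numeric"))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope == 0)
    msg <- c(msg, "'slope' must be a single non-zero number")
  if (!is.na(object@lod) && object@lod < 0)
    msg <- c(msg, "LOD must be non-negative")
  if (!is.na(object@lod) && !is.na(object@loq) && object@loq < object@lod)
    msg <- c(msg, "LOQ must be >= LOD")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve '%s' (%g nm): Y = %gX %+g, R^2 = %s, LOD %s, LOQ %s ug/mL\n",
              object@analyte, object@wavelength, object@slope,
              object@intercept,
              ifelse(is.na(object@rSquared), "n/a",
                     sprintf("%.4f", object@rSquared)),
              ifelse(is.na(object@lod), "n/a", format(object@lod)),
              ifelse(is.na(object@loq), "n/a", format(object@loq))))
})

#' @rdname accessors
#' @export
setMethod("rSquared", "CalibrationCurve", function(x) x@rSquared)

#' Calibration line coefficients
#' @param object a [CalibrationCurve-class].
#' @param ... ignored.
#' @return named numeric vector `c(intercept, slope)`.
#' @export
setMethod("coef", "CalibrationCurve", function(object, ...)
  c(intercept = object@intercept, slope = object@slope))

# ---- InternalStandardSpec ----------------------------------------------

#' Internal standard measurement
#'
#' Fixed-concentration internal standard spiked into the sample extract,
#' with its observed peak area; the anchor of relative-response-factor
#' quantification.
#'
#' @slot name internal standard compound name.
#' @slot concentration spiked concentration (ug/mL).
#' @slot area observed peak area.
#'
#' @seealso [relativeResponseFactor()], [quantifyUnknown()]
#' @exportClass InternalStandardSpec
setClass("InternalStandardSpec",
  representation(name = "character", concentration = "numeric",
                 area = "numeric"))

setValidity("InternalStandardSpec", function(object) {
  msg <- character()
  if (object@concentration <= 0) msg <- c(msg, "concentration must be > 0")
  if (object@area <= 0) msg <- c(msg, "area must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create an internal standard specification
#'
#' @param name compound name.
#' @param concentration spiked concentration (ug/mL), > 0.
#' @param area observed peak area, > 0.
#' @return an [InternalStandardSpec-class].
#' @examples
#' internalStandard("ferulic acid", concentration = 20, area = 5e5)
#' @export
internalStandard <- function(name, concentration, area) {
  new("InternalStandardSpec", name = as.character(name),
      concentration = as.numeric(concentration), area = as.numeric(area))
}

setMethod("show", "InternalStandardSpec", function(object) {
  cat(sprintf("InternalStandardSpec '%s': %g ug/mL, area %g\n",
              object@name, object@concentration, object@area))
})
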
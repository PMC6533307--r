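#' @include annotate.R quant.R
NULL

# Reference identifications for the packaged 23-peak spectral dataset;
# the generating truth for round-trip tests and the naming source for
# compoundLibrary(). Two co-eluting dihydroxy acid isomers share one
# name; three peaks are genuine unknowns shipped as distractors.
.referenceAnnotations <- function() {
  data.frame(
    peak_id = as.character(1:23),
    name = c("3-O-caffeoyl-5-O-p-coumaroylquinic acid",
             "coumaroyloleuropein", "luteolin-O-glucoside",
             "3,5-dicaffeoylquinic acid monohydrate",
             "3,5-dicaffeoylquinic acid", "gallic acid monohydrate",
             "shikimic acid isomer", "methoxyoleuropein isomer",
             "luteolin", "prenyl-dimethoxy-caffeoyl-p-coumaric acid",
             "apigenin", "chrysoeriol", "tricin", "unknown",
             "monohydroxy-octadecaditrienoic acid", "unknown", "acacetin",
             "unknown", "dihydroxy-octadecenoic acid",
             "dihydroxy-octadecatrienoic acid",
             "dihydroxy-octadecatrienoic acid",
             "monohydroxy-octadecadienoic acid",
             "monohydroxy-octadecenoic acid"),
    class = c("hydroxycinnamic_acid", "hydroxycinnamic_acid", "flavonoid",
              "hydroxycinnamic_acid", "hydroxycinnamic_acid",
              "hydroxybenzoic_acid", "hydroxybenzoic_acid",
              "hydroxycinnamic_acid", "flavonoid", "hydroxycinnamic_acid",
              "flavonoid", "flavonoid", "flavonoid", "unknown",
              "hydroxy_fatty_acid", "unknown", "flavonoid", "unknown",
              "hydroxy_fatty_acid", "hydroxy_fatty_acid",
              "hydroxy_fatty_acid", "hydroxy_fatty_acid",
              "hydroxy_fatty_acid"))
}

#' Simulate responses on a design from a known surface
#'
#' Evaluates a user-supplied coefficient vector (full quadratic basis
#' in the coded factors: intercept, linear, squared, interactions) at
#' every design point and adds independent Gaussian noise — the
#' data-generating process a CCC experiment assumes. Bit-reproducible
#' under a fixed seed.
#'
#' @param coefficients numeric vector matching the full quadratic basis
#'   (10 values for three factors, ordered as [fitQuadratic()]
#'   coefficients).
#' @param design a [CCCDesign-class].
#' @param noiseSd response noise standard deviation (>= 0).
#' @param seed optional integer seed.
#' @return the design with simulated responses attached.
#' @examples
#' d <- buildCCCDesign(list(factorSpec("a", 0, 1), factorSpec("b", 0, 1),
#'                          factorSpec("c", 0, 1)))
#' genResponseSurface(c(1, .1, .2, .3, -.1, -.2, -.3, 0, 0, 0), d)
#' @export
genResponseSurface <- function(coefficients, design, noiseSd = 0,
                               seed = NULL) {
  stopifnot(is(design, "CCCDesign"), noiseSd >= 0)
  X <- .quadraticBasis(codedValues(design))
  if (length(coefficients) != ncol(X))
    stop("coefficient vector must have ", ncol(X), " entries")
  if (!is.null(seed)) set.seed(seed)
  y <- drop(X %*% coefficients)
  if (noiseSd > 0) y <- y + stats::rnorm(length(y), 0, noiseSd)
  responses(design) <- y
  design
}

#' Compound library for spectral simulation
#'
#' The package's reference library of phenolics and hydroxy fatty
#' acids: each entry carries the compound name, class and a template
#' spectral tree (precursor, UV maxima, MSn fragments with relative
#' intensities). Entries named "unknown" are unidentifiable
#' distractors and are emitted as such. [genSpectralTree()] realizes
#' noisy instances of a template.
#'
#' @return named list of entries, each `list(peak_id, name, class, tree)`.
#' @export
compoundLibrary <- function() {
  trees <- exampleSpectralTrees()
  ref <- .referenceAnnotations()
  ids <- vapply(trees, peakId, character(1))
  lapply(seq_len(nrow(ref)), function(i) {
    list(peak_id = ref$peak_id[i], name = ref$name[i], class = ref$class[i],
         tree = trees[[match(ref$peak_id[i], ids)]])
  })
}

#' Simulate a spectral tree from a library template
#'
#' Perturbs a template tree with (a) a mass-axis calibration offset,
#' drawn once per simulated acquisition uniformly in `[-mzJitter,
#' +mzJitter]` and applied to the precursor and every fragment — the
#' way unit-resolution ion-trap calibration drift actually shifts a
#' spectrum, which leaves neutral losses invariant; and (b)
#' multiplicative Gaussian noise of the stated percent CV on non-base
#' fragment intensities (base peaks stay at 100 by definition, other
#' intensities are clamped to (0, 100)). Zero-perturbation output is
#' identical to the template and satisfies every tree invariant.
#'
#' @param spec a library entry from [compoundLibrary()] or a
#'   [SpectralTree-class] template.
#' @param mzJitter maximum mass-axis offset (Da, >= 0).
#' @param intensityNoise intensity CV in percent (>= 0).
#' @param seed optional integer seed.
#' @param peakId identifier for the simulated tree; defaults to the
#'   template's.
#' @return a [SpectralTree-class].
#' @examples
#' lib <- compoundLibrary()
#' genSpectralTree(lib[[3]], mzJitter = 0.3, seed = 1)
#' @export
genSpectralTree <- function(spec, mzJitter = 0, intensityNoise = 0,
                            seed = NULL, peakId = NULL) {
  tree <- if (is(spec, "SpectralTree")) spec else spec$tree
  stopifnot(is(tree, "SpectralTree"), mzJitter >= 0, intensityNoise >= 0)
  if (!is.null(seed)) set.seed(seed)
  fr <- fragments(tree)
  offset <- if (mzJitter > 0) stats::runif(1, -mzJitter, mzJitter) else 0
  p <- precursorMz(tree) + offset
  if (nrow(fr) > 0) {
    fr$mz <- fr$mz + offset
    if (intensityNoise > 0) {
      nb <- fr$rel_intensity < 100
      fac <- exp(stats::rnorm(sum(nb), 0, log1p(intensityNoise / 100)))
      fr$rel_intensity[nb] <-
        pmin(pmax(fr$rel_intensity[nb] * fac, 1e-3), 99.9)
    }
  }
  spectralTree(if (is.null(peakId)) peakId(tree) else peakId,
               precursorMz = p, uvLambdaMax = uvLambdaMax(tree),
               rtMin = retentionTime(tree), fragments = fr)
}

#' Simulate a peak table from known concentrations
#'
#' Inverts the quantification relations of [quantifyBatch()]: external
#' -standard compounds get `area = slope * conc + intercept` from
#' their calibration curve; RRF compounds get
#' `area = conc * RRF * R * A_i / C_i` from their internal standard.
#' Multiplicative lognormal noise with the requested coefficient of
#' variation (mean-corrected so E[noise] = 1) emulates injection-to-
#' injection area variability. At zero noise, quantification of the
#' output recovers the true concentrations exactly.
#'
#' @param concentrations data.frame with columns `compound` and
#'   `concentration` (ug/mL).
#' @param map quantification map as in [quantifyBatch()] with `rrf` and
#'   `recovery` filled for the RRF rows.
#' @param curves named list of [CalibrationCurve-class].
#' @param isSpecs named list of [InternalStandardSpec-class].
#' @param areaNoiseCv area coefficient of variation (fraction, e.g.
#'   0.01 for 1%).
#' @param seed optional integer seed.
#' @return data.frame with columns compound and area.
#' @export
genPeakTable <- function(concentrations, map, curves, isSpecs,
                         areaNoiseCv = 0, seed = NULL) {
  stopifnot(all(c("compound", "concentration") %in% names(concentrations)),
            areaNoiseCv >= 0)
  if (!is.null(seed)) set.seed(seed)
  idx <- match(concentrations$compound, map$compound)
  if (anyNA(idx))
    stop("no quantification mapping for: ",
         paste(concentrations$compound[is.na(idx)], collapse = ", "))
  m <- map[idx, , drop = FALSE]
  area <- numeric(nrow(concentrations))
  for (i in seq_along(area)) {
    conc <- concentrations$concentration[i]
    if (m$method[i] == "external_standard") {
      cur <- curves[[m$standard[i]]]
      if (is.null(cur)) stop("missing calibration curve: ", m$standard[i])
      area[i] <- cur@slope * conc + cur@intercept
    } else {
      is_spec <- isSpecs[[m$standard[i]]]
      if (is.null(is_spec)) stop("missing internal standard: ", m$standard[i])
      area[i] <- conc * m$rrf[i] * m$recovery[i] * is_spec@area /
        is_spec@concentration
    }
  }
  if (areaNoiseCv > 0) {
    sdlog <- sqrt(log1p(areaNoiseCv^2))
    area <- area * exp(stats::rnorm(length(area), -sdlog^2 / 2, sdlog))
  }
  data.frame(compound = concentrations$compound, area = area)
}
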
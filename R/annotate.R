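#' @include loss-rules.R
NULL

.annotation <- function(peakId, name, class, confidence,
                        evidence = character(), notes = character()) {
  new("Annotation", peakId = peakId, name = name, compoundClass = class,
      confidence = confidence, evidence = evidence, notes = notes)
}

.unknownAnnotation <- function(peakId, notes = character()) {
  .annotation(peakId, "unknown", "unknown", "unknown", notes = notes)
}

#' Candidate compound classes from UV absorbance maxima
#'
#' Heuristic windows over the PDA absorbance maxima, calibrated on the
#' behaviour of phenolic subclasses in negative-mode LC-PDA work:
#' flavones show band II in 240-280 nm plus band I in 330-360 nm;
#' hydroxycinnamates absorb in 300-335 nm; hydroxybenzoic acids keep
#' all maxima below 330 nm or show the 250/270/320 triple pattern.
#' Hydroxy fatty acids impose no UV requirement and are always
#' candidates. Windows overlap deliberately: the result is a candidate
#' set that the fragmentation rules narrow down, not a verdict. An
#' empty input (no usable UV spectrum) leaves every class a candidate.
#'
#' @param uv numeric vector of absorbance maxima (nm); may be empty.
#' @return character vector of candidate classes (subset of
#'   hydroxybenzoic_acid, hydroxycinnamic_acid, flavonoid,
#'   hydroxy_fatty_acid).
#' @examples
#' classifyUv(c(250, 340))  # flavonoid among candidates
#' classifyUv(c(240, 330))  # hydroxycinnamic_acid among candidates
#' classifyUv(numeric())    # everything
#' @export
classifyUv <- function(uv) {
  all4 <- setdiff(.compoundClasses, "unknown")
  if (length(uv) == 0) return(all4)
  out <- "hydroxy_fatty_acid"
  if (any(uv >= 330 & uv <= 360) && any(uv >= 240 & uv <= 280))
    out <- c(out, "flavonoid")
  if (any(uv >= 300 & uv <= 335))
    out <- c(out, "hydroxycinnamic_acid")
  if (all(uv < 330) ||
      (any(abs(uv - 250) <= 5) && any(abs(uv - 270) <= 5) &&
       any(abs(uv - 320) <= 5)))
    out <- c(out, "hydroxybenzoic_acid")
  intersect(all4, out)
}

#' Detect hydroxy fatty acids
#'
#' Oxygenated C18 fatty acids elute late and betray themselves by
#' water cleavage from the aliphatic chain in MS2. The rule fires when
#' the precursor falls in the 290-320 Da window, a
#' `[M-H-H2O]-` ion is present at or above 25% relative intensity, and
#' the precursor does not coincide with a flavone aglycone mass (which
#' would be claimed by the flavone rule instead). The name is looked
#' up from the nominal-mass table ([hydroxyFattyAcidTable()]).
#'
#' @param tree a [SpectralTree-class].
#' @param tolerance m/z tolerance in Da.
#' @return an [Annotation-class], or NULL when the rule does not fire.
#' @export
detectHydroxyFattyAcid <- function(tree, tolerance = 0.5) {
  p <- precursorMz(tree)
  if (is.na(p) || p < 290 || p > 320) return(NULL)
  ag <- flavoneAglycones()
  if (any(abs(p - ag) <= tolerance)) return(NULL)
  ms2 <- .levelFragments(tree, 2L)
  water <- ms2[abs((p - ms2$mz) - 18) <= tolerance &
               ms2$rel_intensity >= 25, , drop = FALSE]
  if (nrow(water) == 0) return(NULL)
  tab <- hydroxyFattyAcidTable()
  hit <- which(abs(p - as.numeric(names(tab))) <= tolerance)
  if (length(hit) == 0) return(NULL)
  ev <- c(sprintf("[M-H]- %.0f in hydroxy fatty acid window 290-320", p),
          sprintf("[M-H-H2O]- at m/z %.0f (%g%%)", water$mz[1],
                  water$rel_intensity[1]))
  if (.hasIon(ms2, p - 36, tolerance))
    ev <- c(ev, sprintf("second water loss at m/z %.0f", p - 36))
  notes <- character()
  if (abs(p - 293) <= tolerance)
    notes <- "name kept as printed in the source identification; orthodox spelling would be monohydroxy-octadecatrienoic acid"
  .annotation(peakId(tree), unname(tab[hit[1]]), "hydroxy_fatty_acid",
              "deduced", ev, notes)
}

#' Identify caffeoyl/coumaroylquinic acid esters
#'
#' Hydroxycinnamoyl esters of quinic acid lose their acyl groups
#' (146 Da coumaroyl, 162 Da caffeoyl) and terminate in the quinic
#' acid marker ion at m/z 191 (with 179/173/135 secondary markers).
#' The rule requires the 191 marker somewhere in the tree plus an acyl
#' loss from the precursor (or from precursor - 18 for the monohydrate
#' adduct, 18 Da above the anhydrous ester). Names follow the
#' precursor mass: 499 is the mixed caffeoyl/coumaroyl diester, 515
#' the dicaffeoyl ester, 533 its monohydrate. The 3,5-regiochemistry
#' is assigned by the simplified intensity key: MS2 base peak at 353
#' whose MS3 has base 191 with 179 present at >= 10%; trees failing
#' the key are reported as unlocalized isomers.
#'
#' @inheritParams detectHydroxyFattyAcid
#' @param rules neutral-loss rule table.
#' @return an [Annotation-class] or NULL.
#' @export
identifyQuinicEster <- function(tree, rules = defaultLossRules(),
                                tolerance = 0.5) {
  p <- precursorMz(tree)
  if (is.na(p)) return(NULL)
  fr <- fragments(tree)
  if (nrow(fr) == 0 || !.hasIon(fr, 191, tolerance)) return(NULL)
  targets <- c(499, 515, 533)
  hit <- targets[abs(p - targets) <= tolerance]
  if (length(hit) == 0) return(NULL)
  hit <- hit[1]
  hydrate <- hit == 533
  core <- if (hydrate) p - 18 else p
  acyl <- character()
  for (d in c(146, 162)) {
    who <- if (d == 146) "coumaroyl" else "caffeoyl"
    if (any(abs((core - fr$mz) - d) <= tolerance))
      acyl <- c(acyl, sprintf("%s loss (%d Da)", who, d))
  }
  if (length(acyl) == 0) return(NULL)
  ev <- c(acyl, "quinic acid marker ion m/z 191")
  sec <- c(179, 173, 135)
  sec <- sec[vapply(sec, function(m) .hasIon(fr, m, tolerance), logical(1))]
  if (length(sec))
    ev <- c(ev, paste("secondary quinic markers m/z",
                      paste(sec, collapse = "/")))
  notes <- character()
  if (hydrate) {
    ev <- c(ev, "precursor 18 Da above the anhydrous ester (monohydrate rule)")
  }
  regio <- FALSE
  ms2 <- .levelFragments(tree, 2L)
  b2 <- .basePeak(ms2)
  if (!is.null(b2) && abs(b2$mz - 353) <= tolerance) {
    ms3 <- .levelFragments(tree, 3L, parent = b2$node)
    b3 <- .basePeak(ms3)
    if (!is.null(b3) && abs(b3$mz - 191) <= tolerance &&
        .hasIon(ms3, 179, tolerance, min_intensity = 10)) {
      regio <- TRUE
      ev <- c(ev, "3,5-regiochemistry intensity key (MS2 base 353; MS3 base 191 with 179 >= 10%)")
    }
  }
  if (hit == 499) {
    name <- "3-O-caffeoyl-5-O-p-coumaroylquinic acid"
    conf <- "deduced"
  } else if (regio) {
    name <- paste0("3,5-dicaffeoylquinic acid",
                   if (hydrate) " monohydrate" else "")
    conf <- "deduced"
  } else {
    name <- paste0("dicaffeoylquinic acid",
                   if (hydrate) " monohydrate" else "", " isomer")
    conf <- "tentative_isomer"
    notes <- c(notes, "regiochemistry intensity key not satisfied")
  }
  .annotation(peakId(tree), name, "hydroxycinnamic_acid", conf, ev, notes)
}

#' Identify flavones and their O-glucosides
#'
#' Matches the precursor to the flavone aglycone library (luteolin 285,
#' apigenin 269, acacetin 283, chrysoeriol 299, tricin 329). Luteolin,
#' apigenin and acacetin correspond to authentic standards and are
#' reported as `standard_matched`; the methoxylated flavones
#' chrysoeriol and tricin additionally require their diagnostic
#' methyl-radical chain (base peak at precursor - 15, and - 30 for the
#' dimethoxylated tricin) and are reported as `deduced`. A 162 Da
#' hexosyl loss landing on a library aglycone names the O-glucoside.
#' The rule only fires when the UV candidate set contains flavonoid.
#'
#' @inheritParams identifyQuinicEster
#' @param aglycones named mass vector as [flavoneAglycones()].
#' @return an [Annotation-class] or NULL.
#' @export
identifyFlavone <- function(tree, aglycones = flavoneAglycones(),
                            rules = defaultLossRules(), tolerance = 0.5) {
  if (!"flavonoid" %in% classifyUv(uvLambdaMax(tree))) return(NULL)
  p <- precursorMz(tree)
  if (is.na(p)) return(NULL)
  hit <- which(abs(p - aglycones) <= tolerance)
  if (length(hit)) {
    name <- names(aglycones)[hit[1]]
    ev <- c(sprintf("[M-H]- matches %s aglycone (m/z %g)", name,
                    aglycones[hit[1]]),
            "flavone UV bands")
    if (name %in% c("chrysoeriol", "tricin")) {
      ms2 <- .levelFragments(tree, 2L)
      b2 <- .basePeak(ms2)
      if (is.null(b2) || abs((p - b2$mz) - 15) > tolerance) return(NULL)
      ev <- c(ev, sprintf("methyl loss to base peak m/z %.0f", b2$mz))
      if (name == "tricin") {
        ms3 <- .levelFragments(tree, 3L, parent = b2$node)
        b3 <- .basePeak(ms3)
        if (is.null(b3) || abs((b2$mz - b3$mz) - 15) > tolerance)
          return(NULL)
        ev <- c(ev, sprintf("second methyl loss to m/z %.0f", b3$mz))
      }
      conf <- "deduced"
    } else conf <- "standard_matched"
    return(.annotation(peakId(tree), name, "flavonoid", conf, ev))
  }
  ms2 <- .levelFragments(tree, 2L)
  for (i in seq_along(aglycones)) {
    a <- aglycones[i]
    if (abs((p - 162) - a) <= tolerance && .hasIon(ms2, a, tolerance)) {
      name <- paste0(names(aglycones)[i], "-O-glucoside")
      ev <- c(sprintf("hexosyl loss (162 Da) to %s aglycone m/z %g",
                      names(aglycones)[i], a),
              "flavone UV bands")
      return(.annotation(peakId(tree), name, "flavonoid", "deduced", ev))
    }
  }
  NULL
}

#' Identify oleuropein derivatives
#'
#' The oleuropein skeleton is recognized by its glucosyl-cleavage
#' signature: MS2 base peak at m/z 539 whose MS3 base peak is 377. An
#' acyl loss from the precursor onto that signature names the ester
#' (685 - 146 gives coumaroyloleuropein). A precursor 30 Da above
#' oleuropein (m/z 569) lacking the 539/377 signature is reported as a
#' methoxyoleuropein isomer with `tentative_isomer` confidence.
#'
#' @inheritParams identifyQuinicEster
#' @return an [Annotation-class] or NULL.
#' @export
identifyOleuropeinDerivative <- function(tree, rules = defaultLossRules(),
                                         tolerance = 0.5) {
  p <- precursorMz(tree)
  if (is.na(p)) return(NULL)
  ms2 <- .levelFragments(tree, 2L)
  b2 <- .basePeak(ms2)
  signature <- FALSE
  if (!is.null(b2) && abs(b2$mz - 539) <= tolerance) {
    b3 <- .basePeak(.levelFragments(tree, 3L, parent = b2$node))
    if (!is.null(b3) && abs(b3$mz - 377) <= tolerance) signature <- TRUE
  }
  if (signature) {
    moiety <- matchLoss(p - 539, rules)
    if (is.na(moiety)) return(NULL)
    stem <- sub("/.*", "", moiety)
    if (!stem %in% c("coumaroyl", "caffeoyl")) return(NULL)
    ev <- c("oleuropein glucosyl signature (MS2 base 539, MS3 base 377)",
            sprintf("%s loss (%.0f Da) from [M-H]- %.0f", stem, p - 539, p))
    return(.annotation(peakId(tree), paste0(stem, "oleuropein"),
                       "hydroxycinnamic_acid", "deduced", ev))
  }
  if (abs(p - 569) <= tolerance) {
    ev <- c("[M-H]- 30 Da above oleuropein (m/z 539)",
            "539/377 glucosyl signature absent")
    return(.annotation(peakId(tree), "methoxyoleuropein isomer",
                       "hydroxycinnamic_acid", "tentative_isomer", ev))
  }
  NULL
}

# Hydroxybenzoic specials: gallic acid monohydrate (+18 above the
# gallic acid standard, with its 169/125 water + CO2 cascade) and the
# shikimic-mass isomer whose fragments diverge from the standard.
.identifyHydroxybenzoic <- function(tree, tolerance = 0.5) {
  p <- precursorMz(tree)
  if (is.na(p)) return(NULL)
  ms2 <- .levelFragments(tree, 2L)
  if (abs(p - 187) <= tolerance && .hasIon(ms2, 169, tolerance)) {
    b2 <- .basePeak(ms2)
    if (!is.null(b2) && abs(b2$mz - 125) <= tolerance) {
      ev <- c("[M-H]- 18 Da above gallic acid (m/z 169)",
              "[M-H-H2O]- at m/z 169",
              "[M-H-H2O-CO2]- base peak at m/z 125")
      return(.annotation(peakId(tree), "gallic acid monohydrate",
                         "hydroxybenzoic_acid", "deduced", ev))
    }
  }
  if (abs(p - 173) <= tolerance) {
    b2 <- .basePeak(ms2)
    if (!is.null(b2) && abs(b2$mz - 131) <= tolerance) {
      ev <- c("[M-H]- matches shikimic acid (m/z 173)",
              "MS2 base peak 131 diverges from the shikimic acid standard")
      return(.annotation(peakId(tree), "shikimic acid isomer",
                         "hydroxybenzoic_acid", "tentative_isomer", ev,
                         notes = "UV and MS2 pattern inconsistent with authentic shikimic acid"))
    }
  }
  NULL
}

# Precursor-453 rule: base MS2 peak at 393 ([M-H-60]-, read as two
# 30 Da methoxy-pair units) names the prenylated dimethoxy
# hydroxycinnamate; the 60 Da reading is chemically loose but kept as
# the annotation convention for this mass.
.identifyPrenylCoumarate <- function(tree, tolerance = 0.5) {
  p <- precursorMz(tree)
  if (is.na(p) || abs(p - 453) > tolerance) return(NULL)
  ms2 <- .levelFragments(tree, 2L)
  b2 <- .basePeak(ms2)
  if (is.null(b2) || abs((p - b2$mz) - 60) > tolerance) return(NULL)
  ev <- c("loss of 60 Da (two 30 Da methoxy-pair units) to MS2 base m/z 393")
  ms3 <- .levelFragments(tree, 3L, parent = b2$node)
  if (.hasIon(ms3, b2$mz - 162, tolerance))
    ev <- c(ev, sprintf("caffeoyl loss (162 Da) to m/z %.0f", b2$mz - 162))
  if (.hasIon(ms3, 231, tolerance))
    ev <- c(ev, "prenylcoumaric acid marker m/z 231")
  .annotation(peakId(tree), "prenyl-dimethoxy-caffeoyl-p-coumaric acid",
              "hydroxycinnamic_acid", "deduced", ev,
              notes = "60 Da loss read as two methoxy units per the annotation convention; assignment chemically loose")
}

#' Annotate one spectral tree
#'
#' Applies the rule cascade in a fixed priority order — flavone
#' aglycones/glucosides, quinic acid esters, oleuropein derivatives,
#' hydroxybenzoic specials, the precursor-453 rule, hydroxy fatty
#' acids — and returns the first firing rule's annotation, or an
#' unknown. The order mirrors the reasoning priority of targeted
#' phenolic profiling: an aglycone match outranks generic loss
#' matching. The cascade is deterministic: identical trees always
#' yield identical annotations.
#'
#' @param tree a [SpectralTree-class].
#' @param rules neutral-loss rule table ([defaultLossRules()]).
#' @param tolerance m/z tolerance in Da (0.5 for unit-resolution data).
#' @return an [Annotation-class] (never NULL).
#' @examples
#' tr <- spectralTree("3", 447, c(250, 340), 11.17,
#'                    list(list(mz = 285, rel_intensity = 100)))
#' annotate(tr)
#' @export
annotate <- function(tree, rules = defaultLossRules(), tolerance = 0.5) {
  stopifnot(is(tree, "SpectralTree"))
  for (f in list(
    function(t) identifyFlavone(t, rules = rules, tolerance = tolerance),
    function(t) identifyQuinicEster(t, rules, tolerance),
    function(t) identifyOleuropeinDerivative(t, rules, tolerance),
    function(t) .identifyHydroxybenzoic(t, tolerance),
    function(t) .identifyPrenylCoumarate(t, tolerance),
    function(t) detectHydroxyFattyAcid(t, tolerance))) {
    ann <- f(tree)
    if (!is.null(ann)) return(ann)
  }
  .unknownAnnotation(peakId(tree))
}

#' Annotate a batch of spectral trees
#'
#' Runs [annotate()] over a list of trees and tabulates class counts.
#' "Phenolic" totals the hydroxybenzoic, hydroxycinnamic and flavonoid
#' classes; hydroxy fatty acids are tallied separately. Results are
#' independent of input order (up to row order of the table).
#'
#' @param trees list of [SpectralTree-class] objects with unique peak ids.
#' @inheritParams annotate
#' @return list with `annotations` (data.frame: peak_id, rt,
#'   precursor_mz, name, class, confidence, evidence, notes) and
#'   `counts` (named vector over classes plus `phenolic` and
#'   `phenolic_acid` totals).
#' @export
annotateBatch <- function(trees, rules = defaultLossRules(),
                          tolerance = 0.5) {
  ids <- vapply(trees, peakId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate peak id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  anns <- lapply(trees, annotate, rules = rules, tolerance = tolerance)
  tab <- data.frame(
    peak_id = ids,
    rt = vapply(trees, retentionTime, numeric(1)),
    precursor_mz = vapply(trees, precursorMz, numeric(1)),
    name = vapply(anns, compoundName, character(1)),
    class = vapply(anns, compoundClass, character(1)),
    confidence = vapply(anns, confidence, character(1)),
    evidence = vapply(anns, function(a) paste(evidence(a), collapse = "; "),
                      character(1)),
    notes = vapply(anns, function(a) paste(a@notes, collapse = "; "),
                   character(1)))
  counts <- vapply(.compoundClasses, function(cl) sum(tab$class == cl),
                   integer(1))
  counts["phenolic_acid"] <- counts[["hydroxybenzoic_acid"]] +
    counts[["hydroxycinnamic_acid"]]
  counts["phenolic"] <- counts[["phenolic_acid"]] + counts[["flavonoid"]]
  list(annotations = tab, counts = counts)
}
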
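#' @include spectral-tree.R
NULL

#' Default neutral-loss rule table
#'
#' Diagnostic neutral losses for negative-mode phenolic fragmentation
#' at unit (ion-trap) resolution: methyl (15 Da), water (18), carbon
#' dioxide (44), coumaroyl/deoxyhexosyl (146) and caffeoyl/hexosyl
#' (162). The 30 Da "methoxy-pair unit" is carried only for the
#' prenyl-dimethoxy ester rule, where two such units (60 Da) leave the
#' precursor; the assignment is chemically loose but kept as the
#' annotation convention for that compound. Tolerance defaults to
#' 0.5 Da everywhere, matching nominal-mass spectra.
#'
#' @param tolerance matching tolerance in Da applied to every rule.
#' @return data.frame with columns delta, moiety, tolerance.
#' @examples
#' defaultLossRules()
#' @export
defaultLossRules <- function(tolerance = 0.5) {
  stopifnot(tolerance >= 0)
  data.frame(
    delta = c(15, 18, 44, 146, 162, 30),
    moiety = c("methyl", "water", "carbon dioxide",
               "coumaroyl/deoxyhexosyl", "caffeoyl/hexosyl",
               "methoxy-pair unit"),
    tolerance = tolerance)
}

#' Match a neutral loss against a rule table
#'
#' Returns the moiety whose nominal loss is within tolerance of
#' `delta`; when several rules overlap, the nearest wins.
#'
#' @param delta observed neutral loss (Da).
#' @param rules rule table as from [defaultLossRules()].
#' @return the matched moiety name, or `NA_character_` when no rule is
#'   within tolerance.
#' @examples
#' matchLoss(146.0)   # coumaroyl/deoxyhexosyl
#' matchLoss(18.2)    # water
#' matchLoss(146.6, defaultLossRules(tolerance = 0.5))  # NA
#' @export
matchLoss <- function(delta, rules = defaultLossRules()) {
  stopifnot(is.data.frame(rules),
            all(c("delta", "moiety", "tolerance") %in% names(rules)))
  dist <- abs(rules$delta - delta)
  ok <- dist <= rules$tolerance
  if (!any(ok)) return(NA_character_)
  rules$moiety[ok][which.min(dist[ok])]
}

#' Flavone aglycone mass library
#'
#' Nominal [M-H]- masses of the flavone aglycones recognized by the
#' cascade. A 162 Da (hexosyl) loss onto one of these masses names the
#' corresponding O-glucoside.
#'
#' @return named numeric vector (names are aglycones, values [M-H]- m/z).
#' @export
flavoneAglycones <- function() {
  c(luteolin = 285, apigenin = 269, acacetin = 283,
    chrysoeriol = 299, tricin = 329)
}

#' Hydroxy fatty acid mass table
#'
#' Nominal [M-H]- masses of the oxygenated C18 fatty acids recognized
#' by their consecutive water losses in MS2. The m/z 293 entry keeps
#' the literature spelling "monohydroxy-octadecaditrienoic acid"
#' as printed in the source identification; the orthodox name would be
#' monohydroxy-octadecatrienoic acid (see the annotation's note).
#'
#' @return named character vector (names are nominal masses).
#' @export
hydroxyFattyAcidTable <- function() {
  c(`293` = "monohydroxy-octadecaditrienoic acid",
    `295` = "monohydroxy-octadecadienoic acid",
    `297` = "monohydroxy-octadecenoic acid",
    `309` = "dihydroxy-octadecatrienoic acid",
    `313` = "dihydroxy-octadecenoic acid")
}
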
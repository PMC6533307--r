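#' @include AllClasses.R
NULL

# Flatten nested fragment records ({mz, rel_intensity, children}) into
# the internal node/parent/level data.frame.
.flattenFragments <- function(fragments) {
  rows <- list()
  nid <- 0L
  walk <- function(frs, parent, level) {
    for (fr in frs) {
      nid <<- nid + 1L
      this <- nid
      rows[[this]] <<- data.frame(
        node = this, parent = parent, level = level,
        mz = as.numeric(fr$mz),
        rel_intensity = as.numeric(fr$rel_intensity))
      if (!is.null(fr$children) && length(fr$children))
        walk(fr$children, parent = this, level = level + 1L)
    }
  }
  walk(fragments, parent = 0L, level = 2L)
  if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(), parent = integer(), level = integer(),
               mz = numeric(), rel_intensity = numeric())
}

#' Create a spectral tree
#'
#' Builds a [SpectralTree-class] from either a nested fragment list
#' (each element `list(mz=, rel_intensity=, children=list(...))`, the
#' JSON schema used by [readSpectralTrees()]) or a pre-flattened
#' data.frame with columns node, parent, level, mz, rel_intensity.
#' Validity (fragments lighter than their parents, intensities in
#' (0, 100], one base peak per level, consecutive levels from MS2) is
#' enforced on construction.
#'
#' @param peakId peak identifier.
#' @param precursorMz deprotonated molecular ion m/z; NA allowed only
#'   when there are no fragments.
#' @param uvLambdaMax numeric vector of UV maxima (nm).
#' @param rtMin retention time in minutes.
#' @param fragments nested list or flat data.frame of fragments.
#' @return a [SpectralTree-class].
#' @examples
#' spectralTree("3", 447, c(250, 340), 11.17,
#'              list(list(mz = 285, rel_intensity = 100)))
#' @export
spectralTree <- function(peakId, precursorMz = NA_real_,
                         uvLambdaMax = numeric(), rtMin = NA_real_,
                         fragments = list()) {
  fr <- if (is.data.frame(fragments)) fragments else
    .flattenFragments(fragments)
  new("SpectralTree", peakId = as.character(peakId),
      precursorMz = as.numeric(precursorMz),
      uvLambdaMax = as.numeric(uvLambdaMax), rtMin = as.numeric(rtMin),
      fragments = fr)
}

#' Neutral losses of a spectral tree
#'
#' One row per precursor-to-fragment or fragment-to-fragment edge, with
#' the mass difference (neutral loss) of the transition. Losses are
#' strictly positive by the tree's validity.
#'
#' @param tree a [SpectralTree-class].
#' @return data.frame with columns parent_mz, child_mz, delta, level
#'   (the child's MS stage); zero rows for fragment-free trees.
#' @examples
#' tr <- spectralTree("x", 499, numeric(), 1,
#'   list(list(mz = 353, rel_intensity = 100,
#'             children = list(list(mz = 191, rel_intensity = 100)))))
#' neutralLosses(tr)
#' @export
neutralLosses <- function(tree) {
  stopifnot(is(tree, "SpectralTree"))
  fr <- fragments(tree)
  if (nrow(fr) == 0)
    return(data.frame(parent_mz = numeric(), child_mz = numeric(),
                      delta = numeric(), level = integer()))
  parent_mz <- ifelse(fr$parent == 0, precursorMz(tree),
                      fr$mz[match(fr$parent, fr$node)])
  if (any(fr$mz >= parent_mz))
    stop("malformed tree: fragment m/z not below parent m/z")
  data.frame(parent_mz = parent_mz, child_mz = fr$mz,
             delta = parent_mz - fr$mz, level = fr$level)
}

# Fragments at a given level, optionally restricted to children of one
# parent node; base peak helpers used by the rule cascade.
.levelFragments <- function(tree, level, parent = NULL) {
  fr <- fragments(tree)
  fr <- fr[fr$level == level, , drop = FALSE]
  if (!is.null(parent)) fr <- fr[fr$parent == parent, , drop = FALSE]
  fr
}

.basePeak <- function(fr) {
  if (nrow(fr) == 0) return(NULL)
  fr[which.max(fr$rel_intensity), , drop = FALSE]
}

# Is any fragment in `fr` within `tol` of mass `mz`?
.hasIon <- function(fr, mz, tol = 0.5, min_intensity = 0) {
  any(abs(fr$mz - mz) <= tol & fr$rel_intensity >= min_intensity)
}
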
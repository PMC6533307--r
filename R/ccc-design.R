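#' @include AllClasses.R
NULL

#' Coded/uncoded factor transforms
#'
#' Coded units rescale a factor as `(x - center) / step`, so the
#' factorial levels sit at +/-1 and the design center at 0.
#' `uncodeValue()` is the exact inverse.
#'
#' @param x uncoded factor value(s).
#' @param z coded factor value(s).
#' @param f a [FactorSpec-class].
#' @return numeric vector of transformed values.
#' @examples
#' f <- factorSpec("time", 30, 10, "min")
#' codeValue(20, f)        # -1
#' uncodeValue(1.68, f)    # 46.8
#' @export
codeValue <- function(x, f) {
  stopifnot(is(f, "FactorSpec"))
  (x - f@center) / f@step
}

#' @rdname codeValue
#' @export
uncodeValue <- function(z, f) {
  stopifnot(is(f, "FactorSpec"))
  f@center + f@step * z
}

#' Build a central composite circumscribed design
#'
#' Assembles the 2^k factorial block (standard order, first factor
#' varying fastest), 2k axial points at -alpha/+alpha on each axis in
#' turn, and `nCenter` replicated center runs. For three factors with
#' six center points this is the classical 20-run CCC layout. Uncoded
#' settings are computed exactly from each factor's center/step; any
#' rounding is left to display.
#'
#' @param factors list of [FactorSpec-class] objects (one per factor).
#' @param alpha axial distance in coded units; must exceed 1 so the star
#'   points fall outside the factorial cube.
#' @param nCenter number of center replicates (>= 1).
#' @return a [CCCDesign-class] with all responses NA.
#' @examples
#' fs <- list(factorSpec("time", 30, 10, "min"),
#'            factorSpec("ratio", 20, 10, "mL/g"),
#'            factorSpec("temperature", 50, 10, "degC"))
#' buildCCCDesign(fs, alpha = 1.68, nCenter = 6)
#' @export
buildCCCDesign <- function(factors, alpha = 1.68, nCenter = 6) {
  if (!is.list(factors) || !all(vapply(factors, is, logical(1), "FactorSpec")))
    stop("invalid factor specification: 'factors' must be a list of FactorSpec")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 1)
    stop("invalid factor specification: 'alpha' must be a single number > 1")
  nCenter <- as.integer(nCenter)
  if (is.na(nCenter) || nCenter < 0L)
    stop("'nCenter' must be a non-negative integer")
  k <- length(factors)
  fac <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2L * k, k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -alpha
    axial[2L * j, j] <- alpha
  }
  ctr <- matrix(0, nCenter, k)
  coded <- rbind(fac, axial, ctr)
  dimnames(coded) <- list(NULL, vapply(factors, function(f) f@name,
                                       character(1)))
  uncoded <- coded
  for (j in seq_len(k)) uncoded[, j] <- uncodeValue(coded[, j], factors[[j]])
  new("CCCDesign", factors = factors, alpha = alpha, coded = coded,
      uncoded = uncoded,
      role = c(rep("factorial", nrow(fac)), rep("axial", 2L * k),
               rep("center", nCenter)),
      response = rep(NA_real_, nrow(coded)))
}

#' Construct a design from explicit settings
#'
#' Low-level constructor used by the readers and generators when the
#' run layout comes from a file rather than [buildCCCDesign()].
#'
#' @param factors list of [FactorSpec-class].
#' @param coded numeric matrix of coded settings.
#' @param role character vector of run roles.
#' @param response numeric responses (NA allowed).
#' @param alpha axial distance; defaults to the largest coded magnitude.
#' @return a [CCCDesign-class].
#' @export
cccDesign <- function(factors, coded, role, response = NA_real_,
                      alpha = max(abs(coded))) {
  coded <- as.matrix(coded)
  dimnames(coded) <- list(NULL, vapply(factors, function(f) f@name,
                                       character(1)))
  uncoded <- coded
  for (j in seq_along(factors))
    uncoded[, j] <- uncodeValue(coded[, j], factors[[j]])
  new("CCCDesign", factors = factors, alpha = alpha, coded = coded,
      uncoded = uncoded, role = role,
      response = rep_len(as.numeric(response), nrow(coded)))
}

#' Design table as a data.frame
#'
#' @param design a [CCCDesign-class].
#' @return data.frame with run order, role, coded and uncoded settings
#'   and the response column.
#' @export
designTable <- function(design) {
  stopifnot(is(design, "CCCDesign"))
  cd <- codedValues(design)
  uc <- uncodedValues(design)
  colnames(uc) <- paste0(colnames(uc), "_uncoded")
  colnames(cd) <- paste0(colnames(cd), "_coded")
  data.frame(run = seq_len(nrow(cd)), role = designRoles(design), cd, uc,
             response = responses(design), check.names = FALSE)
}
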
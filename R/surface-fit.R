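#' @include ccc-design.R
NULL

# Full quadratic basis on coded settings: 1, x_j, x_j^2, x_i x_j (i < j).
# Column order fixed so coefficient vectors are comparable across fits.
.quadraticBasis <- function(coded) {
  coded <- as.matrix(coded)
  k <- ncol(coded)
  nm <- colnames(coded)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  cols <- list(`(Intercept)` = rep(1, nrow(coded)))
  for (j in seq_len(k)) cols[[nm[j]]] <- coded[, j]
  for (j in seq_len(k)) cols[[paste0(nm[j], "^2")]] <- coded[, j]^2
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k))
      cols[[paste0(nm[i], ":", nm[j])]] <- coded[, i] * coded[, j]
  do.call(cbind, cols)
}

#' Fit the full second-order model to a CCC design
#'
#' Ordinary least squares of the observed responses on the full
#' quadratic basis in the *coded* factors: intercept, linear, pure
#' quadratic and two-way interaction terms (10 coefficients for three
#' factors). Fitting on coded variables keeps the design matrix well
#' conditioned and makes coefficients directly comparable across
#' factors; uncoded values are for display only.
#'
#' @param design a [CCCDesign-class] with all responses observed.
#' @return a [QuadraticSurfaceModel-class] carrying coefficients and the
#'   overall fit statistics (R^2, F, p, degrees of freedom).
#' @examples
#' d <- exampleDesign()
#' m <- fitQuadratic(d)
#' rSquared(m)
#' @export
fitQuadratic <- function(design) {
  stopifnot(is(design, "CCCDesign"))
  y <- responses(design)
  if (anyNA(y))
    stop("incomplete design: ", sum(is.na(y)), " run(s) lack responses")
  X <- .quadraticBasis(codedValues(design))
  p <- ncol(X)
  if (nrow(X) < p)
    stop("incomplete design: need at least ", p,
         " runs to fit the full quadratic")
  if (qr(X)$rank < p)
    stop("singular design: quadratic design matrix is rank deficient")
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  df_model <- p - 1L
  df_res <- length(y) - p
  r2 <- 1 - sse / sst
  fstat <- ((sst - sse) / df_model) / (sse / df_res)
  pval <- stats::pf(fstat, df_model, df_res, lower.tail = FALSE)
  new("QuadraticSurfaceModel", coefficients = fit$coefficients,
      factors = factorSpecs(design), rSquared = r2, fStatistic = fstat,
      pValue = pval, dfModel = as.integer(df_model),
      dfResidual = as.integer(df_res), sigma = sqrt(sse / max(df_res, 1L)))
}

#' Evaluate a fitted surface at coded points
#'
#' @param object a [QuadraticSurfaceModel-class].
#' @param coded numeric vector (one point) or matrix (one point per row)
#'   of coded factor settings.
#' @param ... ignored.
#' @return numeric vector of predicted responses.
#' @export
setMethod("predict", "QuadraticSurfaceModel", function(object, coded, ...) {
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1L)
  coded <- as.matrix(coded)
  stopifnot(ncol(coded) == length(object@factors))
  colnames(coded) <- vapply(object@factors, function(f) f@name, character(1))
  as.vector(.quadraticBasis(coded) %*% object@coefficients)
})

#' ANOVA decomposition with lack of fit
#'
#' Partitions the total sum of squares into model and residual terms,
#' and — when the design carries replicated center points — further
#' splits the residual into pure error (center-replicate scatter) and
#' lack of fit. Each line carries its mean square, F statistic against
#' the appropriate error term and p-value.
#'
#' Without center replicates the pure-error split is unavailable; the
#' returned table then omits those rows and the `lack_of_fit_available`
#' attribute is set to FALSE (no error is raised).
#'
#' @param model a [QuadraticSurfaceModel-class] fitted to `design`.
#' @param design the [CCCDesign-class] the model was fitted to.
#' @return data.frame with columns source, df, ss, ms, f, p and
#'   attribute `lack_of_fit_available`.
#' @examples
#' d <- exampleDesign()
#' anovaTable(fitQuadratic(d), d)
#' @export
anovaTable <- function(model, design) {
  stopifnot(is(model, "QuadraticSurfaceModel"), is(design, "CCCDesign"))
  y <- responses(design)
  fitted <- predict(model, codedValues(design))
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted)^2)
  ssr <- sst - sse
  df_model <- model@dfModel
  df_res <- model@dfResidual
  ms_model <- ssr / df_model
  ms_res <- sse / df_res
  f_model <- ms_model / ms_res
  p_model <- stats::pf(f_model, df_model, df_res, lower.tail = FALSE)
  out <- data.frame(
    source = c("model", "residual"),
    df = c(df_model, df_res),
    ss = c(ssr, sse),
    ms = c(ms_model, ms_res),
    f = c(f_model, NA),
    p = c(p_model, NA))
  yc <- y[designRoles(design) == "center"]
  lof_ok <- length(yc) >= 2L
  if (lof_ok) {
    ss_pe <- sum((yc - mean(yc))^2)
    df_pe <- length(yc) - 1L
    ss_lof <- sse - ss_pe
    df_lof <- df_res - df_pe
    f_lof <- if (df_lof > 0 && ss_pe > 0)
      (ss_lof / df_lof) / (ss_pe / df_pe) else NA_real_
    p_lof <- if (is.finite(f_lof))
      stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE) else NA_real_
    out <- rbind(out,
      data.frame(source = c("lack_of_fit", "pure_error"),
                 df = c(df_lof, df_pe), ss = c(ss_lof, ss_pe),
                 ms = c(if (df_lof > 0) ss_lof / df_lof else NA,
                        ss_pe / df_pe),
                 f = c(f_lof, NA), p = c(p_lof, NA)))
  }
  out <- rbind(out,
    data.frame(source = "total", df = length(y) - 1L, ss = sst,
               ms = NA, f = NA, p = NA))
  attr(out, "lack_of_fit_available") <- lof_ok
  out
}
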
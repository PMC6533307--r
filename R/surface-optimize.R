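#' @include surface-fit.R
NULL

#' Maximize a fitted surface over a coded box
#'
#' Deterministic constrained maximization of the fitted quadratic over
#' a finite box in coded space: a dense grid scan (default resolution
#' 0.01 coded units) locates the basin, then a box-constrained
#' quasi-Newton polish (`L-BFGS-B`) refines the maximizer. Grid ties
#' (within 1e-10 of the maximum) are broken toward the
#' lexicographically smallest coded point, so the result is
#' reproducible bit for bit. The default region is the factorial cube
#' [-1, 1]^k; pass the axial cube via `region` to search the full
#' design envelope.
#'
#' @param model a [QuadraticSurfaceModel-class].
#' @param region 2 x k matrix (rows: lower, upper) or a length-2 vector
#'   recycled to all factors; bounds must be finite.
#' @param resolution grid spacing in coded units (<= 0.05 recommended).
#' @param factors optional list of [FactorSpec-class] for the uncoded
#'   report; defaults to the factors carried by the model.
#' @return an [OptimizationResult-class].
#' @examples
#' m <- fitQuadratic(exampleDesign())
#' optimizeSurface(m)
#' @export
optimizeSurface <- function(model, region = c(-1, 1), resolution = 0.01,
                            factors = NULL) {
  stopifnot(is(model, "QuadraticSurfaceModel"))
  k <- length(model@factors)
  if (is.null(dim(region))) {
    if (length(region) != 2L)
      stop("invalid region: give c(lower, upper) or a 2 x k matrix")
    region <- matrix(rep(region, k), nrow = 2L)
  }
  region <- as.matrix(region)
  if (!identical(dim(region), c(2L, as.integer(k))) ||
      any(!is.finite(region)) || any(region[1, ] >= region[2, ]))
    stop("invalid region: bounds must be a finite 2 x k box with lower < upper")
  if (!is.numeric(resolution) || resolution <= 0)
    stop("'resolution' must be a positive number")

  axes <- lapply(seq_len(k), function(j)
    unique(c(seq(region[1, j], region[2, j], by = resolution), region[2, j])))
  # Scan in chunks over the first axis; within a chunk rows are ordered
  # lexicographically in the remaining axes so tie-breaks are stable.
  tailgrid <- as.matrix(rev(expand.grid(rev(axes[-1]))))
  best_val <- -Inf
  best_pt <- NULL
  for (v1 in axes[[1]]) {
    chunk <- cbind(v1, tailgrid)
    vals <- predict(model, chunk)
    mx <- max(vals)
    if (mx > best_val + 1e-10) {
      best_val <- mx
      best_pt <- chunk[which(vals >= mx - 1e-10)[1], ]
    }
  }
  polish <- stats::optim(best_pt, function(p) -predict(model, p),
                         method = "L-BFGS-B",
                         lower = region[1, ], upper = region[2, ])
  opt <- best_pt
  val <- best_val
  if (-polish$value > best_val + 1e-12) {
    opt <- pmin(pmax(polish$par, region[1, ]), region[2, ])
    val <- predict(model, opt)
  }
  if (is.null(factors)) factors <- model@factors
  uncoded <- vapply(seq_len(k), function(j) uncodeValue(opt[j], factors[[j]]),
                    numeric(1))
  names(opt) <- names(uncoded) <- vapply(factors, function(f) f@name,
                                         character(1))
  new("OptimizationResult", codedOpt = opt, uncodedOpt = uncoded,
      predictedResponse = as.numeric(val), region = region)
}
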
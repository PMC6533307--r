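#' @include io.R
NULL

.md5Of <- function(object) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(object, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Run the full profiling pipeline
#'
#' Executes the configured stages in order — response-surface
#' optimization, spectral annotation, quantification — each only when
#' its inputs are configured. The stages are independent: any subset
#' may run. Outputs are written under `outDir` when given (fit summary
#' and optimum as JSON, annotations as TSV, quantification report as
#' JSON + TSV), and the full report is returned invisibly. Reports
#' embed the neutral-loss rule table and an MD5 hash of the effective
#' configuration for provenance; given the same configuration and
#' seed, reports are byte-identical.
#'
#' Config elements (all optional, but at least one stage must be
#' configured):
#' \describe{
#'   \item{design}{path to a CCC design/response table
#'     ([readDesign()]).}
#'   \item{spectra}{path to a spectral-tree JSON
#'     ([readSpectralTrees()]).}
#'   \item{contents}{path to a per-compound content table with columns
#'     peak, compound, class, content_mg_g (aggregation only).}
#'   \item{peaks, calibration}{paths to a peak table and calibration
#'     point table for full quantification (with `quant$map`,
#'     `quant$is` describing the RRF setup).}
#'   \item{rsm}{list: `region` (c(lower, upper), default c(-1, 1)),
#'     `resolution` (default 0.01).}
#'   \item{annotator}{list: `tolerance` (default 0.5).}
#'   \item{quant}{list: `extract_volume` (mL, default 15), `dry_mass`
#'     (g, default 0.5), `dilution` (default 1).}
#'   \item{seed}{integer seed recorded in the provenance block.}
#' }
#'
#' @param config a named list, or path to a JSON file holding one.
#' @param outDir optional output directory (created if missing).
#' @return the report list, invisibly.
#' @examples
#' cfg <- list(design = system.file("extdata", "ccc_design_tp.csv",
#'                                  package = "phenolProfiler"))
#' rep <- runPipeline(cfg)
#' rep$rsm$optimum
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  if (!is.list(config) || length(config) == 0)
    stop("usage: runPipeline(config) needs a non-empty configuration ",
         "(see ?runPipeline)")
  stages <- intersect(c("design", "spectra", "contents", "peaks"),
                      names(config))
  if (length(stages) == 0)
    stop("usage: configure at least one stage input ",
         "(design, spectra, contents or peaks)")
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  tol <- config$annotator$tolerance %||% 0.5
  rules <- defaultLossRules(tol)
  report <- list(provenance = list(
    package = "phenolProfiler",
    version = as.character(utils::packageVersion("phenolProfiler")),
    seed = config$seed,
    config_md5 = .md5Of(config),
    rules_md5 = .md5Of(rules),
    rules = rules))

  if ("design" %in% stages) {
    design <- readDesign(config$design)
    model <- fitQuadratic(design)
    anova <- anovaTable(model, design)
    region <- config$rsm$region %||% c(-1, 1)
    opt <- optimizeSurface(model, region = region,
                           resolution = config$rsm$resolution %||% 0.01)
    report$rsm <- list(
      coefficients = as.list(coef(model)),
      r_squared = rSquared(model),
      f_statistic = model@fStatistic, p_value = model@pValue,
      anova = anova,
      optimum = list(coded = as.list(opt@codedOpt),
                     uncoded = as.list(opt@uncodedOpt),
                     predicted_response = opt@predictedResponse))
    if (!is.null(outDir))
      jsonlite::write_json(report$rsm, file.path(outDir, "rsm_fit.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
  }

  if ("spectra" %in% stages) {
    trees <- readSpectralTrees(config$spectra)
    batch <- annotateBatch(trees, rules = rules, tolerance = tol)
    report$annotation <- batch
    if (!is.null(outDir))
      writeAnnotations(batch, file.path(outDir, "annotations.tsv"))
  }

  quant_cfg <- config$quant %||% list()
  if ("contents" %in% stages) {
    tab <- .readDelim(config$contents)
    recs <- data.frame(compound = tab$compound, class = tab$class,
                       content = tab$content_mg_g)
    report$quant <- c(list(records = recs), aggregateByClass(recs))
  } else if ("peaks" %in% stages) {
    peaks <- readPeaks(config$peaks)
    pts <- .readDelim(config$calibration)
    curves <- lapply(split(pts, pts$analyte), function(d)
      fitCalibration(d$conc, d$area, d$analyte[1],
                     d$wavelength[1] %||% NA_real_))
    names(curves) <- tolower(names(curves))
    map <- .readDelim(quant_cfg$map)
    is_tab <- .readDelim(quant_cfg$is)
    isSpecs <- lapply(seq_len(nrow(is_tab)), function(i)
      internalStandard(is_tab$name[i], is_tab$concentration[i],
                       is_tab$area[i]))
    names(isSpecs) <- tolower(is_tab$name)
    recs <- quantifyBatch(peaks, map, curves, isSpecs,
                          extractVolume = quant_cfg$extract_volume %||% 15,
                          dryMass = quant_cfg$dry_mass %||% 0.5,
                          dilution = quant_cfg$dilution %||% 1)
    report$quant <- c(list(records = recs), aggregateByClass(recs))
  }
  if (!is.null(report$quant) && !is.null(outDir))
    writeQuantReport(report$quant$records,
                     file.path(outDir, "quant_report.json"),
                     file.path(outDir, "quant_report.tsv"),
                     extra = list(provenance = report$provenance[
                       c("version", "config_md5", "rules_md5")]))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
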
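#' @include synthgen.R
NULL

# Delimited text with a header row; comma or tab, sniffed from the
# header line. Decimal point only.
.readDelim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read and write CCC design tables
#'
#' Delimited text (comma or tab, header required) with columns `run`,
#' `role`, one `<factor>_coded` and `<factor>_uncoded` pair per factor,
#' and `response`. When `factors` is not supplied, each factor's
#' center and step are recovered from the exact linear relation
#' between its coded and uncoded columns.
#'
#' @param path file path.
#' @param factors optional list of [FactorSpec-class]; inferred from
#'   the file when NULL.
#' @return [readDesign()]: a [CCCDesign-class]. [writeDesign()]: the
#'   path, invisibly.
#' @export
readDesign <- function(path, factors = NULL) {
  tab <- .readDelim(path)
  coded_cols <- grep("_coded$", names(tab), value = TRUE)
  if (length(coded_cols) == 0)
    stop("parse error in ", path, ": no '<factor>_coded' columns found")
  fnames <- sub("_coded$", "", coded_cols)
  need <- c("role", paste0(fnames, "_uncoded"), "response")
  if (!all(need %in% names(tab)))
    stop("parse error in ", path, ": missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  coded <- as.matrix(tab[, coded_cols, drop = FALSE])
  if (is.null(factors)) {
    factors <- lapply(seq_along(fnames), function(j) {
      cf <- stats::coef(stats::lm(tab[[paste0(fnames[j], "_uncoded")]] ~
                                    coded[, j]))
      factorSpec(fnames[j], center = unname(cf[1]), step = unname(cf[2]))
    })
  }
  cccDesign(factors, coded, role = tab$role, response = tab$response)
}

#' @rdname readDesign
#' @param design a [CCCDesign-class].
#' @param sep field separator ("," or "\t").
#' @export
writeDesign <- function(design, path, sep = ",") {
  utils::write.table(designTable(design), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fragment data.frame -> nested list of {mz, rel_intensity, children}
.nestFragments <- function(fr, parent = 0L) {
  rows <- which(fr$parent == parent)
  lapply(rows, function(i) {
    list(mz = fr$mz[i], rel_intensity = fr$rel_intensity[i],
         children = .nestFragments(fr, fr$node[i]))
  })
}

#' Read and write spectral trees (JSON)
#'
#' The JSON schema is a top-level object with a `trees` array (a bare
#' array is also accepted); each tree has `peak_id`, `precursor_mz`
#' (null for peaks without MS data), `uv_lambda_max`, `rt_min` and a
#' nested `fragments` array of `{mz, rel_intensity, children}`
#' records. All tree invariants are enforced on read; violations
#' report the offending peak.
#'
#' @param path file path.
#' @return [readSpectralTrees()]: list of [SpectralTree-class].
#' @export
readSpectralTrees <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  recs <- if (!is.null(doc$trees)) doc$trees else doc
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    id <- if (!is.null(r$peak_id)) as.character(r$peak_id) else
      as.character(i)
    tryCatch(
      spectralTree(id,
                   precursorMz = if (is.null(r$precursor_mz)) NA_real_
                                 else r$precursor_mz,
                   uvLambdaMax = as.numeric(unlist(r$uv_lambda_max)),
                   rtMin = if (is.null(r$rt_min)) NA_real_ else r$rt_min,
                   fragments = if (is.null(r$fragments)) list()
                               else r$fragments),
      error = function(e)
        stop("parse error in ", path, ", peak '", id, "': ",
             conditionMessage(e), call. = FALSE))
  })
}

#' @rdname readSpectralTrees
#' @param trees list of [SpectralTree-class].
#' @export
writeSpectralTrees <- function(trees, path) {
  recs <- lapply(trees, function(tr) {
    list(peak_id = peakId(tr),
         precursor_mz = if (is.na(precursorMz(tr))) NULL else
           precursorMz(tr),
         uv_lambda_max = as.list(uvLambdaMax(tr)),
         rt_min = retentionTime(tr),
         fragments = .nestFragments(fragments(tr)))
  })
  jsonlite::write_json(list(trees = recs), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read flat MS2 spectra from an MGF file
#'
#' Minimal Mascot Generic Format reader: each BEGIN IONS/END IONS block
#' becomes a single-level [SpectralTree-class] with the PEPMASS m/z as
#' the precursor (read as the [M-H]- ion for negative-mode data) and
#' the peak list as MS2 fragments scaled to percent of the base peak.
#' Peaks at or above the precursor m/z are dropped with a warning.
#'
#' @param path MGF file path.
#' @return list of [SpectralTree-class].
#' @export
readMgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  trees <- list()
  i <- 1L
  n <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      n <- n + 1L
      title <- paste0("mgf_", n)
      pep <- NA_real_
      rt <- NA_real_
      mz <- numeric()
      int <- numeric()
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (grepl("^TITLE=", ln)) title <- sub("^TITLE=", "", ln)
        else if (grepl("^PEPMASS=", ln))
          pep <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]")[[1]][1])
        else if (grepl("^RTINSECONDS=", ln))
          rt <- as.numeric(sub("^RTINSECONDS=", "", ln)) / 60
        else if (grepl("^[0-9]", ln)) {
          xy <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
          mz <- c(mz, xy[1])
          int <- c(int, xy[2])
        }
        i <- i + 1L
      }
      if (is.na(pep))
        stop("parse error in ", path, ", spectrum '", title,
             "': missing PEPMASS")
      keep <- mz < pep
      if (any(!keep)) {
        warning("spectrum '", title, "': dropped ", sum(!keep),
                " peak(s) at or above the precursor m/z")
        mz <- mz[keep]
        int <- int[keep]
      }
      fr <- if (length(mz))
        data.frame(node = seq_along(mz), parent = 0L, level = 2L, mz = mz,
                   rel_intensity = int / max(int) * 100)
      else
        data.frame(node = integer(), parent = integer(), level = integer(),
                   mz = numeric(), rel_intensity = numeric())
      trees[[length(trees) + 1L]] <-
        spectralTree(title, precursorMz = pep, rtMin = rt, fragments = fr)
    }
    i <- i + 1L
  }
  trees
}

#' Write an annotation table as TSV
#'
#' @param batch result of [annotateBatch()] (or its `annotations`
#'   data.frame).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeAnnotations <- function(batch, path) {
  tab <- if (is.data.frame(batch)) batch else batch$annotations
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak table
#'
#' Delimited text with columns `compound`, `area` and optionally
#' `wavelength`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPeaks <- function(path) {
  tab <- .readDelim(path)
  if (!all(c("compound", "area") %in% names(tab)))
    stop("parse error in ", path, ": need columns 'compound' and 'area'")
  tab
}

#' Write a quantification report
#'
#' JSON report (per-compound records, class totals, provenance) with a
#' TSV mirror of the per-compound table.
#'
#' @param records data.frame of quantification records (see
#'   [quantifyBatch()]).
#' @param jsonPath output JSON path.
#' @param tsvPath optional output TSV path.
#' @param extra named list merged into the JSON report (e.g.
#'   provenance).
#' @return the aggregate list from [aggregateByClass()], invisibly.
#' @export
writeQuantReport <- function(records, jsonPath, tsvPath = NULL,
                             extra = list()) {
  agg <- aggregateByClass(records)
  report <- c(list(records = records,
                   class_totals = as.list(agg$class_totals),
                   phenolic_acid_total = agg$phenolic_acid,
                   phenolic_total = agg$total,
                   top_compound = agg$top_compound,
                   top_content = agg$top_content), extra)
  jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(tsvPath))
    utils::write.table(records, tsvPath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(agg)
}

# ---- packaged example data --------------------------------------------

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "phenolProfiler")
  if (p == "") stop("packaged data file not found: ", file)
  p
}

#' Packaged example data
#'
#' Transcriptions of the ultrasound-assisted extraction study of
#' *Dendranthema indicum* var. *aromaticum* flower that the package's
#' defaults are calibrated on: the 20-run CCC design with observed
#' total-phenolic yields, the 23 HPLC-PDA-ESI-MSn spectral trees, the
#' five external-standard calibration curves with validation
#' statistics, and the per-compound dry-weight contents.
#'
#' @return `exampleDesign()`: a [CCCDesign-class];
#'   `exampleSpectralTrees()`: list of [SpectralTree-class];
#'   `exampleCalibrationCurves()`: named list of
#'   [CalibrationCurve-class] plus a `validation` attribute
#'   (data.frame of recovery/RSD statistics);
#'   `exampleContents()`: data.frame of contents (mg/g DW).
#' @examples
#' exampleDesign()
#' @export
exampleDesign <- function() {
  readDesign(.extdata("ccc_design_tp.csv"))
}

#' @rdname exampleDesign
#' @export
exampleSpectralTrees <- function() {
  readSpectralTrees(.extdata("spectral_trees.json"))
}

#' @rdname exampleDesign
#' @export
exampleCalibrationCurves <- function() {
  tab <- .readDelim(.extdata("calibration_curves.csv"))
  curves <- lapply(seq_len(nrow(tab)), function(i)
    calibrationCurve(tab$analyte[i], tab$slope[i], tab$intercept[i],
                     wavelength = tab$wavelength_nm[i],
                     rSquared = tab$r_squared[i], lod = tab$lod_ugml[i],
                     loq = tab$loq_ugml[i]))
  names(curves) <- tolower(tab$analyte)
  attr(curves, "validation") <-
    tab[, c("analyte", "recovery_pct", "recovery_sd", "rsd_intraday_pct",
            "rsd_interday_pct")]
  curves
}

#' @rdname exampleDesign
#' @export
exampleContents <- function() {
  tab <- .readDelim(.extdata("phenolic_contents.csv"))
  data.frame(peak_id = as.character(tab$peak), compound = tab$compound,
             class = tab$class, area_pct = tab$area_pct,
             content = tab$content_mg_g, content_sd = tab$content_sd)
}
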
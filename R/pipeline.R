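# Whole-study orchestration: per-subscale, per-contrast DIF analysis with
# the full listwise -> collapse -> calibrate -> thresholds -> purify ->
# impact chain, plus dimensionality reports and structured logging.

#' Define an analysis plan
#'
#' @param contrasts list of contrasts, each a list with \code{name},
#'   \code{variable} (column of the covariate table holding the group
#'   labels) and optional \code{levels} (subset of labels to compare).
#'   Default: a between-group contrast on \code{"group"} and a gender
#'   contrast on \code{"gender"}.
#' @param subscales character vector of subscale names to analyse
#'   (default: all in the scale definition).
#' @param cfg a \code{\link{difConfig}} applied to every cell.
#' @param outDir output directory (NULL = no files written).
#' @param seed master seed; per-cell seeds are derived deterministically
#'   from it and the contrast/subscale names, so cells are independent
#'   and removing one never changes another's results.
#' @param salienceCutoff impact salience cutoff (default 0.20).
#' @param minCell sparse-category collapsing threshold (default 5).
#' @param includeDimensionality run the per-subscale dimensionality
#'   report (default TRUE).
#' @export
analysisPlan <- function(contrasts = NULL, subscales = NULL,
                         cfg = difConfig(), outDir = NULL, seed = 1L,
                         salienceCutoff = 0.20, minCell = 5L,
                         includeDimensionality = TRUE) {
  contrasts <- contrasts %||% list(
    list(name = "between_groups", variable = "group"),
    list(name = "gender", variable = "gender"))
  for (ct in contrasts)
    if (is.null(ct$name) || is.null(ct$variable))
      stop("each contrast needs a 'name' and a 'variable'")
  structure(list(contrasts = contrasts, subscales = subscales, cfg = cfg,
                 outDir = outDir, seed = as.integer(seed),
                 salienceCutoff = salienceCutoff,
                 minCell = as.integer(minCell),
                 includeDimensionality = includeDimensionality),
            class = "AnalysisPlan")
}

# deterministic 31-bit seed from the master seed and a cell label
deriveCellSeed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 1073741789
  as.integer((seed + h) %% 2147483647L + 1L)
}

#' Run the full DIF study workflow
#'
#' For every contrast-by-subscale cell: reverse-code, listwise-subset on
#' the subscale's items and the contrast's group labels, collapse sparse
#' categories, calibrate, simulate Monte-Carlo thresholds, run the
#' purification loop, and — when items are flagged — recalibrate
#' group-specifically and summarise the individual-level impact (skipped
#' with a note otherwise). Failures in one cell are recorded and the
#' remaining cells continue.
#'
#' @param plan an \code{\link{analysisPlan}}
#' @param responses \code{\linkS4class{ResponseMatrix}} on the
#'   instrument scale (reverse items unrecoded).
#' @param covariates data.frame aligned with the persons of
#'   \code{responses}, holding every column the contrasts reference
#'   (e.g. \code{group}, \code{gender}).
#' @param scale a \code{\linkS4class{ScaleDefinition}}.
#' @return list of class \code{AnalysisBundle}: per-cell results
#'   (\code{dif}, \code{impact}, \code{collapseReport}, \code{error}),
#'   per-subscale \code{dimensionality} reports, and a \code{log}
#'   data.frame; written to \code{plan$outDir} when set.
#' @export
runAnalysis <- function(plan, responses, covariates,
                        scale = hivStigmaScale32()) {
  stopifnot(is(responses, "ResponseMatrix"),
            nrow(covariates) == nPersons(responses))
  for (ct in plan$contrasts)
    if (!ct$variable %in% names(covariates))
      stop("contrast '", ct$name, "' references missing column '",
           ct$variable, "'")
  subs <- plan$subscales %||% names(subscales(scale))
  bad <- setdiff(subs, names(subscales(scale)))
  if (length(bad)) stop("unknown subscale(s): ", paste(bad, collapse = ", "))

  recoded <- applyReverseCoding(responses, scale)
  out <- list(cells = list(), dimensionality = list())
  logRows <- list()
  addLog <- function(...) logRows[[length(logRows) + 1L]] <<-
    data.frame(..., stringsAsFactors = FALSE)

  if (!is.null(plan$outDir))
    dir.create(plan$outDir, recursive = TRUE, showWarnings = FALSE)

  for (ct in plan$contrasts) {
    for (sb in subs) {
      cellName <- paste(ct$name, sb, sep = ".")
      items <- subscales(scale)[[sb]]
      g <- covariates[[ct$variable]]
      if (!is.null(ct$levels)) g[!g %in% ct$levels] <- NA
      cell <- tryCatch({
        ls <- listwiseSubset(recoded, g, items)
        cc <- collapseSparseCategories(ls$responses, ls$groups,
                                       minCell = plan$minCell)
        cfg <- plan$cfg
        cfg$seed <- deriveCellSeed(plan$seed, cellName)
        dif <- runDIFPurification(cc$responses, ls$groups, cfg)
        impact <- NULL
        if (length(flaggedItems(dif))) {
          initial <- eapScores(fitGRM(cc$responses), cc$responses)
          purified <- purifiedCalibration(cc$responses, ls$groups,
                                          flaggedItems(dif))
          impact <- cumulativeImpact(initial, purified, ls$groups,
                                     cutoff = plan$salienceCutoff)
        }
        addLog(cell = cellName, stage = "dif", n = nPersons(cc$responses),
               flagged = paste(flaggedItems(dif), collapse = ","),
               threshold = thresholds(dif)$threshold,
               iterations = dif@nIterations, converged = isConverged(dif),
               note = if (is.null(impact))
                 "no items flagged; impact analysis skipped" else "")
        list(dif = dif, impact = impact, collapseReport = cc$report,
             error = NULL)
      }, error = function(e) {
        addLog(cell = cellName, stage = "error", n = NA_integer_,
               flagged = "", threshold = NA_real_, iterations = NA_integer_,
               converged = NA, note = conditionMessage(e))
        list(dif = NULL, impact = NULL, collapseReport = NULL,
             error = conditionMessage(e))
      })
      out$cells[[cellName]] <- cell

      if (!is.null(plan$outDir) && is.null(cell$error)) {
        prefix <- file.path(plan$outDir, cellName)
        exportStatsTable(cell$dif, paste0(prefix, ".stats.tsv"))
        writeDIFRunResult(cell$dif, paste0(prefix, ".dif.json"))
        if (!is.null(cell$impact))
          writeImpactTables(cell$impact,
                            paste0(prefix, ".impact_persons.csv"),
                            paste0(prefix, ".impact_groups.csv"),
                            provenance = sprintf("seed=%d cell=%s",
                                                 plan$seed, cellName))
      }
    }
  }

  if (plan$includeDimensionality) {
    for (sb in subs) {
      items <- subscales(scale)[[sb]]
      rep <- tryCatch({
        ls <- listwiseSubset(recoded, covariates[[
          plan$contrasts[[1]]$variable]], items)
        dimensionalityReport(ls$responses,
                             seed = deriveCellSeed(plan$seed,
                                                   paste0("dim.", sb)))
      }, error = function(e) conditionMessage(e))
      out$dimensionality[[sb]] <- rep
      if (!is.null(plan$outDir) && is(rep, "EigenReport"))
        writeEigenReport(rep, file.path(plan$outDir,
                                        paste0("dimensionality.", sb,
                                               ".json")))
    }
  }

  out$log <- do.call(rbind, logRows)
  out$plan <- plan
  if (!is.null(plan$outDir))
    write.csv(out$log, file.path(plan$outDir, "run_log.csv"),
              row.names = FALSE)
  class(out) <- "AnalysisBundle"
  out
}

#' @export
print.AnalysisBundle <- function(x, ...) {
  cat(sprintf("AnalysisBundle: %d cells\n", length(x$cells)))
  if (!is.null(x$log)) print(x$log[, c("cell", "stage", "flagged",
                                       "converged", "note")])
  invisible(x)
}
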
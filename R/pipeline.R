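# End-to-end pipeline: read inputs, score, search for outliers, compare
# samples, and write deterministic TSV/JSON reports plus a run manifest.

#' Pipeline run configuration
#'
#' @slot oboPath,annotationPath,expressionPath Input files.
#' @slot annotationFormat \code{"tsv"} or \code{"gaf"}.
#' @slot mode \code{"abundance"} or \code{"log_fold_change"}.
#' @slot namespaces Namespaces to analyse.
#' @slot alpha Grubbs significance level, in (0, 1).
#' @slot relations Relations for levels and propagation.
#' @slot propagate Apply the true-path rule before scoring.
#' @slot outputDir Report directory (created if missing).
#' @slot seed Seed recorded in every output header.
#' @export
setClass("RunConfig",
  representation(oboPath = "character", annotationPath = "character",
                 annotationFormat = "character", expressionPath = "character",
                 mode = "character", namespaces = "character",
                 alpha = "numeric", relations = "character",
                 propagate = "logical", outputDir = "character",
                 seed = "integer")
)

setValidity("RunConfig", function(object) {
  msgs <- character()
  if (object@alpha <= 0 || object@alpha >= 1)
    msgs <- c(msgs, "alpha must lie strictly between 0 and 1")
  if (length(object@namespaces) == 0L)
    msgs <- c(msgs, "at least one namespace must be selected")
  if (!all(object@namespaces %in% .NAMESPACES))
    msgs <- c(msgs, "unknown namespace selected")
  if (!object@mode %in% .MODES) msgs <- c(msgs, "unknown expression mode")
  if (!object@annotationFormat %in% c("tsv", "gaf"))
    msgs <- c(msgs, "annotation format must be 'tsv' or 'gaf'")
  if (length(msgs)) msgs else TRUE
})

#' Build a RunConfig
#'
#' @param oboPath,annotationPath,expressionPath Input files.
#' @param annotationFormat \code{"tsv"} or \code{"gaf"}.
#' @param mode Expression mode (never inferred from the data).
#' @param namespaces Namespaces to analyse (default: all three).
#' @param alpha Grubbs significance level (default 0.05).
#' @param relations Relations for levels/propagation.
#' @param propagate Apply the true-path rule (default TRUE).
#' @param outputDir Where reports are written.
#' @param seed Recorded in every output header.
#' @return A [RunConfig-class].
#' @export
runConfig <- function(oboPath, annotationPath, expressionPath,
                      annotationFormat = c("tsv", "gaf"),
                      mode = c("abundance", "log_fold_change"),
                      namespaces = .NAMESPACES, alpha = 0.05,
                      relations = c("is_a", "part_of"), propagate = TRUE,
                      outputDir = "ewgo-out", seed = 1L) {
  new("RunConfig", oboPath = oboPath, annotationPath = annotationPath,
      annotationFormat = match.arg(annotationFormat),
      expressionPath = expressionPath, mode = match.arg(mode),
      namespaces = namespaces, alpha = alpha, relations = relations,
      propagate = propagate, outputDir = outputDir, seed = as.integer(seed))
}

.headerLines <- function(config) {
  sprintf("# ewGO %s seed=%d", as.character(utils::packageVersion("ewGO")),
          config@seed)
}

# deterministic report order: level desc, |F_avg_log| desc (NA last),
# then accession
.reportOrder <- function(level, flog, ids) {
  key <- abs(flog)
  key[is.na(key)] <- -Inf
  order(-level, -key, ids)
}

.writeTSV <- function(df, path, header) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- .fmtNum(df[[j]])
  lines <- c(header, paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, path)
  path
}

#' Run the full enrichment pipeline
#'
#' Per selected namespace: expression-weighted enrichment scores over the
#' (optionally propagated) annotations, stepwise and average fold changes,
#' per-level enrichment proportions, monotone trend flags, and the
#' recursive Grubbs outlier search. With exactly two samples the chi-square
#' and Kolmogorov-Smirnov comparisons of the two enrichment distributions
#' are added. All results are written to \code{outputDir} as TSV and JSON
#' with fully specified ordering (reruns on identical inputs are
#' byte-identical) plus a manifest recording the configuration, input
#' checksums and package version. Partial outputs are removed on failure.
#'
#' @param config A [RunConfig-class].
#' @return Invisibly, a list with per-namespace \code{tables}
#'   ([EnrichmentTable-class]), \code{outliers} ([OutlierReport-class]),
#'   \code{comparisons} (NULL unless K = 2) and \code{files} written.
#' @export
runPipeline <- function(config) {
  validObject(config)
  set.seed(config@seed)
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit({
    if (!ok && length(written)) {
      .log("WARN", "run failed; removing partial outputs")
      unlink(written)
    }
  })

  graph <- parseOBO(config@oboPath)
  ann <- loadAnnotations(config@annotationPath, config@annotationFormat,
                         graph)
  levels <- computeLevels(graph, config@relations, annotations = ann)
  if (config@propagate)
    ann <- propagateAnnotations(ann, graph, config@relations)
  expr <- readExpressionTSV(config@expressionPath, config@mode)
  K <- ncol(expr)
  header <- .headerLines(config)

  nsOf <- structure(graph@terms$namespace, names = graph@terms$term_id)
  map <- if (config@propagate) ann@propagated else ann@direct
  allTerms <- sort(unique(unlist(map, use.names = FALSE)))

  tables <- list(); outReports <- list(); comparisons <- list()
  for (space in config@namespaces) {
    nsTerms <- allTerms[nsOf[allTerms] == space]
    nsTerms <- nsTerms[!is.na(nsTerms)]
    if (length(nsTerms) == 0L) {
      .log("WARN", sprintf("no annotated terms in %s; skipped", space))
      next
    }
    table <- enrichmentScores(expr, ann, terms = nsTerms)
    table <- averageFold(table)
    table <- monotonePatterns(table)

    lv <- levels@level[rownames(table)]
    # proportions within each level (the per-level pie chart view)
    for (L in sort(unique(lv))) {
      atL <- rownames(table)[lv == L]
      if (sum(colSums(esMatrix(table)[atL, , drop = FALSE]) <= 0) == 0L)
        table <- enrichmentProportions(table, atL)
    }
    report <- findSignificantTerms(table, graph, levels, space,
                                   alpha = config@alpha)
    tables[[space]] <- table
    outReports[[space]] <- report

    ES <- esMatrix(table)
    rd <- rowData(table)
    ord <- .reportOrder(lv, rd$FavgLog, rownames(table))
    termName <- graph@terms$name[match(rownames(table), graph@terms$term_id)]
    FS <- foldSteps(table)
    EP <- if ("EP" %in% assayNames(table)) assay(table, "EP") else
      matrix(NA_real_, nrow(ES), ncol(ES), dimnames = dimnames(ES))
    enrDf <- data.frame(
      term_id = rownames(table), name = termName, level = unname(lv),
      included = rd$included, stringsAsFactors = FALSE)
    ES2 <- ES; colnames(ES2) <- paste0("ES_", colnames(ES))
    EP2 <- EP; colnames(EP2) <- paste0("EP_", colnames(EP))
    FS2 <- FS; colnames(FS2) <- paste0("F_", seq_len(ncol(FS)))
    enrDf <- cbind(enrDf, as.data.frame(ES2), as.data.frame(FS2),
                   F_avg_linear = rd$FavgLinear, F_avg_log = rd$FavgLog,
                   as.data.frame(EP2),
                   monotone_up = rd$monotoneUp,
                   monotone_down = rd$monotoneDown)
    enrDf <- enrDf[ord, , drop = FALSE]
    f <- file.path(config@outputDir, sprintf("enrichment_%s.tsv", space))
    written <- c(written, .writeTSV(enrDf, f, header))

    zero <- enrDf[!enrDf$included, c("term_id", "name", "level"),
                  drop = FALSE]
    f <- file.path(config@outputDir,
                   sprintf("zero_score_terms_%s.tsv", space))
    written <- c(written, .writeTSV(zero, f, header))

    hits <- outlierHits(report)
    outDf <- data.frame(
      namespace = rep(space, nrow(hits)),
      level = rep(levelFound(report), nrow(hits)),
      term_id = hits$term_id,
      term_name = graph@terms$name[match(hits$term_id,
                                         graph@terms$term_id)],
      F_avg_log = hits$F_avg_log,
      F_avg_linear = 2^hits$F_avg_log,
      G = hits$G, critical = hits$critical,
      direction = hits$direction, iteration = hits$iteration,
      stringsAsFactors = FALSE)
    f <- file.path(config@outputDir, sprintf("outliers_%s.tsv", space))
    written <- c(written, .writeTSV(outDf, f, header))
    f <- file.path(config@outputDir, sprintf("outliers_%s.json", space))
    jsonlite::write_json(list(
      seed = config@seed, namespace = space,
      alpha = report@alpha,
      levels_searched = report@levelsSearched,
      level_found = if (is.na(levelFound(report))) NULL else
        levelFound(report),
      n_terms_tested_per_level = as.list(report@nTested),
      outliers = hits), f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)

    if (K == 2L) {
      inc <- rownames(table)[rd$included]
      cmp <- list(
        chi_square = compareChiSq(table, colnames(ES)[1L],
                                  colnames(ES)[2L], inc),
        kolmogorov_smirnov = compareKS(table, colnames(ES)[1L],
                                       colnames(ES)[2L], inc))
      comparisons[[space]] <- cmp
      f <- file.path(config@outputDir, sprintf("comparison_%s.json", space))
      jsonlite::write_json(list(
        seed = config@seed, namespace = space,
        samples = cmp$chi_square@samples,
        chi_square = list(statistic = cmp$chi_square@statistic,
                          df = cmp$chi_square@df,
                          p_value = cmp$chi_square@pValue,
                          n_low_expected = cmp$chi_square@nLowExpected),
        kolmogorov_smirnov = list(statistic =
                                    cmp$kolmogorov_smirnov@statistic,
                                  p_value = cmp$kolmogorov_smirnov@pValue),
        bins = cmp$chi_square@bins), f,
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written <- c(written, f)
    } else {
      .log("INFO", sprintf(
        "two-sample comparisons skipped: %d samples (they need exactly 2)",
        K))
    }
  }

  manifest <- list(
    tool = "ewGO",
    version = as.character(utils::packageVersion("ewGO")),
    seed = config@seed,
    config = list(obo = config@oboPath,
                  annotations = config@annotationPath,
                  annotation_format = config@annotationFormat,
                  expression = config@expressionPath, mode = config@mode,
                  namespaces = config@namespaces, alpha = config@alpha,
                  relations = config@relations,
                  propagate = config@propagate),
    input_md5 = as.list(tools::md5sum(c(config@oboPath,
                                        config@annotationPath,
                                        config@expressionPath))),
    n_samples = K)
  f <- file.path(config@outputDir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, f)

  ok <- TRUE
  invisible(list(tables = tables, outliers = outReports,
                 comparisons = if (K == 2L) comparisons else NULL,
                 files = written))
}
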
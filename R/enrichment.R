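# Expression-weighted enrichment scores and their cross-sample statistics.
#
# For term t and sample s the enrichment score is
#   abundance mode:        ES[t, s] = sum_i log2(e(i, s) + 1) * I(i, t)
#   log-fold-change mode:  ES[t, s] = sum_i log2(2^e(i, s) + 1) * I(i, t)
# where I(i, t) = 1 iff gene i is annotated (directly or via the true-path
# closure) to term t. Every expressed gene contributes - there is no
# differential-expression cutoff - so lowly expressed genes enter through
# their cumulative weight.

#' Compute expression-weighted enrichment scores
#'
#' @param expr An [ExpressionMatrix-class].
#' @param ann An [AnnotationSet-class]. The propagated (true-path) map is
#'   used when available and \code{usePropagated} is TRUE, otherwise the
#'   direct map.
#' @param terms Character vector of GO accessions to score; defaults to
#'   every term annotating at least one gene. A requested term annotating
#'   no gene scores 0 in every sample.
#' @param usePropagated Use the propagated map when present.
#' @return An [EnrichmentTable-class] with the \code{"ES"} assay filled.
#' @examples
#' ann <- new("AnnotationSet",
#'   direct = list(g1 = "GO:0000002", g2 = "GO:0000002"),
#'   propagated = list(), isPropagated = FALSE, dropped = 0L)
#' e <- ExpressionMatrix(matrix(c(3, 1, 7, 0), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("A", "B"))))
#' esMatrix(enrichmentScores(e, ann))   # ES[,"A"] = log2(4) + log2(2) = 3
#' @export
enrichmentScores <- function(expr, ann, terms = NULL, usePropagated = TRUE) {
  stopifnot(is(expr, "ExpressionMatrix"), is(ann, "AnnotationSet"))
  map <- if (usePropagated && ann@isPropagated) ann@propagated else ann@direct
  if (is.null(terms))
    terms <- sort(unique(unlist(map, use.names = FALSE)))
  terms <- unique(as.character(terms))
  if (length(terms) == 0L)
    .domainError("empty term set: nothing to score")

  v <- exprValues(expr)
  genes <- rownames(v)
  nUnannotated <- sum(!(genes %in% names(map)))
  if (nUnannotated)
    .log("INFO", sprintf("%d of %d expressed genes carry no annotation",
                         nUnannotated, length(genes)))

  # sparse indicator I (terms x genes), restricted to expressed genes
  mapHere <- map[intersect(genes, names(map))]
  gIdx <- rep(match(names(mapHere), genes), lengths(mapHere))
  tIdx <- match(unlist(mapHere, use.names = FALSE), terms)
  keep <- !is.na(tIdx)
  I <- Matrix::sparseMatrix(i = tIdx[keep], j = gIdx[keep], x = 1,
                            dims = c(length(terms), length(genes)))

  W <- if (exprMode(expr) == "abundance") log2(v + 1) else log2(2^v + 1)
  ES <- as.matrix(I %*% W)
  dimnames(ES) <- list(terms, colnames(v))
  ES[ES < 0] <- 0   # guard against -0 artefacts; weights are >= 0
  EnrichmentTable(ES, mode = exprMode(expr))
}

#' Stepwise fold changes between consecutive samples
#'
#' Fills the terms x (K-1) matrix of ratios
#' \code{F[t, s] = ES[t, s+1] / ES[t, s]} and marks terms carrying a zero
#' enrichment score in any sample as excluded (\code{included = FALSE}):
#' a zero score admits no ratio and no log, and inventing a pseudocount
#' would manufacture fold changes, so such terms are reported separately
#' instead.
#'
#' @param table An [EnrichmentTable-class].
#' @return The table with \code{FStep} and \code{included} filled.
#' @export
stepwiseFold <- function(table) {
  stopifnot(is(table, "EnrichmentTable"))
  ES <- esMatrix(table)
  K <- ncol(ES)
  if (K < 2L) .domainError("stepwise fold changes need K >= 2 samples")
  included <- rowSums(ES == 0) == 0L
  FS <- ES[, -1L, drop = FALSE] / ES[, -K, drop = FALSE]
  FS[!included, ] <- NA_real_
  colnames(FS) <- paste0(colnames(ES)[-K], "->", colnames(ES)[-1L])
  nZero <- sum(!included)
  if (nZero)
    .log("INFO", sprintf(
      "%d term(s) with a zero enrichment score excluded from fold statistics",
      nZero))
  table@FStep <- FS
  rowData(table)$included <- unname(included)
  table
}

#' Average fold change across samples
#'
#' For each included term the linear average fold is the geometric mean of
#' the stepwise ratios, \code{(prod F[t, s])^(1/(K-1))}, and the log form
#' is the arithmetic mean of their log2. The product telescopes, so the
#' linear form equals \code{(ES[t, K] / ES[t, 1])^(1/(K-1))}: the interior
#' samples cancel in the average, while the stepwise ratios themselves, and
#' therefore the sample order, remain visible in \code{foldSteps()}.
#' Excluded terms get NA (flagged missing, never a silent zero).
#'
#' @param table An [EnrichmentTable-class]; stepwise folds are computed
#'   first if absent.
#' @return The table with \code{FavgLinear} and \code{FavgLog} filled.
#' @export
averageFold <- function(table) {
  stopifnot(is(table, "EnrichmentTable"))
  if (nrow(table@FStep) == 0L) table <- stepwiseFold(table)
  FS <- table@FStep
  km1 <- ncol(FS)
  lin <- apply(FS, 1L, function(r) prod(r)^(1 / km1))
  lg <- rowMeans(log2(FS))
  rowData(table)$FavgLinear <- unname(lin)
  rowData(table)$FavgLog <- unname(lg)
  table
}

#' Enrichment proportions
#'
#' Within each sample, a term's proportion is its enrichment score divided
#' by the summed scores of all terms in the chosen subset, so the subset's
#' proportions sum to 1 per sample (the quantity drawn as a pie chart).
#'
#' @param table An [EnrichmentTable-class].
#' @param termSubset Accessions to normalize over (default: all terms in
#'   the table). Repeated calls with disjoint subsets fill disjoint rows of
#'   the \code{"EP"} assay.
#' @return The table with the \code{"EP"} assay filled for the subset.
#' @export
enrichmentProportions <- function(table, termSubset = NULL) {
  stopifnot(is(table, "EnrichmentTable"))
  ES <- esMatrix(table)
  if (is.null(termSubset)) termSubset <- rownames(ES)
  termSubset <- as.character(termSubset)
  if (!all(termSubset %in% rownames(ES)))
    .domainError(sprintf("term(s) not in table: %s",
                         paste(setdiff(termSubset, rownames(ES)), collapse = ", ")))
  if (length(termSubset) == 0L) .domainError("empty term subset")
  sub <- ES[termSubset, , drop = FALSE]
  tot <- colSums(sub)
  if (any(tot <= 0))
    .domainError(sprintf(
      "no proportion defined: zero total enrichment in sample '%s'",
      colnames(ES)[which(tot <= 0)[1L]]))
  EP <- if ("EP" %in% assayNames(table)) assay(table, "EP") else
    matrix(NA_real_, nrow(ES), ncol(ES), dimnames = dimnames(ES))
  EP[termSubset, ] <- sweep(sub, 2L, tot, "/")
  SummarizedExperiment::assay(table, "EP") <- EP
  table
}

#' Monotone trend flags
#'
#' Flags terms whose enrichment scores never decrease
#' (\code{monotoneUp}: ES[t, s] <= ES[t, s+1] for every consecutive pair)
#' or never increase (\code{monotoneDown}). The inequalities are non-strict,
#' so a constant trajectory satisfies both.
#'
#' @param table An [EnrichmentTable-class].
#' @return The table with both flags filled.
#' @export
monotonePatterns <- function(table) {
  stopifnot(is(table, "EnrichmentTable"))
  ES <- esMatrix(table)
  if (ncol(ES) < 2L) .domainError("monotone patterns need K >= 2 samples")
  d <- ES[, -1L, drop = FALSE] - ES[, -ncol(ES), drop = FALSE]
  rowData(table)$monotoneUp <- unname(rowSums(d < 0) == 0L)
  rowData(table)$monotoneDown <- unname(rowSums(d > 0) == 0L)
  table
}

#' One-call enrichment analysis
#'
#' [enrichmentScores()] followed by [stepwiseFold()], [averageFold()],
#' [monotonePatterns()] and - unless some sample has zero total score -
#' [enrichmentProportions()] over all scored terms.
#'
#' @inheritParams enrichmentScores
#' @return A fully annotated [EnrichmentTable-class].
#' @export
analyzeEnrichment <- function(expr, ann, terms = NULL, usePropagated = TRUE) {
  table <- enrichmentScores(expr, ann, terms, usePropagated)
  table <- averageFold(table)        # computes stepwise folds on the way
  table <- monotonePatterns(table)
  if (all(colSums(esMatrix(table)) > 0)) {
    table <- enrichmentProportions(table)
  } else {
    .log("INFO", "skipping proportions: a sample has zero total enrichment")
  }
  table
}
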
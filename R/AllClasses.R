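#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays rowData rowData<- assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.NAMESPACES <- c("biological_process", "molecular_function", "cellular_component")
.MODES <- c("abundance", "log_fold_change")

# ---------------------------------------------------------------------------
# OntologyGraph
# ---------------------------------------------------------------------------

#' Gene Ontology DAG
#'
#' Holds the parsed ontology: one record per term (accession, name,
#' namespace, obsolete flag) and one record per parent edge
#' (child, parent, relation such as \code{is_a} or \code{part_of}).
#' Alternative accessions (\code{alt_id}) map onto their canonical term and
#' \code{replaced_by} targets of obsolete terms are retained so that
#' annotations can be remapped.
#'
#' Cross-namespace edges are dropped at construction: the three GO
#' namespaces are analysed independently. Within every namespace the parent
#' relation must be acyclic; a cycle raises an integrity error.
#'
#' @slot terms data.frame with columns \code{term_id}, \code{name},
#'   \code{namespace}, \code{obsolete}.
#' @slot edges data.frame with columns \code{child}, \code{parent},
#'   \code{relation}.
#' @slot altIds named character vector, alternative accession -> canonical.
#' @slot replacedBy named character vector, obsolete accession -> replacement.
#'
#' @seealso [parseOBO()], [computeLevels()], [propagateAnnotations()]
#' @export
setClass("OntologyGraph",
  representation(
    terms = "data.frame",
    edges = "data.frame",
    altIds = "character",
    replacedBy = "character"
  )
)

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  needT <- c("term_id", "name", "namespace", "obsolete")
  if (!all(needT %in% names(object@terms)))
    msgs <- c(msgs, "terms must have columns term_id, name, namespace, obsolete")
  needE <- c("child", "parent", "relation")
  if (!all(needE %in% names(object@edges)))
    msgs <- c(msgs, "edges must have columns child, parent, relation")
  if (length(msgs) == 0L) {
    if (anyDuplicated(object@terms$term_id))
      msgs <- c(msgs, "duplicated term_id in terms")
    if (!all(object@terms$namespace %in% .NAMESPACES))
      msgs <- c(msgs, "unknown namespace in terms")
    known <- object@terms$term_id
    if (nrow(object@edges) &&
        !all(c(object@edges$child, object@edges$parent) %in% known))
      msgs <- c(msgs, "edge endpoint not present in terms")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OntologyGraph
#'
#' Programmatic constructor used by [parseOBO()] and the synthetic-data
#' generator. Cross-namespace edges are removed, is_a acyclicity is enforced
#' per namespace, and every non-obsolete, non-root term must have at least
#' one parent in its own namespace.
#'
#' @param terms data.frame with columns \code{term_id}, \code{name},
#'   \code{namespace}, \code{obsolete}.
#' @param edges data.frame with columns \code{child}, \code{parent},
#'   \code{relation}.
#' @param altIds named character vector (alternative -> canonical accession).
#' @param replacedBy named character vector (obsolete -> replacement).
#' @return An [OntologyGraph-class] object.
#' @export
OntologyGraph <- function(terms, edges = NULL, altIds = character(),
                          replacedBy = character()) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  }
  rownames(terms) <- NULL
  rownames(edges) <- NULL
  terms$obsolete <- as.logical(terms$obsolete)

  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$term_id)
  if (length(unknown))
    .integrityError(sprintf("edge references unknown term(s): %s",
                            paste(unknown, collapse = ", ")))

  ns <- terms$namespace[match(edges$child, terms$term_id)]
  nsP <- terms$namespace[match(edges$parent, terms$term_id)]
  cross <- ns != nsP
  if (any(cross)) {
    .log("INFO", sprintf("dropping %d cross-namespace edge(s)", sum(cross)))
    edges <- edges[!cross, , drop = FALSE]
  }

  obj <- new("OntologyGraph", terms = terms, edges = edges,
             altIds = altIds, replacedBy = replacedBy)

  # is_a closure must be acyclic within every namespace
  isa <- obj@edges[obj@edges$relation == "is_a", , drop = FALSE]
  if (nrow(isa)) {
    g <- igraph::graph_from_data_frame(
      isa[, c("child", "parent")], directed = TRUE,
      vertices = terms$term_id)
    if (!igraph::is_dag(g))
      .integrityError("cycle detected in is_a closure")
  }

  # every non-obsolete non-root term needs a parent in its own namespace
  live <- terms[!terms$obsolete, , drop = FALSE]
  for (space in unique(live$namespace)) {
    ids <- live$term_id[live$namespace == space]
    hasParent <- ids %in% obj@edges$child
    if (sum(!hasParent) > 1L)
      .integrityError(sprintf(
        "namespace %s has %d parentless non-obsolete terms (expected exactly one root)",
        space, sum(!hasParent)))
    if (sum(!hasParent) == 0L && length(ids))
      .integrityError(sprintf("namespace %s has no root term", space))
  }
  obj
}

#' @describeIn OntologyGraph-class Term table accessor.
#' @param graph An OntologyGraph.
#' @export
goTerms <- function(graph) graph@terms

#' @describeIn OntologyGraph-class Edge table accessor.
#' @export
goEdges <- function(graph) graph@edges

#' Root term of each namespace
#'
#' @param graph An [OntologyGraph-class].
#' @return Named character vector, namespace -> root accession.
#' @export
goRoots <- function(graph) {
  live <- graph@terms[!graph@terms$obsolete, , drop = FALSE]
  out <- character()
  for (space in unique(live$namespace)) {
    ids <- live$term_id[live$namespace == space]
    root <- ids[!(ids %in% graph@edges$child)]
    out[space] <- root[1L]
  }
  out
}

setMethod("show", "OntologyGraph", function(object) {
  live <- !object@terms$obsolete
  cat(sprintf("OntologyGraph: %d terms (%d obsolete), %d edges\n",
              nrow(object@terms), sum(!live), nrow(object@edges)))
  tab <- table(object@terms$namespace[live])
  for (nm in names(tab)) cat(sprintf("  %s: %d terms\n", nm, tab[[nm]]))
})

# ---------------------------------------------------------------------------
# TermLevels
# ---------------------------------------------------------------------------

#' GO term levels
#'
#' A term's level is the length of the shortest directed path from the term
#' to its namespace root over a chosen set of relations (default
#' \code{is_a} + \code{part_of}); roots sit at level 0 and the "last" or
#' "deepest" level of a namespace is \code{maxLevel}. Obsolete terms carry
#' no level.
#'
#' @slot level named integer vector, term accession -> level.
#' @slot maxLevel named integer vector, namespace -> deepest level.
#' @slot relations character, the relations the levels were computed over.
#' @seealso [computeLevels()], [termsAtLevel()]
#' @export
setClass("TermLevels",
  representation(level = "integer", maxLevel = "integer",
                 relations = "character")
)

#' @describeIn TermLevels-class Level of one or more terms.
#' @param levels A TermLevels object.
#' @param term_id Character vector of accessions.
#' @export
termLevel <- function(levels, term_id) levels@level[term_id]

#' @describeIn TermLevels-class Deepest level of a namespace.
#' @param namespace One of the three GO namespaces.
#' @export
maxLevel <- function(levels, namespace) {
  if (!namespace %in% names(levels@maxLevel))
    .domainError(sprintf("no levels computed for namespace '%s'", namespace))
  levels@maxLevel[[namespace]]
}

setMethod("show", "TermLevels", function(object) {
  cat(sprintf("TermLevels over {%s}: %d terms\n",
              paste(object@relations, collapse = ", "),
              length(object@level)))
  for (nm in names(object@maxLevel))
    cat(sprintf("  %s: max level %d\n", nm, object@maxLevel[[nm]]))
})

# ---------------------------------------------------------------------------
# AnnotationSet
# ---------------------------------------------------------------------------

#' Gene-to-term annotations
#'
#' Stores the direct gene -> GO term assignments read from a GAF or
#' two-column TSV file and, after [propagateAnnotations()], the true-path
#' closure (a gene annotated to a term is implicitly annotated to all of the
#' term's ancestors). The indicator I(gene, term) used by the enrichment
#' score is 1 exactly when the term is in the gene's (propagated) set.
#'
#' @slot direct named list, gene_id -> character vector of accessions.
#' @slot propagated named list, gene_id -> ancestor-closed accession sets
#'   (empty until propagation).
#' @slot isPropagated logical flag.
#' @slot dropped integer, number of annotation rows dropped at load time.
#' @seealso [loadAnnotations()], [propagateAnnotations()]
#' @export
setClass("AnnotationSet",
  representation(direct = "list", propagated = "list",
                 isPropagated = "logical", dropped = "integer")
)

setValidity("AnnotationSet", function(object) {
  if (object@isPropagated &&
      !all(names(object@direct) %in% names(object@propagated)))
    return("propagated map must cover all directly annotated genes")
  if (object@isPropagated) {
    ok <- vapply(names(object@direct), function(g)
      all(object@direct[[g]] %in% object@propagated[[g]]), logical(1))
    if (!all(ok)) return("direct(g) must be a subset of propagated(g)")
  }
  TRUE
})

#' @describeIn AnnotationSet-class Direct annotation map.
#' @param ann An AnnotationSet.
#' @export
directAnnotations <- function(ann) ann@direct

#' @describeIn AnnotationSet-class Propagated (true-path) annotation map;
#'   errors if [propagateAnnotations()] has not been run.
#' @export
propagatedAnnotations <- function(ann) {
  if (!ann@isPropagated)
    .domainError("annotations have not been propagated")
  ann@propagated
}

#' @describeIn AnnotationSet-class Gene identifiers with >= 1 annotation.
#' @export
annotatedGenes <- function(ann) names(ann@direct)

setMethod("show", "AnnotationSet", function(object) {
  nterm <- length(unique(unlist(object@direct, use.names = FALSE)))
  cat(sprintf("AnnotationSet: %d genes, %d distinct terms (direct)%s\n",
              length(object@direct), nterm,
              if (object@isPropagated) ", propagated" else ""))
  if (object@dropped > 0L)
    cat(sprintf("  %d annotation rows dropped at load\n", object@dropped))
})

# ---------------------------------------------------------------------------
# ExpressionMatrix
# ---------------------------------------------------------------------------

#' Genes-by-samples expression matrix
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"expr"}
#' (genes in rows, samples in columns) plus a mode flag. Sample order is
#' experiment order and is preserved end-to-end: the cross-sample fold
#' statistics are sensitive to it. Two modes are supported:
#' \describe{
#'   \item{abundance}{RPKM/FPKM-like non-negative values; the per-gene
#'     weight is \code{log2(e + 1)}.}
#'   \item{log_fold_change}{microarray log2 ratios, may be negative; the
#'     weight is \code{log2(2^e + 1)}.}
#' }
#'
#' @slot exprMode \code{"abundance"} or \code{"log_fold_change"}.
#' @seealso [readExpressionTSV()], [enrichmentScores()]
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(exprMode = "character")
)

setValidity("ExpressionMatrix", function(object) {
  if (length(object@exprMode) != 1L || !object@exprMode %in% .MODES)
    return("exprMode must be 'abundance' or 'log_fold_change'")
  v <- assay(object, "expr")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("expression assay needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(v)))
    return("duplicated gene identifiers")
  if (any(!is.finite(v)))
    return("expression values must be finite")
  if (object@exprMode == "abundance" && any(v < 0))
    return("negative values in abundance mode")
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample names, experiment order).
#' @param mode \code{"abundance"} (RPKM/FPKM) or \code{"log_fold_change"}.
#' @return An [ExpressionMatrix-class].
#' @export
ExpressionMatrix <- function(values, mode = c("abundance", "log_fold_change")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    .validationError("expression matrix needs gene identifiers as rownames")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    .validationError(sprintf("duplicated gene identifier '%s'", dup))
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    .validationError(sprintf("non-finite expression value for gene '%s', sample '%s'",
                             rownames(values)[bad[1L, 1L]],
                             colnames(values)[bad[1L, 2L]]))
  if (mode == "abundance") {
    neg <- which(values < 0, arr.ind = TRUE)
    if (nrow(neg))
      .validationError(sprintf(
        "negative abundance for gene '%s' in sample '%s'",
        rownames(values)[neg[1L, 1L]], colnames(values)[neg[1L, 2L]]))
  }
  se <- SummarizedExperiment(assays = list(expr = values))
  new("ExpressionMatrix", se, exprMode = mode)
}

#' @describeIn ExpressionMatrix-class Mode flag accessor.
#' @param x An ExpressionMatrix or EnrichmentTable.
#' @export
exprMode <- function(x) x@exprMode

#' @describeIn ExpressionMatrix-class The numeric expression matrix.
#' @export
exprValues <- function(x) assay(x, "expr")

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, mode = %s\n",
              nrow(object), ncol(object), object@exprMode))
  cat("  samples: ", paste(colnames(object), collapse = ", "), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# EnrichmentTable
# ---------------------------------------------------------------------------

#' Per-term, per-sample enrichment results
#'
#' A \linkS4class{SummarizedExperiment} with GO terms in rows and samples in
#' columns. Assay \code{"ES"} holds the expression-weighted enrichment
#' scores; assay \code{"EP"} (once computed) the enrichment proportions.
#' Stepwise fold changes live in the \code{FStep} slot (terms x K-1) and the
#' per-term summaries in \code{rowData()}:
#' \code{included} (FALSE when any ES is zero, which would break the fold
#' ratios), \code{FavgLinear} (geometric mean of stepwise folds),
#' \code{FavgLog} (its log2 form), and the monotone trend flags
#' \code{monotoneUp} / \code{monotoneDown}.
#'
#' @slot FStep numeric matrix of stepwise ES ratios (0x0 until computed).
#' @slot exprMode mode of the expression data the scores came from.
#' @seealso [enrichmentScores()], [stepwiseFold()], [averageFold()],
#'   [enrichmentProportions()], [monotonePatterns()]
#' @export
setClass("EnrichmentTable",
  contains = "SummarizedExperiment",
  representation(FStep = "matrix", exprMode = "character")
)

setValidity("EnrichmentTable", function(object) {
  es <- assay(object, "ES")
  if (any(es < 0)) return("enrichment scores must be non-negative")
  if (is.null(rownames(es))) return("ES assay needs term rownames")
  TRUE
})

#' Construct an EnrichmentTable from a score matrix
#'
#' Mostly useful for tests and for feeding externally computed scores into
#' the outlier search; the usual entry point is [enrichmentScores()].
#'
#' @param ES Non-negative numeric matrix, terms x samples, with dimnames.
#' @param mode Expression mode the scores were derived from.
#' @return An [EnrichmentTable-class].
#' @export
EnrichmentTable <- function(ES, mode = c("abundance", "log_fold_change")) {
  mode <- match.arg(mode)
  ES <- as.matrix(ES)
  if (is.null(rownames(ES)))
    .validationError("ES matrix needs term rownames")
  if (is.null(colnames(ES)))
    colnames(ES) <- paste0("S", seq_len(ncol(ES)))
  if (any(!is.finite(ES)) || any(ES < 0))
    .validationError("enrichment scores must be finite and non-negative")
  m <- nrow(ES)
  rd <- DataFrame(
    included = rep(NA, m),
    FavgLinear = rep(NA_real_, m),
    FavgLog = rep(NA_real_, m),
    monotoneUp = rep(NA, m),
    monotoneDown = rep(NA, m),
    row.names = rownames(ES)
  )
  se <- SummarizedExperiment(assays = list(ES = ES), rowData = rd)
  new("EnrichmentTable", se, FStep = matrix(numeric(0), 0, 0), exprMode = mode)
}

#' @describeIn EnrichmentTable-class Enrichment-score matrix.
#' @param x An EnrichmentTable.
#' @export
esMatrix <- function(x) assay(x, "ES")

#' @describeIn EnrichmentTable-class Enrichment-proportion matrix (errors
#'   when [enrichmentProportions()] has not been run).
#' @export
epMatrix <- function(x) {
  if (!"EP" %in% assayNames(x))
    .domainError("enrichment proportions have not been computed")
  assay(x, "EP")
}

#' @describeIn EnrichmentTable-class Stepwise fold-change matrix (terms x
#'   K-1); errors when [stepwiseFold()] has not been run.
#' @export
foldSteps <- function(x) {
  if (nrow(x@FStep) == 0L && nrow(x) > 0L)
    .domainError("stepwise fold changes have not been computed")
  x@FStep
}

#' @describeIn EnrichmentTable-class Per-term geometric-mean fold change.
#' @export
avgFoldLinear <- function(x) structure(rowData(x)$FavgLinear,
                                       names = rownames(x))

#' @describeIn EnrichmentTable-class Per-term log2 average fold change.
#' @export
avgFoldLog <- function(x) structure(rowData(x)$FavgLog, names = rownames(x))

#' @describeIn EnrichmentTable-class Which terms enter the fold statistics
#'   (no zero ES in any sample).
#' @export
isIncluded <- function(x) structure(rowData(x)$included, names = rownames(x))

setMethod("show", "EnrichmentTable", function(object) {
  cat(sprintf("EnrichmentTable: %d terms x %d samples (mode %s)\n",
              nrow(object), ncol(object), object@exprMode))
  inc <- rowData(object)$included
  if (!all(is.na(inc)))
    cat(sprintf("  included in fold statistics: %d; zero-score terms: %d\n",
                sum(inc, na.rm = TRUE), sum(!inc, na.rm = TRUE)))
  cat("  assays: ", paste(assayNames(object), collapse = ", "),
      if (nrow(object@FStep)) " + stepwise folds" else "", "\n", sep = "")
})

# ---------------------------------------------------------------------------
# Reports
# ---------------------------------------------------------------------------

#' Result of the recursive Grubbs outlier search
#'
#' The search walks GO levels from the deepest annotated level upward and
#' stops at the first level where the Grubbs test flags at least one term's
#' log2 average fold change as an outlier.
#'
#' @slot namespace GO namespace searched.
#' @slot levelsSearched integer, the levels visited (strictly decreasing).
#' @slot levelFound level at which outliers were found, or NA.
#' @slot outliers data.frame: term_id, F_avg_log, G, critical, direction
#'   (up/down), iteration.
#' @slot nTested named integer, terms eligible for testing per level.
#' @slot alpha significance level used.
#' @seealso [findSignificantTerms()], [grubbsTest()]
#' @export
setClass("OutlierReport",
  representation(namespace = "character", levelsSearched = "integer",
                 levelFound = "integer", outliers = "data.frame",
                 nTested = "integer", alpha = "numeric")
)

#' @describeIn OutlierReport-class Flagged-term table.
#' @param report An OutlierReport.
#' @export
outlierHits <- function(report) report@outliers

#' @describeIn OutlierReport-class Level at which outliers were found (NA
#'   when the search exhausted all levels).
#' @export
levelFound <- function(report) report@levelFound

#' @describeIn OutlierReport-class Levels visited, deepest first.
#' @export
levelsSearched <- function(report) report@levelsSearched

setMethod("show", "OutlierReport", function(object) {
  cat(sprintf("OutlierReport [%s], alpha = %g\n", object@namespace,
              object@alpha))
  cat(sprintf("  levels searched: %s\n",
              paste(object@levelsSearched, collapse = ", ")))
  if (is.na(object@levelFound)) {
    cat("  no outlying term found at any level\n")
  } else {
    cat(sprintf("  %d outlier(s) at level %d:\n", nrow(object@outliers),
                object@levelFound))
    print(object@outliers, row.names = FALSE)
  }
})

#' Two-sample comparison of enrichment distributions
#'
#' GO terms act as bins; each sample's per-term enrichment scores form one
#' distribution. The chi-square variant treats the scores directly as bin
#' counts (so the statistic scales with overall expression depth); the
#' Kolmogorov-Smirnov variant compares the two empirical score
#' distributions.
#'
#' @slot test \code{"chi_square"} or \code{"kolmogorov_smirnov"}.
#' @slot statistic test statistic (chi-square X2 or KS D).
#' @slot df degrees of freedom (bins - 1 for chi-square, NA for KS).
#' @slot pValue p-value.
#' @slot bins term accessions used as bins.
#' @slot nLowExpected for chi-square, number of cells with expected < 5.
#' @slot samples the two sample names compared.
#' @seealso [compareChiSq()], [compareKS()]
#' @export
setClass("ComparisonReport",
  representation(test = "character", statistic = "numeric", df = "integer",
                 pValue = "numeric", bins = "character",
                 nLowExpected = "integer", samples = "character")
)

setValidity("ComparisonReport", function(object) {
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("p-value outside [0, 1]")
  TRUE
})

#' @describeIn ComparisonReport-class Test statistic.
#' @param report A ComparisonReport.
#' @export
testStatistic <- function(report) report@statistic

#' @describeIn ComparisonReport-class P-value.
#' @export
pValue <- function(report) report@pValue

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport: %s, samples %s vs %s\n", object@test,
              object@samples[1L], object@samples[2L]))
  cat(sprintf("  statistic = %.6g%s, p = %.6g, bins = %d\n",
              object@statistic,
              if (!is.na(object@df)) sprintf(", df = %d", object@df) else "",
              object@pValue, length(object@bins)))
  if (!is.na(object@nLowExpected) && object@nLowExpected > 0L)
    cat(sprintf("  warning: %d cell(s) with expected value < 5\n",
                object@nLowExpected))
})
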
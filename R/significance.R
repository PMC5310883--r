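# Recursive outlier search over GO levels and two-sample comparison of
# enrichment distributions.

#' Find GO terms with outlying average fold change
#'
#' The search starts at the deepest (most specific) annotated level of the
#' namespace and applies the two-sided Grubbs test to the log2 average fold
#' changes of the included terms at exactly that level. If no outlier is
#' flagged, the next (more general) level up is searched, recursively,
#' until a level yields at least one outlier or level 1 has been visited.
#' Levels holding fewer than 3 eligible terms (or with zero spread) cannot
#' be tested and are recorded as skipped. No multiple-testing correction is
#' applied across the visited levels by default; \code{bonferroni = TRUE}
#' divides alpha by the number of testable levels.
#'
#' @param table An [EnrichmentTable-class]; average folds are computed
#'   first if absent.
#' @param graph An [OntologyGraph-class].
#' @param levels A [TermLevels-class] from [computeLevels()].
#' @param namespace Namespace to search.
#' @param alpha Two-sided significance level (default 0.05).
#' @param iterative Iterative outlier removal within a level (default TRUE,
#'   so several terms can be flagged).
#' @param bonferroni Divide alpha by the number of levels searched.
#' @return An [OutlierReport-class].
#' @export
findSignificantTerms <- function(table, graph, levels, namespace,
                                 alpha = 0.05, iterative = TRUE,
                                 bonferroni = FALSE) {
  stopifnot(is(table, "EnrichmentTable"), is(graph, "OntologyGraph"),
            is(levels, "TermLevels"))
  if (!namespace %in% .NAMESPACES)
    .domainError(sprintf("unknown namespace '%s'", namespace))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    .domainError("alpha must lie strictly between 0 and 1")
  if (all(is.na(rowData(table)$FavgLog))) table <- averageFold(table)

  nsOf <- structure(graph@terms$namespace, names = graph@terms$term_id)
  ids <- rownames(table)
  inNs <- ids[!is.na(nsOf[ids]) & nsOf[ids] == namespace]
  if (length(inNs) == 0L)
    .domainError(sprintf("no scored terms in namespace %s", namespace))

  flog <- avgFoldLog(table)[inNs]
  inc <- isIncluded(table)[inNs]
  eligible <- inNs[inc & is.finite(flog)]
  lv <- levels@level[eligible]
  eligible <- eligible[!is.na(lv)]
  lv <- lv[!is.na(lv)]

  top <- maxLevel(levels, namespace)
  searched <- integer(0)
  nTested <- integer(0)
  found <- NA_integer_
  outliers <- data.frame(term_id = character(), value = numeric(),
                         G = numeric(), critical = numeric(),
                         direction = character(), iteration = integer(),
                         stringsAsFactors = FALSE)
  if (top >= 1L) {
    testable <- sum(vapply(seq(top, 1L), function(L) {
      v <- flog[eligible[lv == L]]
      length(v) >= 3L && stats::sd(v) > 0
    }, logical(1)))
    effAlpha <- if (bonferroni && testable > 0L) alpha / testable else alpha
    for (L in seq(top, 1L)) {
      searched <- c(searched, L)
      vals <- flog[eligible[lv == L]]
      nTested[as.character(L)] <- length(vals)
      if (length(vals) < 3L) {
        .log("DEBUG", sprintf("level %d skipped: %d eligible term(s) (< 3)",
                              L, length(vals)))
        next
      }
      if (stats::sd(vals) == 0) {
        .log("DEBUG", sprintf("level %d skipped: zero spread", L))
        next
      }
      hits <- grubbsTest(vals, alpha = effAlpha, iterative = iterative)
      if (nrow(hits)) {
        found <- L
        outliers <- hits
        break
      }
    }
  }
  if (is.na(found))
    .log("INFO", sprintf(
      "no outlying term found in %s (levels %s visited)", namespace,
      paste(searched, collapse = ", ")))
  names(outliers)[names(outliers) == "value"] <- "F_avg_log"
  new("OutlierReport", namespace = namespace,
      levelsSearched = as.integer(searched), levelFound = found,
      outliers = outliers, nTested = nTested, alpha = alpha)
}

# pull two samples' ES vectors over a term subset, with shared checks
.twoSampleES <- function(table, sampleA, sampleB, termSubset) {
  ES <- esMatrix(table)
  for (s in c(sampleA, sampleB))
    if (!s %in% colnames(ES))
      .domainError(sprintf("sample '%s' not in table", s))
  if (is.null(termSubset)) termSubset <- rownames(ES)
  termSubset <- as.character(termSubset)
  if (!all(termSubset %in% rownames(ES)))
    .domainError("term subset contains accessions not in the table")
  if (length(termSubset) < 2L)
    .domainError("two-sample comparison needs at least 2 term bins")
  list(a = ES[termSubset, sampleA], b = ES[termSubset, sampleB],
       bins = termSubset)
}

#' Chi-square comparison of two samples' enrichment distributions
#'
#' GO terms are bins; each sample's enrichment scores are used directly,
#' unrounded, as the bin "counts" of a 2 x m homogeneity table
#' (df = m - 1). Because real-valued scores stand in for counts, the
#' statistic scales with overall expression depth: doubling every score
#' doubles the statistic. Cells with expected value below 5 are counted and
#' reported as a warning.
#'
#' @param table An [EnrichmentTable-class].
#' @param sampleA,sampleB Sample names (columns of the table).
#' @param termSubset Bins to use (default: all terms in the table).
#' @return A [ComparisonReport-class].
#' @export
compareChiSq <- function(table, sampleA, sampleB, termSubset = NULL) {
  es <- .twoSampleES(table, sampleA, sampleB, termSubset)
  if (sum(es$a) <= 0 || sum(es$b) <= 0)
    .domainError("zero total enrichment in one of the samples")
  tab <- rbind(es$a, es$b)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  nLow <- sum(res$expected < 5)
  if (nLow > 0L)
    warning(sprintf("%d of %d cells have expected value < 5; the chi-square approximation may be poor",
                    nLow, length(res$expected)), call. = FALSE)
  new("ComparisonReport", test = "chi_square",
      statistic = unname(res$statistic), df = as.integer(res$parameter),
      pValue = unname(res$p.value), bins = es$bins,
      nLowExpected = as.integer(nLow), samples = c(sampleA, sampleB))
}

#' Kolmogorov-Smirnov comparison of two samples' enrichment distributions
#'
#' Each sample's per-term enrichment scores are treated as one empirical
#' distribution and compared with the standard two-sample KS statistic
#' D = sup |ECDF_a - ECDF_b| and its asymptotic p-value. (KS is not a
#' paired test; the term-to-score pairing is preserved only in the
#' report's bin listing.)
#'
#' @inheritParams compareChiSq
#' @return A [ComparisonReport-class].
#' @export
compareKS <- function(table, sampleA, sampleB, termSubset = NULL) {
  es <- .twoSampleES(table, sampleA, sampleB, termSubset)
  res <- suppressWarnings(stats::ks.test(es$a, es$b, exact = FALSE))
  new("ComparisonReport", test = "kolmogorov_smirnov",
      statistic = unname(res$statistic), df = NA_integer_,
      pValue = unname(res$p.value), bins = es$bins,
      nLowExpected = NA_integer_, samples = c(sampleA, sampleB))
}
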
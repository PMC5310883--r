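# GO level computation: shortest directed path to the namespace root.

# igraph over the selected relations, restricted to non-obsolete terms.
# Edges are directed child -> parent.
.relationGraph <- function(graph, relations, namespace = NULL) {
  terms <- graph@terms[!graph@terms$obsolete, , drop = FALSE]
  if (!is.null(namespace))
    terms <- terms[terms$namespace == namespace, , drop = FALSE]
  edges <- graph@edges[graph@edges$relation %in% relations &
                       graph@edges$child %in% terms$term_id &
                       graph@edges$parent %in% terms$term_id, , drop = FALSE]
  igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                directed = TRUE, vertices = terms$term_id)
}

#' Compute GO term levels
#'
#' A term's level is the number of edges on the shortest directed path from
#' the term to its namespace root, following the chosen relations (default
#' \code{is_a} and \code{part_of}, the common practice of GO browsers;
#' regulates-type relations are excluded by default). Roots sit at level 0,
#' so \code{level(t) = 1 + min(level(parent))} for every non-root term.
#' Obsolete terms are skipped. The "last" (deepest, most specific) level of
#' a namespace is the maximum level over its terms; when an
#' [AnnotationSet-class] is supplied the maximum is taken over annotated
#' terms only.
#'
#' @param graph An [OntologyGraph-class].
#' @param relations Relations to traverse.
#' @param annotations Optional [AnnotationSet-class] restricting the
#'   per-namespace maximum level to annotated terms.
#' @return A [TermLevels-class].
#' @export
computeLevels <- function(graph, relations = c("is_a", "part_of"),
                          annotations = NULL) {
  live <- graph@terms[!graph@terms$obsolete, , drop = FALSE]
  levelVec <- integer(0)
  maxVec <- integer(0)
  annTerms <- if (!is.null(annotations))
    unique(unlist(annotations@direct, use.names = FALSE)) else NULL

  for (space in sort(unique(live$namespace))) {
    ids <- live$term_id[live$namespace == space]
    g <- .relationGraph(graph, relations, space)
    if (!igraph::is_dag(g))
      .integrityError(sprintf("cycle over relations {%s} in namespace %s",
                              paste(relations, collapse = ", "), space))
    roots <- ids[igraph::degree(g, v = ids, mode = "out") == 0L]
    if (length(roots) != 1L)
      .integrityError(sprintf(
        "namespace %s has %d root terms over relations {%s} (expected 1)",
        space, length(roots), paste(relations, collapse = ", ")))
    d <- igraph::distances(g, v = ids, to = roots, mode = "out")[, 1L]
    if (any(!is.finite(d)))
      .integrityError(sprintf(
        "term(s) unreachable from root %s: %s", roots,
        paste(ids[!is.finite(d)], collapse = ", ")))
    lv <- structure(as.integer(d), names = ids)
    levelVec <- c(levelVec, lv)
    pool <- if (is.null(annTerms)) ids else intersect(ids, annTerms)
    if (length(pool) == 0L) pool <- ids
    maxVec[space] <- max(lv[pool])
  }
  new("TermLevels", level = levelVec, maxLevel = maxVec,
      relations = relations)
}

#' Terms at one GO level
#'
#' @param graph An [OntologyGraph-class].
#' @param levels A [TermLevels-class] from [computeLevels()].
#' @param namespace One of the three GO namespaces.
#' @param L Level, between 0 (root) and \code{maxLevel(levels, namespace)}.
#' @return Sorted character vector of accessions at exactly level \code{L}.
#' @export
termsAtLevel <- function(graph, levels, namespace, L) {
  top <- maxLevel(levels, namespace)
  if (!is.numeric(L) || length(L) != 1L || L < 0 || L > top)
    .domainError(sprintf("level %s out of range [0, %d] for namespace %s",
                         as.character(L)[1L], top, namespace))
  live <- graph@terms[!graph@terms$obsolete &
                      graph@terms$namespace == namespace, , drop = FALSE]
  ids <- intersect(live$term_id, names(levels@level))
  sort(ids[levels@level[ids] == as.integer(L)])
}
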
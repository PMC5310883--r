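# Gene -> GO annotation loading (GAF 2.x / two-column TSV) and true-path
# propagation to ancestor terms.

#' Load gene-to-GO annotations
#'
#' Reads either a GAF 2.1/2.2 file (17 tab-separated columns, `!` comment
#' lines; column 2 = gene product id, column 4 = qualifier, column 5 = GO
#' accession) or a simple two-column TSV (\code{gene_id}, \code{go_id},
#' optional header starting with \code{gene_id}, `#` comments ignored).
#'
#' GAF rows carrying a \code{NOT} qualifier are excluded. Accessions are
#' resolved against the ontology: alternative ids map to their canonical
#' term; annotations to obsolete terms follow \code{replaced_by} (or an
#' alt_id) when possible and are otherwise dropped; accessions absent from
#' the ontology are dropped with a warning. Dropped rows are counted and
#' logged. Genes absent from the expression matrix are retained here -
#' filtering happens at scoring time.
#'
#' @param path Annotation file path.
#' @param format \code{"tsv"} or \code{"gaf"}.
#' @param graph An [OntologyGraph-class] used to resolve accessions.
#' @return An [AnnotationSet-class] (direct annotations only; see
#'   [propagateAnnotations()]).
#' @export
loadAnnotations <- function(path, format = c("tsv", "gaf"), graph) {
  format <- match.arg(format)
  if (!file.exists(path))
    .parseError(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)

  if (format == "gaf") {
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(fields)
    # trailing empty columns are legal (and dropped by the split)
    bad <- nc < 15L | nc > 17L
    if (any(bad))
      .parseError(sprintf(
        "GAF line %d has %d columns (17 expected)",
        which(bad)[1L], nc[bad][1L]))
    genes <- vapply(fields, `[[`, character(1), 2L)
    quals <- vapply(fields, `[[`, character(1), 4L)
    gos   <- vapply(fields, `[[`, character(1), 5L)
    isNot <- vapply(strsplit(quals, "|", fixed = TRUE),
                    function(q) "NOT" %in% q, logical(1))
    nNot <- sum(isNot)
    genes <- genes[!isNot]; gos <- gos[!isNot]
    if (nNot) .log("INFO", sprintf("excluded %d NOT-qualified GAF row(s)", nNot))
  } else {
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines) && startsWith(lines[1L], "gene_id"))
      lines <- lines[-1L]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(fields)
    if (length(fields) && any(nc != 2L))
      .parseError(sprintf(
        "annotation TSV line %d has %d columns (2 expected)",
        which(nc != 2L)[1L], nc[nc != 2L][1L]))
    genes <- vapply(fields, `[[`, character(1), 1L)
    gos   <- vapply(fields, `[[`, character(1), 2L)
  }

  known <- graph@terms$term_id
  obsolete <- structure(graph@terms$obsolete, names = known)
  resolved <- gos
  # alternative accessions -> canonical term
  isAlt <- !(resolved %in% known) & resolved %in% names(graph@altIds)
  resolved[isAlt] <- graph@altIds[resolved[isAlt]]
  unknown <- !(resolved %in% known)
  if (any(unknown)) {
    warning(sprintf("dropped %d annotation(s) to unknown GO accession(s): %s",
                    sum(unknown),
                    paste(utils::head(unique(gos[unknown]), 5L),
                          collapse = ", ")),
            call. = FALSE)
  }
  # annotations landing on obsolete terms: remap where possible
  obs <- !unknown & obsolete[resolved]
  if (any(obs)) {
    tgt <- resolved[obs]
    repl <- ifelse(tgt %in% names(graph@replacedBy),
                   graph@replacedBy[tgt],
                   ifelse(tgt %in% names(graph@altIds),
                          graph@altIds[tgt], NA_character_))
    ok <- !is.na(repl) & repl %in% known & !obsolete[repl]
    resolved[obs][ok] <- repl[ok]
    resolved[obs][!ok] <- NA_character_
    nDropObs <- sum(!ok)
    if (nDropObs)
      .log("INFO", sprintf(
        "dropped %d annotation(s) to obsolete terms with no replacement",
        nDropObs))
  }
  keep <- !unknown & !is.na(resolved)
  dropped <- sum(!keep)
  .log("INFO", sprintf("loaded %d annotation rows (%d dropped)",
                       sum(keep), dropped))
  direct <- lapply(split(resolved[keep], genes[keep]),
                   function(x) sort(unique(x)))
  direct <- direct[order(names(direct))]
  new("AnnotationSet", direct = direct, propagated = list(),
      isPropagated = FALSE, dropped = as.integer(dropped))
}

# ancestor closure (including the term itself) for each requested term,
# within its namespace, over the chosen relations
.ancestorSets <- function(graph, terms, relations) {
  g <- .relationGraph(graph, relations)
  present <- terms[terms %in% igraph::V(g)$name]
  anc <- lapply(present, function(t)
    sort(igraph::V(g)$name[as.integer(
      igraph::subcomponent(g, t, mode = "out"))]))
  names(anc) <- present
  anc
}

#' Propagate annotations to ancestor terms (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term within the term's namespace. Propagation follows the same
#' relations as level computation (default \code{is_a} + \code{part_of});
#' obsolete terms and cross-namespace edges are ignored. The operation is
#' idempotent: it always recomputes the closure from the direct map.
#'
#' @param ann An [AnnotationSet-class].
#' @param graph An [OntologyGraph-class].
#' @param relations Relations to traverse.
#' @return The [AnnotationSet-class] with the propagated map filled.
#' @export
propagateAnnotations <- function(ann, graph,
                                 relations = c("is_a", "part_of")) {
  used <- unique(unlist(ann@direct, use.names = FALSE))
  anc <- .ancestorSets(graph, used, relations)
  prop <- lapply(ann@direct, function(ts) {
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
  new("AnnotationSet", direct = ann@direct, propagated = prop,
      isPropagated = TRUE, dropped = ann@dropped)
}

#' Write annotations as two-column TSV
#'
#' @param ann An [AnnotationSet-class] (direct annotations are written).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationsTSV <- function(ann, path) {
  genes <- rep(names(ann@direct), lengths(ann@direct))
  gos <- unlist(ann@direct, use.names = FALSE)
  writeLines(c("gene_id\tgo_id", paste(genes, gos, sep = "\t")), path)
  invisible(path)
}
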
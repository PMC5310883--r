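# Stanza-based reader/writer for OBO 1.2/1.4 flat files. Only the tags the
# enrichment pipeline needs are interpreted; everything else is skipped.

#' Parse an OBO ontology file
#'
#' Reads \code{[Term]} stanzas from an OBO 1.2/1.4 flat file into an
#' [OntologyGraph-class]. Recognized tags: \code{id}, \code{name},
#' \code{namespace} (falling back to the header's
#' \code{default-namespace}), \code{is_a}, \code{relationship} (e.g.
#' \code{part_of}), \code{alt_id}, \code{replaced_by} and
#' \code{is_obsolete}. Trailing \code{!} comments are stripped. Obsolete
#' terms are kept but flagged; they are excluded from level computation and
#' enrichment, and annotations pointing at them are remapped where an
#' alternative accession allows. A malformed accession raises a parse error
#' naming the offending line; a cycle in the is_a closure raises an
#' integrity error.
#'
#' @param path Path to an OBO file.
#' @return An [OntologyGraph-class].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2",
#'   "default-namespace: biological_process", "",
#'   "[Term]", "id: GO:0000001", "name: root", "",
#'   "[Term]", "id: GO:0000002", "name: child", "is_a: GO:0000001"), obo)
#' parseOBO(obo)
#' @export
parseOBO <- function(path) {
  if (!file.exists(path)) .parseError(sprintf("OBO file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  # strip trailing comments (unescaped '!') and surrounding whitespace
  stripped <- trimws(sub("(?<!\\\\)!.*$", "", lines, perl = TRUE))

  defaultNs <- NA_character_
  stanzaType <- NA_character_   # NA = header
  cur <- NULL
  terms <- list()

  newTerm <- function() list(id = NA_character_, name = "",
                             namespace = NA_character_, obsolete = FALSE,
                             parents = character(), relations = character(),
                             altIds = character(), replacedBy = character())

  checkAcc <- function(acc, lineno, what) {
    if (!.isGOAccession(acc))
      .parseError(sprintf("line %d: malformed %s accession '%s'",
                          lineno, what, acc))
    acc
  }

  flush <- function() {
    if (!is.null(cur) && identical(stanzaType, "Term")) {
      if (is.na(cur$id)) .parseError("a [Term] stanza has no id tag")
      terms[[length(terms) + 1L]] <<- cur
    }
    cur <<- NULL
  }

  for (i in seq_along(stripped)) {
    line <- stripped[i]
    if (line == "") next
    if (grepl("^\\[.*\\]$", line)) {
      flush()
      stanzaType <- sub("^\\[(.*)\\]$", "\\1", line)
      if (identical(stanzaType, "Term")) cur <- newTerm()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_-]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3L)
      .parseError(sprintf("line %d: malformed stanza line '%s'", i, lines[i]))
    key <- m[2]; val <- trimws(m[3])

    if (is.na(stanzaType)) {                   # header
      if (key == "default-namespace") defaultNs <- val
      next
    }
    if (!identical(stanzaType, "Term")) next   # e.g. [Typedef]: skipped
    switch(key,
      id = { cur$id <- checkAcc(val, i, "term") },
      name = { cur$name <- val },
      namespace = { cur$namespace <- val },
      is_a = {
        cur$parents <- c(cur$parents, checkAcc(val, i, "is_a"))
        cur$relations <- c(cur$relations, "is_a")
      },
      relationship = {
        parts <- strsplit(val, "\\s+")[[1]]
        if (length(parts) < 2L)
          .parseError(sprintf("line %d: malformed relationship '%s'", i, val))
        cur$parents <- c(cur$parents, checkAcc(parts[2], i, parts[1]))
        cur$relations <- c(cur$relations, parts[1])
      },
      alt_id = { cur$altIds <- c(cur$altIds, checkAcc(val, i, "alt_id")) },
      replaced_by = { cur$replacedBy <- c(cur$replacedBy,
                                          checkAcc(val, i, "replaced_by")) },
      is_obsolete = { cur$obsolete <- identical(tolower(val), "true") },
      NULL)                                    # unknown tags skipped
  }
  flush()

  if (length(terms) == 0L) .parseError("no [Term] stanzas found")

  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    .parseError(sprintf("duplicated term id '%s'", ids[duplicated(ids)][1L]))

  nsRaw <- vapply(terms, `[[`, character(1), "namespace")
  nsRaw[is.na(nsRaw)] <- defaultNs
  if (any(is.na(nsRaw)))
    .parseError(sprintf(
      "term %s has no namespace and the file has no default-namespace",
      ids[which(is.na(nsRaw))[1L]]))
  if (!all(nsRaw %in% .NAMESPACES))
    .parseError(sprintf("unknown namespace '%s'",
                        setdiff(nsRaw, .NAMESPACES)[1L]))

  termDf <- data.frame(
    term_id = ids,
    name = vapply(terms, `[[`, character(1), "name"),
    namespace = nsRaw,
    obsolete = vapply(terms, `[[`, logical(1), "obsolete"),
    stringsAsFactors = FALSE)

  edgeDf <- do.call(rbind, lapply(terms, function(tm) {
    if (length(tm$parents) == 0L) return(NULL)
    data.frame(child = tm$id, parent = tm$parents, relation = tm$relations,
               stringsAsFactors = FALSE)
  }))

  altIds <- unlist(lapply(terms, function(tm)
    structure(rep(tm$id, length(tm$altIds)), names = tm$altIds)))
  if (is.null(altIds)) altIds <- character()
  replacedBy <- unlist(lapply(terms, function(tm)
    structure(tm$replacedBy[1L][length(tm$replacedBy) > 0],
              names = tm$id[length(tm$replacedBy) > 0])))
  if (is.null(replacedBy)) replacedBy <- character()

  OntologyGraph(termDf, edgeDf, altIds = altIds, replacedBy = replacedBy)
}

#' Serialize an OntologyGraph to OBO
#'
#' Writes a minimal, deterministic OBO 1.2 rendering (terms sorted by
#' accession) that [parseOBO()] reads back into an isomorphic graph.
#'
#' @param graph An [OntologyGraph-class].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeOBO <- function(graph, path) {
  terms <- graph@terms[order(graph@terms$term_id), , drop = FALSE]
  edges <- graph@edges
  alt <- graph@altIds
  out <- c("format-version: 1.2")
  for (i in seq_len(nrow(terms))) {
    id <- terms$term_id[i]
    out <- c(out, "", "[Term]", paste0("id: ", id),
             paste0("name: ", terms$name[i]),
             paste0("namespace: ", terms$namespace[i]))
    myAlt <- sort(names(alt)[alt == id])
    if (length(myAlt)) out <- c(out, paste0("alt_id: ", myAlt))
    e <- edges[edges$child == id, , drop = FALSE]
    if (nrow(e)) {
      e <- e[order(e$relation, e$parent), , drop = FALSE]
      tag <- ifelse(e$relation == "is_a",
                    paste0("is_a: ", e$parent),
                    paste0("relationship: ", e$relation, " ", e$parent))
      out <- c(out, tag)
    }
    if (terms$obsolete[i]) out <- c(out, "is_obsolete: true")
    if (id %in% names(graph@replacedBy))
      out <- c(out, paste0("replaced_by: ", graph@replacedBy[[id]]))
  }
  writeLines(out, path)
  invisible(path)
}
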
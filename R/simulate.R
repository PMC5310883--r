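# Deterministic synthetic fixtures: layered toy ontologies, annotations and
# expression matrices with an optional planted fold-change signal, so every
# stage of the pipeline is testable without downloading GO or annotation
# snapshots. Fixtures are written as standard OBO / TSV and follow the same
# code paths as real data.

#' Scenario specification for the synthetic-data generator
#'
#' Describes a single-namespace layered DAG (one root, a fixed number of
#' terms per level, each non-root term with 1-2 parents in the level
#' above), gene annotations concentrated on the deepest level, and a
#' genes-by-samples abundance matrix evolving across K ordered samples.
#'
#' Baseline abundances are log-normal with median ~10 RPKM and log-sd 1.5,
#' resembling the dynamic range of typical RPKM tables. Sample-to-sample
#' evolution acts on the log2(e + 1) scale (the scale on which genes enter
#' the enrichment score): each step adds Gaussian noise with sd
#' \code{noiseSd}, and for the genes of \code{plantedTerm} multiplies
#' log2(e + 1) by \code{plantedFold}. That planting scales the planted
#' term's enrichment score by exactly \code{plantedFold} per step, so its
#' theoretical average fold change equals \code{plantedFold} in the
#' noiseless limit while all other terms sit at 1.
#'
#' @slot nTermsPerLevel integer vector, terms per level from the root down
#'   (first element must be 1).
#' @slot nGenes total genes (annotated deepest-level genes plus
#'   unannotated background genes).
#' @slot genesPerTerm genes directly annotated to each deepest-level term.
#' @slot K number of ordered samples.
#' @slot baselineMeanlog,baselineSdlog log-normal baseline parameters
#'   (natural-log scale).
#' @slot plantedTerm accession of the term carrying the signal, or NA.
#' @slot plantedFold per-step multiplicative signal (> 0) on the enrichment
#'   score of the planted term.
#' @slot noiseSd per-step Gaussian noise sd on the log2(e + 1) scale.
#' @slot seed RNG seed; identical seeds give identical scenarios.
#' @export
setClass("ScenarioSpec",
  representation(nTermsPerLevel = "integer", nGenes = "integer",
                 genesPerTerm = "integer", K = "integer",
                 baselineMeanlog = "numeric", baselineSdlog = "numeric",
                 plantedTerm = "character", plantedFold = "numeric",
                 noiseSd = "numeric", seed = "integer")
)

setValidity("ScenarioSpec", function(object) {
  msgs <- character()
  if (length(object@nTermsPerLevel) < 2L)
    msgs <- c(msgs, "need depth >= 2 (root plus at least one level)")
  if (length(object@nTermsPerLevel) &&
      object@nTermsPerLevel[1L] != 1L)
    msgs <- c(msgs, "the first level must hold exactly the root")
  if (any(object@nTermsPerLevel < 1L))
    msgs <- c(msgs, "every level needs at least one term")
  if (object@plantedFold <= 0)
    msgs <- c(msgs, "plantedFold must be > 0")
  if (object@K < 2L) msgs <- c(msgs, "K must be >= 2")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

# deterministic accessions: level-major, GO:0000001 = root
.specTermIds <- function(nPerLevel) {
  total <- sum(nPerLevel)
  ids <- sprintf("GO:%07d", seq_len(total))
  split(ids, rep(seq_along(nPerLevel) - 1L, nPerLevel))
}

#' Build a ScenarioSpec
#'
#' @param nTermsPerLevel Terms per level, root first (default c(1, 3, 9)).
#' @param genesPerTerm Genes per deepest-level term (default 20).
#' @param nGenes Total genes; default = annotated genes only.
#' @param K Number of ordered samples (default 3).
#' @param baselineMeanlog,baselineSdlog Log-normal baseline (default
#'   median 10 RPKM, log-sd 1.5).
#' @param plantedTerm Accession, NA for no signal, or \code{"deepest"} for
#'   the first deepest-level term.
#' @param plantedFold Per-step fold signal (default 4).
#' @param noiseSd Per-step noise sd on the log2(e + 1) scale (default 0.1).
#' @param seed RNG seed.
#' @return A [ScenarioSpec-class].
#' @export
scenarioSpec <- function(nTermsPerLevel = c(1L, 3L, 9L), genesPerTerm = 20L,
                         nGenes = NULL, K = 3L,
                         baselineMeanlog = log(10), baselineSdlog = 1.5,
                         plantedTerm = NA_character_, plantedFold = 4,
                         noiseSd = 0.1, seed = 1L) {
  nTermsPerLevel <- as.integer(nTermsPerLevel)
  nDeep <- nTermsPerLevel[length(nTermsPerLevel)]
  if (is.null(nGenes)) nGenes <- nDeep * as.integer(genesPerTerm)
  if (identical(plantedTerm, "deepest"))
    plantedTerm <- .specTermIds(nTermsPerLevel)[[length(nTermsPerLevel)]][1L]
  spec <- new("ScenarioSpec", nTermsPerLevel = nTermsPerLevel,
              nGenes = as.integer(nGenes),
              genesPerTerm = as.integer(genesPerTerm), K = as.integer(K),
              baselineMeanlog = baselineMeanlog,
              baselineSdlog = baselineSdlog,
              plantedTerm = as.character(plantedTerm),
              plantedFold = plantedFold, noiseSd = noiseSd,
              seed = as.integer(seed))
  if (spec@nGenes < nDeep * spec@genesPerTerm)
    .domainError("nGenes smaller than the number of annotated genes requested")
  spec
}

#' Generate a toy ontology and its annotations
#'
#' Builds the layered single-namespace DAG described by \code{spec}: each
#' non-root term gets one round-robin parent in the level above (so every
#' term has descendants) plus, with probability 1/3, a second random
#' parent; each deepest-level term directly annotates its own block of
#' \code{genesPerTerm} genes (ids \code{g00001}, ...). Deterministic under
#' the spec's seed.
#'
#' @param spec A [ScenarioSpec-class].
#' @return List with elements \code{graph} ([OntologyGraph-class]),
#'   \code{annotations} ([AnnotationSet-class], direct only),
#'   \code{termsByLevel} (list of accessions per level) and
#'   \code{plantedTerm}.
#' @export
simulateOntology <- function(spec) {
  validObject(spec)
  byLevel <- .specTermIds(spec@nTermsPerLevel)
  depth <- length(byLevel)
  allIds <- unlist(byLevel, use.names = FALSE)

  edges <- .withSeed(spec@seed, {
    rows <- list()
    for (L in 2:depth) {
      children <- byLevel[[L]]
      parents <- byLevel[[L - 1L]]
      for (j in seq_along(children)) {
        p1 <- parents[((j - 1L) %% length(parents)) + 1L]
        ps <- p1
        if (length(parents) > 1L && stats::runif(1) < 1 / 3) {
          extra <- sample(setdiff(parents, p1), 1L)
          ps <- c(ps, extra)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          child = children[j], parent = ps, relation = "is_a",
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  terms <- data.frame(
    term_id = allIds,
    name = paste0("toy term ", sub("^GO:0*", "", allIds)),
    namespace = "biological_process",
    obsolete = FALSE, stringsAsFactors = FALSE)
  graph <- OntologyGraph(terms, edges)

  deepest <- byLevel[[depth]]
  geneIds <- sprintf("g%05d", seq_len(spec@nGenes))
  direct <- list()
  for (j in seq_along(deepest)) {
    block <- geneIds[((j - 1L) * spec@genesPerTerm + 1L):
                     (j * spec@genesPerTerm)]
    for (g in block) direct[[g]] <- deepest[j]
  }
  direct <- direct[order(names(direct))]
  ann <- new("AnnotationSet", direct = direct, propagated = list(),
             isPropagated = FALSE, dropped = 0L)

  planted <- spec@plantedTerm
  if (!is.na(planted) && !planted %in% allIds)
    .domainError(sprintf("planted term %s not in the generated ontology",
                         planted))
  list(graph = graph, annotations = ann, termsByLevel = byLevel,
       plantedTerm = planted)
}

#' Generate an expression matrix for a scenario
#'
#' Baseline abundances are drawn log-normal; each later sample evolves the
#' previous one on the log2(e + 1) scale with i.i.d. Gaussian noise
#' (\code{noiseSd}) and, for genes of the planted term, multiplication by
#' \code{plantedFold}. Log-abundances pushed below zero by noise are
#' clipped at zero (i.e. expression 0) and the clip count logged. With
#' \code{noiseSd = 0} the planted term's average fold change equals
#' \code{plantedFold} exactly and every other term's equals 1.
#'
#' @param spec A [ScenarioSpec-class].
#' @param ann The [AnnotationSet-class] from [simulateOntology()] (used to
#'   locate the planted term's genes).
#' @return An [ExpressionMatrix-class] in abundance mode, samples
#'   \code{S1..SK}.
#' @export
simulateExpression <- function(spec, ann) {
  validObject(spec)
  geneIds <- sprintf("g%05d", seq_len(spec@nGenes))
  plantedGenes <- if (is.na(spec@plantedTerm)) character() else
    names(ann@direct)[vapply(ann@direct, function(ts)
      spec@plantedTerm %in% ts, logical(1))]
  foldPerGene <- ifelse(geneIds %in% plantedGenes, spec@plantedFold, 1)

  L <- .withSeed(spec@seed + 1L, {
    base <- log2(stats::rlnorm(spec@nGenes, spec@baselineMeanlog,
                               spec@baselineSdlog) + 1)
    out <- matrix(0, spec@nGenes, spec@K)
    out[, 1L] <- base
    nClipped <- 0L
    for (s in 2:spec@K) {
      step <- out[, s - 1L] * foldPerGene
      if (spec@noiseSd > 0)
        step <- step + stats::rnorm(spec@nGenes, 0, spec@noiseSd)
      clip <- step < 0
      nClipped <- nClipped + sum(clip)
      step[clip] <- 0
      out[, s] <- step
    }
    if (nClipped)
      .log("INFO", sprintf("clipped %d negative log-abundance value(s) to 0",
                           nClipped))
    out
  })
  e <- 2^L - 1
  e[e < 0] <- 0   # numerical guard
  dimnames(e) <- list(geneIds, paste0("S", seq_len(spec@K)))
  ExpressionMatrix(e, mode = "abundance")
}

#' Generate a complete scenario
#'
#' Convenience wrapper: ontology + annotations + expression matrix.
#'
#' @param spec A [ScenarioSpec-class].
#' @return List with \code{graph}, \code{annotations}, \code{expr},
#'   \code{termsByLevel}, \code{plantedTerm}.
#' @export
simulateScenario <- function(spec) {
  sim <- simulateOntology(spec)
  sim$expr <- simulateExpression(spec, sim$annotations)
  sim
}
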
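# In-code fixtures and independent oracles shared across the suite.

options(ewGO.logLevel = "WARN")

# write OBO text to a temp file, return the path
oboFile <- function(...) {
  path <- tempfile(fileext = ".obo")
  writeLines(c(...), path)
  path
}

# root <- A <- B <- C chain, biological_process
chainOBO <- function() {
  oboFile(
    "format-version: 1.2",
    "default-namespace: biological_process",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "",
    "[Term]", "id: GO:0000002", "name: A", "is_a: GO:0000001",
    "",
    "[Term]", "id: GO:0000003", "name: B", "is_a: GO:0000002",
    "",
    "[Term]", "id: GO:0000004", "name: C", "is_a: GO:0000003")
}

# diamond: root <- A, root <- B, A <- C, B <- C
diamondOBO <- function() {
  oboFile(
    "format-version: 1.2",
    "default-namespace: biological_process",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "",
    "[Term]", "id: GO:0000002", "name: A", "is_a: GO:0000001",
    "",
    "[Term]", "id: GO:0000003", "name: B", "is_a: GO:0000001",
    "",
    "[Term]", "id: GO:0000004", "name: C", "is_a: GO:0000002",
    "is_a: GO:0000003")
}

tsvFile <- function(...) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(...), path)
  path
}

# minimal AnnotationSet from a named list gene -> term vector
annSet <- function(direct) {
  direct <- lapply(direct, sort)
  if (length(direct)) direct <- direct[order(names(direct))]
  new("AnnotationSet", direct = direct,
      propagated = list(), isPropagated = FALSE, dropped = 0L)
}

exprMat <- function(values, mode = "abundance") {
  ExpressionMatrix(values, mode = mode)
}

# brute-force ancestor closure by repeated expansion to fixpoint,
# independent of the igraph-based implementation
bruteClosure <- function(graph, terms, relations = c("is_a", "part_of")) {
  edges <- goEdges(graph)
  edges <- edges[edges$relation %in% relations, , drop = FALSE]
  ns <- structure(goTerms(graph)$namespace, names = goTerms(graph)$term_id)
  edges <- edges[ns[edges$child] == ns[edges$parent], , drop = FALSE]
  out <- terms
  repeat {
    more <- unique(edges$parent[edges$child %in% out])
    grown <- union(out, more)
    if (length(grown) == length(out)) return(sort(out))
    out <- grown
  }
}

# brute-force two-sample KS D by sweeping both ECDFs over all breakpoints
bruteKS <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
}

# textbook chi-square homogeneity statistic on a 2 x m table
bruteChi2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# t quantile by numerical integration of the closed-form density plus
# root-finding; independent of stats::qt
tQuantileOracle <- function(p, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  # CDF(q) = 1/2 + integral of the density over (0, q); bracket the root by
  # doubling, then bisect with uniroot
  cdf <- function(q) 0.5 + stats::integrate(dens, 0, q,
                                            rel.tol = 1e-12,
                                            abs.tol = 1e-14)$value
  f <- function(q) cdf(q) - p
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, lower = hi / 2, upper = hi, tol = 1e-10)$root
}

grubbsCriticalOracle <- function(n, alpha) {
  t <- tQuantileOracle(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

# random layered scenario used by several property tests
randomScenario <- function(seed, noiseSd = 0.2, planted = NA_character_) {
  scenarioSpec(nTermsPerLevel = c(1L, 2L, 4L), genesPerTerm = 3L,
               K = 3L, plantedTerm = planted, plantedFold = 2,
               noiseSd = noiseSd, seed = seed)
}
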
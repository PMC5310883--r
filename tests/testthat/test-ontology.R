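# OBO parsing, term levels, annotation loading and true-path propagation.

test_that("parseOBO reads a minimal chain and flags obsolete terms", {
  g <- parseOBO(chainOBO())
  expect_s4_class(g, "OntologyGraph")
  expect_equal(nrow(goTerms(g)), 4L)
  expect_equal(unname(goRoots(g)["biological_process"]), "GO:0000001")

  obs <- parseOBO(oboFile(
    "format-version: 1.2",
    "default-namespace: biological_process",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "",
    "[Term]", "id: GO:0000002", "name: gone", "is_obsolete: true"))
  tt <- goTerms(obs)
  expect_true(tt$obsolete[tt$term_id == "GO:0000002"])
  # obsolete terms need no parent and carry no level
  lv <- computeLevels(obs)
  expect_false("GO:0000002" %in% names(lv@level))
})

test_that("parseOBO rejects malformed accessions, naming the line", {
  bad <- oboFile(
    "format-version: 1.2",
    "default-namespace: biological_process",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "",
    "[Term]", "id: GO:0000002", "name: A", "is_a: GO:xxxx")
  expect_error(parseOBO(bad), "line 11.*GO:xxxx",
               class = "ewgo_parse_error")
})

test_that("cycles in the is_a closure raise an integrity error", {
  cyc <- oboFile(
    "format-version: 1.2",
    "default-namespace: biological_process",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "",
    "[Term]", "id: GO:0000002", "name: A", "is_a: GO:0000001",
    "is_a: GO:0000003",
    "",
    "[Term]", "id: GO:0000003", "name: B", "is_a: GO:0000002")
  expect_error(parseOBO(cyc), "cycle", class = "ewgo_integrity_error")
})

test_that("levels are shortest paths to the namespace root", {
  g <- parseOBO(chainOBO())
  lv <- computeLevels(g)
  expect_equal(unname(lv@level[c("GO:0000001", "GO:0000002",
                                 "GO:0000003", "GO:0000004")]),
               0:3)
  expect_equal(maxLevel(lv, "biological_process"), 3L)

  d <- computeLevels(parseOBO(diamondOBO()))
  expect_equal(unname(d@level["GO:0000004"]), 2L)

  # parents at levels 1 and 4 -> child level 2 (min over parents + 1)
  mixed <- parseOBO(oboFile(
    "format-version: 1.2",
    "default-namespace: biological_process",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "",
    "[Term]", "id: GO:0000002", "name: L1", "is_a: GO:0000001",
    "",
    "[Term]", "id: GO:0000003", "name: L2", "is_a: GO:0000002",
    "",
    "[Term]", "id: GO:0000004", "name: L3", "is_a: GO:0000003",
    "",
    "[Term]", "id: GO:0000005", "name: L4", "is_a: GO:0000004",
    "",
    "[Term]", "id: GO:0000006", "name: X", "is_a: GO:0000002",
    "is_a: GO:0000005"))
  lv <- computeLevels(mixed)
  expect_equal(unname(lv@level["GO:0000006"]), 2L)
})

test_that("level(t) = 1 + min(level(parent)) holds on random DAGs", {
  for (seed in 1:10) {
    sim <- simulateOntology(randomScenario(seed))
    lv <- computeLevels(sim$graph)
    e <- goEdges(sim$graph)
    minParent <- tapply(lv@level[e$parent], e$child, min)
    expect_equal(unname(lv@level[names(minParent)]),
                 as.vector(minParent) + 1L)
  }
})

test_that("unreachable terms and multiple roots are integrity errors", {
  # part_of-only link, levels computed over is_a alone -> unreachable
  g <- parseOBO(oboFile(
    "format-version: 1.2",
    "default-namespace: biological_process",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "",
    "[Term]", "id: GO:0000002", "name: A",
    "relationship: part_of GO:0000001"))
  expect_error(computeLevels(g, relations = "is_a"),
               class = "ewgo_integrity_error")
  expect_equal(unname(computeLevels(g)@level["GO:0000002"]), 1L)
})

test_that("termsAtLevel returns exactly one level and checks its range", {
  g <- parseOBO(chainOBO())
  lv <- computeLevels(g)
  expect_equal(termsAtLevel(g, lv, "biological_process", 0), "GO:0000001")
  top <- maxLevel(lv, "biological_process")
  expect_gt(length(termsAtLevel(g, lv, "biological_process", top)), 0L)
  expect_error(termsAtLevel(g, lv, "biological_process", top + 1),
               class = "ewgo_domain_error")
})

test_that("loadAnnotations reads TSV, resolves alt_ids, drops unknowns", {
  g <- parseOBO(oboFile(
    "format-version: 1.2",
    "default-namespace: biological_process",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "",
    "[Term]", "id: GO:0000002", "name: A", "is_a: GO:0000001",
    "alt_id: GO:0000099",
    "",
    "[Term]", "id: GO:0000003", "name: B", "is_a: GO:0000001"))
  ann <- loadAnnotations(tsvFile(
    "gene_id\tgo_id",
    "g1\tGO:0000002", "g1\tGO:0000003", "g2\tGO:0000002"), "tsv", g)
  expect_equal(directAnnotations(ann),
               list(g1 = c("GO:0000002", "GO:0000003"),
                    g2 = "GO:0000002"))

  # alt_id accession maps to its canonical term
  ann <- loadAnnotations(tsvFile("g9\tGO:0000099"), "tsv", g)
  expect_equal(directAnnotations(ann)$g9, "GO:0000002")

  # unknown accession dropped with a warning, not fatal
  expect_warning(
    ann <- loadAnnotations(tsvFile("g1\tGO:0000002", "g2\tGO:1234567"),
                           "tsv", g),
    "unknown")
  expect_equal(annotatedGenes(ann), "g1")
  expect_equal(ann@dropped, 1L)

  expect_error(loadAnnotations(tsvFile("g1\tGO:0000002\textra"), "tsv", g),
               class = "ewgo_parse_error")
})

test_that("GAF rows are read by column position and NOT rows excluded", {
  g <- parseOBO(chainOBO())
  gafRow <- function(gene, qual, go)
    paste(c("DB", gene, gene, qual, go, "REF", "IEA", "", "P", "", "",
            "protein", "taxon:9606", "20200101", "DB", "", ""),
          collapse = "\t")
  gaf <- tsvFile("!gaf-version: 2.1",
                 gafRow("g1", "", "GO:0000002"),
                 gafRow("g2", "NOT", "GO:0000002"),
                 gafRow("g2", "NOT|contributes_to", "GO:0000003"),
                 gafRow("g3", "contributes_to", "GO:0000004"))
  ann <- loadAnnotations(gaf, "gaf", g)
  expect_equal(annotatedGenes(ann), c("g1", "g3"))
  expect_error(loadAnnotations(tsvFile("only\tthree\tcolumns"), "gaf", g),
               class = "ewgo_parse_error")
})

test_that("annotations to obsolete terms are remapped or dropped", {
  g <- parseOBO(oboFile(
    "format-version: 1.2",
    "default-namespace: biological_process",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "",
    "[Term]", "id: GO:0000002", "name: live", "is_a: GO:0000001",
    "",
    "[Term]", "id: GO:0000003", "name: dead", "is_obsolete: true",
    "replaced_by: GO:0000002",
    "",
    "[Term]", "id: GO:0000004", "name: gone", "is_obsolete: true"))
  ann <- loadAnnotations(tsvFile("g1\tGO:0000003", "g2\tGO:0000004"),
                         "tsv", g)
  expect_equal(directAnnotations(ann), list(g1 = "GO:0000002"))
  expect_equal(ann@dropped, 1L)
})

test_that("propagation closes annotations over ancestors and is idempotent", {
  g <- parseOBO(chainOBO())
  ann <- annSet(list(g1 = "GO:0000004", g2 = character()))
  p <- propagateAnnotations(ann, g)
  expect_equal(propagatedAnnotations(p)$g1,
               c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"))
  expect_equal(propagatedAnnotations(p)$g2, character(0))
  p2 <- propagateAnnotations(p, g)
  expect_identical(propagatedAnnotations(p2), propagatedAnnotations(p))
})

test_that("propagated sets equal the brute-force fixpoint closure", {
  for (seed in 1:10) {
    sim <- simulateOntology(randomScenario(seed))
    p <- propagateAnnotations(sim$annotations, sim$graph)
    prop <- propagatedAnnotations(p)
    for (gene in sample(names(prop), 5L)) {
      expect_equal(prop[[gene]],
                   bruteClosure(sim$graph,
                                directAnnotations(p)[[gene]]))
    }
  }
})

test_that("OBO write/parse round-trip preserves the graph", {
  sim <- simulateOntology(randomScenario(3))
  path <- tempfile(fileext = ".obo")
  writeOBO(sim$graph, path)
  g2 <- parseOBO(path)
  t1 <- goTerms(sim$graph); t1 <- t1[order(t1$term_id), ]
  t2 <- goTerms(g2); t2 <- t2[order(t2$term_id), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
  key <- function(g) {
    e <- goEdges(g)
    sort(paste(e$child, e$relation, e$parent))
  }
  expect_equal(key(sim$graph), key(g2))
})
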
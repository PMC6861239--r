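test_that("read_obo parses terms, edges, obsolete flags and alt ids", {
  path <- write_test_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: child one",
    "namespace: biological_process", "alt_id: GO:0000099",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: child two",
    "namespace: biological_process",
    "relationship: part_of GO:0000001 ! root", "",
    "[Term]", "id: GO:0000004", "name: gone",
    "namespace: biological_process", "is_obsolete: true",
    "is_a: GO:0000001", "",
    "[Typedef]", "id: part_of"))
  dag <- read_obo(path)
  expect_setequal(dag$terms, sprintf("GO:%07d", 1:4))
  expect_equal(dag$parents[["GO:0000002"]]$parent, "GO:0000001")
  expect_equal(dag$parents[["GO:0000002"]]$relation, "is_a")
  expect_equal(dag$parents[["GO:0000003"]]$relation, "part_of")
  # obsolete term present, flagged, and carries no edges
  expect_true(dag$obsolete[["GO:0000004"]])
  expect_equal(nrow(dag$parents[["GO:0000004"]]), 0L)
  # alt_id resolves to canonical id
  expect_equal(resolve_term(dag, "GO:0000099"), "GO:0000002")
  expect_equal(resolve_term(dag, "GO:0000002"), "GO:0000002")
  expect_true(is.na(resolve_term(dag, "GO:1234567")))
})

test_that("read_obo warns on unknown relations and errors on cycles", {
  path <- write_test_obo(c(
    "[Term]", "id: A", "name: a", "namespace: biological_process", "",
    "[Term]", "id: B", "name: b", "namespace: biological_process",
    "is_a: A", "relationship: regulates A"))
  expect_warning(read_obo(path), "regulates")

  cyc <- write_test_obo(c(
    "[Term]", "id: A", "name: a", "namespace: biological_process",
    "is_a: B", "",
    "[Term]", "id: B", "name: b", "namespace: biological_process",
    "is_a: A"))
  expect_error(read_obo(cyc), "cyclic")
})

test_that("svalues matches the closed-form chain and handles roots", {
  dag <- go_dag_from_edges(chain_edges())
  sv <- svalues(dag, "A")
  expect_equal(sv$s[["A"]], 1)
  expect_equal(sv$s[["B"]], 0.8, tolerance = 1e-12)
  expect_equal(sv$s[["R"]], 0.64, tolerance = 1e-12)
  expect_equal(sv$sv, 2.44, tolerance = 1e-12)

  root_only <- svalues(dag, "R")
  expect_equal(root_only$s, c(R = 1))
  expect_equal(root_only$sv, 1)

  expect_error(svalues(dag, "ZZZ"), "absent")
  dag2 <- go_dag_from_edges(chain_edges(), terms = c("A", "B", "R", "OBS"),
                            obsolete = "OBS")
  expect_error(svalues(dag2, "OBS"), "obsolete")
})

test_that("svalues takes the max-product path through a diamond", {
  dag <- go_dag_from_edges(diamond_edges())
  sv <- svalues(dag, "D")
  # via B: 0.8 * 0.8 = 0.64; via C: 0.6 * 0.8 = 0.48 -> max wins
  expect_equal(sv$s[["R"]], 0.64, tolerance = 1e-12)
  expect_equal(sv$s[["B"]], 0.8, tolerance = 1e-12)
  expect_equal(sv$s[["C"]], 0.6, tolerance = 1e-12)
  oracle <- oracle_svalues(diamond_edges(), "D")
  expect_equal(sv$s[order(names(sv$s))], oracle, tolerance = 1e-12)
})

test_that("svalues agrees with the exhaustive-path oracle on random DAGs", {
  for (seed in c(11L, 23L, 47L)) {
    dag <- random_go_dag(seed, widths = c(4L, 9L, 15L))  # <= 30 terms
    edges <- do.call(rbind, lapply(dag$terms, function(t) {
      ps <- dag$parents[[t]]
      if (!nrow(ps)) return(NULL)
      data.frame(child = t, parent = ps$parent, relation = ps$relation,
                 stringsAsFactors = FALSE)
    }))
    for (t in dag$terms) {
      sv <- svalues(dag, t)
      oracle <- oracle_svalues(edges, t)
      expect_equal(sv$s[order(names(sv$s))], oracle, tolerance = 1e-12)
      expect_equal(sv$sv, sum(oracle), tolerance = 1e-12)
    }
  }
})

test_that("term similarity: identity, siblings, disjoint, cross-namespace", {
  dag <- go_dag_from_edges(sibling_edges())
  expect_equal(term_similarity(dag, "A", "A"), 1.0)
  # common = {R}: (0.8 + 0.8) / (1.8 + 1.8)
  expect_equal(term_similarity(dag, "A", "B"), 1.6 / 3.6, tolerance = 1e-12)
  expect_equal(term_similarity(dag, "A", "B"),
               oracle_term_similarity(sibling_edges(), "A", "B"),
               tolerance = 1e-12)

  two_comp <- go_dag_from_edges(data.frame(
    child = c("A", "B"), parent = c("R1", "R2"), relation = "is_a",
    stringsAsFactors = FALSE))
  expect_equal(term_similarity(two_comp, "A", "B"), 0)

  mixed <- go_dag_from_edges(
    sibling_edges(), namespace = c(A = "biological_process",
                                   B = "molecular_function",
                                   R = "biological_process"))
  expect_warning(s <- term_similarity(mixed, "A", "B"), "namespace")
  expect_equal(s, 0)
})

test_that("similarities are symmetric and bounded on a random DAG", {
  dag <- random_go_dag(5L, widths = c(5L, 12L, 20L))
  set.seed(99)
  pairs <- cbind(sample(dag$terms, 1000L, replace = TRUE),
                 sample(dag$terms, 1000L, replace = TRUE))
  # full recomputation in both orders on a subsample ...
  for (i in seq_len(100L)) {
    ab <- term_similarity(dag, pairs[i, 1], pairs[i, 2])
    ba <- term_similarity(dag, pairs[i, 2], pairs[i, 1])
    expect_equal(ab, ba, tolerance = 1e-15)
  }
  # ... bounds and self-similarity across all 1000 pairs
  cache <- wang_cache(dag, structure(list(), class = "gene_annotation"))
  for (i in seq_len(nrow(pairs))) {
    ab <- cache$term_sim(pairs[i, 1], pairs[i, 2])
    expect_gte(ab, 0); expect_lte(ab, 1)
    if (pairs[i, 1] == pairs[i, 2]) expect_equal(ab, 1)
  }
})

test_that("gene and gene-set similarity follow the BMA definition", {
  dag <- go_dag_from_edges(sibling_edges())
  annot <- gene_annotation(list(g1 = "A", g2 = "B", g3 = c("A", "B"),
                                g4 = "A"), dag)
  # singleton sets: equals the term similarity
  expect_equal(gene_set_similarity(dag, annot, "g1", "g2"),
               term_similarity(dag, "A", "B"), tolerance = 1e-12)
  # identical annotations -> 1
  expect_equal(gene_set_similarity(dag, annot, c("g1", "g3"), c("g1", "g3")),
               1.0)
  # 2x2 case against brute-force BMA of gene-level BMAs
  gs <- function(a, b) gene_similarity(dag, annot, a, b)
  m <- matrix(c(gs("g1", "g2"), gs("g1", "g3"),
                gs("g4", "g2"), gs("g4", "g3")), 2, 2, byrow = TRUE)
  expect_equal(gene_set_similarity(dag, annot, c("g1", "g4"), c("g2", "g3")),
               oracle_bma(m), tolerance = 1e-12)
})

test_that("unannotated genes are dropped; fully unannotated sets error", {
  dag <- go_dag_from_edges(sibling_edges())
  annot <- gene_annotation(list(g1 = "A", g2 = "B"), dag)
  expect_message(
    s <- gene_set_similarity(dag, annot, c("g1", "nope"), "g2"),
    "unannotated")
  expect_equal(s, gene_set_similarity(dag, annot, "g1", "g2"))
  expect_error(gene_set_similarity(dag, annot, "nope1", "nope2"),
               "no annotated genes")
})

test_that("pooled-terms set similarity is a valid alternative aggregation", {
  dag <- go_dag_from_edges(sibling_edges())
  annot <- gene_annotation(list(g1 = "A", g2 = "B", g3 = c("A", "B")), dag)
  s <- gene_set_similarity(dag, annot, c("g1", "g2"), "g3",
                           method = "pooled_terms")
  expect_gte(s, 0); expect_lte(s, 1)
  expect_equal(gene_set_similarity(dag, annot, c("g1", "g2"), c("g1", "g2"),
                                   method = "pooled_terms"), 1.0)
})

test_that("adding a shared ancestor never decreases term similarity", {
  # A and B unrelated below R0 vs additionally sharing a new parent X
  base <- data.frame(
    child = c("A", "B", "P", "Q"), parent = c("P", "Q", "R0", "R0"),
    relation = "is_a", stringsAsFactors = FALSE)
  with_shared <- rbind(base, data.frame(
    child = c("A", "B", "X"), parent = c("X", "X", "R0"),
    relation = "is_a", stringsAsFactors = FALSE))
  s0 <- term_similarity(go_dag_from_edges(base), "A", "B")
  s1 <- term_similarity(go_dag_from_edges(with_shared), "A", "B")
  expect_gte(s1, s0)
})

test_that("annotation readers accept 2-column TSV and GAF, filter namespace", {
  dag <- go_dag_from_edges(
    sibling_edges(),
    terms = c("A", "B", "R", "M"),
    namespace = c(A = "biological_process", B = "biological_process",
                  R = "biological_process", M = "molecular_function"))
  tsv <- tempfile()
  writeLines(c("gene\tgo_id", "g1\tA", "g1\tM", "g2\tB", "g3\tZZZ"), tsv)
  expect_message(ann <- read_gene_annotations(tsv, dag), "dropped")
  expect_equal(ann$g1, "A")   # MF annotation filtered out
  expect_equal(ann$g2, "B")
  expect_null(ann$g3)

  gaf <- tempfile()
  writeLines(c(
    "!gaf-version: 2.1",
    paste("DB", "g1", "g1", "", "A", "PMID:1", "IEA", "", "P", "g one",
          "", "protein", "taxon:9606", "20180101", "DB", sep = "\t"),
    paste("DB", "g2", "g2", "", "M", "PMID:1", "IDA", "", "F", "g two",
          "", "protein", "taxon:9606", "20180101", "DB", sep = "\t")),
    gaf)
  ann2 <- read_gene_annotations(gaf, dag)
  expect_equal(ann2$g1, "A")
  expect_null(ann2$g2)        # molecular_function aspect filtered
})
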
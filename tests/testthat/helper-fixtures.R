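# Small hand-built structures shared across test files.

# chain: A is_a B is_a R
chain_edges <- function() {
  data.frame(child = c("A", "B"), parent = c("B", "R"),
             relation = "is_a", stringsAsFactors = FALSE)
}

# siblings: A is_a R, B is_a R
sibling_edges <- function() {
  data.frame(child = c("A", "B"), parent = c("R", "R"),
             relation = "is_a", stringsAsFactors = FALSE)
}

# diamond: D reaches R via B (is_a, is_a) and via C (part_of, is_a)
diamond_edges <- function() {
  data.frame(child = c("D", "D", "B", "C"),
             parent = c("B", "C", "R", "R"),
             relation = c("is_a", "part_of", "is_a", "is_a"),
             stringsAsFactors = FALSE)
}

# path graph a - b - c - d as an igraph with sorted vertex names
path4_graph <- function() {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")),
    directed = FALSE)
  igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
}

path4_lcc <- function() list(graph = path4_graph(), diameter = 3L)

# a minimal OBO file written to a temp path
write_test_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

# stub similarity cache returning fixed gene-level similarities
stub_cache <- function(sims, annot_genes) {
  annot <- stats::setNames(rep(list("GO:1"), length(annot_genes)),
                           annot_genes)
  list(
    term_sim = function(a, b) 1,
    gene_sim = function(g1, g2) {
      key <- paste(sort(c(g1, g2)), collapse = "|")
      if (key %in% names(sims)) sims[[key]] else 0
    },
    annot = annot
  )
}
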
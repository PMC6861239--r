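#' Read a drug-target table
#'
#' Columns: `drug_id`, `name`, `target`, `action`, `status`,
#' `pharm_active` (logical or 0/1). By default only approved drugs with a
#' nonempty target and a pharmacologically active drug-target interaction are
#' retained, mirroring the loading filters applied to the source database.
#'
#' @param x Path to a TSV with a header, or a data frame.
#' @param approved_only,active_only Apply the respective filters.
#' @return Data frame, one row per drug-target pair.
#' @export
read_drug_table <- function(x, approved_only = TRUE, active_only = TRUE) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.table(x, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  }
  req <- c("drug_id", "name", "target", "action", "status", "pharm_active")
  stopifnot(all(req %in% names(x)))
  x$pharm_active <- as.logical(x$pharm_active)
  x <- x[nzchar(x$target) & !is.na(x$target), , drop = FALSE]
  if (approved_only) x <- x[x$status == "approved", , drop = FALSE]
  if (active_only) x <- x[x$pharm_active, , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read a drug expression-signature table
#'
#' Long format: one row per (signature, gene). Columns: `drug_id`,
#' `signature_id`, `is_gold` (0/1), `strength` (signature-strength value),
#' `direction` (`up`/`down`), `gene`, `rank`.
#'
#' @param x Path to a TSV with a header, or a data frame.
#' @return Data frame.
#' @export
read_signature_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.table(x, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  }
  req <- c("drug_id", "signature_id", "is_gold", "strength", "direction",
           "gene", "rank")
  stopifnot(all(req %in% names(x)))
  x
}

#' Select one expression signature for a drug
#'
#' Keeps gold-quality signatures only; among them takes the one with the
#' highest signature strength, breaking ties towards the lexicographically
#' smallest signature id.
#'
#' @param signatures Signature rows for one drug (long format as in
#'   [read_signature_table()]).
#' @return List with `signature_id`, `strength`, `up` and `down` gene
#'   vectors (rank order). When no gold signature exists, an object of class
#'   `drug_skip` with element `reason = "no_gold_signature"`.
#' @export
select_signature <- function(signatures) {
  stopifnot(nrow(signatures) >= 1L)
  gold <- signatures[as.integer(signatures$is_gold) == 1L, , drop = FALSE]
  if (!nrow(gold)) {
    return(structure(list(reason = "no_gold_signature"),
                     class = "drug_skip"))
  }
  per_sig <- unique(gold[, c("signature_id", "strength")])
  per_sig <- per_sig[order(-per_sig$strength, per_sig$signature_id), ,
                     drop = FALSE]
  chosen <- per_sig$signature_id[1L]
  rows <- gold[gold$signature_id == chosen, , drop = FALSE]
  rows <- rows[order(rows$rank), , drop = FALSE]
  list(signature_id = chosen,
       strength = per_sig$strength[1L],
       up = rows$gene[rows$direction == "up"],
       down = rows$gene[rows$direction == "down"])
}

#' Filter signature genes by semantic similarity to the drug target
#'
#' Pools the up- and down-regulated signature genes, intersects them with the
#' network node set, and retains the genes whose Wang/BMA gene-level
#' similarity to the target is at least `sim_min` (0.5, a medium-to-high
#' similarity). Direction is kept as metadata on the result.
#'
#' @param target Target gene symbol (must be a network node).
#' @param signature A list with `up`/`down` gene vectors
#'   (see [select_signature()]).
#' @param lcc LCC list from [lcc_and_diameter()] (or an igraph graph).
#' @param dag,annot Ontology and annotation for the similarity.
#' @param sim_min Inclusive similarity cut-off.
#' @param cache Optional [wang_cache()].
#' @return Data frame `gene`, `direction`, `similarity`, `retained`;
#'   attribute `excluded_reason` is `"target not in network"` when the target
#'   does not map (then the frame is empty).
#' @export
filter_signature <- function(target, signature, lcc, dag, annot,
                             sim_min = 0.5, cache = NULL) {
  g <- .as_graph(lcc)
  nodes <- igraph::V(g)$name
  empty <- data.frame(gene = character(0), direction = character(0),
                      similarity = numeric(0), retained = logical(0))
  if (!(target %in% nodes)) {
    attr(empty, "excluded_reason") <- "target not in network"
    return(empty)
  }
  part <- function(genes, direction) {
    if (!length(genes)) return(NULL)
    data.frame(gene = genes, direction = direction, stringsAsFactors = FALSE)
  }
  sig <- rbind(part(signature$up, "up"), part(signature$down, "down"))
  if (is.null(sig)) return(empty)
  sig <- sig[!duplicated(sig$gene), , drop = FALSE]
  sig <- sig[sig$gene %in% nodes & sig$gene != target, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  if (is.null(cache)) cache <- wang_cache(dag, annot)
  sig$similarity <- vapply(sig$gene, function(gn) cache$gene_sim(target, gn),
                           1.0)
  sig$retained <- !is.na(sig$similarity) & sig$similarity >= sim_min
  rownames(sig) <- NULL
  sig
}

#' Build a network drug module
#'
#' The module is the drug target, the retained signature genes, and the nodes
#' of one shortest path from the target to each retained gene. Among
#' equal-length shortest paths the lexicographically smallest node sequence
#' is chosen, which makes the module deterministic.
#'
#' @param lcc LCC list from [lcc_and_diameter()] (or an igraph graph); all
#'   inputs must lie in it.
#' @param target Target node name.
#' @param retained Character vector of retained signature gene names.
#' @param drug_id Identifier stored on the module.
#' @param dists Optional precomputed distance matrix over the LCC
#'   (see [node_distances()]); computed on the fly when missing.
#' @return List of class `drug_module`: `drug_id`, `target`, `retained`,
#'   `path_nodes` (interior nodes), `nodes` (the full set T),
#'   `distances` (named, target to each retained gene).
#' @export
build_drug_module <- function(lcc, target, retained, drug_id = NA_character_,
                              dists = NULL, adj = NULL) {
  g <- .as_graph(lcc)
  nodes <- igraph::V(g)$name
  stopifnot(target %in% nodes)
  retained <- setdiff(unique(retained), target)
  if (!all(retained %in% nodes)) {
    stop("retained genes absent from the network: ",
         paste(setdiff(retained, nodes), collapse = ", "))
  }
  if (is.null(dists)) dists <- node_distances(g)
  stopifnot(identical(rownames(dists), nodes))
  if (is.null(adj)) adj <- .adjacency_list(g)
  interiors <- character(0)
  dvec <- stats::setNames(numeric(length(retained)), retained)
  for (gene in retained) {
    d <- dists[target, gene]
    if (!is.finite(d)) stop("retained gene unreachable from target: ", gene)
    dvec[[gene]] <- d
    interiors <- c(interiors, .lex_shortest_path_interior(
      target, gene, dists, adj, nodes))
  }
  structure(list(
    drug_id = drug_id, target = target, retained = retained,
    path_nodes = sort(unique(interiors)),
    nodes = sort(unique(c(target, retained, interiors))),
    distances = dvec
  ), class = "drug_module")
}

#' @export
print.drug_module <- function(x, ...) {
  cat("Drug module", if (!is.na(x$drug_id)) paste0("(", x$drug_id, ")"), ":",
      "target", x$target, "+", length(x$retained), "signature genes,",
      length(x$nodes), "nodes in total\n")
  invisible(x)
}

# Interior nodes of the lexicographically smallest shortest path from
# `from` to `to`. Walks forward greedily: at each step takes the smallest
# neighbor (vertex-name order) that still lies on some shortest path.
# Vertices are assumed name-sorted so index order == lexicographic order.
.lex_shortest_path_interior <- function(from, to, dists, adj, nodes) {
  d <- dists[from, to]
  if (d <= 1) return(character(0))
  interior <- character(d - 1L)
  cur <- match(from, nodes)
  to_i <- match(to, nodes)
  rem <- d
  k <- 0L
  while (rem > 1L) {
    nb <- adj[[cur]]
    cand <- nb[dists[nb, to_i] == rem - 1L]
    cur <- min(cand)
    k <- k + 1L
    interior[k] <- nodes[cur]
    rem <- rem - 1L
  }
  interior
}

# adjacency list in vertex-index space, each entry sorted increasingly
.adjacency_list <- function(g) {
  al <- igraph::as_adj_list(g, mode = "all")
  lapply(al, function(v) sort(as.integer(v)))
}

#' All-pairs hop distances of a graph
#'
#' @param g An igraph graph (or LCC list / `tissue_network`).
#' @return Integer-valued numeric matrix with node names as dimnames.
#' @export
node_distances <- function(g) {
  g <- .as_graph(g)
  igraph::distances(g, weights = NA)
}
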
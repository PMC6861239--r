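#' Random-walk community detection (walktrap)
#'
#' Wraps igraph's walktrap clustering (short random walks, agglomerative
#' merging, cut at maximal modularity) on the undirected network. The walk
#' length defaults to the implementation's standard 4 steps. The algorithm is
#' deterministic for a given graph and vertex ordering.
#'
#' @param network A `tissue_network`, an LCC list from [lcc_and_diameter()],
#'   or an igraph graph. The graph should be connected; pass the LCC.
#' @param walk_length Random-walk length.
#' @return List of class `community_partition`: `membership` (named integer),
#'   `sizes` (community sizes), `modularity` (at the chosen cut),
#'   `communities` (list of node-name vectors).
#' @export
detect_communities <- function(network, walk_length = 4) {
  g <- .as_graph(network)
  if (igraph::vcount(g) < 3L) {
    warning("graph has fewer than 3 nodes; returning a single community")
    mem <- stats::setNames(rep(1L, igraph::vcount(g)), igraph::V(g)$name)
    return(structure(list(membership = mem, sizes = length(mem),
                          modularity = NA_real_,
                          communities = list(names(mem))),
                     class = "community_partition"))
  }
  if (igraph::components(g)$no > 1L) {
    stop("graph is disconnected; run community detection on the LCC")
  }
  wt <- igraph::cluster_walktrap(g, steps = walk_length, weights = NULL)
  mem <- stats::setNames(as.integer(igraph::membership(wt)),
                         igraph::V(g)$name)
  comms <- split(names(mem), mem)
  structure(list(membership = mem,
                 sizes = vapply(comms, length, 1L),
                 modularity = max(wt$modularity),
                 communities = comms),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Partition:", length(x$communities), "communities over",
      length(x$membership), "nodes; modularity",
      format(x$modularity, digits = 4), "\n")
  invisible(x)
}

.as_graph <- function(network) {
  if (inherits(network, "tissue_network")) return(network$graph)
  if (is.list(network) && !is.null(network$graph)) return(network$graph)
  stopifnot(igraph::is_igraph(network))
  network
}

#' Call disease modules by over-representation of disease genes
#'
#' Tests each community for enrichment in disease genes with a one-sided
#' Fisher's exact test (hypergeometric upper tail) on the 2x2 table
#' in/out-community by disease/non-disease, with the partitioned network's
#' node set as universe. No multiple-testing correction is applied by default
#' (each module is judged at its own threshold); Benjamini-Hochberg can be
#' switched on.
#'
#' @param partition A `community_partition`.
#' @param disease_genes Character vector of disease gene symbols.
#' @param alpha Per-module significance level on the (possibly adjusted) p.
#' @param min_size Communities smaller than this are not tested.
#' @param adjust If `TRUE`, BH-adjust across tested communities.
#' @return Data frame of class `disease_modules`: `community`, `size`,
#'   `n_disease`, `p`, `p_adj` (equal to `p` unless `adjust`), `significant`,
#'   sorted by `p`; attribute `members` is a named list community ->
#'   node names, attribute `universe_size` the network size.
#' @export
call_disease_modules <- function(partition, disease_genes, alpha = 0.05,
                                 min_size = 3L, adjust = FALSE) {
  stopifnot(inherits(partition, "community_partition"))
  universe <- names(partition$membership)
  dg <- intersect(unique(disease_genes), universe)
  n_univ <- length(universe)
  if (!length(dg)) {
    warning("no disease genes present in the network")
  }
  comms <- partition$communities
  if (is.null(names(comms))) names(comms) <- as.character(seq_along(comms))
  tested <- comms[vapply(comms, length, 1L) >= min_size]

  rows <- lapply(names(tested), function(cid) {
    members <- tested[[cid]]
    k <- length(intersect(members, dg))
    # one-sided Fisher == hypergeometric upper tail P[X >= k]
    p <- stats::phyper(k - 1L, length(dg), n_univ - length(dg),
                       length(members), lower.tail = FALSE)
    data.frame(community = cid, size = length(members), n_disease = k,
               p = p, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    res <- data.frame(community = character(0), size = integer(0),
                      n_disease = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0))
  } else {
    res <- do.call(rbind, rows)
    res$p_adj <- if (adjust) stats::p.adjust(res$p, method = "BH") else res$p
    res$significant <- res$p_adj < alpha
    res <- res[order(res$p), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "members") <- comms
  attr(res, "universe_size") <- n_univ
  class(res) <- c("disease_modules", class(res))
  res
}

#' Node sets of the significant disease modules
#'
#' @param modules Output of [call_disease_modules()].
#' @return Named list community id -> character vector of node names, for
#'   the significant modules only, ordered by increasing p.
#' @export
disease_module_members <- function(modules) {
  stopifnot(inherits(modules, "disease_modules"))
  sig <- modules$community[modules$significant]
  attr(modules, "members")[sig]
}

#' Pathway annotation of a module
#'
#' Over-representation of the module's genes against GMT libraries, as a
#' functional readout of what the module does. Thin delegation to
#' [ora_test()].
#'
#' @param module_genes Character vector of module node names.
#' @param libraries GMT libraries (named list, or list of lists).
#' @param universe Background universe (e.g. network node names).
#' @param alpha BH-adjusted significance level.
#' @return The [ora_test()] table.
#' @export
annotate_module <- function(module_genes, libraries, universe, alpha = 0.05) {
  ora_test(module_genes, libraries, universe = universe, alpha = alpha)
}
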
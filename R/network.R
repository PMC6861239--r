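#' Load and threshold a regulatory edge list
#'
#' Reads TF-to-target edges with activity-based weights in `[0, 2]` and keeps
#' edges whose weight is at least `weight_min` (0.4 by default, the point at
#' which the regulatory networks retain high-evidence interactions without
#' collapsing). Rows with weights outside `[0, 2]` are rejected with a
#' message; duplicate TF-target pairs keep the maximum weight.
#'
#' @param edges Either a path to a 3-column TSV (`tf`, `target`, `weight`,
#'   header optional) or a data frame with those columns.
#' @param weight_min Inclusive weight threshold.
#' @return Data frame `from`, `to`, `weight` of retained edges.
#' @export
load_regulatory <- function(edges, weight_min = 0.4) {
  df <- .read_edge_table(edges, c("tf", "target", "weight"))
  names(df) <- c("from", "to", "weight")
  if (!nrow(df)) {
    warning("regulatory edge list is empty")
    return(df)
  }
  bad <- df$weight < 0 | df$weight > 2 | is.na(df$weight)
  if (any(bad)) {
    message(sum(bad), " regulatory rows rejected (weight outside [0,2])")
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[df$weight >= weight_min, , drop = FALSE]
  .dedup_max_weight(df)
}

#' Load and filter a protein-protein interaction edge list
#'
#' Keeps interactions with confidence at least `score_min` (0.73, the
#' high-evidence level of the source database) whose two endpoints are both
#' expressed in the tissue (RPKM at least `rpkm_min`). Endpoints absent from
#' the expression table count as not expressed.
#'
#' @param edges Path to a 3-column TSV (`protein_a`, `protein_b`,
#'   `confidence`) or an equivalent data frame.
#' @param expression Data frame with columns `gene` and `rpkm`, or a named
#'   numeric vector, or a path to a 2-column TSV. When a data frame contains
#'   several rows per gene (e.g. two adipose depots), the per-gene maximum
#'   RPKM is used.
#' @param score_min Inclusive confidence threshold in `[0, 1]`.
#' @param rpkm_min Inclusive expression threshold.
#' @return Data frame `from`, `to`, `weight`; attribute `n_unexpressed`
#'   counts edges dropped for lack of expression.
#' @export
load_ppi <- function(edges, expression, score_min = 0.73, rpkm_min = 1.0) {
  df <- .read_edge_table(edges, c("protein_a", "protein_b", "confidence"))
  names(df) <- c("from", "to", "weight")
  if (!nrow(df)) {
    warning("PPI edge list is empty")
    return(df)
  }
  bad <- df$weight < 0 | df$weight > 1 | is.na(df$weight)
  if (any(bad)) {
    message(sum(bad), " PPI rows rejected (confidence outside [0,1])")
    df <- df[!bad, , drop = FALSE]
  }
  rpkm <- expression_vector(expression)
  df <- df[df$weight >= score_min, , drop = FALSE]
  expr_ok <- function(g) {
    v <- rpkm[g]
    !is.na(v) & v >= rpkm_min
  }
  keep <- expr_ok(df$from) & expr_ok(df$to)
  n_unexpr <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  df <- .dedup_max_weight(df)
  attr(df, "n_unexpressed") <- n_unexpr
  df
}

.read_edge_table <- function(x, cols) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.table(x, sep = "\t", header = .has_header(x, cols),
                           stringsAsFactors = FALSE,
                           col.names = cols, fill = TRUE)
  }
  stopifnot(is.data.frame(x), ncol(x) >= 3L)
  df <- x[, 1:3]
  names(df) <- cols
  df[[1L]] <- as.character(df[[1L]])
  df[[2L]] <- as.character(df[[2L]])
  df[[3L]] <- as.numeric(df[[3L]])
  df
}

.has_header <- function(path, cols) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
}

# undirected dedup keeping the maximum weight per unordered pair
.dedup_max_weight <- function(df) {
  if (!nrow(df)) return(df)
  a <- pmin(df$from, df$to)
  b <- pmax(df$from, df$to)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -df$weight)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(key[o]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a tissue expression table
#'
#' @param x Path to a TSV with columns `gene` and `rpkm` (additional tissue
#'   columns allowed if `column` names one), a data frame, or a named
#'   numeric vector.
#' @param column Optional column name holding the RPKM values.
#' @return Named numeric vector gene -> RPKM (per-gene maximum when a gene
#'   appears in several rows, e.g. combined adipose depots).
#' @export
expression_vector <- function(x, column = NULL) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.table(x, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  val_col <- if (!is.null(column)) column else setdiff(names(x), "gene")[1L]
  v <- tapply(as.numeric(x[[val_col]]), x$gene, max)
  stats::setNames(as.numeric(v), names(v))
}

#' Integrate regulatory and PPI edges into a tissue network
#'
#' Starting from the regulatory node set R, PPI edges are admitted when at
#' least one endpoint lies in R or among R's first PPI neighbors; endpoints of
#' admitted edges join the network. The result is an undirected simple graph
#' whose edges carry a weight and a provenance tag (`regulatory`, `ppi`, or
#' `regulatory+ppi` for pairs present in both sources). Regulatory direction
#' is retained as edge metadata only; all downstream distance and community
#' computations are undirected.
#'
#' @param reg_edges Output of [load_regulatory()].
#' @param ppi_edges Output of [load_ppi()].
#' @param tissue Tissue label stored on the network.
#' @return An object of class `tissue_network`: list with `graph` (igraph),
#'   `tissue`, and a `report` of node/edge counts by provenance.
#' @export
integrate_network <- function(reg_edges, ppi_edges, tissue = "unspecified") {
  if (is.null(reg_edges) || !nrow(reg_edges)) stop("no seed network")
  reg_nodes <- unique(c(reg_edges$from, reg_edges$to))

  if (!is.null(ppi_edges) && nrow(ppi_edges)) {
    touches_r <- ppi_edges$from %in% reg_nodes | ppi_edges$to %in% reg_nodes
    first_nb <- setdiff(unique(c(ppi_edges$from[touches_r],
                                 ppi_edges$to[touches_r])), reg_nodes)
    admitted <- c(reg_nodes, first_nb)
    keep <- ppi_edges$from %in% admitted | ppi_edges$to %in% admitted
    ppi_kept <- ppi_edges[keep, , drop = FALSE]
  } else {
    ppi_kept <- data.frame(from = character(0), to = character(0),
                           weight = numeric(0))
  }

  reg <- data.frame(from = reg_edges$from, to = reg_edges$to,
                    weight = reg_edges$weight, provenance = "regulatory",
                    stringsAsFactors = FALSE)
  ppi <- if (nrow(ppi_kept)) {
    data.frame(from = ppi_kept$from, to = ppi_kept$to,
               weight = ppi_kept$weight, provenance = "ppi",
               stringsAsFactors = FALSE)
  } else reg[0, ]
  all_e <- rbind(reg, ppi)
  all_e <- all_e[all_e$from != all_e$to, , drop = FALSE]  # no self-loops

  a <- pmin(all_e$from, all_e$to)
  b <- pmax(all_e$from, all_e$to)
  key <- paste(a, b, sep = "\r")
  prov <- tapply(all_e$provenance, key, function(p) {
    paste(sort(unique(p)), collapse = "+")
  })
  wt <- tapply(all_e$weight, key, max)
  ord <- sort(unique(key))
  pair <- do.call(rbind, strsplit(ord, "\r", fixed = TRUE))
  edges <- data.frame(from = pair[, 1L], to = pair[, 2L],
                      weight = as.numeric(wt[ord]),
                      provenance = as.character(prov[ord]),
                      stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::permute(g, match(igraph::V(g)$name,
                                sort(igraph::V(g)$name)))
  kind <- ifelse(igraph::V(g)$name %in% unique(reg_edges$from), "TF",
          ifelse(igraph::V(g)$name %in% reg_nodes, "gene", "protein"))
  igraph::V(g)$kind <- kind

  report <- list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_regulatory_nodes = length(reg_nodes),
    n_first_neighbors = if (nrow(ppi_kept)) {
      length(setdiff(igraph::V(g)$name, reg_nodes))
    } else 0L,
    provenance = table(igraph::E(g)$provenance),
    isolated_regulatory_dropped =
      length(setdiff(reg_nodes, igraph::V(g)$name))
  )
  structure(list(graph = g, tissue = tissue, report = report),
            class = "tissue_network")
}

#' @export
print.tissue_network <- function(x, ...) {
  cat("Tissue network (", x$tissue, "): ", x$report$n_nodes, " nodes, ",
      x$report$n_edges, " edges\n", sep = "")
  print(x$report$provenance)
  invisible(x)
}

#' Largest connected component and its diameter
#'
#' Extracts the largest connected component of the network and computes its
#' unweighted (hop-count) diameter, the normalization constant of the
#' proximity score. Ties between equally large components break towards the
#' one containing the alphabetically first node.
#'
#' @param network A `tissue_network` or an igraph graph.
#' @return List with `graph` (igraph, the LCC, vertices in name order),
#'   `diameter` (integer hops) and `tissue`.
#' @export
lcc_and_diameter <- function(network) {
  g <- if (inherits(network, "tissue_network")) network$graph else network
  stopifnot(igraph::vcount(g) > 0L)
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    firsts <- vapply(big, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, "")
    big <- big[order(firsts)][1L]
  }
  lcc <- igraph::induced_subgraph(g, which(comp$membership == big))
  lcc <- igraph::permute(lcc, match(igraph::V(lcc)$name,
                                    sort(igraph::V(lcc)$name)))
  d <- igraph::diameter(lcc, directed = FALSE, weights = NA)
  list(graph = lcc, diameter = as.integer(d),
       tissue = if (inherits(network, "tissue_network")) network$tissue
                else "unspecified")
}

#' Write a network to a GraphML file
#'
#' @param network A `tissue_network` or igraph graph.
#' @param path Output path.
#' @export
write_network_graphml <- function(network, path) {
  g <- if (inherits(network, "tissue_network")) network$graph else network
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
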
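#' Closest network distance between a drug module and a disease module
#'
#' `d_c = (1/|T|) * sum over t in T of min over s in S of d(s, t)`, the mean
#' over drug-module nodes of the hop distance to the nearest disease-module
#' node. Nodes shared by both modules contribute 0.
#'
#' @param network LCC list, `tissue_network`, or igraph graph.
#' @param t_nodes Drug-module node set T.
#' @param s_nodes Disease-module node set S.
#' @param dists Optional precomputed distance matrix (see [node_distances()]).
#' @return The closest distance `d_c` (numeric, in hops).
#' @export
closest_distance <- function(network, t_nodes, s_nodes, dists = NULL) {
  if (!length(t_nodes) || !length(s_nodes)) {
    stop("both node sets must be nonempty")
  }
  if (is.null(dists)) dists <- node_distances(network)
  missing <- setdiff(c(t_nodes, s_nodes), rownames(dists))
  if (length(missing)) {
    stop("nodes absent from the network: ", paste(missing, collapse = ", "))
  }
  sub <- dists[t_nodes, s_nodes, drop = FALSE]
  mins <- apply(sub, 1L, min)
  if (any(!is.finite(mins))) stop("modules span disconnected components")
  mean(mins)
}

#' Diameter-normalized network proximity component
#'
#' `1 - d_c / diameter`, a score in `[0, 1]` that is 1 when the drug module
#' sits on the disease module and 0 at the network's diameter.
#'
#' @param d_c Closest distance from [closest_distance()].
#' @param diameter Unweighted diameter of the LCC.
#' @return Score in `[0, 1]`.
#' @export
network_score <- function(d_c, diameter) {
  stopifnot(diameter >= 1)
  if (d_c < 0 || d_c > diameter) {
    stop("d_c must lie in [0, diameter]; got ", d_c, " vs diameter ",
         diameter)
  }
  1 - d_c / diameter
}

#' Combined drug-disease proximity score
#'
#' Sum of the diameter-normalized network component and the Wang/BMA semantic
#' similarity of the two modules' gene sets, a score in `[0, 2]`.
#'
#' @param lcc LCC list from [lcc_and_diameter()].
#' @param dag,annot Ontology and gene annotation.
#' @param drug_module A `drug_module` (or a plain node-set character vector).
#' @param disease_nodes Node set S of the disease module.
#' @param dists Optional precomputed distance matrix.
#' @param cache Optional [wang_cache()].
#' @param module_id Identifier of the disease module (metadata).
#' @return List of class `proximity_result`: `drug_id`, `target`,
#'   `module_id`, `d_c`, `diameter`, `network_score`, `semantic_score`,
#'   `total`.
#' @export
proximity_score <- function(lcc, dag, annot, drug_module, disease_nodes,
                            dists = NULL, cache = NULL,
                            module_id = NA_character_) {
  t_nodes <- if (inherits(drug_module, "drug_module")) drug_module$nodes
             else as.character(drug_module)
  diam <- if (is.list(lcc) && !is.null(lcc$diameter)) lcc$diameter
          else as.integer(igraph::diameter(.as_graph(lcc), weights = NA))
  d_c <- closest_distance(lcc, t_nodes, disease_nodes, dists = dists)
  ns <- network_score(d_c, diam)
  ss <- gene_set_similarity(dag, annot, t_nodes, disease_nodes, cache = cache)
  structure(list(
    drug_id = if (inherits(drug_module, "drug_module")) drug_module$drug_id
              else NA_character_,
    target = if (inherits(drug_module, "drug_module")) drug_module$target
             else NA_character_,
    module_id = module_id,
    d_c = d_c, diameter = diam,
    network_score = ns, semantic_score = ss, total = ns + ss
  ), class = "proximity_result")
}

#' Degree bins for topology-matched random targets
#'
#' Sorts nodes by degree and greedily accumulates bins until each holds at
#' least `min_occupancy` nodes, never splitting a degree value across bins; a
#' trailing remainder is absorbed into the last bin. On networks smaller than
#' the requested occupancy a single bin is returned with a warning. The
#' default occupancy of 100 suits genome-scale networks and is auto-reduced
#' (with a message) to `floor(n/3)` when the network has fewer than
#' `3 * min_occupancy` nodes, so small fixtures still get several bins.
#'
#' @param network LCC list, `tissue_network`, or igraph graph.
#' @param min_occupancy Minimum nodes per bin.
#' @return List of class `degree_binning`: `bin` (named integer, node ->
#'   bin id), `levels` (list: bin id -> node names), `degree` (named).
#' @export
degree_bins <- function(network, min_occupancy = 100L) {
  g <- .as_graph(network)
  deg <- igraph::degree(g)
  n <- length(deg)
  if (min_occupancy > n) {
    warning("min_occupancy exceeds network size; using a single bin")
    min_occupancy <- n
  } else if (n < 3L * min_occupancy && min_occupancy > 1L) {
    min_occupancy <- max(1L, n %/% 3L)
    message("degree-bin occupancy reduced to ", min_occupancy,
            " for this network size")
  }
  node_bin <- .greedy_bins(deg, min_occupancy)
  structure(list(
    bin = node_bin,
    levels = split(names(node_bin), node_bin),
    degree = deg
  ), class = "degree_binning")
}

# Greedy degree binning on a named degree vector: accumulate nodes in
# increasing degree order until a bin reaches the occupancy, never splitting
# one degree value across bins; an underfull trailing bin is absorbed into
# the previous one.
.greedy_bins <- function(deg, min_occupancy) {
  uniq <- sort(unique(deg))
  counts <- table(factor(deg, levels = uniq))
  bin_of_degree <- integer(length(uniq))
  bin_id <- 1L
  acc <- 0L
  for (i in seq_along(uniq)) {
    bin_of_degree[i] <- bin_id
    acc <- acc + counts[[i]]
    if (acc >= min_occupancy && i < length(uniq)) {
      bin_id <- bin_id + 1L
      acc <- 0L
    }
  }
  if (bin_id > 1L && acc > 0L && acc < min_occupancy) {
    bin_of_degree[bin_of_degree == bin_id] <- bin_id - 1L
  }
  stats::setNames(bin_of_degree[match(deg, uniq)], names(deg))
}

#' Draw one randomized drug module
#'
#' Mirrors the construction of the observed module under a topology-matched
#' null: a random target is drawn uniformly from the original target's degree
#' bin; for every retained signature gene at hop distance `d` from the
#' original target, a node is drawn uniformly (without replacement where
#' possible) from the set of nodes at distance exactly `d` from the random
#' target, falling back to the nearest nonempty distance shell (ties towards
#' the smaller distance) when the `d`-shell is empty. The module is then
#' assembled exactly like an observed module (shortest paths to the target).
#'
#' @param lcc LCC list.
#' @param original The observed `drug_module`.
#' @param bins A `degree_binning` built on the same LCC.
#' @param dists Precomputed distance matrix (required for speed; computed if
#'   missing).
#' @param adj Optional precomputed adjacency list (internal use).
#' @return A `drug_module` whose `drug_id` is tagged `"<id>:random"`.
#' @export
random_drug_module <- function(lcc, original, bins, dists = NULL, adj = NULL) {
  g <- .as_graph(lcc)
  nodes <- igraph::V(g)$name
  if (is.null(dists)) dists <- node_distances(g)
  pool <- bins$levels[[as.character(bins$bin[[original$target]])]]
  rt <- if (length(pool) == 1L) pool else sample(pool, 1L)

  drow <- dists[rt, ]
  picked <- character(0)
  for (d in unname(original$distances)) {
    shell <- names(drow)[drow == d]
    if (!length(shell)) {
      # nearest nonempty shell, ties towards the smaller distance
      avail <- sort(unique(drow[is.finite(drow)]))
      avail <- setdiff(avail, 0)
      dd <- avail[order(abs(avail - d), avail)][1L]
      shell <- names(drow)[drow == dd]
    }
    shell_new <- setdiff(shell, c(picked, rt))
    pick_from <- if (length(shell_new)) shell_new else setdiff(shell, rt)
    if (!length(pick_from)) next
    picked <- c(picked, if (length(pick_from) == 1L) pick_from
                        else sample(pick_from, 1L))
  }
  build_drug_module(lcc, rt, unique(picked),
                    drug_id = paste0(original$drug_id, ":random"),
                    dists = dists, adj = adj)
}

#' Significance of a proximity score against the randomization null
#'
#' Builds `n_random` randomized drug modules (see [random_drug_module()]),
#' scores each against the same disease module, and calls the observed score
#' significant when it is strictly greater than the empirical `q`-quantile
#' (nearest-rank order statistic) of the null scores. The empirical p-value
#' uses the add-one estimator `(1 + #{null >= observed}) / (1 + n_random)`.
#'
#' @param lcc LCC list.
#' @param dag,annot Ontology and annotation.
#' @param drug_module Observed `drug_module`.
#' @param disease_nodes Disease-module node set S.
#' @param bins Optional `degree_binning`; built on demand.
#' @param n_random Number of null draws.
#' @param q Quantile of the null that the observed score must exceed.
#' @param seed Optional integer seed for reproducible nulls.
#' @param dists,cache Optional precomputed distance matrix and [wang_cache()].
#' @param module_id Disease-module identifier (metadata).
#' @return List of class `proximity_significance`: the observed
#'   `proximity_result` fields plus `null_scores`, `null_quantile`,
#'   `empirical_p`, `significant`, `q`, `n_random`.
#' @export
proximity_significance <- function(lcc, dag, annot, drug_module,
                                   disease_nodes, bins = NULL,
                                   n_random = 1000L, q = 0.95, seed = NULL,
                                   dists = NULL, cache = NULL,
                                   module_id = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dists)) dists <- node_distances(lcc)
  if (is.null(bins)) bins <- degree_bins(lcc)
  if (is.null(cache)) cache <- wang_cache(dag, annot)

  obs <- proximity_score(lcc, dag, annot, drug_module, disease_nodes,
                         dists = dists, cache = cache, module_id = module_id)
  engine <- .module_score_engine(lcc, disease_nodes, dists, cache)
  adj <- .adjacency_list(.as_graph(lcc))
  null_scores <- numeric(n_random)
  for (i in seq_len(n_random)) {
    rm_i <- NULL
    for (attempt in 1:10) {
      rm_i <- tryCatch(
        random_drug_module(lcc, drug_module, bins, dists = dists, adj = adj),
        error = function(e) NULL)
      if (!is.null(rm_i)) break
    }
    if (is.null(rm_i)) stop("random module construction failed 10 times")
    null_scores[i] <- engine(rm_i$nodes)
  }
  thr <- .nearest_rank_quantile(null_scores, q)
  p <- (1 + sum(null_scores >= obs$total)) / (1 + n_random)
  structure(c(unclass(obs), list(
    null_scores = null_scores, null_quantile = thr, empirical_p = p,
    significant = obs$total > thr, q = q, n_random = n_random
  )), class = "proximity_significance")
}

# nearest-rank empirical quantile: the ceil(q*n)-th order statistic
.nearest_rank_quantile <- function(x, q) {
  sort(x)[max(1L, ceiling(q * length(x)))]
}

# Precomputes the gene-level similarity matrix of every annotated LCC node
# against the (fixed) disease-module genes, so that scoring one candidate
# node set against that module costs only row/column maxima plus one
# distance-matrix slice. Numerically identical to
# network_score + gene_set_similarity (same BMA, same unannotated-gene drop).
.module_score_engine <- function(lcc, disease_nodes, dists, cache) {
  g <- .as_graph(lcc)
  diam <- if (is.list(lcc) && !is.null(lcc$diameter)) lcc$diameter
          else as.integer(igraph::diameter(g, weights = NA))
  nodes <- igraph::V(g)$name
  annotated <- nodes[vapply(nodes, function(x) {
    t <- cache$annot[[x]]; !is.null(t) && length(t) > 0L
  }, TRUE)]
  s_ann <- intersect(disease_nodes, annotated)
  if (!length(s_ann)) stop("no annotated genes in the disease module")
  gsim <- matrix(NA_real_, length(annotated), length(s_ann),
                 dimnames = list(annotated, s_ann))
  for (a in annotated) for (s in s_ann) gsim[a, s] <- cache$gene_sim(a, s)

  s_idx <- match(disease_nodes, rownames(dists))
  function(t_nodes) {
    sub <- dists[match(t_nodes, rownames(dists)), s_idx, drop = FALSE]
    d_c <- mean(apply(sub, 1L, min))
    t_ann <- intersect(t_nodes, annotated)
    if (!length(t_ann)) stop("no annotated genes")
    m <- gsim[t_ann, , drop = FALSE]
    ss <- (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) /
      (nrow(m) + ncol(m))
    (1 - d_c / diam) + ss
  }
}

#' @export
print.proximity_significance <- function(x, ...) {
  cat(sprintf(
    "drug %s (target %s) vs module %s: total %.4f (network %.4f + semantic %.4f)\n",
    x$drug_id, x$target, x$module_id, x$total, x$network_score,
    x$semantic_score))
  cat(sprintf("  null %d draws, %.0f%% quantile %.4f, empirical p %.4g -> %s\n",
              x$n_random, 100 * x$q, x$null_quantile, x$empirical_p,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Score a drug against every significant disease module
#'
#' Convenience wrapper: builds the drug module (signature selection, semantic
#' filter, shortest-path assembly), scores it against each disease module,
#' and assesses significance against the randomization null.
#'
#' @param lcc LCC list.
#' @param dag,annot Ontology and annotation.
#' @param drug One row of [read_drug_table()] (list or 1-row data frame).
#' @param signatures Signature rows for this drug.
#' @param modules Named list module id -> node set
#'   (see [disease_module_members()]).
#' @param sim_min Semantic cut-off for signature genes.
#' @param n_random,q,seed Null parameters (see [proximity_significance()]).
#' @param bins,dists,cache Optional precomputed helpers.
#' @return Data frame, one row per disease module, with score components,
#'   empirical p and significance flag; or `NULL` with attribute `reason`
#'   when the drug is skipped (no gold signature / target not in network).
#' @export
score_drug <- function(lcc, dag, annot, drug, signatures, modules,
                       sim_min = 0.5, n_random = 1000L, q = 0.95,
                       seed = NULL, bins = NULL, dists = NULL, cache = NULL) {
  sig <- select_signature(signatures)
  if (inherits(sig, "drug_skip")) {
    out <- NULL; attr(out, "reason") <- sig$reason; return(out)
  }
  flt <- filter_signature(drug$target, sig, lcc, dag, annot,
                          sim_min = sim_min, cache = cache)
  if (identical(attr(flt, "excluded_reason"), "target not in network")) {
    out <- NULL; attr(out, "reason") <- "target not in network"; return(out)
  }
  dm <- build_drug_module(lcc, drug$target, flt$gene[flt$retained],
                          drug_id = drug$drug_id, dists = dists)
  rows <- lapply(names(modules), function(mid) {
    sg <- proximity_significance(lcc, dag, annot, dm, modules[[mid]],
                                 bins = bins, n_random = n_random, q = q,
                                 seed = seed, dists = dists, cache = cache,
                                 module_id = mid)
    data.frame(drug_id = drug$drug_id, name = drug$name,
               action = drug$action, target = drug$target, module = mid,
               d_c = sg$d_c, network_score = sg$network_score,
               semantic_score = sg$semantic_score, total = sg$total,
               empirical_p = sg$empirical_p, significant = sg$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
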
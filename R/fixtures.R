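#' Build a GO DAG object from an edge table
#'
#' Programmatic constructor mirroring what [read_obo()] produces, for building
#' small ontologies in code (fixtures, examples, tests).
#'
#' @param edges Data frame with columns `child`, `parent`, `relation`
#'   (`is_a` or `part_of`).
#' @param terms Optional character vector of term ids (defaults to all ids in
#'   `edges`); terms not appearing in `edges` become isolated roots.
#' @param namespace Single namespace or named vector per term.
#' @param names Optional named character vector of term names.
#' @param obsolete Optional character vector of obsolete term ids (their
#'   edges are dropped).
#' @return A `go_dag`.
#' @export
go_dag_from_edges <- function(edges, terms = NULL,
                              namespace = "biological_process",
                              names = NULL, obsolete = character(0)) {
  if (is.null(terms)) terms <- unique(c(edges$child, edges$parent))
  terms <- unique(terms)
  ns <- if (length(namespace) == 1L) {
    stats::setNames(rep(namespace, length(terms)), terms)
  } else namespace[terms]
  nm <- if (is.null(names)) stats::setNames(terms, terms) else names[terms]
  obs <- stats::setNames(terms %in% obsolete, terms)
  edges <- edges[!(edges$child %in% obsolete) &
                   !(edges$parent %in% obsolete), , drop = FALSE]
  parents <- split(
    data.frame(parent = edges$parent, relation = edges$relation,
               stringsAsFactors = FALSE),
    factor(edges$child, levels = terms))
  children <- split(
    data.frame(child = edges$child, relation = edges$relation,
               stringsAsFactors = FALSE),
    factor(edges$parent, levels = terms))
  dag <- structure(
    list(terms = terms, name = nm, namespace = ns, obsolete = obs,
         parents = parents, children = children,
         alt = stats::setNames(character(0), character(0))),
    class = "go_dag")
  cyc <- .dag_find_cycle(dag)
  if (!is.null(cyc)) stop("edge table is cyclic; cycle involves term ", cyc)
  dag
}

#' Write a GO DAG to an OBO file
#'
#' @param dag A `go_dag`.
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    out <- c("[Term]", paste0("id: ", t),
             paste0("name: ", dag$name[[t]]),
             paste0("namespace: ", dag$namespace[[t]]))
    alts <- names(dag$alt)[dag$alt == t]
    out <- c(out, paste0("alt_id: ", alts))
    if (dag$obsolete[[t]]) {
      out <- c(out, "is_obsolete: true")
    } else {
      ps <- dag$parents[[t]]
      if (!is.null(ps) && nrow(ps)) {
        for (i in seq_len(nrow(ps))) {
          out <- c(out, if (ps$relation[i] == "is_a") {
            paste0("is_a: ", ps$parent[i])
          } else {
            paste0("relationship: ", ps$relation[i], " ", ps$parent[i])
          })
        }
      }
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Random layered GO DAG
#'
#' Generates a random hierarchy for testing the semantic-similarity stack:
#' one root, then `layers` layers of the given widths; each term draws one or
#' two parents from the previous layer; a fixed fraction of edges is
#' `part_of`, the rest `is_a`.
#'
#' @param seed Integer seed.
#' @param widths Integer vector, terms per layer below the root.
#' @param p_two_parents Probability a term gets a second parent.
#' @param p_part_of Probability an edge is `part_of`.
#' @return A `go_dag` with roughly `1 + sum(widths)` biological_process terms.
#' @export
random_go_dag <- function(seed, widths = c(5L, 15L, 30L),
                          p_two_parents = 0.3, p_part_of = 0.1) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(1L + sum(widths)))
  root <- ids[1L]
  layer_of <- split(ids[-1L], rep(seq_along(widths), widths))
  edges <- list()
  prev <- root
  for (l in seq_along(widths)) {
    for (t in layer_of[[l]]) {
      np <- 1L + (length(prev) > 1L && stats::runif(1) < p_two_parents)
      ps <- if (length(prev) == 1L) prev else sample(prev, np)
      rel <- ifelse(stats::runif(length(ps)) < p_part_of, "part_of", "is_a")
      edges[[length(edges) + 1L]] <-
        data.frame(child = t, parent = ps, relation = rel,
                   stringsAsFactors = FALSE)
    }
    prev <- layer_of[[l]]
  }
  go_dag_from_edges(do.call(rbind, edges), terms = ids)
}

#' Planted two-or-more-block partition graph
#'
#' Stochastic block model with equal blocks: within-block edge probability
#' `p_in`, between-block `p_out`. Extra bridging edges are added if needed to
#' make the graph connected (between the first nodes of disconnected
#' components). Node names carry no block information; the planted membership
#' is returned alongside.
#'
#' @param n Total nodes.
#' @param k Number of blocks.
#' @param p_in,p_out Edge probabilities.
#' @param seed Integer seed.
#' @return List with `graph` (igraph, vertices name-sorted) and `membership`
#'   (named integer vector).
#' @export
planted_partition_graph <- function(n, k = 2L, p_in = 0.3, p_out = 0.02,
                                    seed = 1L) {
  if (k > n) stop("more blocks than nodes")
  set.seed(seed)
  sizes <- rep(n %/% k, k)
  sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  pm <- matrix(p_out, k, k); diag(pm) <- p_in
  g <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
  member <- rep(seq_len(k), sizes)
  igraph::V(g)$name <- sprintf("G%02d%03d", member, unlist(lapply(sizes, seq_len)))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    firsts <- vapply(seq_len(comp$no), function(cc) {
      min(igraph::V(g)$name[comp$membership == cc])
    }, "")
    ids <- match(firsts, igraph::V(g)$name)
    for (i in seq_len(comp$no - 1L)) {
      g <- igraph::add_edges(g, c(ids[i], ids[i + 1L]))
    }
  }
  membership <- stats::setNames(member, igraph::V(g)$name)
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  list(graph = g, membership = membership[sort(names(membership))])
}

.profile_params <- function(profile) {
  switch(profile,
    tiny = list(k = 2L, block = 16L, p_in = 0.35, p_out = 0.04),
    small = list(k = 4L, block = 50L, p_in = 0.3, p_out = 0.02),
    medium = list(k = 5L, block = 200L, p_in = 0.06, p_out = 0.005),
    stop("unknown size profile: ", profile))
}

# deterministic sub-seed fan-out, kept within 32-bit integer range
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131L + k * 7919) %% 2147483647)
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Produces, in memory, every input the toolkit consumes: a planted-partition
#' gene network split into a regulatory edge list (edges touching designated
#' per-block transcription factors, weights in `[0.4, 2]` plus sub-threshold
#' noise rows) and a PPI edge list (all network edges, confidences in
#' `[0.73, 1]` plus noise and edges to unexpressed genes); a tissue
#' expression table; a layered GO ontology with one branch per block and
#' per-gene annotations drawn from the gene's block branch (so genes of a
#' block are semantically coherent); SNP and gene-model tables that map to a
#' disease-gene list concentrated in block 1; gene-set libraries whose
#' block-1 set makes the disease genes pass the over-representation filter;
#' drug and signature tables containing a positive-control drug (target and
#' signature inside the disease block) and a negative-control drug (distant
#' block, different ontology branch); and the three triage tables. The
#' `ground_truth` element records what was planted.
#'
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param profile `"tiny"` (~30 nodes), `"small"` (~200), `"medium"` (~1000).
#' @return A list of class `fixture_bundle`; see
#'   [write_fixture_bundle()] for the file each element maps to.
#' @export
generate_fixture_bundle <- function(seed, profile = c("small", "tiny",
                                                      "medium")) {
  profile <- match.arg(profile)
  pp <- .profile_params(profile)
  k <- pp$k
  n <- k * pp$block

  ## --- network -------------------------------------------------------------
  net <- planted_partition_graph(n, k, pp$p_in, pp$p_out,
                                 seed = .sub_seed(seed, 1L))
  g <- net$graph
  membership <- net$membership
  nodes <- igraph::V(g)$name
  blocks <- split(names(membership), membership)
  tfs <- unlist(lapply(blocks, function(b) sort(b)[1:3]), use.names = FALSE)

  el <- igraph::as_edgelist(g)
  touches_tf <- el[, 1L] %in% tfs | el[, 2L] %in% tfs

  set.seed(.sub_seed(seed, 2L))
  reg <- data.frame(tf = el[touches_tf, 1L], target = el[touches_tf, 2L],
                    weight = round(stats::runif(sum(touches_tf), 0.4, 2.0), 3),
                    stringsAsFactors = FALSE)
  swap <- !(reg$tf %in% tfs)  # orient TF first where possible
  tmp <- reg$tf[swap]; reg$tf[swap] <- reg$target[swap]; reg$target[swap] <- tmp
  reg_noise <- data.frame(
    tf = sample(tfs, 5L, replace = TRUE),
    target = sample(nodes, 5L),
    weight = round(stats::runif(5L, 0.0, 0.39), 3),
    stringsAsFactors = FALSE)

  unexpressed <- sprintf("X%03d", 1:6)
  ppi <- data.frame(protein_a = el[, 1L], protein_b = el[, 2L],
                    confidence = round(stats::runif(nrow(el), 0.73, 1.0), 3),
                    stringsAsFactors = FALSE)
  ppi_noise <- rbind(
    data.frame(protein_a = sample(nodes, 8L), protein_b = sample(nodes, 8L),
               confidence = round(stats::runif(8L, 0.1, 0.72), 3),
               stringsAsFactors = FALSE),
    data.frame(protein_a = sample(nodes, length(unexpressed)),
               protein_b = unexpressed,
               confidence = round(stats::runif(length(unexpressed), 0.8, 1), 3),
               stringsAsFactors = FALSE))

  expression <- rbind(
    data.frame(gene = nodes, rpkm = round(stats::runif(n, 1.0, 60), 2),
               stringsAsFactors = FALSE),
    data.frame(gene = unexpressed,
               rpkm = round(stats::runif(length(unexpressed), 0, 0.9), 2),
               stringsAsFactors = FALSE),
    # duplicate depot rows for a couple of genes (per-gene max applies)
    data.frame(gene = nodes[1:2], rpkm = c(0.5, 70), stringsAsFactors = FALSE))

  ## --- ontology and annotations -------------------------------------------
  root <- "GO:0000001"
  branch <- sprintf("GO:%07d", 1L + seq_len(k))
  dag_edges <- data.frame(child = branch, parent = root, relation = "is_a",
                          stringsAsFactors = FALSE)
  leaves_of <- vector("list", k)
  nid <- 1L + k
  for (b in seq_len(k)) {
    mids <- sprintf("GO:%07d", nid + 1:2); nid <- nid + 2L
    rel_mid <- c("is_a", "part_of")  # one part_of branch per block
    dag_edges <- rbind(dag_edges,
      data.frame(child = mids, parent = branch[b], relation = rel_mid,
                 stringsAsFactors = FALSE))
    lv <- sprintf("GO:%07d", nid + 1:6); nid <- nid + 6L
    dag_edges <- rbind(dag_edges,
      data.frame(child = lv, parent = rep(mids, each = 3L),
                 relation = "is_a", stringsAsFactors = FALSE))
    leaves_of[[b]] <- lv
  }
  mf_term <- sprintf("GO:%07d", nid + 1L)
  obs_term <- sprintf("GO:%07d", nid + 2L)
  all_terms <- c(root, unique(c(dag_edges$child, dag_edges$parent)),
                 mf_term, obs_term)
  ns <- stats::setNames(rep("biological_process", length(all_terms)),
                        all_terms)
  ns[mf_term] <- "molecular_function"
  dag <- go_dag_from_edges(dag_edges, terms = unique(all_terms),
                           namespace = ns, obsolete = obs_term)
  dag$alt <- stats::setNames(leaves_of[[1L]][1L], sprintf("GO:%07d", 9000001))

  set.seed(.sub_seed(seed, 3L))
  annot_list <- lapply(nodes, function(gene) {
    b <- membership[[gene]]
    terms <- sample(leaves_of[[b]], sample(2:3, 1L))
    if (stats::runif(1) < 0.1) {
      other <- sample(setdiff(seq_len(k), b), 1L)
      terms <- c(terms, sample(leaves_of[[other]], 1L))
    }
    unique(terms)
  })
  names(annot_list) <- nodes
  annot <- gene_annotation(annot_list, dag)

  ## --- disease genes: SNPs, gene models, source lists, GMT ----------------
  set.seed(.sub_seed(seed, 4L))
  disease_block <- 1L
  db_genes <- sort(blocks[[disease_block]])
  catalog_planted <- db_genes[seq_len(ceiling(length(db_genes) * 0.5))]
  catalog_noise <- sort(sample(setdiff(nodes, db_genes), 2L))
  catalog_target_genes <- c(catalog_planted, catalog_noise)

  all_genes <- c(nodes, unexpressed)
  gene_models <- do.call(rbind, lapply(seq_along(all_genes), function(j) {
    chrom <- as.character((j - 1L) %% 22L + 1L)
    slot <- (j - 1L) %/% 22L
    start <- 1e6 + slot * 6e5
    strand <- c("+", "-", ".")[j %% 3L + 1L]
    iso <- data.frame(symbol = all_genes[j], chrom = chrom, strand = strand,
                      start = start, end = start + 2e4,
                      stringsAsFactors = FALSE)
    if (j %% 5L == 0L) {
      iso <- rbind(iso, data.frame(symbol = all_genes[j], chrom = chrom,
                                   strand = strand, start = start + 5e3,
                                   end = start + 3e4,
                                   stringsAsFactors = FALSE))
    }
    iso
  }))

  gm_first <- gene_models[!duplicated(gene_models$symbol), ]
  rownames(gm_first) <- gm_first$symbol
  snp_for <- function(sym, p, off = -1000) {
    r <- gm_first[sym, ]
    data.frame(rsid = paste0("rs", abs(.sub_seed(seed, 100L)) %% 1000L,
                             match(sym, all_genes), round(off)),
               chrom = r$chrom, pos = as.integer(r$start + off), pval = p,
               trait = "trait_block1", stringsAsFactors = FALSE)
  }
  snps_sig <- do.call(rbind, lapply(catalog_target_genes, function(s) {
    snp_for(s, stats::runif(1, 1e-12, 4e-8))
  }))
  snps_weak <- do.call(rbind, lapply(
    sample(setdiff(nodes, catalog_target_genes), 10L),
    function(s) snp_for(s, stats::runif(1, 1e-6, 0.5))))
  snps_desert <- data.frame(
    rsid = sprintf("rsdesert%02d", 1:5), chrom = "1",
    pos = as.integer(1e6 + (0:4) * 6e5 + 3.2e5),
    pval = stats::runif(5, 1e-12, 1e-9), trait = "trait_block1",
    stringsAsFactors = FALSE)
  snps <- rbind(snps_sig, snps_weak, snps_desert)

  sumstat_genes <- sort(unique(c(
    catalog_planted[seq_len(max(1L, length(catalog_planted) %/% 2L))],
    sample(setdiff(db_genes, catalog_planted), 3L),
    sample(blocks[[min(2L, k)]], 2L))))
  textmining_genes <- sort(unique(c(
    sample(db_genes, 3L), c("TMONLY1", "TMONLY2"))))

  set.seed(.sub_seed(seed, 5L))
  # decoy genes pad the enrichment universe so block-level over-representation
  # stands out against a realistic background
  decoys <- sprintf("U%03d", seq_len(n))
  gmt <- stats::setNames(lapply(seq_len(k), function(b) {
    members <- sample(blocks[[b]], ceiling(length(blocks[[b]]) * 0.8))
    unique(c(members, sample(setdiff(nodes, blocks[[b]]), 2L)))
  }), sprintf("BLOCK%d_PROCESS", seq_len(k)))
  gmt <- c(gmt, stats::setNames(lapply(1:3, function(i) {
    unique(c(sample(all_genes, 5L), sample(decoys, max(10L, n %/% 4L))))
  }), sprintf("RANDOM_SET_%d", 1:3)))

  ## --- drugs ---------------------------------------------------------------
  set.seed(.sub_seed(seed, 6L))
  deg <- igraph::degree(g)
  pick_target <- function(b) {
    cand <- setdiff(blocks[[b]], tfs)
    cand[order(-deg[cand], cand)][2L]
  }
  pos_target <- pick_target(disease_block)
  neg_target <- pick_target(k)
  drugs <- data.frame(
    drug_id = c("D_POS", "D_NEG", "D_MID", "D_EXP", "D_INACT"),
    name = c("poscontrolin", "negcontrolin", "midrin", "experimin",
             "inactin"),
    target = c(pos_target, neg_target, pick_target(min(2L, k)),
               pick_target(disease_block), pick_target(min(2L, k))),
    action = c("inhibitor", "agonist", "inhibitor", "inhibitor", "agonist"),
    status = c("approved", "approved", "approved", "experimental",
               "approved"),
    pharm_active = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)

  sig_genes_for <- function(target, b) {
    own <- setdiff(blocks[[b]], target)
    up <- sample(own, min(8L, length(own)))
    down <- c(sample(setdiff(nodes, blocks[[b]]), 4L),
              "OFFNET1", "OFFNET2")
    list(up = up, down = down)
  }
  pos_sig <- sig_genes_for(pos_target, disease_block)
  neg_sig <- sig_genes_for(neg_target, k)
  mid_sig <- sig_genes_for(drugs$target[3L], min(2L, k))

  sig_rows <- function(drug_id, sig_id, gold, strength, genes) {
    one <- function(direction, gg) {
      if (!length(gg)) return(NULL)
      data.frame(drug_id = drug_id, signature_id = sig_id, is_gold = gold,
                 strength = strength, direction = direction, gene = gg,
                 rank = seq_along(gg), stringsAsFactors = FALSE)
    }
    rbind(one("up", genes$up), one("down", genes$down))
  }
  signatures <- rbind(
    sig_rows("D_POS", "SIG_POS_A", 1L, 7.3, pos_sig),
    sig_rows("D_POS", "SIG_POS_B", 1L, 5.1,
             list(up = pos_sig$up[1:4], down = pos_sig$down[1:2])),
    sig_rows("D_POS", "SIG_POS_C", 0L, 9.9,
             list(up = pos_sig$up[1:2], down = character(0))),
    sig_rows("D_NEG", "SIG_NEG_A", 1L, 6.0, neg_sig),
    sig_rows("D_MID", "SIG_MID_A", 1L, 6.5, mid_sig),
    sig_rows("D_INACT", "SIG_INA_A", 1L, 5.0, mid_sig))

  ## --- triage tables -------------------------------------------------------
  association <- data.frame(
    target = c(neg_target, pos_target, drugs$target[3L]),
    trait = c("obesity", "unrelated trait", "hypertension"),
    score = c(0.55, 0.9, 0.05),
    stringsAsFactors = FALSE)
  contraindications <- data.frame(
    drug_id = c("D_MID", "D_NEG"),
    condition = c("Hypertension", "migraine"),
    stringsAsFactors = FALSE)
  tissue_expression <- data.frame(
    gene = c(pos_target, neg_target),
    tissue = c("adipose", "brain"),
    category = c("tissue enriched", "tissue enriched"),
    stringsAsFactors = FALSE)

  ground_truth <- list(
    seed = seed, profile = profile, n_blocks = k,
    membership = as.list(membership),
    tf_nodes = tfs,
    disease_block = disease_block,
    disease_genes = sort(intersect(
      unique(c(catalog_target_genes, sumstat_genes, textmining_genes)),
      db_genes)),
    catalog_genes = catalog_target_genes,
    positive_drug = "D_POS", negative_drug = "D_NEG",
    positive_target = pos_target, negative_target = neg_target)

  structure(list(
    graph = g, membership = membership,
    regulatory = rbind(reg, reg_noise),
    ppi = rbind(ppi, ppi_noise),
    expression = expression,
    dag = dag, annotations = annot,
    gene_models = gene_models, snps = snps,
    sumstat_genes = sumstat_genes, textmining_genes = textmining_genes,
    gmt = gmt,
    drugs = drugs, signatures = signatures,
    association = association, contraindications = contraindications,
    tissue_expression = tissue_expression,
    ground_truth = ground_truth
  ), class = "fixture_bundle")
}

#' Write a fixture bundle to disk in the toolkit's input formats
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Files written: `ontology.obo`,
#'   `annotations.tsv`, `regulatory.tsv`, `ppi.tsv`, `expression.tsv`,
#'   `snps.tsv`, `gene_models.tsv`, `sumstat_genes.txt`,
#'   `textmining_genes.txt`, `libraries.gmt`, `drugs.tsv`, `signatures.tsv`,
#'   `association.tsv`, `contraindications.tsv`, `tissue_expression.tsv`,
#'   `ground_truth.json`.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_obo(bundle$dag, file.path(dir, "ontology.obo"))
  ann <- data.frame(
    gene = rep(names(bundle$annotations),
               vapply(bundle$annotations, length, 1L)),
    go_id = unlist(bundle$annotations, use.names = FALSE),
    stringsAsFactors = FALSE)
  tsv(ann, "annotations.tsv")
  tsv(bundle$regulatory, "regulatory.tsv")
  tsv(bundle$ppi, "ppi.tsv")
  tsv(bundle$expression, "expression.tsv")
  tsv(bundle$snps, "snps.tsv")
  tsv(bundle$gene_models, "gene_models.tsv")
  writeLines(bundle$sumstat_genes, file.path(dir, "sumstat_genes.txt"))
  writeLines(bundle$textmining_genes, file.path(dir, "textmining_genes.txt"))
  gmt_lines <- vapply(names(bundle$gmt), function(nm) {
    paste(c(nm, "synthetic", bundle$gmt[[nm]]), collapse = "\t")
  }, "")
  writeLines(gmt_lines, file.path(dir, "libraries.gmt"))
  tsv(bundle$drugs, "drugs.tsv")
  tsv(bundle$signatures, "signatures.tsv")
  tsv(bundle$association, "association.tsv")
  tsv(bundle$contraindications, "contraindications.tsv")
  tsv(bundle$tissue_expression, "tissue_expression.tsv")
  jsonlite::write_json(bundle$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
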
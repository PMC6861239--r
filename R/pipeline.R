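#' Default run configuration
#'
#' All thresholds default to the framework's canonical values: genome-wide
#' SNP significance 5e-8 (strict), gene-region extension 110 kb upstream /
#' 40 kb downstream, regulatory edge weight >= 0.4, PPI confidence >= 0.73,
#' expression RPKM >= 1, signature-gene semantic similarity >= 0.5,
#' enrichment and module alpha 0.05, association-score exclusion >= 0.2,
#' null quantile 0.95 with 1000 random modules.
#'
#' @param ... Named overrides of the defaults (unknown keys are an error).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    tissue = "unspecified",
    p_threshold = 5e-8,
    up_bp = 110000, down_bp = 40000,
    reg_weight_min = 0.4,
    ppi_score_min = 0.73,
    rpkm_min = 1.0,
    sim_min = 0.5,
    alpha = 0.05,
    module_alpha = 0.05,
    module_min_size = 3L,
    filter_scope = "union",
    assoc_cutoff = 0.2,
    q = 0.95,
    n_random = 1000L,
    seed = 1L,
    min_bin_occupancy = 100L,
    ontology_weights = c(is_a = 0.8, part_of = 0.6),
    namespace = "biological_process",
    relevant_tissues = c("adipose", "liver", "skeletal muscle"),
    # input paths (names as written by write_fixture_bundle)
    ontology = NULL, annotations = NULL, regulatory = NULL, ppi = NULL,
    expression = NULL, snps = NULL, gene_models = NULL,
    sumstat_genes = NULL, textmining_genes = NULL, libraries = NULL,
    drugs = NULL, signatures = NULL, association = NULL,
    contraindications = NULL, tissue_expression = NULL,
    trait_terms = system.file("extdata", "metsyn_trait_terms.txt",
                              package = "netrepurpose"),
    out_dir = "results"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML (key: value) file
#'
#' @param path Path to a YAML file whose keys are [run_config()] fields.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ontology_weights)) {
    raw$ontology_weights <- unlist(raw$ontology_weights)
  }
  do.call(run_config, raw)
}

.validate_config_inputs <- function(cfg, need) {
  missing <- need[vapply(need, function(k) is.null(cfg[[k]]), TRUE)]
  if (length(missing)) {
    stop("configuration is missing input paths: ",
         paste(missing, collapse = ", "))
  }
  absent <- need[!vapply(need, function(k) file.exists(cfg[[k]]), TRUE)]
  if (length(absent)) {
    stop("configured input files do not exist: ",
         paste(vapply(absent, function(k) cfg[[k]], ""), collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' Executes gene-catalog assembly, network construction, disease-module
#' detection, drug-module construction, proximity scoring with the
#' randomization null, and triage, writing per-stage TSV outputs and a run
#' manifest (resolved configuration, its md5, seed, package version, stage
#' counts) into `cfg$out_dir`.
#'
#' @param cfg A `run_config` with all input paths set.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  .validate_config_inputs(cfg, c(
    "ontology", "annotations", "regulatory", "ppi", "expression", "snps",
    "gene_models", "sumstat_genes", "textmining_genes", "libraries",
    "drugs", "signatures"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(cfg$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  stage <- "gene_catalog"
  result <- tryCatch({
    ## 1. disease-gene list
    gm <- utils::read.table(cfg$gene_models, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    snps <- utils::read.table(cfg$snps, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    regions <- merge_and_extend(gm, cfg$up_bp, cfg$down_bp)
    mapped <- map_snps_to_genes(snps, regions, cfg$p_threshold)
    sumstat <- readLines(cfg$sumstat_genes)
    textmining <- readLines(cfg$textmining_genes)
    combined <- combine_sources(mapped$genes$symbol, sumstat, textmining)
    gmt <- read_gmt(cfg$libraries)
    gene_set <- ora_filter(combined, gmt, alpha = cfg$alpha,
                           scope = cfg$filter_scope)
    dg <- disease_genes(gene_set)
    tsv(gene_set$genes, "disease_genes.tsv")
    tsv(gene_set$enrichment, "enrichment.tsv")

    ## 2. tissue network
    stage <- "network_builder"
    reg <- load_regulatory(cfg$regulatory, cfg$reg_weight_min)
    ppi <- load_ppi(cfg$ppi, cfg$expression, cfg$ppi_score_min, cfg$rpkm_min)
    net <- integrate_network(reg, ppi, tissue = cfg$tissue)
    lcc <- lcc_and_diameter(net)
    net_el <- igraph::as_data_frame(net$graph, what = "edges")
    tsv(net_el, "network_edges.tsv")

    ## 3. disease modules
    stage <- "disease_modules"
    part <- detect_communities(lcc)
    mods <- call_disease_modules(part, dg, alpha = cfg$module_alpha,
                                 min_size = cfg$module_min_size)
    mod_tab <- as.data.frame(mods)
    mod_tab$nodes <- vapply(attr(mods, "members")[mod_tab$community],
                            paste, "", collapse = ",")
    tsv(mod_tab, "disease_modules.tsv")
    members <- disease_module_members(mods)

    ## 4. drug modules + proximity scores
    stage <- "proximity"
    dag <- read_obo(cfg$ontology)
    annot <- read_gene_annotations(cfg$annotations, dag,
                                   namespace = cfg$namespace)
    drugs <- read_drug_table(cfg$drugs)
    sigs <- read_signature_table(cfg$signatures)
    dists <- node_distances(lcc$graph)
    bins <- degree_bins(lcc, cfg$min_bin_occupancy)
    cache <- wang_cache(dag, annot, cfg$ontology_weights)
    set.seed(cfg$seed)
    skipped <- list()
    score_rows <- lapply(seq_len(nrow(drugs)), function(i) {
      drug <- drugs[i, ]
      out <- score_drug(lcc, dag, annot, drug,
                        sigs[sigs$drug_id == drug$drug_id, , drop = FALSE],
                        members, sim_min = cfg$sim_min,
                        n_random = cfg$n_random, q = cfg$q,
                        bins = bins, dists = dists, cache = cache)
      if (is.null(out)) {
        skipped[[drug$drug_id]] <<- attr(out, "reason")
      }
      out
    })
    scores <- do.call(rbind, score_rows)
    if (is.null(scores)) stop("no drug could be scored")
    tsv(scores, "proximity_scores.tsv")

    ## 5. triage
    stage <- "prioritization"
    read_opt <- function(p) {
      if (is.null(p)) NULL else utils::read.table(p, sep = "\t",
                                                  header = TRUE,
                                                  stringsAsFactors = FALSE)
    }
    sig_scores <- scores[scores$significant, , drop = FALSE]
    candidates <- triage(
      sig_scores,
      association = read_opt(cfg$association),
      contraindications = read_opt(cfg$contraindications),
      tissue_expression = read_opt(cfg$tissue_expression),
      trait_terms = readLines(cfg$trait_terms),
      relevant_tissues = cfg$relevant_tissues,
      assoc_cutoff = cfg$assoc_cutoff)
    tsv(candidates, "candidates.tsv")

    list(gene_set = gene_set, network = net, lcc = lcc, partition = part,
         modules = mods, scores = scores, candidates = candidates,
         skipped_drugs = skipped)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  cfg_path <- file.path(cfg$out_dir, "config_resolved.yaml")
  yaml::write_yaml(lapply(unclass(cfg), function(x) {
    if (is.null(x)) "" else x
  }), cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("netrepurpose")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed, tissue = cfg$tissue,
    n_disease_genes = length(disease_genes(result$gene_set)),
    n_network_nodes = result$network$report$n_nodes,
    n_network_edges = result$network$report$n_edges,
    lcc_size = igraph::vcount(result$lcc$graph),
    diameter = result$lcc$diameter,
    n_communities = length(result$partition$communities),
    n_significant_modules = sum(result$modules$significant),
    n_scored = nrow(result$scores),
    n_significant_scores = sum(result$scores$significant),
    n_candidates = sum(result$candidates$excluded_by == ""),
    skipped_drugs = result$skipped_drugs)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}
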
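#' Merge transcript isoforms and extend gene regions
#'
#' Collapses per-transcript records to one interval per gene symbol (minimal
#' start, maximal end; 1-based closed coordinates) and extends the merged
#' interval in a strand-aware fashion: 110 kb upstream and 40 kb downstream
#' of the transcript boundaries by default. Genes on the plus strand are
#' extended by `up_bp` before the start and `down_bp` after the end; minus
#' strand genes are extended mirror-wise. Genes with unknown strand are
#' extended by `max(up_bp, down_bp)` on both sides. Extended starts are
#' clipped at 1. Genes outside chromosomes 1-22 are removed first.
#'
#' @param gene_models Data frame with columns `symbol`, `chrom`, `strand`
#'   (`"+"`, `"-"` or anything else for unknown), `start`, `end` (per
#'   transcript, 1-based closed).
#' @param up_bp,down_bp Upstream / downstream extension in bp.
#' @return Data frame with one row per symbol: `symbol`, `chrom`, `strand`,
#'   `start`, `end` (merged) and `ext_start`, `ext_end` (extended).
#' @export
merge_and_extend <- function(gene_models, up_bp = 110000, down_bp = 40000) {
  req <- c("symbol", "chrom", "strand", "start", "end")
  stopifnot(all(req %in% names(gene_models)))
  gm <- gene_models
  gm$chrom <- sub("^chr", "", as.character(gm$chrom))
  gm <- gm[gm$chrom %in% as.character(1:22), , drop = FALSE]

  bad <- gm$start > gm$end
  if (any(bad)) {
    message(sum(bad), " transcript records rejected (start > end)")
    gm <- gm[!bad, , drop = FALSE]
  }
  if (!nrow(gm)) {
    return(data.frame(symbol = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), ext_start = integer(0),
                      ext_end = integer(0)))
  }

  sym <- factor(gm$symbol)
  merged <- data.frame(
    symbol = levels(sym),
    chrom = tapply(gm$chrom, sym, `[`, 1L),
    strand = tapply(as.character(gm$strand), sym, `[`, 1L),
    start = as.integer(tapply(gm$start, sym, min)),
    end = as.integer(tapply(gm$end, sym, max)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  plus <- merged$strand == "+"
  minus <- merged$strand == "-"
  unk <- !plus & !minus
  ext <- max(up_bp, down_bp)
  merged$ext_start <- ifelse(plus, merged$start - up_bp,
                      ifelse(minus, merged$start - down_bp,
                             merged$start - ext))
  merged$ext_end <- ifelse(plus, merged$end + down_bp,
                    ifelse(minus, merged$end + up_bp,
                           merged$end + ext))
  merged$ext_start <- pmax(1L, as.integer(merged$ext_start))
  merged$ext_end <- as.integer(merged$ext_end)
  merged
}

#' Map trait-associated SNPs to extended gene regions
#'
#' Keeps SNPs whose association p-value is strictly below `p_threshold`
#' (genome-wide significance, 5e-8, by default) and returns every gene whose
#' extended interval contains at least one passing SNP on the same
#' chromosome. All overlapping genes are kept: there is no nearest-gene
#' tie-break. Overlap is computed with `GenomicRanges`.
#'
#' @param snps Data frame with columns `rsid`, `chrom`, `pos`, `pval`
#'   (optionally `trait`).
#' @param regions Output of [merge_and_extend()].
#' @param p_threshold Strict upper bound on the association p-value.
#' @return A list with `genes` (data frame `symbol`, `n_snps`, `snps`
#'   comma-joined rsids) and `skipped_snps` (count of passing SNPs whose
#'   chromosome has no gene model).
#' @export
map_snps_to_genes <- function(snps, regions, p_threshold = 5e-8) {
  stopifnot(all(c("rsid", "chrom", "pos", "pval") %in% names(snps)))
  snps$chrom <- sub("^chr", "", as.character(snps$chrom))
  pass <- snps[snps$pval < p_threshold, , drop = FALSE]
  empty <- data.frame(symbol = character(0), n_snps = integer(0),
                      snps = character(0))
  if (!nrow(pass) || !nrow(regions)) {
    return(list(genes = empty, skipped_snps = nrow(pass)))
  }
  known <- pass$chrom %in% unique(regions$chrom)
  skipped <- sum(!known)
  pass <- pass[known, , drop = FALSE]
  if (!nrow(pass)) return(list(genes = empty, skipped_snps = skipped))

  snp_gr <- GenomicRanges::GRanges(
    pass$chrom, IRanges::IRanges(pass$pos, width = 1L))
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$ext_start, regions$ext_end))
  ov <- GenomicRanges::findOverlaps(snp_gr, reg_gr)
  if (!length(ov)) return(list(genes = empty, skipped_snps = skipped))

  hit_sym <- regions$symbol[S4Vectors::subjectHits(ov)]
  hit_rs <- pass$rsid[S4Vectors::queryHits(ov)]
  by_gene <- split(hit_rs, hit_sym)
  genes <- data.frame(
    symbol = names(by_gene),
    n_snps = vapply(by_gene, function(x) length(unique(x)), 1L),
    snps = vapply(by_gene, function(x) paste(unique(x), collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(genes = genes[order(genes$symbol), , drop = FALSE],
       skipped_snps = skipped)
}

#' Enrichment of SNPs in annotated genomic regions
#'
#' Compares the fraction of query SNPs falling inside a set of annotated
#' intervals (e.g. chromatin states) with the fraction of background SNPs,
#' using a two-sided Fisher's exact test on the 2x2 in/out-by-query/background
#' table. The odds ratio reported is the sample (cross-product) odds ratio.
#'
#' @param query_snps,background_snps Data frames with `chrom` and `pos`.
#' @param intervals Data frame with `chrom`, `start`, `end` (1-based closed).
#' @return A list: `table` (2x2 matrix), `odds_ratio` (sample OR; `NaN` with
#'   `degenerate = TRUE` when a margin is zero), `p_value` (two-sided exact),
#'   `degenerate`.
#' @export
region_overlap_enrichment <- function(query_snps, background_snps, intervals) {
  if (is.null(query_snps) || !nrow(query_snps)) stop("empty query")
  count_in <- function(snps) {
    snp_gr <- GenomicRanges::GRanges(
      sub("^chr", "", as.character(snps$chrom)),
      IRanges::IRanges(snps$pos, width = 1L))
    int_gr <- GenomicRanges::GRanges(
      sub("^chr", "", as.character(intervals$chrom)),
      IRanges::IRanges(intervals$start, intervals$end))
    sum(IRanges::overlapsAny(snp_gr, int_gr))
  }
  a <- count_in(query_snps)                    # query, in region
  b <- nrow(query_snps) - a                    # query, out
  c_ <- count_in(background_snps)              # background, in
  d <- nrow(background_snps) - c_              # background, out
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = FALSE,
                dimnames = list(c("in_region", "out_region"),
                                c("query", "background")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(list(table = tab, odds_ratio = NaN, p_value = 1,
                degenerate = TRUE))
  }
  or <- (a * d) / (b * c_)
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p_value = p, degenerate = FALSE)
}

#' Read a GMT gene-set library
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' Combine disease-gene sources
#'
#' Takes the three gene lists (GWAS catalog mapping, gene-level summary
#' statistics, text mining), deduplicates within each source, and returns the
#' union with per-gene source flags plus the seven disjoint Venn-region
#' counts.
#'
#' @param catalog_genes,sumstat_genes,textmining_genes Character vectors.
#' @return List of class `disease_gene_set`: `genes` (data frame `symbol`,
#'   logical columns `catalog`, `sumstats`, `textmining`, `sources`
#'   comma-joined), `venn` (named counts of the 7 disjoint regions).
#' @export
combine_sources <- function(catalog_genes, sumstat_genes, textmining_genes) {
  dedup <- function(x, label) {
    x <- as.character(x)
    nd <- length(x) - length(unique(x))
    if (nd > 0L) message(nd, " duplicate symbols removed from ", label)
    unique(x)
  }
  cat_g <- dedup(catalog_genes, "catalog")
  sum_g <- dedup(sumstat_genes, "sumstats")
  txt_g <- dedup(textmining_genes, "textmining")
  all_g <- sort(union(union(cat_g, sum_g), txt_g))
  if (!length(all_g)) warning("all three sources are empty")

  genes <- data.frame(
    symbol = all_g,
    catalog = all_g %in% cat_g,
    sumstats = all_g %in% sum_g,
    textmining = all_g %in% txt_g,
    stringsAsFactors = FALSE
  )
  genes$sources <- apply(genes[, c("catalog", "sumstats", "textmining")], 1L,
                         function(r) paste(c("catalog", "sumstats",
                                             "textmining")[r], collapse = ","))
  key <- paste0(ifelse(genes$catalog, "C", ""),
                ifelse(genes$sumstats, "S", ""),
                ifelse(genes$textmining, "T", ""))
  venn <- table(factor(key, levels = c("C", "S", "T", "CS", "CT", "ST", "CST")))
  structure(list(genes = genes, venn = c(venn)), class = "disease_gene_set")
}

#' Over-representation test of a gene list against GMT libraries
#'
#' One-sided hypergeometric upper-tail p-value per gene set, with
#' Benjamini-Hochberg correction computed jointly across all sets of all
#' libraries. Gene sets with no overlap with the universe are skipped.
#'
#' @param genes Character vector (query list).
#' @param libraries Named list of gene sets, or a list of such lists (one per
#'   library).
#' @param universe Character vector of background genes. Defaults to the
#'   union of all library genes.
#' @param alpha BH-adjusted significance level for the `significant` flag.
#' @return Data frame: `set`, `size` (in-universe set size), `overlap`,
#'   `odds_ratio`, `p`, `p_adj`, `significant`, sorted by `p`.
#' @export
ora_test <- function(genes, libraries, universe = NULL, alpha = 0.05) {
  if (is.list(libraries) && length(libraries) &&
      is.list(libraries[[1L]]) && !is.character(libraries[[1L]])) {
    libraries <- do.call(c, unname(libraries))
  }
  if (is.null(universe)) {
    universe <- unique(unlist(libraries, use.names = FALSE))
  }
  universe <- unique(as.character(universe))
  q <- unique(intersect(genes, universe))
  n_univ <- length(universe)

  rows <- lapply(names(libraries), function(nm) {
    set <- intersect(libraries[[nm]], universe)
    if (!length(set)) return(NULL)
    k <- length(intersect(q, set))
    # P[X >= k], X ~ Hypergeom(N = n_univ, K = |set|, n = |q|)
    p <- stats::phyper(k - 1L, length(set), n_univ - length(set), length(q),
                       lower.tail = FALSE)
    or_num <- k * (n_univ - length(set) - length(q) + k)
    or_den <- (length(set) - k) * (length(q) - k)
    data.frame(set = nm, size = length(set), overlap = k,
               odds_ratio = if (or_den == 0) Inf else or_num / or_den,
               p = p, stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  if (skipped) message(skipped, " gene sets skipped (no universe overlap)")
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(set = character(0), size = integer(0),
                      overlap = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  res[order(res$p), , drop = FALSE]
}

#' Filter the combined disease-gene set by pathway over-representation
#'
#' Computes over-representation p-values from the data-driven (GWAS-derived)
#' genes only, then retains genes of the chosen scope that belong to at least
#' one significant set (BH-adjusted p below `alpha`). By default the
#' retain rule is applied to the full three-source union
#' (`scope = "union"`); `scope = "gwas_only"` restricts both the test and the
#' retention to the GWAS-derived genes.
#'
#' @param gene_set A `disease_gene_set` from [combine_sources()].
#' @param libraries GMT libraries as in [ora_test()].
#' @param universe Background gene universe (required unless libraries imply
#'   it; see [ora_test()]).
#' @param alpha BH-adjusted significance level.
#' @param scope `"union"` or `"gwas_only"`.
#' @return The input `disease_gene_set` with added `retained` logical column
#'   and attributes: element `enrichment` (the [ora_test()] table over all
#'   sets) and `significant_sets`.
#' @export
ora_filter <- function(gene_set, libraries, universe = NULL, alpha = 0.05,
                       scope = c("union", "gwas_only")) {
  scope <- match.arg(scope)
  stopifnot(inherits(gene_set, "disease_gene_set"))
  g <- gene_set$genes
  gwas_genes <- g$symbol[g$catalog | g$sumstats]
  enr <- ora_test(gwas_genes, libraries, universe = universe, alpha = alpha)

  if (is.list(libraries) && length(libraries) &&
      is.list(libraries[[1L]]) && !is.character(libraries[[1L]])) {
    libraries <- do.call(c, unname(libraries))
  }
  sig_sets <- enr$set[enr$significant]
  sig_members <- unique(unlist(libraries[sig_sets], use.names = FALSE))
  candidates <- if (scope == "union") g$symbol else gwas_genes
  g$retained <- g$symbol %in% candidates & g$symbol %in% sig_members
  gene_set$genes <- g
  gene_set$enrichment <- enr
  gene_set$significant_sets <- sig_sets
  gene_set
}

#' Retained disease genes
#'
#' @param gene_set A `disease_gene_set` after [ora_filter()].
#' @return Character vector of retained gene symbols.
#' @export
disease_genes <- function(gene_set) {
  stopifnot(inherits(gene_set, "disease_gene_set"))
  if (is.null(gene_set$genes$retained)) return(gene_set$genes$symbol)
  gene_set$genes$symbol[gene_set$genes$retained]
}
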
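#' Wang semantic S-values for a GO term
#'
#' Computes the semantic contribution of every ancestor of an anchor term
#' under the Wang graph-based measure: the anchor has S-value 1 and each
#' ancestor `t` receives the best decayed contribution
#' `S(t) = max over children c of t within the anchor's closure of
#' w(relation) * S(c)`, where `w` is a per-relation decay factor.
#'
#' @param dag A `go_dag`.
#' @param term Anchor term id (alt ids are resolved).
#' @param weights Named decay factors per relation. Defaults to the measure's
#'   published values `c(is_a = 0.8, part_of = 0.6)`.
#' @return A list of class `svalue_map` with elements `term` (canonical
#'   anchor), `s` (named numeric, term -> S-value; includes the anchor) and
#'   `sv` (sum of S-values, the semantic value of the anchor).
#' @examples
#' \dontrun{
#' sv <- svalues(dag, "GO:0008150")
#' sv$sv
#' }
#' @export
svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  canon <- resolve_term(dag, term)
  if (is.na(canon)) stop("term absent from ontology: ", term)
  if (dag$obsolete[[canon]]) stop("term is obsolete: ", canon)

  # ancestor closure (anchor + all reachable parents)
  closure <- character(0)
  frontier <- canon
  while (length(frontier)) {
    closure <- c(closure, frontier)
    nxt <- unique(unlist(lapply(frontier, function(t) dag$parents[[t]]$parent),
                         use.names = FALSE))
    frontier <- setdiff(nxt, closure)
  }

  s <- stats::setNames(rep(0, length(closure)), closure)
  s[[canon]] <- 1

  # Kahn order over the closure subgraph (child -> parent edges)
  indeg <- stats::setNames(integer(length(closure)), closure)
  for (t in closure) {
    ps <- dag$parents[[t]]
    if (nrow(ps)) {
      for (p in intersect(ps$parent, closure)) indeg[[p]] <- indeg[[p]] + 1L
    }
  }
  queue <- closure[indeg[closure] == 0L]  # the anchor (leaves of the closure)
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    ps <- dag$parents[[t]]
    if (!nrow(ps)) next
    for (i in seq_len(nrow(ps))) {
      p <- ps$parent[i]
      if (!(p %in% closure)) next
      rel <- ps$relation[i]
      w <- if (rel %in% names(weights)) weights[[rel]] else 0
      cand <- w * s[[t]]
      if (cand > s[[p]]) s[[p]] <- cand
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }

  structure(list(term = canon, s = s, sv = sum(s)), class = "svalue_map")
}

#' Wang similarity between two GO terms
#'
#' `sim(A, B) = sum over shared ancestors t of (S_A(t) + S_B(t)) /
#' (SV(A) + SV(B))`. Terms from different namespaces are defined to have
#' similarity 0 (with a warning).
#'
#' @inheritParams svalues
#' @param a,b Term ids.
#' @return Similarity in `[0, 1]`.
#' @export
term_similarity <- function(dag, a, b, weights = c(is_a = 0.8, part_of = 0.6)) {
  ca <- resolve_term(dag, a); cb <- resolve_term(dag, b)
  if (is.na(ca)) stop("term absent from ontology: ", a)
  if (is.na(cb)) stop("term absent from ontology: ", b)
  nsa <- dag$namespace[[ca]]; nsb <- dag$namespace[[cb]]
  if (!is.na(nsa) && !is.na(nsb) && nsa != nsb) {
    warning("terms belong to different namespaces; similarity defined as 0")
    return(0)
  }
  sa <- svalues(dag, ca, weights)
  sb <- svalues(dag, cb, weights)
  common <- intersect(names(sa$s), names(sb$s))
  if (!length(common)) return(0)
  sum(sa$s[common] + sb$s[common]) / (sa$sv + sb$sv)
}

#' Memoized Wang similarity engine
#'
#' Builds a closure-backed cache of term-level and gene-level similarities so
#' that repeated module scoring (in particular the randomization null) does
#' not recompute S-value maps. The cache is keyed on canonical term pairs and
#' gene pairs; the underlying values are identical to [term_similarity()] and
#' [gene_similarity()].
#'
#' @inheritParams svalues
#' @param annot A `gene_annotation`.
#' @return A list with functions `term_sim(a, b)` and `gene_sim(g1, g2)` and
#'   the annotation used.
#' @export
wang_cache <- function(dag, annot, weights = c(is_a = 0.8, part_of = 0.6)) {
  sv_env <- new.env(parent = emptyenv())
  ts_env <- new.env(parent = emptyenv())
  gs_env <- new.env(parent = emptyenv())

  get_sv <- function(t) {
    v <- sv_env[[t]]
    if (is.null(v)) {
      v <- svalues(dag, t, weights)
      assign(t, v, envir = sv_env)
    }
    v
  }
  term_sim <- function(a, b) {
    key <- if (a <= b) paste(a, b) else paste(b, a)
    v <- ts_env[[key]]
    if (is.null(v)) {
      sa <- get_sv(a); sb <- get_sv(b)
      common <- intersect(names(sa$s), names(sb$s))
      v <- if (length(common)) sum(sa$s[common] + sb$s[common]) / (sa$sv + sb$sv) else 0
      assign(key, v, envir = ts_env)
    }
    v
  }
  gene_sim <- function(g1, g2) {
    key <- if (g1 <= g2) paste(g1, g2) else paste(g2, g1)
    v <- gs_env[[key]]
    if (is.null(v)) {
      t1 <- annot[[g1]]; t2 <- annot[[g2]]
      if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2)) {
        v <- NA_real_
      } else {
        m <- matrix(0, length(t1), length(t2))
        for (i in seq_along(t1)) for (j in seq_along(t2)) {
          m[i, j] <- term_sim(t1[i], t2[j])
        }
        v <- .bma(m)
      }
      assign(key, v, envir = gs_env)
    }
    v
  }
  list(term_sim = term_sim, gene_sim = gene_sim, annot = annot)
}

# Best-Match Average of a similarity matrix: mean of row maxima and column
# maxima pooled, (sum rowmax + sum colmax) / (nrow + ncol).
.bma <- function(m) {
  (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) / (nrow(m) + ncol(m))
}

#' Wang/BMA similarity between two genes
#'
#' Best-Match Average over the two genes' GO term sets: for the pairwise
#' term-similarity matrix, the average of all row maxima and column maxima.
#'
#' @inheritParams svalues
#' @param annot A `gene_annotation`.
#' @param g1,g2 Gene symbols.
#' @return Similarity in `[0, 1]`, or `NA` if either gene has no annotation.
#' @export
gene_similarity <- function(dag, annot, g1, g2,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  wang_cache(dag, annot, weights)$gene_sim(g1, g2)
}

#' Wang/BMA similarity between two gene sets
#'
#' Gene-level similarities are the BMA over term sets; the set-level value is
#' by default the BMA over the gene-by-gene similarity matrix
#' (`method = "bma_genes"`). Alternatively the two sets' term annotations can
#' be pooled and a single term-level BMA computed (`method = "pooled_terms"`).
#' Genes without annotation are dropped from the matrix (with a message).
#'
#' @inheritParams gene_similarity
#' @param genes_a,genes_b Character vectors of gene symbols.
#' @param method `"bma_genes"` (default) or `"pooled_terms"`.
#' @param cache Optional [wang_cache()] to reuse across calls.
#' @return Similarity in `[0, 1]`.
#' @export
gene_set_similarity <- function(dag, annot, genes_a, genes_b,
                                weights = c(is_a = 0.8, part_of = 0.6),
                                method = c("bma_genes", "pooled_terms"),
                                cache = NULL) {
  method <- match.arg(method)
  if (is.null(cache)) cache <- wang_cache(dag, annot, weights)
  annotated <- function(gs) gs[vapply(gs, function(g) {
    t <- cache$annot[[g]]; !is.null(t) && length(t) > 0L
  }, TRUE)]
  ga <- annotated(unique(genes_a))
  gb <- annotated(unique(genes_b))
  n_drop <- (length(unique(genes_a)) - length(ga)) +
    (length(unique(genes_b)) - length(gb))
  if (n_drop > 0L) message(n_drop, " unannotated genes dropped from BMA matrix")
  if (!length(ga) || !length(gb)) stop("no annotated genes")

  if (method == "pooled_terms") {
    ta <- unique(unlist(cache$annot[ga], use.names = FALSE))
    tb <- unique(unlist(cache$annot[gb], use.names = FALSE))
    m <- matrix(0, length(ta), length(tb))
    for (i in seq_along(ta)) for (j in seq_along(tb)) {
      m[i, j] <- cache$term_sim(ta[i], tb[j])
    }
    return(.bma(m))
  }
  m <- matrix(0, length(ga), length(gb))
  for (i in seq_along(ga)) for (j in seq_along(gb)) {
    m[i, j] <- cache$gene_sim(ga[i], gb[j])
  }
  .bma(m)
}
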
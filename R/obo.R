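#' Read a Gene Ontology DAG from an OBO file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file (the go-basic dialect) into
#' a directed acyclic graph over GO terms. Only `is_a` and
#' `relationship: part_of` edges are retained; other relationship types are
#' dropped with a warning. Obsolete terms are kept (so identifiers resolve)
#' but carry no edges. `alt_id` entries are recorded so that secondary
#' identifiers resolve to their canonical term.
#'
#' @param path Path to an OBO file.
#' @return An object of class `go_dag`: a list with elements
#'   `terms` (character vector of canonical ids), `name`, `namespace`,
#'   `obsolete` (named vectors over `terms`), `parents` (named list; each
#'   element a data frame with columns `parent` and `relation`), `children`
#'   (reverse index) and `alt` (named character, alt id -> canonical id).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: GO:1", "name: root", "namespace: biological_process",
#'              "", "[Term]", "id: GO:2", "name: child",
#'              "namespace: biological_process", "is_a: GO:1 ! root"), obo)
#' dag <- read_obo(obo)
#' dag$parents[["GO:2"]]
#' @export
read_obo <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)

  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) stop("no stanzas found in OBO file: ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  keep <- lines[starts] == "[Term]"

  ids <- character(0)
  name <- character(0)
  namespace <- character(0)
  obsolete <- logical(0)
  parent_from <- character(0)
  parent_to <- character(0)
  parent_rel <- character(0)
  alt_from <- character(0)
  alt_to <- character(0)
  unknown_rel <- character(0)

  strip_comment <- function(x) sub("\\s*!.*$", "", x)

  for (k in which(keep)) {
    block <- lines[(starts[k] + 1L):ends[k]]
    block <- block[nzchar(block)]
    field <- sub(":.*$", "", block)
    value <- trimws(sub("^[^:]+:\\s*", "", block))

    id <- value[field == "id"][1L]
    if (is.na(id)) next
    obs <- any(field == "is_obsolete" & value == "true")

    ids <- c(ids, id)
    nm <- value[field == "name"]
    name <- c(name, if (length(nm)) nm[1L] else NA_character_)
    ns <- value[field == "namespace"]
    namespace <- c(namespace, if (length(ns)) ns[1L] else NA_character_)
    obsolete <- c(obsolete, obs)

    alts <- value[field == "alt_id"]
    if (length(alts)) {
      alt_from <- c(alt_from, alts)
      alt_to <- c(alt_to, rep(id, length(alts)))
    }

    if (obs) next  # obsolete terms carry no edges

    isa <- strip_comment(value[field == "is_a"])
    if (length(isa)) {
      parent_from <- c(parent_from, rep(id, length(isa)))
      parent_to <- c(parent_to, trimws(isa))
      parent_rel <- c(parent_rel, rep("is_a", length(isa)))
    }
    rels <- strip_comment(value[field == "relationship"])
    for (r in rels) {
      parts <- strsplit(trimws(r), "\\s+")[[1L]]
      if (length(parts) < 2L) next
      if (parts[1L] == "part_of") {
        parent_from <- c(parent_from, id)
        parent_to <- c(parent_to, parts[2L])
        parent_rel <- c(parent_rel, "part_of")
      } else {
        unknown_rel <- c(unknown_rel, parts[1L])
      }
    }
  }

  if (anyDuplicated(ids)) stop("duplicate term ids in OBO file")
  if (length(unknown_rel)) {
    warning("ignored relationship types: ",
            paste(sort(unique(unknown_rel)), collapse = ", "))
  }

  # drop edges pointing outside the loaded term set (go-basic keeps them in)
  ok <- parent_to %in% ids & parent_from %in% ids
  parent_from <- parent_from[ok]; parent_to <- parent_to[ok]
  parent_rel <- parent_rel[ok]

  names(name) <- ids; names(namespace) <- ids; names(obsolete) <- ids

  parents <- split(
    data.frame(parent = parent_to, relation = parent_rel,
               stringsAsFactors = FALSE),
    factor(parent_from, levels = ids)
  )
  children <- split(
    data.frame(child = parent_from, relation = parent_rel,
               stringsAsFactors = FALSE),
    factor(parent_to, levels = ids)
  )

  dag <- structure(
    list(terms = ids, name = name, namespace = namespace,
         obsolete = obsolete, parents = parents, children = children,
         alt = stats::setNames(alt_to, alt_from)),
    class = "go_dag"
  )
  cyc <- .dag_find_cycle(dag)
  if (!is.null(cyc)) {
    stop("ontology graph is cyclic; cycle involves term ", cyc)
  }
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  nedge <- sum(vapply(x$parents, nrow, 1L))
  cat("GO DAG:", length(x$terms), "terms,", nedge, "edges,",
      sum(x$obsolete), "obsolete\n")
  invisible(x)
}

# Kahn's algorithm; returns NULL when acyclic, otherwise a term on a cycle.
.dag_find_cycle <- function(dag) {
  indeg <- vapply(dag$children, nrow, 1L)  # parents with unprocessed children
  live <- !dag$obsolete
  queue <- dag$terms[indeg == 0L & live]
  seen <- 0L
  total <- sum(live)
  indeg <- stats::setNames(as.integer(indeg), dag$terms)
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    ps <- dag$parents[[t]]
    if (nrow(ps)) {
      for (p in ps$parent) {
        indeg[[p]] <- indeg[[p]] - 1L
        if (indeg[[p]] == 0L) queue <- c(queue, p)
      }
    }
  }
  if (seen < total) {
    dag$terms[live][which(indeg[dag$terms[live]] > 0L)][1L]
  } else NULL
}

#' Resolve a (possibly secondary) term identifier to its canonical id
#'
#' @param dag A `go_dag`.
#' @param term Term identifier, possibly an `alt_id`.
#' @return Canonical term id, or `NA_character_` if unknown.
#' @export
resolve_term <- function(dag, term) {
  if (term %in% dag$terms) return(term)
  if (term %in% names(dag$alt)) return(unname(dag$alt[[term]]))
  NA_character_
}

#' Read gene-to-GO annotations
#'
#' Accepts either a two-column TSV (gene symbol, GO id; a header line is
#' tolerated — its second field fails term validation and is dropped) or a
#' GAF 2.x file, from which the object id, GO id, evidence code and aspect
#' columns (2, 5, 7, 9) are used. Annotations are restricted to one namespace
#' (biological process by default), mapped through `alt_id`, and annotations
#' to unknown or obsolete terms are dropped with a message.
#'
#' @param path Path to the annotation file.
#' @param dag A `go_dag` used to validate terms.
#' @param namespace Namespace to keep (default `"biological_process"`).
#' @param exclude_evidence Optional character vector of GAF evidence codes to
#'   drop (ignored for two-column input).
#' @return A named list of class `gene_annotation`: gene symbol -> character
#'   vector of GO term ids.
#' @export
read_gene_annotations <- function(path, dag,
                                  namespace = "biological_process",
                                  exclude_evidence = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, 1L)
  if (all(ncol >= 9L)) {
    gene <- vapply(fields, `[[`, "", 2L)
    go <- vapply(fields, `[[`, "", 5L)
    ev <- vapply(fields, `[[`, "", 7L)
    aspect <- vapply(fields, `[[`, "", 9L)
    ns <- c(P = "biological_process", F = "molecular_function",
            C = "cellular_component")[aspect]
    keep <- ns == namespace
    if (!is.null(exclude_evidence)) keep <- keep & !(ev %in% exclude_evidence)
    gene <- gene[keep]; go <- go[keep]
  } else {
    gene <- vapply(fields, `[[`, "", 1L)
    go <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", "")
    keep <- nzchar(go)
    # a header line is caught below: its "term" does not resolve in the DAG
    gene <- gene[keep]; go <- go[keep]
  }
  canon <- vapply(go, function(t) resolve_term(dag, t), "")
  valid <- !is.na(canon) & !dag$obsolete[canon] &
    dag$namespace[canon] == namespace
  valid[is.na(valid)] <- FALSE
  if (any(!valid)) {
    message(sum(!valid), " annotation rows dropped (unknown, obsolete or ",
            "off-namespace terms)")
  }
  ann <- lapply(split(canon[valid], gene[valid]), function(x) unique(unname(x)))
  structure(ann, class = "gene_annotation")
}

#' Build an annotation object from an in-memory list
#'
#' @param x Named list: gene symbol -> character vector of term ids.
#' @param dag A `go_dag`; terms are validated against it.
#' @return A `gene_annotation`.
#' @export
gene_annotation <- function(x, dag) {
  stopifnot(is.list(x), !is.null(names(x)))
  for (g in names(x)) {
    bad <- setdiff(x[[g]], dag$terms)
    if (length(bad)) stop("gene ", g, " annotated to unknown terms: ",
                          paste(bad, collapse = ", "))
  }
  structure(lapply(x, function(v) unique(as.character(v))),
            class = "gene_annotation")
}
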
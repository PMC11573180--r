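#' Read a Gene Ontology OBO 1.2 flat file
#'
#' Consumes only `[Term]` stanzas and the tags `id`, `name`, `namespace`,
#' `is_a` and `is_obsolete`. Obsolete terms are excluded. The `is_a`
#' relation must form a directed acyclic graph; a cycle is an error naming
#' the terms involved.
#'
#' @param path Path to an OBO file.
#' @return An object of class `go_ontology`: a list with `terms`
#'   (data.frame: `id`, `name`, `namespace`), `parents` (named list of
#'   direct `is_a` parents) and `graph` (an [igraph::igraph] with edges
#'   child -> parent).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path)
  stanza_starts <- which(lines == "[Term]")
  other_starts <- which(grepl("^\\[", lines) & lines != "[Term]")
  ids <- character(); nms <- character(); nss <- character()
  parents <- list(); obsolete <- logical()
  bounds <- c(sort(c(stanza_starts, other_starts)), length(lines) + 1L)
  for (s in stanza_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):e]
    tagval <- function(tag) {
      hit <- block[startsWith(block, paste0(tag, ": "))]
      sub(paste0("^", tag, ": "), "", hit)
    }
    id <- tagval("id")[1]
    if (is.na(id)) next
    ids <- c(ids, id)
    nm <- tagval("name")[1]
    nms <- c(nms, if (is.na(nm)) "" else nm)
    ns <- tagval("namespace")[1]
    nss <- c(nss, if (is.na(ns)) "" else ns)
    isa <- tagval("is_a")
    # "GO:0000001 ! comment" -> "GO:0000001"
    parents[[id]] <- sub("\\s*!.*$", "", isa)
    obsolete <- c(obsolete, identical(tagval("is_obsolete")[1], "true"))
  }
  keep <- !obsolete
  ids <- ids[keep]; nms <- nms[keep]; nss <- nss[keep]
  parents <- parents[ids]
  # drop is_a edges pointing at obsolete/unknown terms
  parents <- lapply(parents, function(p) p[p %in% ids])
  edges <- do.call(rbind, lapply(ids, function(id) {
    p <- parents[[id]]
    if (length(p)) cbind(id, p) else NULL
  }))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (!is.null(edges))
    g <- igraph::add_edges(g, as.vector(t(edges)))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(which(table(comp$membership) > 1))[1]
    members <- ids[comp$membership == as.integer(cyc)]
    stop("cycle in is_a relation involving: ", paste(members, collapse = ", "))
  }
  structure(list(
    terms = data.frame(id = ids, name = nms, namespace = nss,
                       stringsAsFactors = FALSE),
    parents = parents, graph = g), class = "go_ontology")
}

#' Ancestor closure of ontology terms
#'
#' Reflexive-transitive closure over `is_a`: every term is its own
#' ancestor, so `length(go_ancestors(ont, t)[[1]]) >= 1` for any known
#' term.
#'
#' @param ontology A `go_ontology` from [read_obo()].
#' @param term_ids Character vector of term ids.
#' @return A named list mapping each term id to the character vector of its
#'   ancestors (including itself). Unknown terms map to `character(0)`.
#' @export
go_ancestors <- function(ontology, term_ids) {
  stopifnot(inherits(ontology, "go_ontology"))
  known <- ontology$terms$id
  out <- lapply(term_ids, function(t) {
    if (!t %in% known) return(character(0))
    v <- igraph::subcomponent(ontology$graph, t, mode = "out")
    names(v)
  })
  names(out) <- term_ids
  out
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("go_ontology:", nrow(x$terms), "terms,",
      igraph::ecount(x$graph), "is_a edges\n")
  invisible(x)
}
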
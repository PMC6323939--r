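#' Ontology graphs restricted to is_a / part_of
#'
#' An `ontology_graph` holds a directed acyclic graph of function terms.
#' Edges point from child to parent and carry a relation type, either
#' `"is_a"` or `"part_of"` -- the two relations traversed when counting
#' annotation usage and building a slim. Each of the three GO aspects
#' (biological_process, molecular_function, cellular_component) present in
#' the graph has exactly one root, a term with no parents. Obsolete terms
#' are kept as isolated records so that stale annotations fail loudly.
#'
#' @param terms A data frame with columns `term_id`, `name`, `aspect`,
#'   `obsolete` (logical). Extra columns (e.g. slim provenance) are kept.
#' @param edges A data frame with columns `child`, `parent`, `relation`;
#'   `relation` must be `"is_a"` or `"part_of"`.
#' @return An object of class `ontology_graph`: a list with tibbles
#'   `terms` and `edges` and a character vector `roots` (one per aspect).
#' @examples
#' g <- ontology_graph(
#'   terms = tibble::tibble(
#'     term_id = c("GO:1", "GO:2"), name = c("child", "root"),
#'     aspect = "biological_process", obsolete = FALSE),
#'   edges = tibble::tibble(child = "GO:1", parent = "GO:2", relation = "is_a"))
#' term_ancestors(g, "GO:1")
#' @export
ontology_graph <- function(terms, edges) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("term_id", "name", "aspect", "obsolete") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  if (anyDuplicated(terms$term_id))
    stop("duplicate term_id: ",
         paste(unique(terms$term_id[duplicated(terms$term_id)]), collapse = ", "))
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel))
    stop("unsupported relation type(s): ", paste(bad_rel, collapse = ", "))
  dangling <- setdiff(c(edges$child, edges$parent), terms$term_id)
  if (length(dangling))
    stop("edge references unknown term(s): ", paste(dangling, collapse = ", "))

  aspect_of <- stats::setNames(terms$aspect, terms$term_id)
  cross <- aspect_of[edges$child] != aspect_of[edges$parent]
  if (any(cross))
    stop("edge crosses aspects: ", edges$child[which(cross)[1]], " -> ",
         edges$parent[which(cross)[1]])
  obs <- terms$term_id[terms$obsolete]
  if (any(edges$child %in% obs | edges$parent %in% obs))
    stop("obsolete terms must not carry edges")

  if (nrow(edges)) {
    cyc <- .find_cycle(edges)
    if (!is.null(cyc))
      stop("cycle detected: ", paste(cyc, collapse = " -> "))
  }

  live <- terms[!terms$obsolete, ]
  roots <- live$term_id[!live$term_id %in% edges$child]
  root_aspects <- aspect_of[roots]
  if (anyDuplicated(root_aspects)) {
    a <- root_aspects[duplicated(root_aspects)][1]
    stop("multiple roots in aspect ", a, ": ",
         paste(roots[root_aspects == a], collapse = ", "))
  }

  structure(
    list(terms = terms, edges = edges, roots = sort(unname(roots))),
    parent_index = .edge_index(edges$child, edges$parent),
    child_index = .edge_index(edges$parent, edges$child),
    class = "ontology_graph")
}

# adjacency as named list of character vectors
.edge_index <- function(from, to) {
  if (!length(from)) return(list())
  lapply(split(to, from), unique)
}

# returns one directed cycle (child -> ... -> child) or NULL; uses igraph
# for the DAG test, then a colored DFS to name an offending cycle
.find_cycle <- function(edges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$child, to = edges$parent), directed = TRUE)
  if (igraph::is_dag(g)) return(NULL)
  idx <- .edge_index(edges$child, edges$parent)
  color <- new.env(parent = emptyenv())
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    assign(v, 1L, envir = color)
    path[[length(path) + 1L]] <<- v
    for (w in idx[[v]] %||% character()) {
      st <- if (exists(w, envir = color, inherits = FALSE))
        get(w, envir = color) else 0L
      if (st == 1L) {
        found <<- c(path[match(w, path):length(path)], w)
        return()
      }
      if (st == 0L) visit(w)
      if (!is.null(found)) return()
    }
    assign(v, 2L, envir = color)
    path <<- path[-length(path)]
  }
  for (v in unique(edges$child)) {
    if (!exists(v, envir = color, inherits = FALSE)) visit(v)
    if (!is.null(found)) break
  }
  found
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d terms (%d obsolete), %d edges, roots: %s\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

.check_terms_exist <- function(graph, term_ids) {
  missing <- setdiff(term_ids, graph$terms$term_id)
  if (length(missing))
    stop("unknown term(s): ", paste(utils::head(missing, 5), collapse = ", "))
}

.reach <- function(index, start) {
  seen <- character()
  frontier <- index[[start]] %||% character()
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(index[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen))
}

#' Ancestors and descendants of a term
#'
#' Transitive closure over both `is_a` and `part_of` edges, excluding the
#' term itself. `term_descendants()` is the exact dual: `t` is a
#' descendant of `u` iff `u` is an ancestor of `t`.
#'
#' @param graph An [ontology_graph()].
#' @param term A single term identifier present in `graph`.
#' @return Sorted character vector of term identifiers.
#' @export
term_ancestors <- function(graph, term) {
  stopifnot(inherits(graph, "ontology_graph"), length(term) == 1)
  .check_terms_exist(graph, term)
  .reach(attr(graph, "parent_index"), term)
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(graph, term) {
  stopifnot(inherits(graph, "ontology_graph"), length(term) == 1)
  .check_terms_exist(graph, term)
  .reach(attr(graph, "child_index"), term)
}

#' Read and write OBO 1.4
#'
#' `parse_obo()` reads `[Term]` stanzas and keeps only `is_a:` and
#' `relationship: part_of` edges; any other relationship type is dropped
#' with one summary warning. `write_obo()` emits stanzas sorted by term id
#' with sorted relation lines, so identical graphs give byte-identical
#' output and `parse_obo(write_obo(g))` reproduces `g`.
#'
#' @param text Character vector of OBO lines, or a single string with
#'   embedded newlines.
#' @return `parse_obo()`: an [ontology_graph()]. `write_obo()`: the OBO
#'   lines, invisibly if `path` is given.
#' @export
parse_obo <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("\\s+$", "", lines)
  starts <- grep("^\\[", lines)
  term_starts <- starts[lines[starts] == "[Term]"]
  ends <- c(starts[-1] - 1L, length(lines))
  stanza_end <- ends[match(term_starts, starts)]

  terms <- list(); edges <- list(); dropped <- character()
  for (i in seq_along(term_starts)) {
    block <- lines[term_starts[i]:stanza_end[i]]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    kv <- regmatches(block, regexpr("^[^:]+", block))
    val <- sub("^[^:]+:\\s*", "", block)
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    id <- val[kv == "id"][1]
    if (is.na(id)) stop("[Term] stanza without id (stanza ", i, ")")
    ns <- val[kv == "namespace"][1]
    if (is.na(ns)) stop("term ", id, " has no namespace")
    terms[[i]] <- tibble::tibble(
      term_id = id,
      name = if (any(kv == "name")) val[kv == "name"][1] else id,
      aspect = ns,
      obsolete = any(kv == "is_obsolete" & val == "true"))
    is_a <- val[kv == "is_a"]
    rel <- val[kv == "relationship"]
    rel_type <- sub("\\s.*$", "", rel)
    rel_to <- sub("^\\S+\\s+", "", rel)
    keep <- rel_type == "part_of"
    dropped <- c(dropped, rel_type[!keep])
    edges[[i]] <- tibble::tibble(
      child = id,
      parent = c(is_a, rel_to[keep]),
      relation = c(rep("is_a", length(is_a)), rep("part_of", sum(keep))))
  }
  if (length(dropped))
    warning("dropped ", length(dropped), " edge(s) of unsupported type(s): ",
            paste(sort(unique(dropped)), collapse = ", "))
  ontology_graph(
    dplyr::bind_rows(
      tibble::tibble(term_id = character(), name = character(),
                     aspect = character(), obsolete = logical()),
      terms),
    dplyr::bind_rows(
      tibble::tibble(child = character(), parent = character(),
                     relation = character()),
      edges))
}

#' @rdname parse_obo
#' @param path File to read from / write to; `write_obo(graph)` with no
#'   path returns the lines.
#' @export
read_obo <- function(path) parse_obo(readLines(path))

#' @rdname parse_obo
#' @param graph An [ontology_graph()].
#' @export
write_obo <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  out <- c("format-version: 1.4", "")
  terms <- dplyr::arrange(graph$terms, .data$term_id)
  edges <- dplyr::arrange(graph$edges, .data$child, .data$relation, .data$parent)
  by_child <- split(edges, edges$child)
  for (i in seq_len(nrow(terms))) {
    t <- terms[i, ]
    e <- by_child[[t$term_id]]
    rel_lines <- if (is.null(e)) character() else
      ifelse(e$relation == "is_a",
             paste0("is_a: ", e$parent),
             paste0("relationship: part_of ", e$parent))
    out <- c(out, "[Term]",
             paste0("id: ", t$term_id),
             paste0("name: ", t$name),
             paste0("namespace: ", t$aspect),
             sort(rel_lines),
             if (t$obsolete) "is_obsolete: true",
             "")
  }
  out <- out[-length(out)]
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Aspect root of a term
#'
#' @param graph An [ontology_graph()].
#' @param term A term identifier.
#' @return The identifier of the root of `term`'s aspect.
#' @export
aspect_root <- function(graph, term) {
  .check_terms_exist(graph, term)
  aspect <- graph$terms$aspect[match(term, graph$terms$term_id)]
  root_aspect <- graph$terms$aspect[match(graph$roots, graph$terms$term_id)]
  graph$roots[match(aspect, root_aspect)]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
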
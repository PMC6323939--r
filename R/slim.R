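#' Count distinct annotated tree branches per term
#'
#' The usage of a term is the number of distinct (family, branch) pairs
#' on which the term -- or any of its more specific descendants, following
#' `is_a`/`part_of` -- was gained. Loss events never contribute. A branch
#' gaining several descendants of one ancestor still counts once for that
#' ancestor, so `count(ancestor) >= count(descendant)` always holds.
#'
#' @param families A list of `list(tree = , events = )` pairs (named
#'   elements give the family ids; unnamed lists are numbered `FAM1`,
#'   `FAM2`, ...). Events are validated against their tree.
#' @param graph An [ontology_graph()].
#' @return A tibble `term_id`, `n_branches` covering every non-obsolete
#'   term of `graph` (zero counts included), sorted by `term_id`.
#' @export
branch_usage_counts <- function(families, graph) {
  stopifnot(inherits(graph, "ontology_graph"), is.list(families))
  ids <- names(families) %||% rep(NA_character_, length(families))
  ids[is.na(ids) | !nzchar(ids)] <-
    paste0("FAM", which(is.na(ids) | !nzchar(ids)))
  ev <- purrr::map2(families, ids, function(fam, id) {
    viol <- validate_events(fam$tree, fam$events)
    if (nrow(viol))
      stop("family ", id, ": invalid event set (", viol$violation[1], ")")
    dplyr::mutate(fam$events, family_id = id)
  })
  branch_usage_from_events(dplyr::bind_rows(ev), graph)
}

#' @rdname branch_usage_counts
#' @param events Tibble with columns `family_id`, `node_id`, `term_id`
#'   and optionally `kind` (rows with `kind != "gain"` are ignored).
#' @export
branch_usage_from_events <- function(events, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  if ("kind" %in% names(events)) events <- events[events$kind == "gain", ]
  .check_terms_exist(graph, unique(events$term_id))
  live <- graph$terms$term_id[!graph$terms$obsolete]
  base <- tibble::tibble(term_id = sort(live))
  if (!nrow(events))
    return(dplyr::mutate(base, n_branches = 0L))
  up <- tibble::tibble(term_id = unique(events$term_id)) |>
    dplyr::mutate(counted = lapply(.data$term_id,
                                   function(t) c(t, term_ancestors(graph, t)))) |>
    tidyr::unnest_longer("counted")
  counts <- events |>
    dplyr::inner_join(up, by = "term_id",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$family_id, .data$node_id, .data$counted) |>
    dplyr::count(term_id = .data$counted, name = "n_branches")
  base |>
    dplyr::left_join(counts, by = "term_id") |>
    dplyr::mutate(n_branches = dplyr::coalesce(.data$n_branches, 0L))
}

#' Build a GO-slim from branch-usage counts
#'
#' Two-step construction: (1) select every term used on strictly more
#' than `min_branches` distinct tree branches (after descendant-closure
#' counting); (2) add every term of the full graph that is a common
#' ancestor of two or more selected terms, which guarantees that each
#' slim term can be traced to its aspect root inside the slim. Aspect
#' roots are always included. Slim edges are the transitive reduction of
#' the full-graph reachability restricted to slim terms.
#'
#' @param counts A branch-usage tibble from [branch_usage_counts()].
#' @param graph The full [ontology_graph()] the counts were computed on.
#' @param min_branches Usage threshold; a term is selected iff its count
#'   is strictly greater (default 5, i.e. "more than five branches").
#' @return A `slim_graph` (an [ontology_graph()] whose `terms` carry a
#'   `provenance` column: `selected_by_count`, `added_as_ancestor`, or
#'   `root`).
#' @export
build_slim <- function(counts, graph, min_branches = 5) {
  stopifnot(inherits(graph, "ontology_graph"),
            all(c("term_id", "n_branches") %in% names(counts)))
  selected <- counts$term_id[counts$n_branches > min_branches]
  if (!length(selected))
    warning("no term exceeds min_branches = ", min_branches,
            "; slim contains only the aspect roots")

  # ancestors with >= 2 distinct selected descendants
  anc_tally <- table(unlist(lapply(selected, term_ancestors, graph = graph),
                            use.names = FALSE))
  common_anc <- setdiff(names(anc_tally)[anc_tally >= 2], selected)

  keep <- unique(c(selected, common_anc, graph$roots))
  provenance <- dplyr::case_when(
    keep %in% selected ~ "selected_by_count",
    keep %in% common_anc ~ "added_as_ancestor",
    TRUE ~ "root")

  terms <- graph$terms[match(keep, graph$terms$term_id), ]
  terms$provenance <- provenance
  terms <- dplyr::arrange(terms, .data$term_id)

  edges <- .reduced_edges(keep, graph)
  out <- ontology_graph(terms, edges)
  class(out) <- c("slim_graph", class(out))
  # connectivity invariant: every slim term reaches a root inside the slim
  for (t in setdiff(terms$term_id, out$roots)) {
    if (!any(term_ancestors(out, t) %in% out$roots))
      stop("slim term ", t, " cannot reach an aspect root within the slim")
  }
  out
}

# transitive reduction of full-graph reachability restricted to `keep`
.reduced_edges <- function(keep, graph) {
  anc <- lapply(stats::setNames(keep, keep),
                function(t) intersect(term_ancestors(graph, t), keep))
  rows <- purrr::imap(anc, function(a, t) {
    if (!length(a)) return(NULL)
    # u is a parent iff no other kept ancestor of t lies below u
    minimal <- a[vapply(a, function(u) {
      !any(vapply(setdiff(a, u), function(v) u %in% anc[[v]], logical(1)))
    }, logical(1))]
    tibble::tibble(child = t, parent = minimal)
  })
  edges <- dplyr::bind_rows(rows)
  if (!nrow(edges))
    return(tibble::tibble(child = character(), parent = character(),
                          relation = character()))
  edges |>
    dplyr::left_join(graph$edges, by = c("child", "parent")) |>
    dplyr::mutate(relation = dplyr::coalesce(.data$relation, "is_a")) |>
    dplyr::arrange(.data$child, .data$parent)
}

#' Map full-GO annotations onto a slim
#'
#' Each association of a gene to term `t` is rewritten to the
#' most-specific slim terms covering `t`: `t` itself when it is in the
#' slim, otherwise the minimal elements (no slim term below them among
#' the candidates) of `t`'s slim ancestors. A term with no slim ancestor
#' maps to its aspect root.
#'
#' @param annotations Annotation tibble (`gene_id`, `term_id`, ...).
#' @param slim A `slim_graph` from [build_slim()] (any
#'   [ontology_graph()] whose terms are a subset of `graph`'s works).
#' @param graph The full [ontology_graph()].
#' @return Annotation tibble on slim terms, distinct rows.
#' @export
map_to_slim <- function(annotations, slim, graph) {
  stopifnot(inherits(slim, "ontology_graph"), inherits(graph, "ontology_graph"))
  annotations <- positive_annotations(annotations)
  .check_terms_exist(graph, unique(annotations$term_id))
  slim_terms <- slim$terms$term_id[!slim$terms$obsolete]
  targets <- function(t) {
    if (t %in% slim_terms) return(t)
    cand <- intersect(term_ancestors(graph, t), slim_terms)
    if (!length(cand)) return(aspect_root(graph, t))
    cand[vapply(cand, function(u) {
      !any(vapply(setdiff(cand, u),
                  function(v) u %in% term_ancestors(graph, v), logical(1)))
    }, logical(1))]
  }
  if (!"evidence" %in% names(annotations)) annotations$evidence <- NA_character_
  lut <- tibble::tibble(term_id = unique(annotations$term_id)) |>
    dplyr::mutate(slim_term = lapply(.data$term_id, targets)) |>
    tidyr::unnest_longer("slim_term")
  annotations |>
    dplyr::inner_join(lut, by = "term_id",
                      relationship = "many-to-many") |>
    dplyr::transmute(gene_id = .data$gene_id, term_id = .data$slim_term,
                     evidence = .data$evidence) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene_id, .data$term_id)
}
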
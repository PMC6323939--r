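#' Read and write gene association files (GAF 2.2)
#'
#' `parse_gaf()` reads tab-separated GAF rows (17 columns; lines starting
#' with `!` are comments) into a tidy annotation table. Rows whose
#' qualifier contains `NOT` are negative assertions: they are kept with
#' `negated = TRUE` for audit, and every downstream operation (closure,
#' propagation, enrichment counting) ignores them.
#'
#' @param text Character vector of GAF lines (or one string with
#'   newlines).
#' @return A tibble with columns `gene_id`, `term_id`, `evidence`,
#'   `aspect`, `negated`; one row per distinct association.
#' @export
parse_gaf <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "!")
  if (!any(keep))
    return(tibble::tibble(gene_id = character(), term_id = character(),
                          evidence = character(), aspect = character(),
                          negated = logical()))
  idx <- which(keep)
  nf <- nchar(lines[idx]) -
    nchar(gsub("\t", "", lines[idx], fixed = TRUE)) + 1L
  if (any(nf != 17L)) {
    bad <- which(nf != 17L)[1]
    stop("GAF line ", idx[bad], ": expected 17 tab-separated columns, got ",
         nf[bad])
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(fields, function(f) c(f, rep("", 17L - length(f)))))
  tibble::tibble(
    gene_id = m[, 2], term_id = m[, 5], evidence = m[, 7], aspect = m[, 9],
    negated = grepl("(^|\\|)NOT($|\\|)", m[, 4])) |>
    dplyr::distinct()
}

#' @rdname parse_gaf
#' @param path File path.
#' @export
read_gaf <- function(path) parse_gaf(readLines(path))

#' @rdname parse_gaf
#' @param annotations Tibble with `gene_id`, `term_id`, `evidence` and
#'   optionally `aspect`, `negated`.
#' @param db Source database label for column 1.
#' @export
write_gaf <- function(annotations, path = NULL, db = "GOFAM") {
  aspect <- if ("aspect" %in% names(annotations)) annotations$aspect else ""
  qualifier <- if ("negated" %in% names(annotations))
    ifelse(annotations$negated, "NOT|involved_in", "involved_in")
  else "involved_in"
  rows <- paste(db, annotations$gene_id, annotations$gene_id, qualifier,
                annotations$term_id, "GOFAM:0000000", annotations$evidence, "",
                aspect, "", "", "protein", "taxon:0", "20180101", db, "", "",
                sep = "\t")
  out <- c("!gaf-version: 2.2", rows)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

positive_annotations <- function(annotations) {
  if ("negated" %in% names(annotations))
    annotations <- annotations[!annotations$negated, ]
  annotations
}

# ---- branch events ----

#' Validate gain/loss events against a tree
#'
#' Curated function events live on the branch above a node and apply to
#' that node and all of its descendants. A valid event set has at most
#' one event per (node, term) pair, and every loss of a term lies
#' strictly below a gain of the same term on its root path.
#'
#' @param tree A [family_tree()].
#' @param events Tibble with columns `node_id`, `term_id`,
#'   `kind` (`"gain"` or `"loss"`).
#' @return Tibble of violations (`violation`, `node_id`, `term_id`);
#'   zero rows when the event set is valid.
#' @export
validate_events <- function(tree, events) {
  stopifnot(inherits(tree, "family_tree"),
            all(c("node_id", "term_id", "kind") %in% names(events)))
  v <- list()
  bad_kind <- !events$kind %in% c("gain", "loss")
  if (any(bad_kind))
    v[[length(v) + 1]] <- tibble::tibble(
      violation = "unknown_kind", node_id = events$node_id[bad_kind],
      term_id = events$term_id[bad_kind])
  unknown <- !events$node_id %in% tree$nodes$node_id
  if (any(unknown))
    v[[length(v) + 1]] <- tibble::tibble(
      violation = "unknown_node", node_id = events$node_id[unknown],
      term_id = events$term_id[unknown])
  dup <- duplicated(events[c("node_id", "term_id")])
  if (any(dup))
    v[[length(v) + 1]] <- tibble::tibble(
      violation = "duplicate_event", node_id = events$node_id[dup],
      term_id = events$term_id[dup])

  losses <- events[events$kind == "loss" & !unknown & !bad_kind, ]
  if (nrow(losses)) {
    gains <- events[events$kind == "gain", ]
    orphan <- vapply(seq_len(nrow(losses)), function(i) {
      anc <- .ancestor_nodes(tree, losses$node_id[i])
      !any(gains$term_id == losses$term_id[i] & gains$node_id %in% anc)
    }, logical(1))
    if (any(orphan))
      v[[length(v) + 1]] <- tibble::tibble(
        violation = "loss_without_gain", node_id = losses$node_id[orphan],
        term_id = losses$term_id[orphan])
  }
  if (!length(v))
    return(tibble::tibble(violation = character(), node_id = integer(),
                          term_id = character()))
  dplyr::bind_rows(v)
}

# strict ancestors of a node, nearest first
.ancestor_nodes <- function(tree, node_id) {
  anc <- integer()
  p <- tree$nodes$parent_id[node_id]
  while (!is.na(p)) {
    anc <- c(anc, p)
    p <- tree$nodes$parent_id[p]
  }
  anc
}

#' Propagate ancestral functions to descendant genes
#'
#' Walks the tree from the root, switching each term on at a gain and off
#' at a loss; the event nearest to a leaf on its root path wins, so a
#' re-gain below a loss re-activates the term for that clade. Each leaf
#' is annotated with every term that is switched on when the walk reaches
#' it, with evidence code `IBA` (inferred from biological aspect of
#' ancestor).
#'
#' @inheritParams validate_events
#' @return Annotation tibble (`gene_id`, `term_id`, `evidence`,
#'   `negated`), sorted by gene then term.
#' @export
propagate_annotations <- function(tree, events) {
  viol <- validate_events(tree, events)
  if (nrow(viol))
    stop("invalid event set: ", nrow(viol), " violation(s), first: ",
         viol$violation[1], " at node ", viol$node_id[1])
  ev_by_node <- split(events[c("term_id", "kind")], events$node_id)
  out <- list()
  walk <- function(id, active) {
    e <- ev_by_node[[as.character(id)]]
    if (!is.null(e))
      active[e$term_id] <- e$kind == "gain"
    row <- tree$nodes[id, ]
    if (row$event == "leaf") {
      on <- names(active)[active]
      if (length(on))
        out[[length(out) + 1L]] <<- tibble::tibble(
          gene_id = row$gene_id, term_id = on)
      return(invisible())
    }
    for (k in tree_children(tree, id)) walk(k, active)
  }
  walk(tree_root(tree), stats::setNames(logical(), character()))
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(gene_id = character(), term_id = character())
  res |>
    dplyr::mutate(evidence = "IBA", negated = FALSE) |>
    dplyr::arrange(.data$gene_id, .data$term_id)
}

#' Expand annotations over the ontology
#'
#' Every association of a gene to a term induces associations to all
#' ancestors of that term over `is_a`/`part_of`. Evidence codes are
#' preserved; the operation is idempotent and never removes a record.
#' Negated rows are dropped before expansion.
#'
#' @param annotations Annotation tibble (`gene_id`, `term_id`,
#'   `evidence`, optionally `negated`).
#' @param graph An [ontology_graph()].
#' @return Expanded annotation tibble, distinct rows.
#' @export
close_over_ontology <- function(annotations, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  annotations <- positive_annotations(annotations)
  if (!"evidence" %in% names(annotations)) annotations$evidence <- NA_character_
  .check_terms_exist(graph, unique(annotations$term_id))
  expand <- tibble::tibble(term_id = unique(annotations$term_id)) |>
    dplyr::mutate(closure = lapply(.data$term_id,
                                   function(t) c(t, term_ancestors(graph, t)))) |>
    tidyr::unnest_longer("closure")
  annotations |>
    dplyr::inner_join(expand, by = "term_id",
                      relationship = "many-to-many") |>
    dplyr::transmute(gene_id = .data$gene_id, term_id = .data$closure,
                     evidence = .data$evidence, negated = FALSE) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene_id, .data$term_id)
}
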
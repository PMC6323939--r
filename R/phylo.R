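#' Event-labeled gene family trees
#'
#' A `family_tree` is a rooted tree whose internal nodes are labeled with
#' the evolutionary event that caused the divergence -- speciation, gene
#' duplication, or horizontal transfer -- and whose leaves carry a gene
#' identifier and a species label. Nodes are stored as a flat tibble in
#' preorder; `branch_length` is the length of the edge above a node
#' (`NA` for the root).
#'
#' @param nodes A data frame with columns `node_id` (integer, preorder),
#'   `parent_id` (integer, `NA` for the root), `event` (one of
#'   `"speciation"`, `"duplication"`, `"horizontal_transfer"`, `"leaf"`),
#'   `gene_id` and `species` (leaves only, `NA` otherwise), and
#'   `branch_length`.
#' @return An object of class `family_tree`.
#' @export
family_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  req <- c("node_id", "parent_id", "event", "gene_id", "species", "branch_length")
  stopifnot(all(req %in% names(nodes)))
  nodes <- dplyr::arrange(nodes, .data$node_id)
  if (!identical(nodes$node_id, seq_len(nrow(nodes))))
    stop("node_id must be 1..n")
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1) stop("tree must have exactly one root")
  bad_ev <- setdiff(unique(nodes$event),
                    c("speciation", "duplication", "horizontal_transfer", "leaf"))
  if (length(bad_ev)) stop("unknown event(s): ", paste(bad_ev, collapse = ", "))

  is_leaf <- nodes$event == "leaf"
  n_child <- tabulate(nodes$parent_id[!is.na(nodes$parent_id)], nrow(nodes))
  if (any(is_leaf & n_child > 0)) stop("leaves must not have children")
  if (any(!is_leaf & n_child < 2))
    stop("internal nodes must have at least 2 children")
  if (any(is.na(nodes$gene_id[is_leaf])) || any(is.na(nodes$species[is_leaf])))
    stop("every leaf needs gene_id and species")
  if (anyDuplicated(nodes$gene_id[is_leaf]))
    stop("duplicate gene_id: ",
         nodes$gene_id[is_leaf][duplicated(nodes$gene_id[is_leaf])][1])
  if (any(nodes$branch_length < 0, na.rm = TRUE))
    stop("branch lengths must be non-negative")

  structure(list(nodes = nodes),
            children_index = split(nodes$node_id[!is.na(nodes$parent_id)],
                                   nodes$parent_id[!is.na(nodes$parent_id)]),
            class = "family_tree")
}

#' @export
print.family_tree <- function(x, ...) {
  n <- x$nodes
  cat(sprintf("<family_tree> %d leaves, %d internal nodes (%d duplication)\n",
              sum(n$event == "leaf"), sum(n$event != "leaf"),
              sum(n$event == "duplication")))
  invisible(x)
}

tree_children <- function(tree, node_id) {
  attr(tree, "children_index")[[as.character(node_id)]] %||% integer()
}

tree_root <- function(tree) tree$nodes$node_id[is.na(tree$nodes$parent_id)]

#' Leaves below a node
#'
#' @param tree A [family_tree()].
#' @param node_id Node to start from; defaults to the root.
#' @return Tibble of leaf rows (subset of `tree$nodes`) in preorder.
#' @export
tree_leaves <- function(tree, node_id = tree_root(tree)) {
  ids <- .subtree_ids(tree, node_id)
  out <- tree$nodes[tree$nodes$node_id %in% ids & tree$nodes$event == "leaf", ]
  out
}

.subtree_ids <- function(tree, node_id) {
  acc <- integer()
  frontier <- node_id
  while (length(frontier)) {
    acc <- c(acc, frontier)
    frontier <- unlist(lapply(frontier, tree_children, tree = tree),
                       use.names = FALSE)
  }
  acc
}

# ---- Newick/NHX ----

#' Read and write Newick trees with NHX event tags
#'
#' The NHX comment `[&&NHX:...]` after a node carries `Ev` (event code:
#' `S` speciation, `D` duplication, `H` horizontal transfer) on internal
#' nodes and optionally `Sp` (species) on leaves. A leaf without an `Sp`
#' tag takes its species from the suffix after the last underscore of its
#' name (`geneA_human` -> species `human`); a leaf with neither is a
#' validation error, as is an internal node without an event tag.
#'
#' @param text A Newick/NHX string (possibly split over lines).
#' @return `parse_nhx()`: a [family_tree()]. `write_nhx()`: a single
#'   Newick/NHX string; parsing it back reproduces the tree.
#' @examples
#' tr <- parse_nhx("((a_sp1:0.1,b_sp2:0.2)[&&NHX:Ev=S]);")
#' infer_orthologs(tr)
#' @export
parse_nhx <- function(text) {
  s <- gsub("[\r\n\t ]", "", paste(text, collapse = ""))
  if (!nzchar(s)) stop("empty Newick string")
  if (!endsWith(s, ";")) stop("malformed Newick: missing ';'")
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  take <- function() { ch <- peek(); pos <<- pos + 1L; ch }
  expect <- function(ch) {
    if (peek() != ch)
      stop("malformed Newick at position ", pos, ": expected '", ch, "'")
    pos <<- pos + 1L
  }
  read_until <- function(stops) {
    start <- pos
    while (pos <= n && !(substr(s, pos, pos) %in% stops)) pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  read_nhx <- function() {
    if (peek() != "[") return(list())
    close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
    if (close < 0) stop("malformed NHX comment: missing ']'")
    body <- substr(s, pos, pos + close - 1L)
    pos <<- pos + close
    inner <- sub("^\\[&&NHX:?", "", sub("\\]$", "", body))
    if (!startsWith(body, "[&&NHX"))
      stop("unsupported comment (not NHX): ", body)
    if (!nzchar(inner)) return(list())
    kv <- strsplit(inner, ":", fixed = TRUE)[[1]]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    stats::setNames(as.list(vals), keys)
  }
  parse_clade <- function() {
    if (peek() == "(") {
      expect("(")
      children <- list(parse_clade())
      while (peek() == ",") { take(); children[[length(children) + 1L]] <- parse_clade() }
      expect(")")
      label <- read_until(c(":", "[", ",", ")", ";"))
      bl <- NA_real_
      if (peek() == ":") { take(); bl <- as.numeric(read_until(c("[", ",", ")", ";"))) }
      tags <- read_nhx()
      ev_code <- tags[["Ev"]] %||% (if (nzchar(label)) label else NULL)
      if (is.null(ev_code)) {
        # "(X);"-style wrapper: a bare single-child node is unwrapped
        if (length(children) == 1 && is.na(bl)) return(children[[1]])
        stop("internal node without event tag")
      }
      event <- unname(c(S = "speciation", D = "duplication",
                        H = "horizontal_transfer")[ev_code])
      if (is.na(event)) stop("unknown event code: ", ev_code)
      list(event = event, branch_length = bl, children = children)
    } else {
      name <- read_until(c(":", "[", ",", ")", ";"))
      if (!nzchar(name)) stop("malformed Newick: empty leaf name at ", pos)
      bl <- NA_real_
      if (peek() == ":") { take(); bl <- as.numeric(read_until(c("[", ",", ")", ";"))) }
      tags <- read_nhx()
      species <- tags[["Sp"]]
      if (is.null(species)) {
        if (grepl("_", name)) species <- sub("^.*_", "", name)
        else stop("leaf '", name, "' has no species (no Sp tag, no _suffix)")
      }
      list(event = "leaf", gene_id = name, species = species, branch_length = bl)
    }
  }
  root <- parse_clade()
  expect(";")
  if (root$event == "leaf") stop("tree must have at least one internal node")

  rows <- list()
  flatten <- function(node, parent_id) {
    id <- length(rows) + 1L
    rows[[id]] <<- tibble::tibble(
      node_id = id, parent_id = parent_id, event = node$event,
      gene_id = node$gene_id %||% NA_character_,
      species = node$species %||% NA_character_,
      branch_length = node$branch_length)
    for (ch in node$children %||% list()) flatten(ch, id)
  }
  flatten(root, NA_integer_)
  family_tree(dplyr::bind_rows(rows))
}

#' @rdname parse_nhx
#' @param tree A [family_tree()].
#' @param path Optional file to write to.
#' @export
write_nhx <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "family_tree"))
  nodes <- tree$nodes
  fmt_bl <- function(bl) if (is.na(bl)) "" else
    paste0(":", format(bl, digits = 15, scientific = FALSE, trim = TRUE))
  ev_code <- c(speciation = "S", duplication = "D", horizontal_transfer = "H")
  render <- function(id) {
    row <- nodes[id, ]
    if (row$event == "leaf")
      return(paste0(row$gene_id, fmt_bl(row$branch_length),
                    "[&&NHX:Sp=", row$species, "]"))
    kids <- vapply(tree_children(tree, id), render, character(1))
    paste0("(", paste(kids, collapse = ","), ")", fmt_bl(row$branch_length),
           "[&&NHX:Ev=", ev_code[[row$event]], "]")
  }
  out <- paste0(render(tree_root(tree)), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @rdname parse_nhx
#' @export
read_nhx <- function(path) parse_nhx(readLines(path))

# ---- subfamilies ----

#' Assign subfamilies at duplication nodes
#'
#' The root founds subfamily `SF0`. Walking the tree in preorder, each
#' duplication node creates new subfamilies for its more diverged child
#' subtrees: the child with the smallest mean root-to-leaf path length
#' (summed branch lengths measured from the duplication node) keeps the
#' parental subfamily, and every other child founds a new one. The
#' exception is a recent duplication confined to a single reference
#' species: if all leaves below the duplication belong to one species and
#' that species is in `reference_species`, no subfamily is created. Ties
#' on mean depth are broken by keeping the parental label on the child
#' whose lexicographically smallest leaf gene id is least.
#'
#' @param tree A [family_tree()].
#' @param reference_species Character vector of reference species labels.
#' @return Tibble with one row per leaf: `gene_id`, `subfamily`,
#'   `founding_node` (the node at which that subfamily was founded).
#' @export
assign_subfamilies <- function(tree, reference_species) {
  stopifnot(inherits(tree, "family_tree"), length(reference_species) >= 1)
  nodes <- tree$nodes
  counter <- 0L
  out <- vector("list", nrow(nodes))

  # distance-to-leaves aggregates per node
  depth_stats <- function(id) {
    row <- nodes[id, ]
    if (row$event == "leaf") return(c(sum = 0, count = 1))
    kids <- tree_children(tree, id)
    agg <- c(sum = 0, count = 0)
    for (k in kids) {
      st <- depth_stats(k)
      bl <- nodes$branch_length[k]
      if (is.na(bl)) bl <- 0
      agg <- agg + c(sum = st[["sum"]] + st[["count"]] * bl,
                     count = st[["count"]])
    }
    agg
  }
  min_gene <- function(id) min(tree_leaves(tree, id)$gene_id)

  walk <- function(id, label, founder) {
    force(label); force(founder)  # label depends on a mutable counter
    row <- nodes[id, ]
    if (row$event == "leaf") {
      out[[id]] <<- tibble::tibble(gene_id = row$gene_id, subfamily = label,
                                   founding_node = founder)
      return(invisible())
    }
    kids <- tree_children(tree, id)
    new_per_child <- rep(FALSE, length(kids))
    if (row$event == "duplication") {
      sp <- unique(tree_leaves(tree, id)$species)
      recent <- length(sp) == 1 && sp %in% reference_species
      if (!recent) {
        means <- vapply(kids, function(k) {
          st <- depth_stats(k)
          bl <- nodes$branch_length[k]
          (st[["sum"]] + st[["count"]] * (if (is.na(bl)) 0 else bl)) / st[["count"]]
        }, numeric(1))
        keep_pool <- which(means == min(means))
        keeper <- keep_pool[order(vapply(kids[keep_pool], min_gene, character(1)))[1]]
        new_per_child[-keeper] <- TRUE
      }
    }
    for (j in seq_along(kids)) {
      if (new_per_child[j]) {
        counter <<- counter + 1L
        walk(kids[j], paste0("SF", counter), kids[j])
      } else {
        walk(kids[j], label, founder)
      }
    }
  }
  root <- tree_root(tree)
  walk(root, "SF0", root)
  dplyr::bind_rows(out)
}

# ---- orthologs ----

#' Infer pairwise orthologs from an event-labeled tree
#'
#' Two genes are orthologs iff the lowest common ancestor of their leaves
#' is a speciation node and they come from different species. Duplication
#' and horizontal-transfer ancestors never produce ortholog calls, and
#' same-species pairs under a speciation node (possible with unsampled
#' lineages) are excluded.
#'
#' @param tree A [family_tree()].
#' @return Tibble with columns `gene1`, `gene2` (`gene1 < gene2`), one row
#'   per unordered ortholog pair, sorted.
#' @export
infer_orthologs <- function(tree) {
  stopifnot(inherits(tree, "family_tree"))
  nodes <- tree$nodes
  pairs <- list()
  collect <- function(id) {
    row <- nodes[id, ]
    if (row$event == "leaf")
      return(tibble::tibble(gene_id = row$gene_id, species = row$species))
    groups <- lapply(tree_children(tree, id), collect)
    if (row$event == "speciation" && length(groups) > 1) {
      for (i in seq_len(length(groups) - 1)) {
        for (j in (i + 1):length(groups)) {
          cross <- tidyr::crossing(
            a = seq_len(nrow(groups[[i]])), b = seq_len(nrow(groups[[j]])))
          g1 <- groups[[i]]$gene_id[cross$a]
          g2 <- groups[[j]]$gene_id[cross$b]
          ok <- groups[[i]]$species[cross$a] != groups[[j]]$species[cross$b]
          if (any(ok))
            pairs[[length(pairs) + 1L]] <<- tibble::tibble(
              gene1 = pmin(g1[ok], g2[ok]), gene2 = pmax(g1[ok], g2[ok]))
        }
      }
    }
    dplyr::bind_rows(groups)
  }
  collect(tree_root(tree))
  out <- dplyr::bind_rows(pairs)
  if (!nrow(out)) return(tibble::tibble(gene1 = character(), gene2 = character()))
  dplyr::arrange(dplyr::distinct(out), .data$gene1, .data$gene2)
}
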
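#' Deterministic synthetic data generators
#'
#' These generators produce random but fully reproducible instances of
#' every container the package consumes -- ontology DAGs, event-labeled
#' family trees with planted gain/loss events, block alignments with a
#' known split structure, and gene lists with a planted enrichment.
#' Identical arguments (including `seed`) give byte-identical objects;
#' each generator seeds its own stream and leaves the global RNG state
#' untouched. They emulate structural properties only (tree shapes,
#' event layering, column occupancy), not sequence evolution.
#'
#' @name simulate
NULL

#' Random single-root ontology DAG
#'
#' Terms are distributed across the requested aspects; within an aspect
#' the first term is the root and every later term attaches to one or
#' more already-created terms (edges always point from a
#' higher-numbered child to a lower-numbered parent, so the graph is
#' acyclic and single-rooted by construction).
#'
#' @param n_terms Total number of terms (>= number of aspects).
#' @param seed Integer seed.
#' @param aspects Aspects to generate (default biological_process only).
#' @param p_part_of Probability that an edge is `part_of` rather than
#'   `is_a`.
#' @param p_extra_parent Probability weight for additional parents
#'   beyond the first.
#' @return An [ontology_graph()].
#' @export
make_dag <- function(n_terms, seed, aspects = "biological_process",
                     p_part_of = 0.2, p_extra_parent = 0.25) {
  stopifnot(n_terms >= length(aspects), length(aspects) >= 1)
  withr::with_seed(seed, {
    sizes <- diff(round(seq(0, n_terms, length.out = length(aspects) + 1)))
    next_id <- 0L
    parts <- purrr::map2(aspects, sizes, function(aspect, size) {
      ids <- sprintf("GO:%07d", next_id + seq_len(size))
      next_id <<- next_id + size
      terms <- tibble::tibble(
        term_id = ids, name = paste0("synthetic ", sub("GO:0*", "term ", ids)),
        aspect = aspect, obsolete = FALSE)
      edges <- purrr::map(seq_along(ids)[-1], function(i) {
        n_par <- 1L + stats::rbinom(1, 2, p_extra_parent)
        parents <- ids[sample.int(i - 1, min(n_par, i - 1))]
        tibble::tibble(
          child = ids[i], parent = parents,
          relation = sample(c("is_a", "part_of"), length(parents),
                            replace = TRUE, prob = c(1 - p_part_of, p_part_of)))
      })
      list(terms = terms, edges = dplyr::bind_rows(edges))
    })
    edge_template <- tibble::tibble(child = character(), parent = character(),
                                    relation = character())
    ontology_graph(dplyr::bind_rows(purrr::map(parts, "terms")),
                   dplyr::bind_rows(edge_template, purrr::map(parts, "edges")))
  })
}

#' Random event-labeled family tree with planted gain/loss events
#'
#' Grows a random rooted binary tree, labels each internal node
#' duplication with probability `dup_prob` (speciation otherwise), and
#' plants function events along root-to-leaf paths: on each branch a
#' term not currently active is gained with probability `gain_rate`, and
#' an active term is lost with probability `loss_rate` (re-gain below a
#' loss is possible). Planted event sets always pass
#' [validate_events()].
#'
#' @param n_leaves Number of leaf genes (>= 2).
#' @param dup_prob Probability an internal node is a duplication.
#' @param gain_rate Per-branch gain probability for an inactive term.
#' @param loss_rate Per-branch loss probability for an active term.
#' @param graph An [ontology_graph()] supplying the term vocabulary.
#' @param seed Integer seed.
#' @param n_species Size of the species pool for leaf labels.
#' @param n_terms_used How many terms to draw events for (capped at the
#'   number of non-root terms in `graph`).
#' @param gene_prefix Prefix for leaf gene ids; give each family its own
#'   prefix when building multi-family corpora so gene ids stay unique.
#' @return `list(tree = family_tree, events = tibble(node_id, term_id,
#'   kind))`.
#' @export
make_family <- function(n_leaves, dup_prob, gain_rate, loss_rate, graph, seed,
                        n_species = 5, n_terms_used = 8, gene_prefix = "g") {
  stopifnot(n_leaves >= 2, inherits(graph, "ontology_graph"))
  withr::with_seed(seed, {
    leaf_i <- 0L
    grow <- function(n) {
      if (n == 1) {
        leaf_i <<- leaf_i + 1L
        sp <- paste0("sp", sample.int(n_species, 1))
        return(list(event = "leaf",
                    gene_id = sprintf("%s%03d_%s", gene_prefix, leaf_i, sp),
                    species = sp,
                    branch_length = round(stats::rexp(1, 8) + 0.01, 4)))
      }
      n1 <- sample.int(n - 1, 1)
      list(event = if (stats::runif(1) < dup_prob) "duplication" else "speciation",
           branch_length = round(stats::rexp(1, 8) + 0.01, 4),
           children = list(grow(n1), grow(n - n1)))
    }
    top <- grow(n_leaves)
    top$branch_length <- NA_real_
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
    flatten(top, NA_integer_)
    tree <- family_tree(dplyr::bind_rows(rows))

    pool <- setdiff(graph$terms$term_id[!graph$terms$obsolete], graph$roots)
    if (!length(pool)) pool <- graph$roots
    terms <- sample(pool, min(n_terms_used, length(pool)))
    ev <- list()
    for (t in terms) {
      walk <- function(id, active) {
        if (!active && stats::runif(1) < gain_rate) {
          ev[[length(ev) + 1L]] <<- tibble::tibble(
            node_id = id, term_id = t, kind = "gain")
          active <- TRUE
        } else if (active && stats::runif(1) < loss_rate) {
          ev[[length(ev) + 1L]] <<- tibble::tibble(
            node_id = id, term_id = t, kind = "loss")
          active <- FALSE
        }
        for (k in tree_children(tree, id)) walk(k, active)
      }
      walk(tree_root(tree), FALSE)
    }
    events <- if (length(ev)) dplyr::bind_rows(ev) else
      tibble::tibble(node_id = integer(), term_id = character(),
                     kind = character())
    list(tree = tree, events = events)
  })
}

#' Block alignment with a known tree split
#'
#' Builds an alignment of two dense sequence blocks: clade A occupies
#' columns `1..width_a`, clade B occupies the last `width_b` columns,
#' and the blocks overlap in exactly `overlap` columns. The matching
#' tree splits A from B at the root, so [criterion_p2()] sees exactly
#' `overlap` shared sites on the A|B split.
#'
#' @param n_members_a,n_members_b Members per clade.
#' @param width_a,width_b Block widths (columns).
#' @param overlap Number of columns shared by the two blocks
#'   (`0 <= overlap <= min(width_a, width_b)`).
#' @param seed Integer seed.
#' @return `list(msa = character matrix, tree = family_tree)`.
#' @export
make_split_msa <- function(n_members_a, n_members_b, width_a, width_b,
                           overlap, seed) {
  stopifnot(width_a >= 1, width_b >= 1, overlap >= 0,
            overlap <= min(width_a, width_b),
            n_members_a >= 1, n_members_b >= 1)
  withr::with_seed(seed, {
    width <- width_a + width_b - overlap
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    ids_a <- sprintf("a%02d_spA", seq_len(n_members_a))
    ids_b <- sprintf("b%02d_spB", seq_len(n_members_b))
    m <- matrix("-", n_members_a + n_members_b, width,
                dimnames = list(c(ids_a, ids_b), NULL))
    for (i in seq_len(n_members_a))
      m[i, seq_len(width_a)] <- sample(aa, width_a, replace = TRUE)
    for (j in seq_len(n_members_b))
      m[n_members_a + j, (width_a - overlap + 1):width] <-
        sample(aa, width_b, replace = TRUE)

    clade <- function(ids, species, first_id, parent) {
      if (length(ids) == 1)
        return(tibble::tibble(node_id = first_id, parent_id = parent,
                              event = "leaf", gene_id = ids,
                              species = species, branch_length = 0.1))
      dplyr::bind_rows(
        tibble::tibble(node_id = first_id, parent_id = parent,
                       event = "speciation", gene_id = NA_character_,
                       species = NA_character_, branch_length = 0.1),
        tibble::tibble(node_id = first_id + seq_along(ids), parent_id = first_id,
                       event = "leaf", gene_id = ids, species = species,
                       branch_length = 0.1))
    }
    root <- tibble::tibble(node_id = 1L, parent_id = NA_integer_,
                           event = "speciation", gene_id = NA_character_,
                           species = NA_character_, branch_length = NA_real_)
    a_rows <- clade(ids_a, "spA", 2L, 1L)
    b_rows <- clade(ids_b, "spB", 2L + nrow(a_rows), 1L)
    tree <- family_tree(dplyr::bind_rows(root, a_rows, b_rows))
    list(msa = m, tree = tree)
  })
}

#' Gene list with a planted enrichment
#'
#' Samples a gene list from the reference without replacement, giving
#' genes annotated to `target_term` a sampling weight `effect` times
#' that of other genes (`effect = 1` is the null).
#'
#' @param annotations Annotation tibble defining the reference universe.
#' @param target_term Term whose genes are oversampled (needs >= 5
#'   annotated genes).
#' @param effect Sampling-weight multiplier for target genes.
#' @param seed Integer seed.
#' @param n_list List size (default 10% of the reference, at least 20).
#' @return `list(gene_list = character, reference = character)`.
#' @export
make_enriched_lists <- function(annotations, target_term, effect, seed,
                                n_list = NULL) {
  annotations <- positive_annotations(annotations)
  reference <- sort(unique(annotations$gene_id))
  target <- unique(annotations$gene_id[annotations$term_id == target_term])
  if (length(target) < 5)
    stop("target_term must have at least 5 annotated genes, has ",
         length(target))
  n_list <- n_list %||% max(20L, round(0.1 * length(reference)))
  stopifnot(n_list <= length(reference))
  withr::with_seed(seed, {
    w <- ifelse(reference %in% target, effect, 1)
    gene_list <- sort(sample(reference, n_list, prob = w))
    list(gene_list = gene_list, reference = reference)
  })
}
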
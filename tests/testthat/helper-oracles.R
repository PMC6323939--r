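# Brute-force reference implementations used as independent oracles.
# They work directly on the tibble representations by repeated expansion
# or exhaustive enumeration, never through the package's traversal code.

oracle_ancestors <- function(graph, term) {
  edges <- graph$edges
  acc <- character()
  frontier <- term
  repeat {
    nxt <- setdiff(edges$parent[edges$child %in% frontier], c(acc, term))
    if (!length(nxt)) break
    acc <- c(acc, nxt)
    frontier <- nxt
  }
  sort(acc)
}

oracle_descendants <- function(graph, term) {
  edges <- graph$edges
  acc <- character()
  frontier <- term
  repeat {
    nxt <- setdiff(edges$child[edges$parent %in% frontier], c(acc, term))
    if (!length(nxt)) break
    acc <- c(acc, nxt)
    frontier <- nxt
  }
  sort(acc)
}

# path from root to a node, as node ids (root first)
oracle_root_path <- function(tree, node_id) {
  p <- node_id
  path <- node_id
  repeat {
    p <- tree$nodes$parent_id[p]
    if (is.na(p)) break
    path <- c(p, path)
  }
  path
}

# per-leaf root-to-leaf scan: nearest event wins
oracle_propagate <- function(tree, events) {
  leaves <- tree$nodes[tree$nodes$event == "leaf", ]
  rows <- list()
  for (i in seq_len(nrow(leaves))) {
    path <- oracle_root_path(tree, leaves$node_id[i])
    for (t in unique(events$term_id)) {
      on_path <- events[events$term_id == t & events$node_id %in% path, ]
      if (!nrow(on_path)) next
      nearest <- on_path$kind[which.max(match(on_path$node_id, path))]
      if (nearest == "gain")
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene_id = leaves$gene_id[i], term_id = t)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(gene_id = character(), term_id = character())
  dplyr::arrange(out, gene_id, term_id)
}

# all-pairs LCA-event check
oracle_orthologs <- function(tree) {
  leaves <- tree$nodes[tree$nodes$event == "leaf", ]
  rows <- list()
  n <- nrow(leaves)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      pi <- oracle_root_path(tree, leaves$node_id[i])
      for (j in (i + 1):n) {
        pj <- oracle_root_path(tree, leaves$node_id[j])
        lca <- max(intersect(pi, pj))  # preorder ids: deepest common = max
        if (tree$nodes$event[lca] == "speciation" &&
            leaves$species[i] != leaves$species[j])
          rows[[length(rows) + 1]] <- tibble::tibble(
            gene1 = min(leaves$gene_id[i], leaves$gene_id[j]),
            gene2 = max(leaves$gene_id[i], leaves$gene_id[j]))
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(gene1 = character(), gene2 = character())
  dplyr::arrange(dplyr::distinct(out), gene1, gene2)
}

# exact hypergeometric tail by explicit enumeration with choose()
oracle_fisher <- function(k, n, K, N, alternative) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  ks <- lo:hi
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  switch(alternative,
         greater = sum(pmf[ks >= k]),
         less = sum(pmf[ks <= k]),
         two_sided = min(1, sum(pmf[pmf <= pmf[ks == k] * (1 + 1e-7)])))
}

oracle_binom <- function(k, n, p0, alternative) {
  ks <- 0:n
  pmf <- choose(n, ks) * p0^ks * (1 - p0)^(n - ks)
  switch(alternative,
         greater = sum(pmf[ks >= k]),
         less = sum(pmf[ks <= k]),
         two_sided = min(1, sum(pmf[pmf <= pmf[ks == k] * (1 + 1e-7)])))
}

# U by direct pair counting, exact p by enumerating all label assignments
oracle_mwu <- function(class_values, other_values) {
  u_of <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  U <- u_of(class_values, other_values)
  all_v <- c(class_values, other_values)
  m <- length(class_values)
  mu <- m * length(other_values) / 2
  combos <- utils::combn(length(all_v), m)
  u_all <- apply(combos, 2, function(idx) u_of(all_v[idx], all_v[-idx]))
  list(U = U, p = mean(abs(u_all - mu) >= abs(U - mu) - 1e-9))
}

# direct step-up formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(pmin(1, p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# distinct (family, node) gains hitting t or any descendant of t
oracle_branch_usage <- function(events, graph) {
  gains <- events[events$kind == "gain", ]
  live <- sort(graph$terms$term_id[!graph$terms$obsolete])
  counts <- vapply(live, function(t) {
    covered <- c(t, oracle_descendants(graph, t))
    hit <- gains[gains$term_id %in% covered, ]
    nrow(unique(hit[c("family_id", "node_id")]))
  }, integer(1))
  tibble::tibble(term_id = live, n_branches = unname(counts))
}

# direct evaluation of the two slim-construction rules
oracle_slim_members <- function(counts, graph, min_branches) {
  selected <- counts$term_id[counts$n_branches > min_branches]
  added <- Filter(function(u)
    sum(selected %in% oracle_descendants(graph, u)) >= 2,
    setdiff(graph$terms$term_id, selected))
  sort(unique(c(selected, unlist(added), graph$roots)))
}

# random valid (tree, events) fixture shorthand
random_family <- function(seed, n_leaves = NULL, graph = NULL) {
  if (is.null(graph)) graph <- make_dag(25, seed + 1000)
  if (is.null(n_leaves))
    n_leaves <- withr::with_seed(seed, sample(4:20, 1))
  make_family(n_leaves, dup_prob = 0.35, gain_rate = 0.2, loss_rate = 0.1,
              graph = graph, seed = seed)
}
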
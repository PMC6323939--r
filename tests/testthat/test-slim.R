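# small fixed graph: R <- P <- {t1, t2}, P <- t3 (child->parent arrows)
slim_graph_fixture <- function() {
  ontology_graph(
    tibble::tibble(term_id = c("R", "P", "t1", "t2", "t3"),
                   name = c("root", "parent", "t1", "t2", "t3"),
                   aspect = "biological_process", obsolete = FALSE),
    tibble::tibble(child = c("P", "t1", "t2", "t3"),
                   parent = c("R", "P", "P", "P"), relation = "is_a"))
}

test_that("one gain counts once for the term and each ancestor", {
  g <- slim_graph_fixture()
  ev <- tibble::tibble(family_id = "F1", node_id = 1L, term_id = "t1",
                       kind = "gain")
  counts <- branch_usage_from_events(ev, g)
  got <- stats::setNames(counts$n_branches, counts$term_id)
  expect_equal(unname(got[c("t1", "P", "R")]), c(1L, 1L, 1L))
  expect_equal(unname(got[c("t2", "t3")]), c(0L, 0L))
})

test_that("sibling gains on one branch count that branch once for the parent", {
  g <- slim_graph_fixture()
  ev <- tibble::tibble(family_id = "F1", node_id = 1L,
                       term_id = c("t1", "t2"), kind = "gain")
  counts <- branch_usage_from_events(ev, g)
  expect_equal(counts$n_branches[counts$term_id == "P"], 1L)
  # ...but distinct branches each count
  ev2 <- dplyr::bind_rows(ev, tibble::tibble(
    family_id = "F2", node_id = 3L, term_id = "t1", kind = "gain"))
  counts2 <- branch_usage_from_events(ev2, g)
  expect_equal(counts2$n_branches[counts2$term_id == "P"], 2L)
})

test_that("loss events never contribute to usage counts", {
  g <- slim_graph_fixture()
  ev <- tibble::tibble(family_id = "F1", node_id = c(1L, 2L),
                       term_id = "t1", kind = c("gain", "loss"))
  counts <- branch_usage_from_events(ev, g)
  expect_equal(counts$n_branches[counts$term_id == "t1"], 1L)
})

test_that("usage counting matches the enumeration oracle and is coherent", {
  g <- make_dag(30, 4)
  for (seed in 1:12) {
    fams <- lapply(1:3, function(i) random_family(seed * 10 + i, graph = g))
    names(fams) <- paste0("F", 1:3)
    counts <- branch_usage_counts(fams, g)
    ev <- dplyr::bind_rows(lapply(names(fams), function(f)
      dplyr::mutate(fams[[f]]$events, family_id = f)))
    expect_equal(counts, oracle_branch_usage(ev, g))
    # count(ancestor) >= count(descendant)
    cnt <- stats::setNames(counts$n_branches, counts$term_id)
    for (t in sample(counts$term_id, 6))
      for (u in term_ancestors(g, t))
        expect_gte(cnt[[u]], cnt[[t]])
  }
})

test_that("selection uses a strict more-than-five-branches rule", {
  g <- slim_graph_fixture()
  counts <- tibble::tibble(term_id = c("R", "P", "t1", "t2", "t3"),
                           n_branches = c(9L, 8L, 6L, 5L, 0L))
  slim <- build_slim(counts, g)
  prov <- stats::setNames(slim$terms$provenance, slim$terms$term_id)
  expect_true("t1" %in% slim$terms$term_id)     # count 6 > 5
  expect_false("t2" %in% slim$terms$term_id)    # count 5 is not enough
  expect_equal(unname(prov["t1"]), "selected_by_count")
})

test_that("common ancestors of two selected terms are pulled in", {
  g <- slim_graph_fixture()
  counts <- tibble::tibble(term_id = c("R", "P", "t1", "t2", "t3"),
                           n_branches = c(0L, 0L, 6L, 6L, 0L))
  slim <- build_slim(counts, g)
  prov <- stats::setNames(slim$terms$provenance, slim$terms$term_id)
  expect_equal(unname(prov["P"]), "added_as_ancestor")
  expect_equal(unname(prov["R"]), "added_as_ancestor")
  expect_false("t3" %in% slim$terms$term_id)
})

test_that("an empty selection degrades to a roots-only slim with a warning", {
  g <- slim_graph_fixture()
  counts <- tibble::tibble(term_id = g$terms$term_id, n_branches = 0L)
  expect_warning(slim <- build_slim(counts, g), "only the aspect roots")
  expect_equal(slim$terms$term_id, "R")
})

test_that("slim membership matches the two-rule oracle on random fixtures", {
  for (seed in 1:25) {
    g <- make_dag(30, seed)
    ev <- withr::with_seed(seed, tibble::tibble(
      family_id = sample(paste0("F", 1:4), 60, replace = TRUE),
      node_id = sample(1:12, 60, replace = TRUE),
      term_id = sample(g$terms$term_id, 60, replace = TRUE),
      kind = "gain"))
    counts <- branch_usage_from_events(ev, g)
    slim <- suppressWarnings(build_slim(counts, g, min_branches = 3))
    expect_equal(sort(slim$terms$term_id),
                 oracle_slim_members(counts, g, min_branches = 3))
    # every slim term reaches a root inside the slim
    for (t in setdiff(slim$terms$term_id, slim$roots))
      expect_true(any(term_ancestors(slim, t) %in% slim$roots))
  }
})

test_that("raising min_branches never adds a selected term", {
  g <- make_dag(30, 77)
  ev <- withr::with_seed(77, tibble::tibble(
    family_id = sample(paste0("F", 1:5), 80, replace = TRUE),
    node_id = sample(1:10, 80, replace = TRUE),
    term_id = sample(g$terms$term_id, 80, replace = TRUE),
    kind = "gain"))
  counts <- branch_usage_from_events(ev, g)
  prev <- NULL
  for (k in 0:6) {
    slim <- suppressWarnings(build_slim(counts, g, min_branches = k))
    sel <- slim$terms$term_id[slim$terms$provenance == "selected_by_count"]
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
})

test_that("identical inputs give byte-identical slim OBO output", {
  g <- make_dag(30, 8)
  ev <- tibble::tibble(family_id = "F1", node_id = 1:5,
                       term_id = g$terms$term_id[10:14], kind = "gain")
  counts <- branch_usage_from_events(ev, g)
  s1 <- suppressWarnings(build_slim(counts, g, min_branches = 0))
  s2 <- suppressWarnings(build_slim(branch_usage_from_events(ev, g), g,
                                    min_branches = 0))
  expect_identical(write_obo(s1), write_obo(s2))
})

test_that("annotations map to the most specific slim terms only", {
  g <- parse_obo(c(
    "[Term]", "id: T", "name: t", "namespace: biological_process",
    "is_a: P", "",
    "[Term]", "id: P", "name: p", "namespace: biological_process",
    "is_a: G", "",
    "[Term]", "id: G", "name: g", "namespace: biological_process",
    "is_a: R", "",
    "[Term]", "id: R", "name: r", "namespace: biological_process"))
  slim <- ontology_graph(
    g$terms[g$terms$term_id %in% c("P", "G", "R"), ],
    tibble::tibble(child = c("P", "G"), parent = c("G", "R"),
                   relation = "is_a"))
  ann <- tibble::tibble(gene_id = "x", term_id = "T", evidence = "IBA")
  mapped <- map_to_slim(ann, slim, g)
  expect_equal(mapped$term_id, "P")  # P, not its ancestors G or R
  # a term already in the slim maps to itself only
  ann2 <- tibble::tibble(gene_id = "x", term_id = "G", evidence = "IBA")
  expect_equal(map_to_slim(ann2, slim, g)$term_id, "G")
})

test_that("slim mapping equals the brute-force minimal-ancestor computation", {
  for (seed in 1:10) {
    g <- make_dag(40, seed + 200)
    ev <- withr::with_seed(seed, tibble::tibble(
      family_id = "F1", node_id = sample(1:20, 30, replace = TRUE),
      term_id = sample(g$terms$term_id, 30, replace = TRUE), kind = "gain"))
    slim <- suppressWarnings(
      build_slim(branch_usage_from_events(ev, g), g, min_branches = 2))
    slim_terms <- slim$terms$term_id
    ann <- withr::with_seed(seed, tibble::tibble(
      gene_id = sample(paste0("g", 1:6), 15, replace = TRUE),
      term_id = sample(g$terms$term_id, 15, replace = TRUE),
      evidence = "IBA")) |> dplyr::distinct()
    mapped <- map_to_slim(ann, slim, g)
    manual <- dplyr::bind_rows(lapply(seq_len(nrow(ann)), function(i) {
      t <- ann$term_id[i]
      cand <- if (t %in% slim_terms) t else
        intersect(oracle_ancestors(g, t), slim_terms)
      if (!length(cand)) cand <- aspect_root(g, t)
      minimal <- cand[vapply(cand, function(u)
        !any(vapply(setdiff(cand, u), function(v)
          u %in% oracle_ancestors(g, v), logical(1))), logical(1))]
      tibble::tibble(gene_id = ann$gene_id[i], term_id = minimal)
    })) |> dplyr::distinct() |> dplyr::arrange(gene_id, term_id)
    expect_equal(mapped[c("gene_id", "term_id")], manual)
  }
})
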
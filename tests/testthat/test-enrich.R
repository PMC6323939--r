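test_that("fisher p-values hit the exact enumeration values", {
  expect_equal(fisher_overrep(5, 5, 5, 10, "greater"), 1 / choose(10, 5),
               tolerance = 1e-14)
  # symmetric table at its expectation: two-sided p is 1
  expect_equal(fisher_overrep(1, 2, 2, 4, "two_sided"), 1)
  # degenerate margin: list = reference
  for (alt in c("greater", "less", "two_sided"))
    expect_equal(fisher_overrep(7, 20, 7, 20, alt), 1)
  expect_error(fisher_overrep(6, 5, 5, 10), "support")
})

test_that("fisher agrees with stats::fisher.test on random tables", {
  set.seed(3)
  for (i in 1:50) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    k <- if (lo == hi) lo else sample(lo:hi, 1)
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    ft <- stats::fisher.test(tab)
    expect_equal(fisher_overrep(k, n, K, N, "two_sided"), ft$p.value,
                 tolerance = 1e-10)
    ft_g <- stats::fisher.test(tab, alternative = "greater")
    expect_equal(fisher_overrep(k, n, K, N, "greater"), ft_g$p.value,
                 tolerance = 1e-10)
  }
})

test_that("binomial tails are exact and match binom.test", {
  expect_equal(binom_overrep(2, 2, 0.5, "greater"), 0.25)
  expect_equal(binom_overrep(0, 17, 0, "greater"), 1)
  set.seed(4)
  for (i in 1:30) {
    n <- sample(1:40, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    bt <- stats::binom.test(k, n, p0)
    expect_equal(binom_overrep(k, n, p0, "two_sided"), bt$p.value,
                 tolerance = 1e-9)
    expect_equal(binom_overrep(k, n, p0, "greater"),
                 stats::binom.test(k, n, p0, "greater")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("binomial approaches fisher when the reference dwarfs the list", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    N <- 100 * n * sample(2:5, 1)
    K <- round(N * runif(1, 0.1, 0.5))
    k <- sample(0:n, 1)
    pf <- fisher_overrep(k, n, K, N, "greater")
    pb <- binom_overrep(k, n, K / N, "greater")
    expect_lt(abs(pf - pb) / pf, 0.1)
  }
})

test_that("mann-whitney exact enumeration matches the textbook example", {
  r <- mann_whitney_enrich(c(3, 4), c(1, 2))
  expect_equal(r$statistic, 4)
  expect_equal(r$p_value, 1 / 3)
  expect_true(r$exact)
  same <- mann_whitney_enrich(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p_value, 1)
})

test_that("mann-whitney agrees with wilcox.test and with the enumeration oracle", {
  set.seed(6)
  for (i in 1:15) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    x <- sample(1:20, m); y <- sample(1:20, n)  # ties possible across draws
    got <- mann_whitney_enrich(x, y)
    orc <- oracle_mwu(x, y)
    expect_equal(got$statistic, orc$U)
    expect_equal(got$p_value, orc$p)
    if (!any(duplicated(c(x, y)))) {
      wt <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(got$statistic, unname(wt$statistic))
      expect_equal(got$p_value, wt$p.value, tolerance = 1e-12)
    }
  }
})

test_that("the normal approximation is close to exact at combined size 20", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    exact <- mann_whitney_enrich(x, y, exact_max = 20)
    approx <- mann_whitney_enrich(x, y, exact_max = 0)
    expect_true(exact$exact); expect_false(approx$exact)
    expect_lt(abs(exact$p_value - approx$p_value), 0.01)
  }
})

test_that("BH step-up matches the direct formula; bonferroni caps at 1", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bonferroni(c(0.01, 0.5)), c(0.02, 1))
  expect_equal(bonferroni(c(0, 0, 1)), c(0, 0, 1))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= bonferroni(p) + 1e-12))
    # reordering the input permutes, never changes, the adjusted values
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

# shared fixture: closed-world annotation corpus with one planted signal
enrich_fixture <- function(seed = 123) {
  g <- make_dag(25, seed)
  genes <- sprintf("gene%03d", 1:400)
  ann <- withr::with_seed(seed, tibble::tibble(
    gene_id = sample(genes, 900, replace = TRUE),
    term_id = sample(setdiff(g$terms$term_id, g$roots), 900, replace = TRUE),
    evidence = "IEA", negated = FALSE)) |> dplyr::distinct()
  list(graph = g, genes = genes, ann = ann)
}

test_that("testing the reference against itself is a perfect null", {
  fx <- enrich_fixture()
  res <- run_overrepresentation(fx$genes, fx$genes, fx$ann, fx$graph)
  expect_true(all(res$p_raw == 1))
  expect_true(all(res$p_adjusted == 1))
  expect_true(all(abs(res$fold_enrichment - 1) < 1e-12))
})

test_that("a term enriched by construction ranks first", {
  fx <- enrich_fixture()
  target <- "GO:0000020"
  carriers <- unique(fx$ann$gene_id[fx$ann$term_id == target])
  outsiders <- setdiff(fx$genes, carriers)
  gene_list <- c(carriers, outsiders[1:5])   # nearly all list genes carry it
  res <- run_overrepresentation(gene_list, fx$genes, fx$ann, fx$graph)
  expect_equal(res$term_id[1], target)
  expect_equal(res$direction[1], "over")
  expect_gt(res$fold_enrichment[1], 1)
})

test_that("direction matches the sign of k - expected", {
  fx <- enrich_fixture()
  lists <- make_enriched_lists(fx$ann, "GO:0000015", effect = 4, seed = 11)
  res <- run_overrepresentation(lists$gene_list, lists$reference, fx$ann,
                                fx$graph)
  expect_equal(res$direction, ifelse(res$k >= res$expected, "over", "under"))
  # count consistency: per-term K totals equal the closed record count
  closed <- close_over_ontology(fx$ann, fx$graph) |>
    dplyr::filter(gene_id %in% lists$reference) |>
    dplyr::distinct(gene_id, term_id)
  expect_equal(sum(res$K[res$term_id != "UNCLASSIFIED"]), nrow(closed))
})

test_that("unannotated genes surface as an UNCLASSIFIED class", {
  g <- make_dag(10, 5)
  ann <- tibble::tibble(gene_id = c("g1", "g2"),
                        term_id = g$terms$term_id[5], evidence = "IEA")
  res <- run_overrepresentation(c("g1", "g3"), c("g1", "g2", "g3", "g4"),
                                ann, g)
  un <- res[res$term_id == "UNCLASSIFIED", ]
  expect_equal(un$K, 2L)  # g3, g4
  expect_equal(un$k, 1L)  # g3
})

test_that("list genes missing from the reference error unless coerced", {
  fx <- enrich_fixture()
  expect_error(
    run_overrepresentation(c(fx$genes[1], "martian"), fx$genes, fx$ann,
                           fx$graph),
    "absent from the reference")
  expect_warning(
    res <- run_overrepresentation(c(fx$genes[1], "martian"), fx$genes,
                                  fx$ann, fx$graph, coerce = TRUE),
    "added 1")
  expect_equal(unique(res$N), length(fx$genes) + 1L)
})

test_that("bonferroni correction is at least as conservative as the FDR", {
  fx <- enrich_fixture()
  lists <- make_enriched_lists(fx$ann, "GO:0000015", effect = 4, seed = 2)
  fdr <- run_overrepresentation(lists$gene_list, lists$reference, fx$ann,
                                fx$graph, correction = "fdr")
  bon <- run_overrepresentation(lists$gene_list, lists$reference, fx$ann,
                                fx$graph, correction = "bonferroni")
  j <- dplyr::inner_join(fdr, bon, by = "term_id",
                         suffix = c("_fdr", "_bon"))
  expect_true(all(j$p_adjusted_bon >= j$p_adjusted_fdr - 1e-12))
})

test_that("constant values give p = 1 for every class", {
  fx <- enrich_fixture()
  v <- tibble::tibble(gene_id = fx$genes, value = 1)
  res <- run_enrichment(v, fx$ann, fx$graph)
  expect_true(all(res$p_raw == 1))
})

test_that("a value shift planted on one class is detected and order-invariant", {
  g <- make_dag(15, 31)
  genes <- sprintf("g%03d", 1:200)
  target <- "GO:0000010"
  carriers <- genes[1:25]
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = carriers, term_id = target, evidence = "IEA"),
    withr::with_seed(31, tibble::tibble(
      gene_id = sample(genes, 300, replace = TRUE),
      term_id = sample(setdiff(g$terms$term_id, c(g$roots, target)), 300,
                       replace = TRUE),
      evidence = "IEA"))) |> dplyr::distinct()
  v <- withr::with_seed(32, tibble::tibble(
    gene_id = genes,
    value = rnorm(200) + ifelse(genes %in% carriers, 2.5, 0)))
  res <- run_enrichment(v, ann, g)
  expect_equal(res$term_id[1], target)
  expect_equal(res$direction[1], "over")
  shuffled <- withr::with_seed(33, v[sample(nrow(v)), ])
  expect_equal(run_enrichment(shuffled, ann, g), res)
})

test_that("result tables serialize identically across formats", {
  fx <- enrich_fixture()
  lists <- make_enriched_lists(fx$ann, "GO:0000015", effect = 4, seed = 2)
  res <- run_overrepresentation(lists$gene_list, lists$reference, fx$ann,
                                fx$graph)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  xm <- withr::local_tempfile(fileext = ".xml")
  write_results(res, tsv, "tsv")
  write_results(res, js, "json")
  write_results(res, xm, "xml")
  back <- tibble::as_tibble(utils::read.delim(tsv))
  expect_equal(back$term_id, res$term_id)
  expect_equal(back$p_adjusted, res$p_adjusted, tolerance = 1e-9)
  jj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(jj$term_id, res$term_id)
  doc <- xml2::read_xml(xm)
  expect_equal(length(xml2::xml_find_all(doc, "//result")), nrow(res))
})
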
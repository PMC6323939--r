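#' Exact overrepresentation p-values
#'
#' `fisher_overrep()` computes the exact hypergeometric (Fisher) p-value
#' for observing `k` annotated genes in a list of size `n`, when `K` of
#' the `N` reference genes are annotated. `binom_overrep()` is the legacy
#' binomial alternative with success probability `p0` (by default the
#' reference annotation rate `K/N`). One-sided p-values are exact tail
#' sums; the two-sided p-value follows the standard point-probability
#' rule (sum of all outcomes whose probability does not exceed that of
#' the observed one, within a relative tolerance of 1e-7).
#'
#' @param k Observed annotated genes in the list (may be a vector;
#'   margins are recycled).
#' @param n List size.
#' @param K Annotated genes in the reference.
#' @param N Reference size.
#' @param alternative `"greater"`, `"less"`, or `"two_sided"`.
#' @return Numeric p-value(s) in (0, 1].
#' @examples
#' fisher_overrep(5, 5, 5, 10, "greater")  # 1/choose(10,5)
#' @export
fisher_overrep <- function(k, n, K, N,
                           alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(N >= 1, K >= 0, K <= N, n >= 0, n <= N)
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  if (any(k < lo | k > hi))
    stop("k outside the hypergeometric support [", lo, ", ", hi, "]")
  switch(alternative,
    greater = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    less = stats::phyper(k, K, N - K, n),
    two_sided = {
      pmf <- stats::dhyper(lo:hi, K, N - K, n)
      vapply(k, function(ki) {
        min(1, sum(pmf[pmf <= pmf[ki - lo + 1] * (1 + 1e-7)]))
      }, numeric(1))
    })
}

#' @rdname fisher_overrep
#' @param p0 Null success probability.
#' @export
binom_overrep <- function(k, n, p0,
                          alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n >= 0, p0 >= 0, p0 <= 1, all(k >= 0), all(k <= n))
  switch(alternative,
    greater = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
    less = stats::pbinom(k, n, p0),
    two_sided = {
      pmf <- stats::dbinom(0:n, n, p0)
      vapply(k, function(ki) {
        min(1, sum(pmf[pmf <= pmf[ki + 1] * (1 + 1e-7)]))
      }, numeric(1))
    })
}

#' Mann-Whitney U enrichment test
#'
#' Compares the numeric values of a gene class against another set of
#' values using the Mann-Whitney U statistic with midranks for ties. The
#' two-sided p-value is exact -- full enumeration of all label
#' assignments -- when the combined sample size is at most `exact_max`,
#' and otherwise uses the normal approximation with tie correction and
#' continuity correction.
#'
#' @param class_values Numeric values of the genes in the class.
#' @param other_values Numeric values they are compared against.
#' @param exact_max Largest combined size for exact enumeration
#'   (default 20).
#' @return One-row tibble: `statistic` (U for the class), `p_value`,
#'   `exact` (logical).
#' @export
mann_whitney_enrich <- function(class_values, other_values, exact_max = 20) {
  m <- length(class_values); n2 <- length(other_values)
  if (m == 0 || n2 == 0) stop("both value sets must be non-empty")
  all_v <- c(class_values, other_values)
  r <- rank(all_v)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n2 / 2
  if (m + n2 <= exact_max) {
    combos <- utils::combn(m + n2, m)
    u_all <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    return(tibble::tibble(statistic = U, p_value = p, exact = TRUE))
  }
  ties <- table(all_v)
  nn <- m + n2
  sigma2 <- m * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0)
    return(tibble::tibble(statistic = U, p_value = 1, exact = FALSE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  tibble::tibble(statistic = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
                 exact = FALSE)
}

#' Multiple-testing corrections
#'
#' `bh_fdr()` is the Benjamini-Hochberg step-up false discovery rate
#' adjustment; `bonferroni()` is the family-wise `min(1, m * p)`
#' correction. Values are returned in input order.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' @rdname bh_fdr
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "bonferroni")
}

.apply_correction <- function(p, correction) {
  switch(correction, fdr = bh_fdr(p), bonferroni = bonferroni(p), none = p)
}

#' Gene-list overrepresentation analysis
#'
#' Tests every annotated class for over- or underrepresentation in a
#' gene list relative to a reference list. Annotations are expanded over
#' the ontology before counting, so a gene annotated to a specific term
#' counts for all its ancestors. Genes with no annotation are collected
#' under an `UNCLASSIFIED` pseudo-class. One test is run per term with at
#' least one annotated reference gene; the multiple-testing correction
#' (Benjamini-Hochberg FDR by default) is applied per ontology aspect.
#'
#' @param gene_list Character vector of gene ids (or a data frame whose
#'   first column holds them).
#' @param reference Character vector of reference gene ids; must contain
#'   the list.
#' @param annotations Annotation tibble (`gene_id`, `term_id`, ...).
#' @param graph An [ontology_graph()].
#' @param test `"fisher"` (default) or `"binomial"`.
#' @param alternative Sidedness of the per-term test (default
#'   `"two_sided"`; direction is reported separately).
#' @param correction `"fdr"` (default), `"bonferroni"`, or `"none"`.
#' @param coerce If `TRUE`, list genes missing from the reference are
#'   added to it with a warning instead of raising an error.
#' @return Tibble with one row per tested term, sorted by adjusted then
#'   raw p-value: `term_id`, `name`, `aspect`, `K` (annotated in
#'   reference), `k` (annotated in list), `n`, `N`, `expected`
#'   (`n * K / N`), `fold_enrichment`, `direction` (`"over"`/`"under"`),
#'   `p_raw`, `p_adjusted`, `method`, `correction`.
#' @export
run_overrepresentation <- function(gene_list, reference, annotations, graph,
                                   test = c("fisher", "binomial"),
                                   alternative = "two_sided",
                                   correction = c("fdr", "bonferroni", "none"),
                                   coerce = FALSE) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  gene_list <- .as_ids(gene_list)
  reference <- .as_ids(reference)
  if (!length(gene_list) || !length(reference))
    stop("gene list and reference must be non-empty")
  missing <- setdiff(gene_list, reference)
  if (length(missing)) {
    if (!coerce)
      stop(length(missing), " list gene(s) absent from the reference ",
           "(first: ", missing[1], "); set coerce = TRUE to add them")
    warning("added ", length(missing), " list gene(s) to the reference")
    reference <- union(reference, missing)
  }

  closed <- close_over_ontology(annotations, graph) |>
    dplyr::filter(.data$gene_id %in% reference) |>
    dplyr::distinct(.data$gene_id, .data$term_id)
  unclassified <- setdiff(reference, closed$gene_id)
  if (length(unclassified))
    closed <- dplyr::bind_rows(
      closed, tibble::tibble(gene_id = unclassified, term_id = "UNCLASSIFIED"))

  N <- length(reference); n <- length(gene_list)
  counts <- closed |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(K = dplyr::n(), k = sum(.data$gene_id %in% gene_list),
                     .groups = "drop")
  meta <- graph$terms[, c("term_id", "name", "aspect")]
  res <- counts |>
    dplyr::left_join(meta, by = "term_id") |>
    dplyr::mutate(
      name = dplyr::coalesce(.data$name, "unclassified"),
      aspect = dplyr::coalesce(.data$aspect, "none"),
      n = n, N = N,
      expected = n * .data$K / N,
      fold_enrichment = .data$k / .data$expected,
      direction = ifelse(.data$k >= .data$expected, "over", "under"),
      p_raw = purrr::map2_dbl(.data$k, .data$K, function(k, K) {
        if (test == "fisher") fisher_overrep(k, n, K, N, alternative)
        else binom_overrep(k, n, K / N, alternative)
      })) |>
    dplyr::group_by(.data$aspect) |>
    dplyr::mutate(p_adjusted = .apply_correction(.data$p_raw, correction)) |>
    dplyr::ungroup() |>
    dplyr::mutate(method = test, correction = correction) |>
    dplyr::select("term_id", "name", "aspect", "K", "k", "n", "N", "expected",
                  "fold_enrichment", "direction", "p_raw", "p_adjusted",
                  "method", "correction") |>
    dplyr::arrange(.data$p_adjusted, .data$p_raw, .data$term_id)
  class(res) <- c("overrep_result", class(res))
  res
}

.as_ids <- function(x) {
  if (is.data.frame(x)) x <- x[[1]]
  unique(as.character(x))
}

#' Value-based gene set enrichment (Mann-Whitney U)
#'
#' For each annotated class with at least `min_genes` genes carrying a
#' value, the values of the class genes are compared to the value
#' distribution of all genes (the class included) with the Mann-Whitney
#' U test. Annotations are expanded over the ontology first; correction
#' is applied per aspect.
#'
#' @param values Data frame with gene ids in the first column and
#'   numeric values in the second (or a named numeric vector).
#' @param annotations Annotation tibble.
#' @param graph An [ontology_graph()].
#' @param correction `"fdr"` (default), `"bonferroni"`, or `"none"`.
#' @param min_genes Minimum annotated genes for a class to be tested
#'   (default 2); smaller classes are skipped.
#' @return Tibble sorted by adjusted p-value: `term_id`, `name`,
#'   `aspect`, `n_genes`, `statistic` (U), `direction` (sign of the
#'   class median shift vs all genes), `p_raw`, `p_adjusted`.
#' @export
run_enrichment <- function(values, annotations, graph,
                           correction = c("fdr", "bonferroni", "none"),
                           min_genes = 2) {
  correction <- match.arg(correction)
  if (is.data.frame(values))
    values <- stats::setNames(as.numeric(values[[2]]), as.character(values[[1]]))
  if (length(values) < 2) stop("need values for at least 2 genes")
  if (anyDuplicated(names(values))) stop("duplicate gene ids in values")

  closed <- close_over_ontology(annotations, graph) |>
    dplyr::filter(.data$gene_id %in% names(values)) |>
    dplyr::distinct(.data$gene_id, .data$term_id)
  sizes <- dplyr::count(closed, .data$term_id, name = "n_genes")
  tested <- sizes$term_id[sizes$n_genes >= min_genes]
  if (!length(tested))
    return(tibble::tibble(term_id = character(), name = character(),
                          aspect = character(), n_genes = integer(),
                          statistic = numeric(), direction = character(),
                          p_raw = numeric(), p_adjusted = numeric()))
  all_med <- stats::median(values)
  meta <- graph$terms[, c("term_id", "name", "aspect")]
  res <- purrr::map(tested, function(t) {
    cls <- values[closed$gene_id[closed$term_id == t]]
    mw <- mann_whitney_enrich(cls, unname(values))
    tibble::tibble(term_id = t, n_genes = length(cls), statistic = mw$statistic,
                   direction = ifelse(stats::median(cls) >= all_med,
                                      "over", "under"),
                   p_raw = mw$p_value)
  }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(meta, by = "term_id") |>
    dplyr::group_by(.data$aspect) |>
    dplyr::mutate(p_adjusted = .apply_correction(.data$p_raw, correction)) |>
    dplyr::ungroup() |>
    dplyr::select("term_id", "name", "aspect", "n_genes", "statistic",
                  "direction", "p_raw", "p_adjusted") |>
    dplyr::arrange(.data$p_adjusted, .data$p_raw, .data$term_id)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Write enrichment results
#'
#' Serializes a result table as TSV, JSON, or XML (the same columns in
#' each format).
#'
#' @param results A result tibble from [run_overrepresentation()] or
#'   [run_enrichment()].
#' @param path Output file; TSV goes to stdout when `NULL`.
#' @param format `"tsv"`, `"json"`, or `"xml"`.
#' @export
write_results <- function(results, path = NULL,
                          format = c("tsv", "json", "xml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- if (is.null(path)) stdout() else path
    utils::write.table(results, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(results, path %||% stop("json output needs a path"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    doc <- xml2::xml_new_root("results")
    for (i in seq_len(nrow(results))) {
      node <- xml2::xml_add_child(doc, "result")
      for (col in names(results))
        xml2::xml_add_child(node, col, format(results[[col]][i], digits = 15))
    }
    xml2::write_xml(doc, path %||% stop("xml output needs a path"))
  }
  invisible(path)
}
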
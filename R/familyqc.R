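#' Multiple sequence alignments as character matrices
#'
#' Alignments are handled as character matrices (one row per member, one
#' column per alignment position, gap = `"-"`) with member ids as row
#' names. `read_msa()`/`write_msa()` go through Biostrings aligned FASTA.
#'
#' @param path Aligned FASTA file.
#' @return `read_msa()`: character matrix. `write_msa()`: invisibly, the
#'   path written.
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(aa))) > 1)
    stop("rows of an alignment must all have the same length")
  m <- as.matrix(aa)
  rownames(m) <- names(aa)
  .validate_msa(m)
}

#' @rdname read_msa
#' @param msa Character matrix with row names.
#' @export
write_msa <- function(msa, path) {
  msa <- .validate_msa(msa)
  seqs <- apply(msa, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(seqs, rownames(msa))), path)
  invisible(path)
}

.validate_msa <- function(msa) {
  if (is.null(dim(msa))) stop("msa must be a matrix")
  if (nrow(msa) < 2) stop("an alignment needs at least 2 members")
  if (is.null(rownames(msa)) || anyDuplicated(rownames(msa)))
    stop("msa rows must carry unique member ids")
  msa
}

#' Core columns of an alignment
#'
#' A column belongs to the retained core iff its non-gap fraction is at
#' least `occupancy` (default 0.5). Indices are 1-based, ascending.
#'
#' @param msa Alignment character matrix (gap = `"-"`).
#' @param occupancy Minimum non-gap fraction, in (0, 1].
#' @return Integer vector of core column indices.
#' @export
core_columns <- function(msa, occupancy = 0.5) {
  msa <- .validate_msa(msa)
  stopifnot(occupancy > 0, occupancy <= 1)
  which(colMeans(msa != "-") >= occupancy)
}

# columns (within `cols`) where a member is non-gap, per member
.aligned_core_cols <- function(msa, cols) {
  if (!length(cols)) return(stats::setNames(rep(0L, nrow(msa)), rownames(msa)))
  rowSums(msa[, cols, drop = FALSE] != "-")
}

#' Family-boundary diagnostics
#'
#' Four criteria flag families whose alignments suggest a poor or wrongly
#' merged family:
#' * `criterion_e1()`: more than half the members fail to align to the
#'   retained core (a member "does not align" when it has residues in
#'   fewer than `min_align_cols` core columns); flag iff the fraction is
#'   strictly greater than `max_fraction` (default 0.5).
#' * `criterion_e2()`: the core is short (fewer than `max_core` columns)
#'   while the full alignment is at least `ratio` times wider than the
#'   core.
#' * `criterion_p1()`: at least `min_fraction` (default 10%) of members
#'   each align to fewer than `min_align_cols` (core) columns.
#' * `criterion_p2()`: some internal-edge split of the family tree
#'   separates two subtrees whose alignments share fewer than
#'   `min_shared` sites (a site is shared when at least half the members
#'   on each side are non-gap there).
#'
#' @param msa Alignment character matrix.
#' @param occupancy Core-column occupancy threshold (see
#'   [core_columns()]).
#' @param min_align_cols Minimum core columns a member must cover to
#'   count as aligned (default 30).
#' @param max_fraction E1 member-fraction cutoff (strict, default 0.5).
#' @return One-row tibbles carrying the flag and its supporting
#'   measurement(s).
#' @export
criterion_e1 <- function(msa, occupancy = 0.5, min_align_cols = 30,
                         max_fraction = 0.5) {
  cols <- core_columns(msa, occupancy)
  frac <- mean(.aligned_core_cols(msa, cols) < min_align_cols)
  tibble::tibble(flag = frac > max_fraction, noncore_member_fraction = frac)
}

#' @rdname criterion_e1
#' @param max_core Core length below which the core counts as short
#'   (strict, default 100).
#' @param ratio Minimum total/core width ratio (inclusive, default 4).
#' @export
criterion_e2 <- function(msa, occupancy = 0.5, max_core = 100, ratio = 4) {
  core <- length(core_columns(msa, occupancy))
  tibble::tibble(flag = core < max_core && ncol(msa) >= ratio * core,
                 core_column_count = core)
}

#' @rdname criterion_e1
#' @param min_fraction P1 member-fraction cutoff (inclusive, default
#'   0.10).
#' @export
criterion_p1 <- function(msa, occupancy = 0.5, min_align_cols = 30,
                         min_fraction = 0.10) {
  cols <- core_columns(msa, occupancy)
  frac <- mean(.aligned_core_cols(msa, cols) < min_align_cols)
  tibble::tibble(flag = frac >= min_fraction, sparse_member_fraction = frac)
}

#' @rdname criterion_e1
#' @param tree A [family_tree()] whose leaf gene ids equal the msa row
#'   names.
#' @param min_shared Minimum shared sites between the two sides of a
#'   split (strict, default 30).
#' @param side_occupancy Per-side non-gap fraction for a column to count
#'   as occupied by that side (default 0.5).
#' @export
criterion_p2 <- function(msa, tree, min_shared = 30, side_occupancy = 0.5) {
  msa <- .validate_msa(msa)
  stopifnot(inherits(tree, "family_tree"))
  leaves <- tree_leaves(tree)$gene_id
  if (!setequal(leaves, rownames(msa)))
    stop("msa members and tree leaves differ")
  nongap <- msa != "-"
  internal <- tree$nodes$node_id[tree$nodes$event != "leaf" &
                                   !is.na(tree$nodes$parent_id)]
  shared_per_split <- vapply(internal, function(v) {
    a <- tree_leaves(tree, v)$gene_id
    b <- setdiff(leaves, a)
    sum(colMeans(nongap[a, , drop = FALSE]) >= side_occupancy &
          colMeans(nongap[b, , drop = FALSE]) >= side_occupancy)
  }, numeric(1))
  worst <- if (length(shared_per_split)) min(shared_per_split) else ncol(msa)
  tibble::tibble(flag = worst < min_shared, worst_split_shared_sites = worst)
}

#' Run all family-boundary diagnostics
#'
#' Applies the two alignment-trimming criteria (E1, E2) and the two
#' divergence criteria (P1, P2) and reports the union of the flags with
#' all supporting measurements. A family is considered flagged when any
#' criterion fires; a family flagged by several criteria still counts
#' once.
#'
#' @inheritParams criterion_e1
#' @param tree A [family_tree()] matching the msa members.
#' @param family_id Identifier reported in the output row.
#' @param ... Threshold overrides passed on to the criteria
#'   (`min_align_cols`, `max_fraction`, `max_core`, `ratio`,
#'   `min_fraction`, `min_shared`, `side_occupancy`).
#' @return One-row tibble: `family_id`, the four measurements, four
#'   logical flag columns (`e1_noncore_members`, `e2_short_core`,
#'   `p1_sparse_members`, `p2_disjoint_subtrees`) and `flagged`.
#' @export
qc_family <- function(msa, tree, family_id = "FAM1", occupancy = 0.5, ...) {
  dots <- list(...)
  pick <- function(f, names) do.call(f, c(list(msa, occupancy = occupancy),
                                          dots[intersect(names(dots), names)]))
  e1 <- pick(criterion_e1, c("min_align_cols", "max_fraction"))
  e2 <- pick(criterion_e2, c("max_core", "ratio"))
  p1 <- pick(criterion_p1, c("min_align_cols", "min_fraction"))
  p2 <- do.call(criterion_p2,
                c(list(msa, tree),
                  dots[intersect(names(dots), c("min_shared", "side_occupancy"))]))
  tibble::tibble(
    family_id = family_id,
    core_column_count = e2$core_column_count,
    noncore_member_fraction = e1$noncore_member_fraction,
    sparse_member_fraction = p1$sparse_member_fraction,
    worst_split_shared_sites = p2$worst_split_shared_sites,
    e1_noncore_members = e1$flag,
    e2_short_core = e2$flag,
    p1_sparse_members = p1$flag,
    p2_disjoint_subtrees = p2$flag,
    flagged = e1$flag | e2$flag | p1$flag | p2$flag)
}

#' Forward-track family identifiers after reclustering
#'
#' Each old family identifier is carried forward to the new cluster that
#' contains the largest number of its former members (ties broken toward
#' the lexicographically smallest cluster id). Clusters that inherit no
#' identifier are given fresh ones; old families whose members appear in
#' no cluster are retired.
#'
#' @param old_members Named list: family id -> character vector of
#'   member ids.
#' @param new_clusters Named list: cluster id -> character vector of
#'   member ids.
#' @param fresh_prefix Prefix for newly minted family identifiers.
#' @return Tibble with columns `family_id`, `cluster_id`, `n_shared`,
#'   `status` (`"tracked"`, `"retired"`, or `"new"` for fresh
#'   identifiers assigned to unclaimed clusters).
#' @export
forward_track_ids <- function(old_members, new_clusters,
                              fresh_prefix = "NEWFAM") {
  stopifnot(length(names(old_members)) == length(old_members),
            length(names(new_clusters)) == length(new_clusters))
  cluster_ids <- sort(names(new_clusters))
  rows <- purrr::map(sort(names(old_members)), function(f) {
    shared <- vapply(cluster_ids,
                     function(cl) length(intersect(old_members[[f]],
                                                   new_clusters[[cl]])),
                     integer(1))
    if (!any(shared > 0))
      return(tibble::tibble(family_id = f, cluster_id = NA_character_,
                            n_shared = 0L, status = "retired"))
    best <- cluster_ids[shared == max(shared)][1]  # ids sorted: ties -> smallest
    tibble::tibble(family_id = f, cluster_id = best,
                   n_shared = max(shared), status = "tracked")
  })
  tracked <- dplyr::bind_rows(rows)
  unclaimed <- setdiff(cluster_ids, tracked$cluster_id)
  fresh <- tibble::tibble(
    family_id = sprintf("%s%04d", fresh_prefix, seq_along(unclaimed)),
    cluster_id = unclaimed,
    n_shared = NA_integer_,
    status = "new")
  dplyr::bind_rows(tracked, fresh)
}
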
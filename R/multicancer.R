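#' Binary membership matrix over gene sets from several datasets
#'
#' Rows are the union of all genes (lexicographic order), columns the
#' datasets; an entry is 1 when the gene belongs to that dataset's set.
#'
#' @param lists Named list (>= 2 entries) of character vectors of gene
#'   ids, one per dataset.
#' @return An integer 0/1 matrix, genes x datasets.
#' @export
build_membership_matrix <- function(lists) {
  if (!length(lists)) stop("`lists` must not be empty")
  if (length(lists) < 2L) stop("need >= 2 datasets to compare")
  if (is.null(names(lists)) || anyDuplicated(names(lists)))
    stop("`lists` must carry unique dataset names")
  universe <- sort(unique(unlist(lists, use.names = FALSE)))
  m <- vapply(lists, function(set) as.integer(universe %in% set),
              integer(length(universe)))
  rownames(m) <- universe
  m
}

#' Hamming distances between the columns of a binary matrix
#'
#' `d(a, b)` counts the rows where columns a and b differ; optionally
#' divided by the number of rows, so universes of different sizes compare
#' sensibly.
#'
#' @param m Binary matrix (genes x datasets) with >= 2 columns.
#' @param normalize Divide by the row count (default `TRUE`).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
hamming_distance_matrix <- function(m, normalize = TRUE) {
  if (ncol(m) < 2L) stop("need >= 2 columns")
  if (!all(m %in% c(0L, 1L))) stop("matrix must be binary (0/1)")
  nd <- ncol(m)
  d <- matrix(0, nd, nd, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(nd - 1L)) for (j in (i + 1L):nd) {
    h <- sum(m[, i] != m[, j])
    d[i, j] <- d[j, i] <- h
  }
  if (normalize) d <- d / nrow(m)
  d
}

#' Agglomerative clustering of datasets from a distance matrix
#'
#' Average-linkage hierarchical clustering (configurable) of the datasets,
#' with the merge heights and leaf order of the dendrogram recorded.
#'
#' @param dist_matrix Symmetric distance matrix (e.g. from
#'   [hamming_distance_matrix()]).
#' @param linkage Linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return A list with the `hclust` object (`tree`), `merge_heights` and
#'   `leaf_order` (dataset names in dendrogram order).
#' @export
cluster_datasets <- function(dist_matrix, linkage = "average") {
  if (!isSymmetric(unname(as.matrix(dist_matrix))))
    stop("distance matrix must be symmetric")
  tree <- stats::hclust(stats::as.dist(dist_matrix), method = linkage)
  list(tree = tree, merge_heights = tree$height,
       leaf_order = tree$labels[tree$order])
}

#' Write a dataset dendrogram in Newick format
#' @param clustering Output of [cluster_datasets()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Venn-cell counts for a subset of datasets
#'
#' Enumerates all `2^n - 1` non-empty membership patterns over the chosen
#' datasets and counts the genes in each exclusive cell; the `shared`
#' element is the intersection of all chosen sets.
#'
#' @param lists Named list of gene sets (as for
#'   [build_membership_matrix()]).
#' @param subset Character vector of 2 to 5 dataset names from `lists`.
#' @return A list with `shared` (character vector), `n_shared`, and
#'   `cells`: a data.frame with one row per membership pattern
#'   (`pattern`, e.g. `"brca&luad"`, and `count` of genes exclusive to
#'   that pattern).
#' @export
shared_genes <- function(lists, subset) {
  miss <- setdiff(subset, names(lists))
  if (length(miss)) stop("unknown dataset(s): ", paste(miss, collapse = ", "))
  if (length(subset) < 2L || length(subset) > 5L)
    stop("`subset` must name between 2 and 5 datasets")
  sets <- lists[subset]
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(universe, subset))
  patterns <- apply(member, 1L, function(row)
    paste(subset[row], collapse = "&"))
  n <- length(subset)
  all_patterns <- unlist(lapply(seq_len(n), function(sz)
    utils::combn(subset, sz, paste, collapse = "&", simplify = TRUE)))
  counts <- table(factor(patterns, levels = all_patterns))
  shared <- universe[rowSums(member) == n]
  list(shared = shared, n_shared = length(shared),
       cells = data.frame(pattern = all_patterns,
                          count = as.integer(counts[all_patterns]),
                          stringsAsFactors = FALSE, row.names = NULL))
}

#' Compare switch-gene neighbour sets across datasets
#'
#' Each dataset contributes the union of the nearest-neighbour sets of its
#' switch genes; those per-dataset neighbour universes are then compared
#' with the same binary-encoding / Hamming-distance / clustering pipeline
#' used for the switch genes themselves.
#'
#' @param neighbor_maps Named list (one entry per dataset) of named lists
#'   mapping each switch gene to its character vector of neighbours (as
#'   returned by [find_switch_genes()]).
#' @param normalize,linkage Passed on to [hamming_distance_matrix()] and
#'   [cluster_datasets()].
#' @return A list with `membership` (binary matrix), `dist` (distance
#'   matrix) and `clustering` (see [cluster_datasets()]).
#' @export
compare_neighbor_sets <- function(neighbor_maps, normalize = TRUE,
                                  linkage = "average") {
  if (length(neighbor_maps) < 2L) stop("need >= 2 datasets with neighbour maps")
  sets <- lapply(neighbor_maps, function(mp)
    sort(unique(unlist(mp, use.names = FALSE))))
  m <- build_membership_matrix(sets)
  d <- hamming_distance_matrix(m, normalize = normalize)
  list(membership = m, dist = d, clustering = cluster_datasets(d, linkage))
}
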
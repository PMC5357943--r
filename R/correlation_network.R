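#' Pearson correlation matrix of gene expression profiles
#'
#' @param em An `expr_set` with at least 3 samples; every gene must have
#'   non-zero variance across samples (filter first otherwise).
#' @return A symmetric genes-by-genes matrix of Pearson r with unit diagonal.
#' @export
pearson_matrix <- function(em) {
  stopifnot(inherits(em, "expr_set"))
  if (n_samples(em) < 3L)
    stop("need >= 3 samples to estimate correlations")
  sds <- apply(em$values, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(em$values)[sds == 0]
    stop("zero-variance gene(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         "; remove them before computing correlations")
  }
  r <- stats::cor(t(em$values))
  # guard against floating-point drift outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Build the co-expression network from a correlation matrix
#'
#' An edge joins genes i and j (i != j) when `|r(i,j)| >= cutoff`; the edge
#' keeps the signed correlation as its `weight` attribute. All genes remain
#' in the node set; genes left without any edge are flagged in the vertex
#' attribute `isolated`.
#'
#' @param corr Symmetric correlation matrix with unit diagonal (as from
#'   [pearson_matrix()]).
#' @param cutoff Correlation threshold in (0, 1).
#' @return An undirected [igraph::igraph] graph with signed edge weights.
#' @export
build_graph <- function(corr, cutoff) {
  check_corr_matrix(corr)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1)
    stop("`cutoff` must lie strictly inside (0, 1)")
  adj <- corr
  adj[abs(adj) < cutoff] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$isolated <- igraph::degree(g) == 0L
  g$cutoff <- cutoff
  g
}

check_corr_matrix <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("`corr` must be a square matrix")
  if (is.null(rownames(corr)))
    stop("`corr` must carry gene ids as dimnames")
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("`corr` must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("`corr` must have unit diagonal")
  invisible(TRUE)
}

#' Audit the correlation cutoff choice
#'
#' Rebuilds the network at each candidate cutoff and reports how much of it
#' survives, so the threshold can be chosen while the integrity of the
#' network is preserved.
#'
#' @param corr Correlation matrix (see [build_graph()]).
#' @param cutoffs Strictly increasing vector of cutoffs in (0, 1).
#' @return A data.frame with columns `cutoff`, `n_nodes_with_edges`,
#'   `n_edges`, `fraction_in_largest_component` (fraction of all genes that
#'   fall in the largest connected component).
#' @export
threshold_scan <- function(corr, cutoffs) {
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("`cutoffs` must be strictly increasing")
  rows <- lapply(cutoffs, function(ct) {
    g <- build_graph(corr, ct)
    comp <- igraph::components(g)
    data.frame(cutoff = ct,
               n_nodes_with_edges = sum(igraph::degree(g) > 0L),
               n_edges = igraph::ecount(g),
               fraction_in_largest_component =
                 max(comp$csize) / igraph::vcount(g))
  })
  do.call(rbind, rows)
}

#' Degree distribution of a network
#'
#' @param g An igraph graph.
#' @return A list with `per_node` (data.frame `gene`, `degree`) and
#'   `histogram` (data.frame `degree`, `count`; counts sum to the number of
#'   nodes).
#' @export
degree_summary <- function(g) {
  deg <- igraph::degree(g)
  per_node <- data.frame(gene = names(deg), degree = unname(deg),
                         stringsAsFactors = FALSE)
  tab <- table(factor(deg, levels = sort(unique(deg))))
  hist <- data.frame(degree = as.integer(names(tab)),
                     count = as.integer(tab))
  list(per_node = per_node, histogram = hist)
}

#' Write the signed edge list of a network as TSV
#' @param g Graph from [build_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("gene_a", "gene_b")
  names(el)[names(el) == "weight"] <- "r"
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
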
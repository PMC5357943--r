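#' Per-node link counts into each community
#'
#' For every node: total degree `k`, internal degree `k_in` (links to the
#' node's own community) and the vector `k_s` of links into each community
#' `s` (own included). Counts run over all incident edges regardless of the
#' sign of the correlation carried by the edge.
#'
#' @param g Graph from [build_graph()] (any igraph graph works).
#' @param ca A `cluster_assignment`, or a named integer vector of community
#'   labels covering every graph node.
#' @return A list of class `link_counts` with `gene`, `community`, `k`,
#'   `k_in` (vectors) and `k_s` (nodes x communities integer matrix).
#' @export
community_link_counts <- function(g, ca) {
  membership <- as_membership(ca)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  miss <- setdiff(nodes, names(membership))
  if (length(miss))
    stop("node(s) without a community label: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  membership <- membership[nodes]
  ncl <- max(membership)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A[A != 0] <- 1  # unweighted counts
  M <- Matrix_indicator(membership, ncl)
  ks <- A %*% M
  storage.mode(ks) <- "integer"
  colnames(ks) <- seq_len(ncl)
  rownames(ks) <- nodes
  k <- rowSums(ks)
  k_in <- ks[cbind(seq_along(nodes), membership)]
  structure(list(gene = nodes, community = unname(membership),
                 k = unname(as.integer(k)), k_in = unname(as.integer(k_in)),
                 k_s = ks),
            class = "link_counts")
}

as_membership <- function(ca) {
  if (inherits(ca, "cluster_assignment")) return(ca$membership)
  if (is.null(names(ca))) stop("community labels must be named by gene id")
  stats::setNames(as.integer(ca), names(ca))
}

# dense indicator matrix: node x community
Matrix_indicator <- function(membership, ncl) {
  M <- matrix(0, length(membership), ncl)
  M[cbind(seq_along(membership), membership)] <- 1
  M
}

#' Participation coefficient
#'
#' `P = 1 - sum_s (k_s / k)^2`: how evenly a node's links spread across all
#' communities (own included). `P = 0` when all links fall in one
#' community; its supremum over allocations into N communities is
#' `1 - 1/N`.
#'
#' @param counts A `link_counts` object, or a bare numeric matrix of
#'   per-node link counts into each community (one row per node).
#' @return Named numeric vector of P; nodes with `k = 0` are dropped with
#'   a warning (P is undefined there).
#' @export
participation_coefficient <- function(counts) {
  ks <- if (inherits(counts, "link_counts")) counts$k_s else as.matrix(counts)
  k <- rowSums(ks)
  if (any(k == 0)) {
    warning(sum(k == 0), " isolated node(s) dropped: participation undefined at k = 0")
    ks <- ks[k > 0, , drop = FALSE]
    k <- k[k > 0]
  }
  p <- 1 - rowSums((ks / k)^2)
  stats::setNames(pmax(p, 0), rownames(ks))
}

#' Clusterphobic coefficient
#'
#' `K_pi = 1 - (k_in / k)^2`: the outward orientation of a node. Zero when
#' every link stays inside the node's own community; approaches 1 when the
#' node interacts mainly outside. Unlike the participation coefficient its
#' upper bound does not depend on the number of communities.
#'
#' @param counts A `link_counts` object.
#' @return Named numeric vector of K_pi; isolated nodes dropped with a
#'   warning.
#' @export
clusterphobic_coefficient <- function(counts) {
  stopifnot(inherits(counts, "link_counts"))
  k <- counts$k; k_in <- counts$k_in
  keep <- k > 0
  if (any(!keep))
    warning(sum(!keep), " isolated node(s) dropped: K_pi undefined at k = 0")
  stats::setNames(1 - (k_in[keep] / k[keep])^2, counts$gene[keep])
}

#' Within-module degree (z)
#'
#' z-score of a node's internal degree against the internal-degree
#' distribution (mean, sample sd) of its own community. Communities with
#' fewer than 2 nodes or zero spread yield `z = 0` with a warning.
#'
#' @param counts A `link_counts` object.
#' @return Named numeric vector of z over all nodes in `counts`.
#' @export
within_module_degree <- function(counts) {
  stopifnot(inherits(counts, "link_counts"))
  module_zscore(counts, reference = "internal")
}

#' Global within-module degree (z_g)
#'
#' The internal degree of a node centred and scaled by the mean and sample
#' sd of the *total* degrees of the nodes in its community, so local
#' connectivity is judged against the community's global connectivity.
#' Degenerate communities yield `z_g = 0` with a warning.
#'
#' @param counts A `link_counts` object.
#' @return Named numeric vector of z_g.
#' @export
global_within_module_degree <- function(counts) {
  stopifnot(inherits(counts, "link_counts"))
  module_zscore(counts, reference = "total")
}

module_zscore <- function(counts, reference = c("internal", "total")) {
  reference <- match.arg(reference)
  ref_deg <- if (reference == "internal") counts$k_in else counts$k
  z <- numeric(length(counts$gene))
  degenerate <- FALSE
  for (cl in unique(counts$community)) {
    idx <- counts$community == cl
    mu <- mean(ref_deg[idx])
    sdv <- if (sum(idx) >= 2L) stats::sd(ref_deg[idx]) else 0
    if (is.na(sdv) || sdv == 0) {
      z[idx] <- 0
      degenerate <- TRUE
    } else {
      z[idx] <- (counts$k_in[idx] - mu) / sdv
    }
  }
  if (degenerate)
    warning("community with degenerate (zero-sd or singleton) ", reference,
            "-degree distribution: z set to 0 there")
  stats::setNames(z, counts$gene)
}

#' Average Pearson correlation with network neighbours (APCC)
#'
#' The arithmetic mean of the signed correlations carried by a node's
#' incident edges, i.e. the mean co-expression of a gene with its first
#' neighbours in the network. Only edges retained by the correlation
#' cutoff contribute.
#'
#' @param g Graph from [build_graph()] with signed `weight` edge
#'   attribute.
#' @param nodes Optional node names; defaults to all non-isolated nodes.
#' @return Named numeric vector of APCC in `[-1, 1]`; isolated nodes are
#'   excluded (APCC undefined).
#' @export
apcc <- function(g, nodes = NULL) {
  if (is.null(igraph::E(g)$weight))
    stop("graph has no signed edge weights")
  deg <- igraph::degree(g)
  wsum <- igraph::strength(g, weights = igraph::E(g)$weight)
  vals <- stats::setNames(unname(wsum) / ifelse(deg > 0, deg, NA),
                          igraph::V(g)$name)
  vals <- vals[!is.na(vals)]
  if (!is.null(nodes)) {
    miss <- setdiff(nodes, names(vals))
    if (length(miss))
      stop("APCC undefined for isolated/unknown node(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    vals <- vals[nodes]
  }
  vals
}

#' Heat-cartography region boundaries
#'
#' The `(K_pi, z_g)` plane is split into seven regions. Below the `z_cut`
#' line: R1 (`K_pi <= low[1]`), R2, R3, R4 (`K_pi > low[3]`); at or above
#' it: R5 (`K_pi <= high[1]`), R6, R7 (`K_pi > high[2]`). The defaults are
#' the classical cartography cut points with the R4 bound at 0.8.
#'
#' @param z_cut Boundary on z_g between the non-hub (R1-R4) and hub
#'   (R5-R7) rows (default 2.5).
#' @param low K_pi breaks for the z_g < z_cut row (default
#'   `c(0.05, 0.625, 0.8)`).
#' @param high K_pi breaks for the z_g >= z_cut row (default
#'   `c(0.3, 0.75)`).
#' @return A named list used by [assign_region()].
#' @export
region_boundaries <- function(z_cut = 2.5, low = c(0.05, 0.625, 0.8),
                              high = c(0.3, 0.75)) {
  stopifnot(length(low) == 3L, !is.unsorted(low, strictly = TRUE),
            length(high) == 2L, !is.unsorted(high, strictly = TRUE))
  list(z_cut = z_cut, low = low, high = high)
}

#' Assign heat-cartography regions
#'
#' @param K_pi,z_g Numeric vectors (equal length) of the clusterphobic
#'   coefficient and the global within-module degree.
#' @param boundaries Output of [region_boundaries()].
#' @return Character vector of regions `"R1"`..`"R7"`.
#' @export
assign_region <- function(K_pi, z_g, boundaries = region_boundaries()) {
  stopifnot(length(K_pi) == length(z_g))
  b <- boundaries
  low_row <- z_g < b$z_cut
  region <- character(length(K_pi))
  region[low_row] <- c("R1", "R2", "R3", "R4")[
    findInterval(K_pi[low_row], b$low, left.open = TRUE) + 1L]
  region[!low_row] <- c("R5", "R6", "R7")[
    findInterval(K_pi[!low_row], b$high, left.open = TRUE) + 1L]
  region
}

#' Classify hubs by neighbour co-expression
#'
#' Nodes with degree below `hub_min_degree` are `"none"`. Hubs with
#' negative APCC are `"fight-club"`; hubs with low positive APCC
#' (`0 <= APCC < party_threshold`) are `"date"`; hubs with high APCC are
#' `"party"`.
#'
#' @param k Integer vector of degrees.
#' @param apcc_values Numeric vector of APCC, aligned with `k`.
#' @param hub_min_degree Minimum degree of a hub (default 5).
#' @param party_threshold APCC cut between date and party hubs
#'   (default 0.5).
#' @return Character vector in `{"date", "party", "fight-club", "none"}`.
#' @export
classify_hubs <- function(k, apcc_values, hub_min_degree = 5L,
                          party_threshold = 0.5) {
  stopifnot(length(k) == length(apcc_values))
  cls <- rep("none", length(k))
  hub <- k >= hub_min_degree
  cls[hub & apcc_values < 0] <- "fight-club"
  cls[hub & apcc_values >= 0 & apcc_values < party_threshold] <- "date"
  cls[hub & apcc_values >= party_threshold] <- "party"
  cls
}

#' Full cartography table for a network and community partition
#'
#' Computes, per node: degree counts, participation coefficient `P`,
#' within-module degree `z`, clusterphobic coefficient `K_pi`, global
#' within-module degree `z_g`, APCC, heat-cartography region, hub flag and
#' class, and the switch call (`region == "R4"` and `APCC < 0`). Isolated
#' nodes are dropped from the table (their statistics are undefined) and
#' reported in the `"isolated"` attribute.
#'
#' @param g Graph from [build_graph()].
#' @param ca Community assignment (see [community_link_counts()]).
#' @param hub_min_degree,party_threshold See [classify_hubs()].
#' @param boundaries See [region_boundaries()].
#' @return A data.frame of class `cartography_table` with columns `gene`,
#'   `community`, `k`, `k_in`, `P`, `z`, `K_pi`, `z_g`, `APCC`, `region`,
#'   `hub`, `hub_class`, `switch`.
#' @export
cartography_table <- function(g, ca, hub_min_degree = 5L,
                              party_threshold = 0.5,
                              boundaries = region_boundaries()) {
  isolated <- igraph::V(g)$name[igraph::degree(g) == 0L]
  if (length(isolated)) {
    warning(length(isolated),
            " isolated node(s) dropped from the cartography: ",
            paste(utils::head(isolated, 5L), collapse = ", "))
    g <- igraph::delete_vertices(g, isolated)
  }
  counts <- community_link_counts(g, ca)
  P <- participation_coefficient(counts)
  K_pi <- clusterphobic_coefficient(counts)
  z <- within_module_degree(counts)
  z_g <- global_within_module_degree(counts)
  ap <- apcc(g, nodes = counts$gene)
  region <- assign_region(K_pi, z_g, boundaries)
  hub_class <- classify_hubs(counts$k, ap, hub_min_degree, party_threshold)
  ct <- data.frame(gene = counts$gene, community = counts$community,
                   k = counts$k, k_in = counts$k_in,
                   P = unname(P), z = unname(z),
                   K_pi = unname(K_pi), z_g = unname(z_g),
                   APCC = unname(ap), region = region,
                   hub = counts$k >= hub_min_degree,
                   hub_class = hub_class,
                   switch = region == "R4" & ap < 0,
                   stringsAsFactors = FALSE, row.names = NULL)
  class(ct) <- c("cartography_table", "data.frame")
  attr(ct, "isolated") <- isolated
  attr(ct, "hub_min_degree") <- hub_min_degree
  attr(ct, "party_threshold") <- party_threshold
  ct
}

#' Call switch genes from a cartography table
#'
#' A switch gene sits in region R4 of the heat cartography (strongly
#' outward-oriented, not a local hub) and is on average anti-correlated
#' with its network neighbours (`APCC < 0`).
#'
#' @param ct A `cartography_table`.
#' @param g Optional graph (as used to build `ct`); when supplied, the
#'   nearest-neighbour gene set of each switch gene is returned too.
#' @return A list with `genes` (character vector) and `neighbors` (named
#'   list of character vectors; empty when `g` is missing). An empty call
#'   set is a valid result.
#' @export
find_switch_genes <- function(ct, g = NULL) {
  stopifnot(inherits(ct, "cartography_table"))
  genes <- ct$gene[ct$switch]
  neighbors <- list()
  if (!is.null(g) && length(genes)) {
    neighbors <- lapply(genes, function(gn)
      igraph::V(g)$name[as.integer(igraph::neighbors(g, gn))])
    names(neighbors) <- genes
  }
  list(genes = genes, neighbors = neighbors)
}

#' Write a cartography table and its switch-gene outputs
#' @param ct A `cartography_table`.
#' @param path Output TSV path for the full table.
#' @param switch_path,neighbor_path Optional paths for the switch-gene
#'   list and the switch-gene neighbour sets (gene followed by tab-joined
#'   neighbours); `neighbor_path` requires `g`.
#' @param g Optional graph for neighbour extraction.
#' @return `path`, invisibly.
#' @export
write_cartography <- function(ct, path, switch_path = NULL,
                              neighbor_path = NULL, g = NULL) {
  utils::write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sw <- find_switch_genes(ct, g)
  if (!is.null(switch_path))
    writeLines(sw$genes, switch_path)
  if (!is.null(neighbor_path)) {
    if (is.null(g)) stop("`neighbor_path` requires the graph `g`")
    lines <- vapply(names(sw$neighbors), function(gn)
      paste(c(gn, sw$neighbors[[gn]]), collapse = "\t"), character(1L))
    writeLines(lines, neighbor_path)
  }
  invisible(path)
}
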
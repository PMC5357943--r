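#' Average shortest path over connected node pairs
#'
#' Mean of the shortest-path lengths (edge counts) over all unordered node
#' pairs that are connected; disconnected pairs are excluded from the mean.
#' This connected-pairs convention keeps the statistic defined while a
#' fragmenting network still contains reachable pairs.
#'
#' @param g An igraph graph with at least 2 nodes.
#' @return A single number `>= 1`, or `NA` when no connected pair remains.
#' @export
average_shortest_path <- function(g) {
  if (igraph::vcount(g) < 2L) stop("graph needs >= 2 nodes")
  D <- igraph::distances(g, weights = NA)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Average-shortest-path curve under progressive node removal
#'
#' For each fraction `f`, the first `ceiling(f * length(ranked_nodes))`
#' nodes of the ranked list are deleted and the average shortest path of
#' the remaining graph is recomputed.
#'
#' @param g An igraph graph.
#' @param ranked_nodes Ordered character vector of node names to remove
#'   (must all be graph nodes).
#' @param fractions Increasing fractions in `[0, 1]` of the ranked list to
#'   remove.
#' @return A data.frame with `fraction`, `n_removed`, `asp`.
#' @export
removal_curve <- function(g, ranked_nodes, fractions) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  miss <- setdiff(ranked_nodes, igraph::V(g)$name)
  if (length(miss)) stop("ranked node(s) not in graph: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  rows <- lapply(fractions, function(f) {
    n_rm <- ceiling(f * length(ranked_nodes))
    h <- if (n_rm > 0L) igraph::delete_vertices(g, ranked_nodes[seq_len(n_rm)]) else g
    data.frame(fraction = f, n_removed = n_rm,
               asp = average_shortest_path(h))
  })
  do.call(rbind, rows)
}

#' Compare targeted hub-removal strategies against matched random removal
#'
#' For every hub category present in the cartography table (`date`,
#' `party`, `fight-club`, plus `switch` and `non-switch-hub`), nodes are
#' removed in descending degree order (ties broken by gene id) and the
#' average shortest path is tracked along `fractions` of the category. A
#' count-matched random baseline is computed per category: at each
#' fraction, the same number of uniformly drawn nodes is removed, averaged
#' over `n_random_reps` replicates. Empty categories are omitted with a
#' warning.
#'
#' @param g Graph from [build_graph()].
#' @param ct A `cartography_table` computed on `g`.
#' @param fractions Increasing removal fractions in `[0, 1]`.
#' @param n_random_reps Random replicates for the baseline (default 20).
#' @param seed Integer seed for the random baseline.
#' @return A data.frame with `strategy`, `fraction`, `n_removed`, `asp`,
#'   `asp_random` (matched random mean). The intact-graph value is
#'   attached as attribute `"asp0"`.
#' @export
compare_strategies <- function(g, ct, fractions = seq(0.05, 0.5, by = 0.05),
                               n_random_reps = 20L, seed = 1L) {
  stopifnot(inherits(ct, "cartography_table"))
  categories <- list(
    "date" = ct$gene[ct$hub_class == "date"],
    "party" = ct$gene[ct$hub_class == "party"],
    "fight-club" = ct$gene[ct$hub_class == "fight-club"],
    "switch" = ct$gene[ct$switch],
    "non-switch-hub" = ct$gene[ct$hub & !ct$switch])
  all_nodes <- igraph::V(g)$name
  out <- list()
  with_seed(seed, {
    for (nm in names(categories)) {
      members <- categories[[nm]]
      if (!length(members)) {
        warning("strategy '", nm, "' omitted: no member nodes")
        next
      }
      deg <- ct$k[match(members, ct$gene)]
      ranked <- members[order(-deg, members)]
      curve <- removal_curve(g, ranked, fractions)
      rand <- matrix(NA_real_, n_random_reps, length(fractions))
      for (rep in seq_len(n_random_reps)) {
        rand_nodes <- sample(all_nodes, length(ranked))
        rand[rep, ] <- removal_curve(g, rand_nodes, fractions)$asp
      }
      curve$asp_random <- colMeans(rand, na.rm = TRUE)
      curve <- cbind(strategy = nm, curve, stringsAsFactors = FALSE)
      out[[nm]] <- curve
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "asp0") <- average_shortest_path(g)
  res
}
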
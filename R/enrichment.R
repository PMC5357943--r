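#' Build an annotation catalog from term gene sets
#'
#' Term gene sets are restricted to the universe; terms left empty after
#' restriction are dropped.
#'
#' @param terms Named list of character vectors (term id -> gene set).
#' @param universe Character vector: the tested gene population
#'   (typically all genes surviving expression filtering).
#' @param term_names Optional named character vector of human-readable
#'   term names.
#' @return A list of class `annotation_catalog` with `terms`, `universe`,
#'   `term_names`.
#' @export
annotation_catalog <- function(terms, universe, term_names = NULL) {
  if (!length(terms) || is.null(names(terms)))
    stop("`terms` must be a non-empty named list")
  universe <- unique(universe)
  restricted <- lapply(terms, function(s) intersect(unique(s), universe))
  keep <- lengths(restricted) > 0L
  if (!any(keep)) stop("no term overlaps the universe")
  restricted <- restricted[keep]
  if (is.null(term_names)) term_names <- stats::setNames(names(restricted),
                                                         names(restricted))
  structure(list(terms = restricted, universe = universe,
                 term_names = term_names[names(restricted)]),
            class = "annotation_catalog")
}

#' Read GMT-format term sets
#'
#' One term per line: term id, description, then member genes, all
#' tab-separated.
#'
#' @param path Path to a GMT file.
#' @return A list with `terms` (named list of gene sets) and `term_names`
#'   (named character vector of descriptions).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1L)) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) stop("duplicated term ids in GMT file")
  list(terms = stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids),
       term_names = stats::setNames(vapply(parts, `[[`, character(1L), 2L), ids))
}

#' Fisher over-representation test over an annotation catalog
#'
#' For each term the one-sided Fisher exact p-value of the 2x2 table
#' (query-in-term, query-outside-term, term-outside-query, rest of the
#' universe) is the hypergeometric upper tail
#' `P(X >= overlap)`; q-values are Benjamini-Hochberg adjusted and a term
#' is significant when `q <= alpha`. Query genes outside the universe are
#' dropped with a warning.
#'
#' @param query Character vector of genes to test.
#' @param catalog An [annotation_catalog()].
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return A data.frame sorted by p with columns `term`, `term_name`,
#'   `n_term`, `overlap`, `odds_ratio`, `p`, `q`, `significant`.
#' @export
fisher_enrichment <- function(query, catalog, alpha = 0.05) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  query <- unique(query)
  outside <- setdiff(query, catalog$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (!length(query)) stop("query is empty after restriction to the universe")
  N <- length(catalog$universe)
  nq <- length(query)
  rows <- lapply(names(catalog$terms), function(term) {
    set <- catalog$terms[[term]]
    K <- length(set)
    a <- length(intersect(query, set))       # query in term
    b <- nq - a                              # query outside term
    c_ <- K - a                              # term outside query
    d <- N - K - b                           # neither
    p <- hyper_upper_tail(a, K, N - K, nq)
    or <- if (b == 0L || c_ == 0L) Inf else (a * d) / (b * c_)
    data.frame(term = term, term_name = unname(catalog$term_names[term]),
               n_term = K, overlap = a, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q <= alpha
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  res
}

# One-sided Fisher exact p for over-representation: P(X >= a) with
# X ~ Hypergeometric(white = K, black = M, drawn = n).
hyper_upper_tail <- function(a, K, M, n) {
  if (a <= 0L) return(1)
  hyper_upper_tail_vec(a, K, M, n)
}

# vectorized over `a` (phyper at a - 1 gives the inclusive upper tail)
hyper_upper_tail_vec <- function(a, K, M, n) {
  stats::phyper(a - 1, K, M, n, lower.tail = FALSE)
}
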
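#' Assemble and validate a pipeline configuration
#'
#' Captures every tunable of the analysis in one serializable object; the
#' fully resolved configuration is written next to the results of each
#' run.
#'
#' @param expression Path to the expression matrix (TSV/CSV), or an
#'   `expr_set` supplied directly.
#' @param sample_sheet Optional path to the sample annotation table.
#' @param clinical Optional path to the clinical table (or a data.frame);
#'   enables the survival stage.
#' @param out_dir Output directory (created if absent).
#' @param min_value,min_fraction Expression filter (see
#'   [filter_low_expression()]); `min_value = 0` disables it.
#' @param log2fc_threshold,eps Differential selection (see
#'   [select_differential()]); the DE stage runs only when a condition
#'   annotation is available.
#' @param cutoff Correlation cutoff for [build_graph()] (default 0.8).
#' @param k Number of communities, or `NULL` to pick it from `k_range`
#'   with [choose_k()].
#' @param k_range Candidate k interval used when `k` is `NULL`
#'   (default 2:8).
#' @param hub_min_degree,party_threshold,boundaries Cartography settings.
#' @param run_robustness Compute removal curves (default `TRUE`).
#' @param fractions,n_random_reps Robustness settings.
#' @param seed Integer seed governing clustering and random removal.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, sample_sheet = NULL, clinical = NULL,
                            out_dir = "switchnet_run",
                            min_value = 0, min_fraction = 0.5,
                            log2fc_threshold = 1, eps = 0.05,
                            cutoff = 0.8, k = NULL, k_range = 2:8,
                            hub_min_degree = 5L, party_threshold = 0.5,
                            boundaries = region_boundaries(),
                            run_robustness = TRUE,
                            fractions = seq(0.05, 0.25, by = 0.05),
                            n_random_reps = 20L, seed) {
  if (missing(expression) || is.null(expression))
    stop("config lacks an expression matrix (path or expr_set)")
  if (is.character(expression) && !file.exists(expression))
    stop("expression file not found: ", expression)
  if (missing(seed)) stop("config needs an explicit `seed`")
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must lie in (0, 1)")
  structure(list(expression = expression, sample_sheet = sample_sheet,
                 clinical = clinical, out_dir = out_dir,
                 min_value = min_value, min_fraction = min_fraction,
                 log2fc_threshold = log2fc_threshold, eps = eps,
                 cutoff = cutoff, k = k, k_range = k_range,
                 hub_min_degree = hub_min_degree,
                 party_threshold = party_threshold,
                 boundaries = boundaries,
                 run_robustness = run_robustness,
                 fractions = fractions, n_random_reps = n_random_reps,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full switch-gene pipeline
#'
#' Executes filter -> differential selection -> correlation network ->
#' community detection -> cartography -> switch calling, optionally
#' followed by robustness curves and survival prioritization of the
#' called switch genes. All tables are written as TSV under the
#' configured output directory together with a JSON report (stage counts,
#' parameters, seed).
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly; its elements mirror
#'   `report.json` and the heavyweight intermediates are attached in the
#'   `objects` element (`em`, `graph`, `clusters`, `cartography`,
#'   `switch`, `robustness`, `survival_ranking`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())

  em <- if (inherits(config$expression, "expr_set")) config$expression
    else read_expression(config$expression, sample_sheet = config$sample_sheet)
  report$stages$input <- list(n_genes = n_genes(em), n_samples = n_samples(em))

  if (config$min_value > 0) {
    em <- filter_low_expression(em, config$min_value, config$min_fraction)
    report$stages$filter <- list(n_genes = n_genes(em))
  }

  if (!is.null(em$condition)) {
    de <- select_differential(em, config$log2fc_threshold, config$eps)
    utils::write.table(de, file.path(config$out_dir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    selected <- de$gene[de$selected]
    if (length(selected) < 3L)
      stop("stage differential: fewer than 3 genes selected; lower the threshold")
    net_em <- subset_expression(em, genes = selected,
                                samples = colnames(em$values)[em$condition == "tumor"])
    report$stages$differential <- list(n_selected = length(selected))
  } else {
    net_em <- em
  }

  corr <- pearson_matrix(net_em)
  graph <- build_graph(corr, config$cutoff)
  report$stages$network <- list(n_nodes = igraph::vcount(graph),
                                n_edges = igraph::ecount(graph),
                                cutoff = config$cutoff)
  write_edge_list(graph, file.path(config$out_dir, "edges.tsv"))

  k <- config$k
  if (is.null(k)) k <- as.integer(choose_k(net_em, config$k_range,
                                           seed = config$seed))
  clusters <- cluster_expression(net_em, k, seed = config$seed)
  utils::write.table(
    data.frame(gene = names(clusters$membership),
               community = unname(clusters$membership)),
    file.path(config$out_dir, "communities.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$community <- list(k = clusters$k, quality = clusters$quality)

  ct <- suppressWarnings(
    cartography_table(graph, clusters,
                      hub_min_degree = config$hub_min_degree,
                      party_threshold = config$party_threshold,
                      boundaries = config$boundaries))
  sw <- find_switch_genes(ct, graph)
  write_cartography(ct, file.path(config$out_dir, "cartography.tsv"),
                    switch_path = file.path(config$out_dir, "switch_genes.tsv"),
                    neighbor_path = file.path(config$out_dir,
                                              "switch_neighbors.tsv"),
                    g = graph)
  report$stages$cartography <- list(
    n_nodes = nrow(ct),
    n_hubs = sum(ct$hub),
    hub_classes = as.list(table(ct$hub_class[ct$hub_class != "none"])),
    n_switch = length(sw$genes))

  robustness <- NULL
  if (isTRUE(config$run_robustness)) {
    robustness <- suppressWarnings(
      compare_strategies(graph, ct, fractions = config$fractions,
                         n_random_reps = config$n_random_reps,
                         seed = config$seed))
    utils::write.table(robustness,
                       file.path(config$out_dir, "robustness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$robustness <- list(asp_intact = attr(robustness, "asp0"),
                                     strategies = unique(robustness$strategy))
  }

  ranking <- NULL
  if (!is.null(config$clinical) && length(sw$genes)) {
    clinical <- if (is.character(config$clinical)) read_clinical(config$clinical)
      else validate_clinical(config$clinical)
    ranking <- rank_switch_genes_by_survival(em, clinical, sw$genes)
    utils::write.table(ranking,
                       file.path(config$out_dir, "survival_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$survival <- list(n_ranked = nrow(ranking),
                                   n_skipped = length(attr(ranking, "skipped")))
  }

  report$config <- config_as_list(config)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$objects <- list(em = em, graph = graph, clusters = clusters,
                         cartography = ct, switch = sw,
                         robustness = robustness,
                         survival_ranking = ranking)
  invisible(report)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$expression <- if (is.character(out$expression)) out$expression
    else "<in-memory expr_set>"
  out$clinical <- if (is.character(out$clinical) || is.null(out$clinical))
    out$clinical else "<in-memory table>"
  out
}
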
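# Small fixtures shared across test files; everything is built in code.

# genes x samples matrix with names
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = length(values) / 4, byrow = TRUE)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# expr_set with two anti-correlated groups plus an uncorrelated gene
toy_expression <- function() {
  base <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(g1 = 20 + base, g2 = 20 + 2 * base, g3 = 20 - base,
             g4 = 20 - 2 * base, g5 = 20 + c(1, -1, 2, -2, 3, -3))
  colnames(m) <- paste0("s", 1:6)
  expression_matrix(m)
}

# deterministic paired tumor/normal fixture
toy_paired <- function(n_genes = 6L, n_patients = 4L, log2fc = 2,
                       de = c("gA"), seed = 11L) {
  set.seed(seed)
  vals <- matrix(runif(n_genes * n_patients, 5, 15), n_genes, n_patients)
  rownames(vals) <- c("gA", paste0("g", seq_len(n_genes - 1L)))
  colnames(vals) <- paste0("P", seq_len(n_patients))
  base <- expression_matrix(vals)
  generate_paired_tumor_normal(base, de_genes = de, log2fc = log2fc,
                               seed = seed)
}

# correlation matrix with two perfect blocks, zero between blocks
block_corr <- function(sizes = c(3L, 2L)) {
  n <- sum(sizes)
  corr <- matrix(0, n, n)
  start <- 1L
  for (s in sizes) {
    idx <- start:(start + s - 1L)
    corr[idx, idx] <- 1
    start <- start + s
  }
  diag(corr) <- 1
  dimnames(corr) <- list(paste0("g", 1:n), paste0("g", 1:n))
  corr
}

# the planted-switch study conditions
planted_sim <- function(seed) {
  generate_modular_expression(n_modules = 4L, genes_per_module = 50L,
                              n_samples = 100L, intra_corr = 0.8,
                              n_switch = 10L, switch_strength = 0.8,
                              noise_sd = 0.3, seed = seed)
}

planted_cartography <- function(seed) {
  sim <- planted_sim(seed)
  corr <- pearson_matrix(sim$em)
  g <- build_graph(corr, 0.6)
  cl <- cluster_expression(sim$em, k = 4L, seed = seed)
  ct <- suppressWarnings(cartography_table(g, cl))
  list(sim = sim, g = g, ct = ct)
}
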
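# build a signed graph from an explicit edge list through the package's
# constructor (correlation matrix -> threshold)
graph_from_edges <- function(edges, nodes) {
  corr <- diag(length(nodes))
  dimnames(corr) <- list(nodes, nodes)
  for (i in seq_len(nrow(edges))) {
    corr[edges$a[i], edges$b[i]] <- edges$w[i]
    corr[edges$b[i], edges$a[i]] <- edges$w[i]
  }
  build_graph(corr, 0.5)
}

test_that("community link counts agree with direct edge enumeration", {
  fx <- random_weighted_graph(22, 0.3, seed = 41)
  mem <- random_membership(fx$nodes, 4L, seed = 42)
  counts <- community_link_counts(fx$g, mem)
  oracle <- oracle_cartography(fx$nodes, fx$edges, mem)
  expect_equal(setNames(counts$k, counts$gene), oracle$k)
  expect_equal(setNames(counts$k_in, counts$gene), oracle$k_in)
  expect_equal(unname(counts$k_s), unname(oracle$k_s))
  # row sums of k_s reproduce k
  expect_equal(rowSums(counts$k_s), as.numeric(counts$k),
               ignore_attr = TRUE)

  mem_missing <- mem[-1]
  expect_error(community_link_counts(fx$g, mem_missing), "without a community")
})

test_that("participation coefficient follows its defining arithmetic", {
  # all links internal -> P = 0
  expect_equal(unname(participation_coefficient(matrix(c(4, 0), 1))), 0)
  # k = 20 spread uniformly over 5 modules -> P = 0.8, the N = 5 supremum
  expect_equal(unname(participation_coefficient(matrix(rep(4, 5), 1))), 0.8)
  # k = 10 split (6, 4) -> 1 - (0.36 + 0.16)
  expect_equal(unname(participation_coefficient(matrix(c(6, 4), 1))), 0.48)
})

test_that("clusterphobic coefficient hits its documented extremes", {
  nodes <- paste0("n", 1:6)
  edges <- data.frame(a = c("n1", "n1", "n1", "n2"),
                      b = c("n2", "n3", "n4", "n3"),
                      w = 0.9, stringsAsFactors = FALSE)
  g <- graph_from_edges(edges, nodes)
  mem <- setNames(c(1L, 1L, 1L, 1L, 2L, 2L), nodes)
  counts <- community_link_counts(g, mem)
  kpi <- suppressWarnings(clusterphobic_coefficient(counts))
  expect_equal(unname(kpi["n1"]), 0)       # all links internal

  # k = 10 with k_in = 0 -> K_pi = 1; k_in = 5 -> 0.75
  fake <- structure(list(gene = c("x", "y"), community = c(1L, 1L),
                         k = c(10L, 10L), k_in = c(0L, 5L),
                         k_s = rbind(c(0, 10), c(5, 5))),
                    class = "link_counts")
  expect_equal(unname(clusterphobic_coefficient(fake)), c(1, 0.75))
})

test_that("z and z_g match hand-computed module statistics", {
  # community A with internal degrees (1, 1, 2, 3, 3); community B separate
  nodes <- c(paste0("a", 1:5), "b1", "b2")
  edges <- data.frame(
    a = c("a1", "a2", "a3", "a3", "a4", "b1", "a4"),
    b = c("a4", "a5", "a4", "a5", "a5", "b2", "b1"),
    w = c(rep(0.9, 6), -0.8), stringsAsFactors = FALSE)
  g <- graph_from_edges(edges, nodes)
  mem <- setNames(c(rep(1L, 5), 2L, 2L), nodes)
  counts <- community_link_counts(g, mem)

  z <- suppressWarnings(within_module_degree(counts))  # community B is degenerate
  kin_A <- c(1, 1, 2, 3, 3)
  expect_equal(unname(z[paste0("a", 1:5)]),
               (kin_A - mean(kin_A)) / sd(kin_A))
  expect_equal(unname(z["a3"]), 0)  # centered node

  zg <- suppressWarnings(global_within_module_degree(counts))
  ktot_A <- c(1, 1, 2, 4, 3)        # a4 carries one external link
  expect_equal(unname(zg[paste0("a", 1:5)]),
               (kin_A - mean(ktot_A)) / sd(ktot_A))
  # a1's internal degree is below every total degree in its module
  expect_lt(zg[["a1"]], 0)

  # degenerate module (identical degrees) yields z = 0 with a warning
  expect_warning(z_all <- within_module_degree(
    community_link_counts(graph_from_edges(
      data.frame(a = "b1", b = "b2", w = 0.9), c("b1", "b2")),
      setNames(c(1L, 1L), c("b1", "b2")))), "degenerate")
  expect_equal(unname(z_all), c(0, 0))
})

test_that("APCC is the mean signed correlation over neighbours", {
  nodes <- paste0("n", 1:4)
  edges <- data.frame(a = c("n1", "n1", "n1"), b = c("n2", "n3", "n4"),
                      w = c(-0.9, -0.8, -0.7), stringsAsFactors = FALSE)
  g <- graph_from_edges(edges, nodes)
  vals <- apcc(g)
  expect_equal(unname(vals["n1"]), -0.8)
  expect_equal(unname(vals["n2"]), -0.9)   # single neighbour: identity

  fx <- random_weighted_graph(24, 0.3, seed = 51)
  oracle <- oracle_cartography(fx$nodes, fx$edges,
                               random_membership(fx$nodes, 2L, seed = 52))
  got <- apcc(fx$g)
  expect_equal(got, oracle$apcc[names(got)], tolerance = 1e-12)
})

test_that("hubs classify into date/party/fight-club by degree and APCC", {
  k <- c(4L, 10L, 10L, 10L, 5L)
  ap <- c(-0.9, -0.3, 0.9, 0.3, 0.5)
  cls <- classify_hubs(k, ap, hub_min_degree = 5L, party_threshold = 0.5)
  expect_identical(cls, c("none", "fight-club", "party", "date", "party"))
})

test_that("regions partition the (K_pi, z_g) plane as documented", {
  expect_identical(assign_region(0.9, 1.0), "R4")
  expect_identical(assign_region(0.0, 0.0), "R1")
  expect_identical(assign_region(0.9, 3.0), "R7")
  expect_identical(assign_region(0.5, 1.0), "R2")
  expect_identical(assign_region(0.7, 0.0), "R3")
  expect_identical(assign_region(0.2, 2.5), "R5")
  expect_identical(assign_region(0.6, 4.0), "R6")
  # boundaries: left-open intervals, bounds belong to the lower region
  expect_identical(assign_region(0.05, 0), "R1")
  expect_identical(assign_region(0.8, 0), "R3")
  expect_identical(assign_region(0.75, 99), "R6")
})

test_that("switch calls require region R4 plus negative APCC", {
  res <- planted_cartography(seed = 77)
  ct <- res$ct
  in_r4_neg <- ct$gene[ct$region == "R4" & ct$APCC < 0]
  expect_setequal(find_switch_genes(ct)$genes, in_r4_neg)
  # R4 with positive APCC, or negative APCC outside R4, is never a switch
  expect_false(any(ct$switch & (ct$region != "R4" | ct$APCC >= 0)))

  sw <- find_switch_genes(ct, res$g)
  expect_identical(names(sw$neighbors), sw$genes)
  nb1 <- sw$neighbors[[1]]
  expect_setequal(nb1, igraph::V(res$g)$name[
    as.integer(igraph::neighbors(res$g, sw$genes[1]))])
})

test_that("P never exceeds K_pi and matches the decomposition", {
  for (seed in 1:5) {
    fx <- random_weighted_graph(20, 0.35, seed = 60 + seed)
    mem <- random_membership(fx$nodes, 3L, seed = 70 + seed)
    counts <- community_link_counts(fx$g, mem)
    keep <- counts$k > 0
    P <- suppressWarnings(participation_coefficient(counts))
    K <- suppressWarnings(clusterphobic_coefficient(counts))
    expect_true(all(P <= K + 1e-12))
    # P = K_pi - sum over foreign modules of (k_s/k)^2
    foreign <- vapply(which(keep), function(i) {
      ks <- counts$k_s[i, ]
      ks[counts$community[i]] <- 0
      sum((ks / counts$k[i])^2)
    }, numeric(1))
    expect_equal(unname(P), unname(K - foreign), tolerance = 1e-12)
  }
})

test_that("cartography_table drops isolated nodes but reports them", {
  corr <- block_corr(c(3L, 2L))
  corr["g4", "g5"] <- corr["g5", "g4"] <- 0  # isolate nothing yet
  corr["g4", "g1"] <- corr["g1", "g4"] <- 0.9
  g <- build_graph(corr, 0.8)
  mem <- setNames(c(1L, 1L, 1L, 1L, 2L), paste0("g", 1:5))
  expect_warning(ct <- cartography_table(g, mem), "isolated")
  expect_identical(attr(ct, "isolated"), "g5")
  expect_false("g5" %in% ct$gene)
})
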
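toy_lists <- function() {
  list(ds1 = c("a", "b", "c"),
       ds2 = c("b", "c", "d"),
       ds3 = c("e", "c"))
}

test_that("membership matrix encodes the union of gene sets", {
  m <- build_membership_matrix(toy_lists())
  expect_identical(rownames(m), c("a", "b", "c", "d", "e"))  # lexicographic
  hand <- rbind(a = c(1L, 0L, 0L), b = c(1L, 1L, 0L), c = c(1L, 1L, 1L),
                d = c(0L, 1L, 0L), e = c(0L, 0L, 1L))
  colnames(hand) <- c("ds1", "ds2", "ds3")
  expect_equal(m, hand)
  expect_true(all(rowSums(m) >= 1L))

  same <- build_membership_matrix(list(x = c("a", "b"), y = c("a", "b")))
  expect_true(all(same == 1L))
  disj <- build_membership_matrix(list(x = "a", y = "b"))
  expect_equal(unname(rowSums(disj)), c(1, 1))

  expect_error(build_membership_matrix(list()), "empty")
  expect_error(build_membership_matrix(list(only = "a")), ">= 2")

  # column sets are exactly recoverable
  for (ds in names(toy_lists()))
    expect_setequal(rownames(m)[m[, ds] == 1L], toy_lists()[[ds]])
})

test_that("Hamming distances match a per-row XOR oracle and the metric axioms", {
  m <- build_membership_matrix(toy_lists())
  d <- hamming_distance_matrix(m, normalize = FALSE)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(d[i, j], sum(xor(m[, i] == 1L, m[, j] == 1L)))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))

  dn <- hamming_distance_matrix(m, normalize = TRUE)
  expect_equal(dn, d / nrow(m))

  # identical and complementary columns
  mm <- cbind(a = c(1L, 0L, 1L), b = c(1L, 0L, 1L), c = c(0L, 1L, 0L))
  dd <- hamming_distance_matrix(mm, normalize = FALSE)
  expect_equal(dd["a", "b"], 0)
  expect_equal(dd["a", "c"], 3)

  # metric axioms on random binary matrices
  set.seed(10)
  for (rep in 1:20) {
    r <- matrix(rbinom(40, 1L, 0.5), 8, 5,
                dimnames = list(NULL, paste0("d", 1:5)))
    h <- hamming_distance_matrix(r, normalize = sample(c(TRUE, FALSE), 1))
    expect_equal(h, t(h))
    expect_true(all(diag(h) == 0))
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(h[i, j], h[i, k] + h[k, j] + 1e-12)
  }
})

test_that("average-linkage clustering reproduces hand-computed merge heights", {
  # 4 datasets with a hand-agglomerable distance structure:
  # d(A,B)=1, d(C,D)=2; cross distances A/B to C/D all >= 6
  d <- matrix(c(0, 1, 6, 8,
                1, 0, 7, 9,
                6, 7, 0, 2,
                8, 9, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  cl <- cluster_datasets(d, linkage = "average")
  # merges: {A,B} at 1, {C,D} at 2, then average of (6,8,7,9) = 7.5
  expect_equal(cl$merge_heights, c(1, 2, 7.5))
  expect_setequal(cl$leaf_order[1:2], c("A", "B"))

  # two datasets merge once at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(cluster_datasets(d2)$merge_heights, 0.4)

  # a zero-distance pair merges first
  d3 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3,
               dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  cl3 <- cluster_datasets(d3)
  expect_equal(cl3$merge_heights[1], 0)

  # Newick export round-trips through ape
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, LETTERS[1:4])
})

test_that("shared_genes enumerates every Venn cell", {
  lists <- list(w = c("a", "b", "c", "x"), x = c("b", "c", "y"),
                y = c("c", "z", "b"), z = c("c", "q"))
  res <- shared_genes(lists, c("w", "x", "y", "z"))
  expect_identical(res$shared, "c")
  expect_equal(res$n_shared, 1L)
  expect_equal(sum(res$cells$count),
               length(unique(unlist(lists))))
  # brute-force every membership pattern
  genes <- sort(unique(unlist(lists)))
  for (gene in genes) {
    pattern <- paste(names(lists)[vapply(lists, function(s) gene %in% s,
                                         logical(1))], collapse = "&")
    expect_equal(res$cells$count[res$cells$pattern == pattern] >= 1, TRUE,
                 info = gene)
  }
  # identical sets: full intersection, empty exclusive cells
  res2 <- shared_genes(list(p = c("a", "b"), q = c("a", "b")), c("p", "q"))
  expect_equal(res2$n_shared, 2L)
  expect_equal(res2$cells$count[res2$cells$pattern %in% c("p", "q")], c(0L, 0L))
  # disjoint sets: empty intersection
  res3 <- shared_genes(list(p = "a", q = "b"), c("p", "q"))
  expect_equal(res3$n_shared, 0L)

  expect_error(shared_genes(lists, c("w", "nope")), "unknown dataset")
  expect_error(shared_genes(lists, "w"), "between 2 and 5")
})

test_that("neighbour-set comparison runs the same binary pipeline", {
  maps <- list(
    ds1 = list(sw1 = c("n1", "n2"), sw2 = c("n2", "n3")),
    ds2 = list(swA = c("n2", "n3", "n4")),
    ds3 = list(swB = c("n9")))
  res <- compare_neighbor_sets(maps, normalize = FALSE)
  expect_setequal(rownames(res$membership), c("n1", "n2", "n3", "n4", "n9"))
  expect_equal(res$membership["n2", ], c(ds1 = 1L, ds2 = 1L, ds3 = 0L))
  expect_equal(res$dist["ds1", "ds2"],
               sum(res$membership[, "ds1"] != res$membership[, "ds2"]))
  expect_s3_class(res$clustering$tree, "hclust")
  expect_error(compare_neighbor_sets(maps["ds1"]), ">= 2")
})
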
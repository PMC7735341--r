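sim_from_dist <- function(d, labels) {
  m <- 1 - as.matrix(d)
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  m
}

test_that("linkage clustering merges the most similar pair first", {
  sim <- matrix(c(1, 1, .2,
                  1, 1, .2,
                  .2, .2, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- linkage_cluster(sim)
  expect_equal(hc$height[1], 0)
  expect_setequal(edge_leaf_sets(hc)[[1]], c("a", "b"))

  # block structure resolves into the two 2-leaf clades
  sim4 <- matrix(.1, 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  sim4[1, 2] <- sim4[2, 1] <- .9
  sim4[3, 4] <- sim4[4, 3] <- .9
  diag(sim4) <- 1
  hc4 <- linkage_cluster(sim4)
  sets <- lapply(edge_leaf_sets(hc4)[1:2], sort)
  expect_true(setequal(sets[[1]], c("a", "b")) ||
                setequal(sets[[1]], c("c", "d")))
  expect_true(setequal(sets[[2]], c("a", "b")) ||
                setequal(sets[[2]], c("c", "d")))
  expect_false(setequal(sets[[1]], sets[[2]]))

  bad <- sim4
  bad[1, 2] <- 2
  expect_error(linkage_cluster(bad), "\\[0, 1\\]")
  nonsym <- sim4
  nonsym[1, 2] <- .5
  expect_error(linkage_cluster(nonsym), "symmetric")
})

test_that("single linkage chains where average linkage does not", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- .20
  d["b", "c"] <- d["c", "b"] <- .22
  d["c", "d"] <- d["d", "c"] <- .30
  d["a", "c"] <- d["c", "a"] <- .50
  d["b", "d"] <- d["d", "b"] <- .50
  d["a", "d"] <- d["d", "a"] <- .90
  sim <- 1 - d
  diag(sim) <- 1
  single <- stats::cutree(linkage_cluster(sim, "single"), k = 2)
  avg <- stats::cutree(linkage_cluster(sim, "average"), k = 2)
  expect_identical(unname(single), c(1L, 1L, 1L, 2L))   # chained
  expect_identical(unname(avg[c("a", "b")]), unname(avg[c("b", "a")]))
  expect_true(avg[["a"]] == avg[["b"]] && avg[["c"]] == avg[["d"]] &&
                avg[["a"]] != avg[["c"]])
})

test_that("cophenetic correlation is 1 for ultrametric input and label-invariant", {
  d <- matrix(.8, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- .2
  d["c", "d"] <- d["d", "c"] <- .3
  diag(d) <- 0
  sim <- 1 - d
  diag(sim) <- 1
  hc <- linkage_cluster(sim)
  expect_equal(cophenetic_correlation(hc, sim), 1.0)

  set.seed(13)
  strs <- replicate(6, random_seq(sample(3:6, 1), letters[1:5]),
                    simplify = FALSE)
  names(strs) <- paste0("s", 1:6)
  m <- similarity_matrix(strs)
  cc <- cophenetic_correlation(linkage_cluster(m), m)
  perm <- sample(6)
  mp <- m[perm, perm]
  expect_equal(cophenetic_correlation(linkage_cluster(mp), mp), cc)

  other <- m
  rownames(other) <- colnames(other) <- paste0("t", 1:6)
  expect_error(cophenetic_correlation(linkage_cluster(m), other),
               "mismatch")
})

test_that("average-linkage heights are monotone on random LSI matrices", {
  set.seed(29)
  for (k in 1:20) {
    strs <- replicate(sample(4:9, 1),
                      random_seq(sample(2:7, 1), letters[1:4]),
                      simplify = FALSE)
    m <- similarity_matrix(strs)
    hc <- linkage_cluster(m)
    expect_true(all(diff(hc$height) >= -1e-8))
  }
})

test_that("weighted and unweighted average linkage agree on balanced clusters", {
  sim <- matrix(.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  sim[1, 2] <- sim[2, 1] <- .9
  sim[3, 4] <- sim[4, 3] <- .9
  diag(sim) <- 1
  u <- linkage_cluster(sim, "average")
  w <- linkage_cluster(sim, "weighted_average")
  expect_equal(u$height, w$height)
  expect_identical(u$merge, w$merge)
})

test_that("default bootstrap scales are log-spaced and include 1", {
  sc <- bootstrap_scales()
  expect_length(sc, 10)
  expect_true(any(sc == 1))
  expect_equal(min(sc), 1 / 1.4, tolerance = 1e-12)
  expect_equal(max(sc), 1.4, tolerance = 1e-12)
})

test_that("fully separated identical groups get BP = AU = 1 on true edges", {
  groups <- list(g1 = rep("A B C", 4), g2 = rep("A B C", 4),
                 g3 = rep("X Y Z W", 4), g4 = rep("X Y Z W", 4))
  bs <- bootstrap_support(groups, "median", B = 50, seed = 1)
  prof <- attr(bs, "bp_profile")
  expect_true(all(prof == 1))   # resampling cannot change the matrix
  expect_true(all(bs$au == 1))
  expect_true(all(bs$bp == 1))
})

test_that("with a single unit scale the AU degrades to the plain BP", {
  set.seed(2)
  groups <- lapply(1:4, function(i) {
    replicate(4, random_seq(4, letters[1:5]), simplify = FALSE)
  })
  names(groups) <- paste0("g", 1:4)
  bs <- bootstrap_support(groups, "median", B = 60, scales = 1, seed = 7)
  expect_equal(bs$au, bs$bp)
  expect_true(all(bs$bp >= 0 & bs$bp <= 1))
})

test_that("bootstrap support is reproducible for a fixed master seed", {
  groups <- list(g1 = c("A B C", "A B", "A B C"),
                 g2 = c("D E F", "D F", "D E F"),
                 g3 = c("G H", "G H I", "G H"))
  b1 <- bootstrap_support(groups, "median", B = 40, seed = 123)
  b2 <- bootstrap_support(groups, "median", B = 40, seed = 123)
  expect_identical(b1$au, b2$au)
  expect_identical(attr(b1, "bp_profile"), attr(b2, "bp_profile"))
  b3 <- bootstrap_support(groups, "full", B = 40, seed = 123)
  expect_identical(nrow(b3), nrow(b1))
})

test_that("the AU fit handles boundary and degenerate profiles", {
  au_fit <- songculture:::au_fit
  sc <- c(0.7, 1, 1.4)
  expect_equal(au_fit(c(1, 1, 1), sc, 100)$au, 1)
  expect_equal(au_fit(c(0, 0, 0), sc, 100)$au, 0)
  deg <- au_fit(c(1, 1, 0.99), sc, 100)
  expect_true(deg$degenerate)
  expect_equal(deg$au, 1)      # falls back to BP at r = 1
  ok <- au_fit(c(0.6, 0.8, 0.9), sc, 100)
  expect_false(ok$degenerate)
  expect_true(ok$au >= 0 && ok$au <= 1)
})

test_that("partition support finds ground-truth splits or reports absence", {
  groups <- list(g1 = rep("A B C", 3), g2 = rep("A B C", 3),
                 g3 = rep("X Y Z", 3), g4 = rep("X Y Z", 3))
  bs <- bootstrap_support(groups, "median", B = 30, seed = 5)
  hit <- partition_support(bs, c("g1", "g2"))
  expect_true(hit$found)
  expect_equal(hit$au, 1)
  miss <- partition_support(bs, c("g1", "g3"))
  expect_false(miss$found)
  expect_equal(miss$au, 0)
})

test_that("newick export carries AU values as internal node labels", {
  groups <- list(g1 = rep("A B C", 3), g2 = rep("A B C", 3),
                 g3 = rep("X Y Z", 3), g4 = rep("X Y Z", 3))
  bs <- bootstrap_support(groups, "median", B = 30, seed = 5)
  path <- tempfile(fileext = ".nwk")
  write_newick(attr(bs, "dendrogram"), path, support = bs)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, names(groups))
  expect_true(any(phy$node.label == "1"))
})
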
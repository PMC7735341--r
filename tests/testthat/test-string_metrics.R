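test_that("levenshtein matches hand-checked edit counts and basic identities", {
  s <- c("A", "B", "C")
  expect_identical(levenshtein(s, s), 0L)
  expect_identical(levenshtein(character(0), c("U1", "U2", "U3", "U4")), 4L)
  expect_identical(levenshtein(c("U1", "U2", "U3", "U4"), c("U1", "U3", "U4")),
                   1L)
  expect_identical(levenshtein(c("U1", "U2"), c("U3", "U4")),
                   levenshtein(c("U3", "U4"), c("U1", "U2")))
  expect_identical(levenshtein(character(0), character(0)), 0L)
})

test_that("lsi normalises by the longer sequence and bounds hold", {
  expect_equal(lsi(c("A", "B", "C"), c("A", "B", "C")), 1.0)
  expect_equal(lsi(c("U1", "U2", "U3"), c("U4", "U5", "U6")), 0.0)
  expect_equal(lsi(c("U1", "U2", "U3", "U4"), c("U1", "U3", "U4")), 0.75)
  expect_error(lsi(character(0), character(0)), "undefined")
  # numeric symbol input (theme IDs) is accepted
  expect_equal(lsi(1:5, 1:5), 1.0)
})

test_that("implementation agrees with the DP oracle exhaustively on short sequences", {
  alphabet <- c("a", "b", "c", "d")
  seqs <- all_seqs(3, alphabet)
  for (i in seq_along(seqs)) {
    for (j in seq(i, length(seqs))) {
      expect_identical(levenshtein(seqs[[i]], seqs[[j]]),
                       lev_oracle(seqs[[i]], seqs[[j]]))
    }
  }
})

test_that("implementation agrees with the DP oracle and adist on random longer pairs", {
  set.seed(404)
  alphabet <- c("a", "b", "c", "d")
  for (k in 1:300) {
    a <- random_seq(sample(0:8, 1), alphabet)
    b <- random_seq(sample(1:8, 1), alphabet)
    d <- levenshtein(a, b)
    expect_identical(d, lev_oracle(a, b))
    # utils::adist as a second, fully independent implementation
    expect_equal(d, as.integer(utils::adist(paste(a, collapse = ""),
                                            paste(b, collapse = ""))))
  }
})

test_that("levenshtein satisfies the triangle inequality", {
  set.seed(11)
  alphabet <- c("w", "x", "y", "z")
  for (k in 1:200) {
    a <- random_seq(sample(0:7, 1), alphabet)
    b <- random_seq(sample(0:7, 1), alphabet)
    cc <- random_seq(sample(0:7, 1), alphabet)
    expect_lte(levenshtein(a, cc),
               levenshtein(a, b) + levenshtein(b, cc))
  }
})

test_that("similarity_matrix is symmetric, unit-diagonal and entrywise equal to lsi", {
  strs <- list(s1 = c("A", "B", "C"), s2 = c("A", "C"),
               s3 = c("D", "E", "F", "G"))
  m <- similarity_matrix(strs)
  expect_identical(rownames(m), names(strs))
  expect_equal(m, t(m))
  expect_equal(diag(m), c(s1 = 1, s2 = 1, s3 = 1))
  for (i in 1:3) {
    for (j in 1:3) {
      if (i != j) expect_equal(m[i, j], lsi(strs[[i]], strs[[j]]))
    }
  }
  m2 <- similarity_matrix(c("A B", "A B"))
  expect_equal(unname(m2), matrix(1, 2, 2))
  expect_error(similarity_matrix(list(a = "X", b = character(0))), "b")
  expect_error(similarity_matrix(list(c("A", "B"))), "at least 2")
})

test_that("median_string maximises summed pairwise LSI with first-index ties", {
  single <- median_string(list(c("A", "B", "C")))
  expect_identical(single$index, 1L)
  expect_identical(single$string, c("A", "B", "C"))
  expect_equal(single$score, 0)
  expect_equal(single$within_set_similarity, 1)

  res <- median_string(c("A B C", "A B C", "A B D"))
  # enumeration: scores are (1 + 2/3, 1 + 2/3, 2/3 + 2/3)
  expect_identical(res$index, 1L)
  expect_identical(res$string, c("A", "B", "C"))
  expect_equal(res$score, 1 + 2 / 3)

  tie <- median_string(c("A", "B"))
  expect_identical(tie$index, 1L)

  expect_error(median_string(list()), "empty")
})

test_that("median_string is stable under duplicating the whole set", {
  set.seed(21)
  alphabet <- c("p", "q", "r", "s")
  for (k in 1:25) {
    strs <- replicate(sample(2:5, 1),
                      random_seq(sample(1:6, 1), alphabet),
                      simplify = FALSE)
    one <- median_string(strs)
    two <- median_string(c(strs, strs))
    expect_identical(two$string, one$string)
  }
})

test_that("within_set_similarity averages the off-diagonal upper triangle", {
  expect_equal(within_set_similarity(c("A B C", "A B C", "A B C")), 1.0)
  expect_equal(within_set_similarity(c("A B C", "D E F")), 0.0)
  strs <- list(c("A", "B", "C"), c("A", "B"), c("C", "B", "A"))
  expected <- mean(c(lsi(strs[[1]], strs[[2]]), lsi(strs[[1]], strs[[3]]),
                     lsi(strs[[2]], strs[[3]])))
  expect_equal(within_set_similarity(strs), expected)
  expect_error(within_set_similarity(c("A B")), "at least 2")
})

test_that("similarity matrix export round-trips through CSV", {
  m <- similarity_matrix(c(a = "A B C", b = "A C", c = "D E"))
  sq <- tempfile(fileext = ".csv")
  lg <- tempfile(fileext = ".csv")
  write_similarity_matrix(m, sq, long_path = lg)
  back <- as.matrix(read.csv(sq, row.names = 1))
  colnames(back) <- rownames(back)
  expect_equal(back, m, tolerance = 1e-12)
  long <- read.csv(lg)
  expect_identical(nrow(long), 3L)
  expect_equal(long$lsi[long$item_i == "a" & long$item_j == "b"],
               m["a", "b"])
})
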
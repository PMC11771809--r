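test_that("two cells give one undirected edge whatever k", {
  g <- build_knn_graph(cbind(c(0, 5), c(0, 0)), k = 5)
  expect_equal(unname(g$edges), cbind(1L, 2L))
})

test_that("collinear points reproduce the all-pairs distance-sort oracle", {
  coords <- cbind(c(0, 1, 3, 7, 15), 0)
  g <- build_knn_graph(coords, k = 2)
  # oracle from first principles
  expect_equal(unname(g$edges), unname(knn_oracle(coords, 2)))
  # hand enumeration: each point picks its two nearest, union symmetrized
  hand <- rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4), c(3, 5), c(4, 5))
  expect_equal(unname(g$edges), hand)
})

test_that("random configurations match the brute-force construction", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    k <- sample(1:4, 1)
    coords <- matrix(runif(2 * n), n, 2)
    g <- build_knn_graph(coords, k)
    expect_equal(unname(g$edges), unname(knn_oracle(coords, k)))
    deg <- tabulate(c(g$edges[, 1], g$edges[, 2]), n)
    expect_true(all(deg >= min(k, n - 1)))
  }
})

test_that("duplicate coordinates are resolved by index tie-break", {
  coords <- rbind(c(0, 0), c(0, 0), c(0, 0), c(9, 9))
  g <- build_knn_graph(coords, k = 1)
  # every zero-distance (and exact-tie) choice resolves to the smallest index
  expect_equal(unname(g$edges), rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
  expect_error(build_knn_graph(cbind(1, 1), k = 1), "at least 2")
})

test_that("split sizes follow the rounding rule and negatives match 1:1", {
  coords <- cbind(c(0, 1, 3, 7, 15, 31, 63, 127), 0)
  g <- build_knn_graph(coords, k = 2)  # chain-like graph
  m <- nrow(g$edges)
  s <- split_edges(g, 0.7, 0.15, seed = 5)
  expect_equal(nrow(s$train_pos), round(0.7 * m))
  expect_equal(nrow(s$val_pos), round(0.15 * m))
  expect_equal(nrow(s$test_pos), m - round(0.7 * m) - round(0.15 * m))
  for (part in c("train", "val", "test")) {
    expect_equal(nrow(s[[paste0(part, "_neg")]]),
                 nrow(s[[paste0(part, "_pos")]]))
  }
})

test_that("split positives reassemble exactly to the edge set", {
  g <- random_graph_case(40, k = 3)
  s <- split_edges(g, 0.7, 0.15, seed = 2)
  reassembled <- rbind(s$train_pos, s$val_pos, s$test_pos)
  key <- function(e) sort((e[, 1] - 1) * g$n + e[, 2])
  expect_equal(key(reassembled), key(g$edges))
})

test_that("negatives avoid true edges, self-loops, and each other", {
  g <- random_graph_case(30, k = 3)
  s <- split_edges(g, 0.7, 0.15, seed = 9)
  negs <- rbind(s$train_neg, s$val_neg, s$test_neg)
  key <- function(e) (pmin(e[, 1], e[, 2]) - 1) * g$n + pmax(e[, 1], e[, 2])
  expect_true(all(negs[, 1] != negs[, 2]))
  expect_equal(anyDuplicated(key(negs)), 0)
  expect_length(intersect(key(negs), key(g$edges)), 0)
})

test_that("splitting is deterministic in the seed and sensitive to it", {
  g <- random_graph_case(25, k = 2)
  expect_identical(split_edges(g, seed = 4), split_edges(g, seed = 4))
  s1 <- split_edges(g, seed = 4); s2 <- split_edges(g, seed = 5)
  expect_false(identical(s1$train_pos, s2$train_pos))
  # size contracts unchanged across seeds
  expect_equal(dim(s1$train_pos), dim(s2$train_pos))
  expect_equal(dim(s1$test_neg), dim(s2$test_neg))
})

test_that("degenerate fractions leaving no test edges error", {
  g <- random_graph_case(12, k = 2)
  expect_error(split_edges(g, 0.9, 0.3, seed = 1), "train_frac")
  m <- nrow(g$edges)
  expect_error(split_edges(g, (m - 0.4) / m, 0.3 / m, seed = 1), "empty")
})

test_that("false-edge injection obeys the counting rule and disjointness", {
  g <- random_graph_case(40, k = 3)
  s <- split_edges(g, 0.7, 0.15, seed = 3)
  s0 <- inject_false_edges(s, g, fraction = 0, seed = 1)
  expect_equal(nrow(s0$injected_false), 0)
  n_train <- nrow(s$train_pos)
  key <- function(e) (pmin(e[, 1], e[, 2]) - 1) * g$n + pmax(e[, 1], e[, 2])
  sizes <- integer(0)
  for (f in seq(0.1, 0.5, by = 0.1)) {
    sf <- inject_false_edges(s, g, f, seed = 2)
    expect_equal(nrow(sf$injected_false), round(f * n_train))
    expect_length(intersect(key(sf$injected_false), key(g$edges)), 0)
    negs <- rbind(sf$train_neg, sf$val_neg, sf$test_neg)
    expect_length(intersect(key(sf$injected_false), key(negs)), 0)
    sizes <- c(sizes, nrow(sf$injected_false))
  }
  expect_true(all(diff(sizes) >= 0))  # monotone over the 10%-50% grid
})

test_that("adjacency matrix is symmetric with zero diagonal", {
  g <- random_graph_case(15, k = 2)
  A <- as_adjacency(g)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_equal(sum(A[upper.tri(A)]), nrow(g$edges))
})
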
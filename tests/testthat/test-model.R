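test_that("attention coefficients match an explicit loop evaluation", {
  g <- make_path_graph(3)
  h <- rbind(c(1, 0), c(0, 1), c(1, 1))
  W <- diag(2)
  a <- c(1, 0, 0, 1)
  res <- attention_coefficients(h, g, W, a, slope = 0.2)
  # e_ij = LeakyReLU(h_i[1] + h_j[2]) for every (i, j in N(i) incl self)
  lk <- function(x) if (x > 0) x else 0.2 * x
  expected <- apply(res$pairs, 1, function(p) {
    lk(h[p[1], 1] + h[p[2], 2])
  })
  expect_equal(res$e, expected)
  # zero attention vector forces e == 0
  res0 <- attention_coefficients(h, g, W, rep(0, 4), slope = 0.2)
  expect_true(all(res0$e == 0))
})

test_that("LeakyReLU applies the 0.2 slope to negative pre-activations", {
  g <- make_path_graph(2)
  h <- rbind(-1, -2)       # single feature
  W <- matrix(1, 1, 1)
  a <- c(1, 0)             # e_ij = leaky(h_i)
  res <- attention_coefficients(h, g, W, a, slope = 0.2)
  i_neg <- res$pairs[, 1] == 1
  expect_equal(unique(res$e[i_neg]), 0.2 * -1)
  expect_equal(unique(res$e[!i_neg]), 0.2 * -2)
})

test_that("attention softmax reproduces hand-computed weights", {
  expect_equal(attention_softmax(c(0, log(2), log(3)), c(1, 1, 1)),
               c(1 / 6, 1 / 3, 1 / 2))
  expect_equal(attention_softmax(5, 1), 1)              # single neighbour
  expect_equal(attention_softmax(rep(2.5, 4), rep(1, 4)), rep(0.25, 4))
  # rows sum to 1 for interleaved nodes
  a <- attention_softmax(rnorm(10), rep(1:2, 5))
  expect_equal(as.vector(tapply(a, rep(1:2, 5), sum)), c(1, 1),
               tolerance = 1e-12)
})

test_that("gat_layer matches the dense double-loop oracle", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(4:10, 1)
    K <- sample(c(1, 2, 4), 1)
    d_in <- sample(2:4, 1); dh <- sample(2:3, 1)
    g <- random_graph_case(n, k = 2)
    h <- matrix(rnorm(n * d_in), n)
    W <- replicate(K, matrix(rnorm(d_in * dh, sd = 0.5), d_in), simplify = FALSE)
    a <- replicate(K, rnorm(2 * dh, sd = 0.5), simplify = FALSE)
    for (combine in c("concat", "average")) {
      got <- gat_layer(h, g, gat_layer_params(W, a, combine, slope = 0.2))
      want <- gat_layer_oracle(h, g$edges, n, W, a, combine, 0.2)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("uniform attention over identical features is an ELU fixed point", {
  n <- 6
  g <- random_graph_case(n, k = 2)
  v <- c(0.3, 0.7)
  h <- matrix(rep(v, each = n), n)
  p <- gat_layer_params(list(diag(2)), list(rep(0, 4)), "concat")
  expect_equal(gat_layer(h, g, p), h)  # convex combo of identical rows, v >= 0
})

test_that("concat and average coincide for a single head", {
  set.seed(5)
  n <- 7
  g <- random_graph_case(n, k = 2)
  h <- matrix(rnorm(n * 3), n)
  W <- list(matrix(rnorm(6, sd = 0.5), 3))
  a <- list(rnorm(4, sd = 0.5))
  expect_equal(gat_layer(h, g, gat_layer_params(W, a, "concat")),
               gat_layer(h, g, gat_layer_params(W, a, "average")))
})

test_that("encoder is permutation-equivariant and decoder permutation-consistent", {
  set.seed(8)
  n <- 12
  coords <- matrix(runif(n * 2), n, 2)
  g <- build_knn_graph(coords, k = 3)
  x_e <- matrix(rnorm(n * 6), n)
  x_i <- matrix(rnorm(n * 4), n)
  m <- init_model(6, 4, model_config(heads = c(2, 2), dims = c(3, 3),
                                     d_z = 4, d_hidden = 5), seed = 2)
  enc <- encode_streams(m, x_e, x_i, g)
  Z <- fuse_embeddings(m, enc$z_expr, enc$z_img)
  A1 <- decode_adjacency(Z)

  perm <- sample(n)
  gp <- build_knn_graph(coords[perm, ], k = 3)
  encp <- encode_streams(m, x_e[perm, ], x_i[perm, ], gp)
  expect_equal(encp$z_expr, enc$z_expr[perm, ], tolerance = 1e-10)
  Zp <- fuse_embeddings(m, encp$z_expr, encp$z_img)
  A2 <- decode_adjacency(Zp)
  expect_equal(unclass(A2), unclass(A1)[perm, perm], tolerance = 1e-10)
})

test_that("encoding is deterministic and ablation drops the image stream", {
  set.seed(9)
  g <- random_graph_case(10, k = 2)
  x_e <- matrix(rnorm(60), 10)
  x_i <- matrix(rnorm(40), 10)
  m <- init_model(6, 4, model_config(heads = c(2, 2), dims = c(3, 3),
                                     d_z = 4, d_hidden = 5), seed = 0)
  e1 <- encode_streams(m, x_e, x_i, g)
  e2 <- encode_streams(m, x_e, x_i, g)
  expect_identical(e1, e2)
  e3 <- encode_streams(m, x_e, NULL, g)
  expect_true(e3$ablation)
  expect_null(e3$z_img)
  m_abl <- init_model(6, NULL, model_config(heads = c(2, 2), dims = c(3, 3),
                                            d_z = 4, d_hidden = 5), seed = 0)
  Z <- fuse_embeddings(m_abl, e3$z_expr)
  expect_equal(ncol(Z), 4)
  rec <- reconstruct_features(m_abl, e3$z_expr)
  expect_null(rec$img_hat)
})

test_that("fusion MLP equals an explicit matrix-product evaluation", {
  set.seed(10)
  m <- init_model(3, 3, model_config(heads = c(1, 1), dims = c(2, 2),
                                     d_z = 3, d_hidden = 4), seed = 1)
  z_e <- matrix(rnorm(10), 5, 2)
  z_i <- matrix(rnorm(10), 5, 2)
  Z <- fuse_embeddings(m, z_e, z_i)
  f <- m$params$fusion
  zc <- cbind(z_e, z_i)
  pre <- zc %*% f$W1 + matrix(f$b1, 5, 4, byrow = TRUE)
  hid <- ifelse(pre > 0, pre, exp(pre) - 1)
  want <- hid %*% f$W2 + matrix(f$b2, 5, 3, byrow = TRUE)
  expect_equal(Z, want)
  # constructed identity: half-sum linear map with z_img = z_expr
  m2 <- m
  m2$params$fusion <- list(W1 = rbind(diag(2), diag(2)) / 2, b1 = rep(0, 2),
                           W2 = diag(2), b2 = rep(0, 2))
  z_pos <- abs(z_e)  # keep the hidden ELU in its identity range
  expect_equal(fuse_embeddings(m2, z_pos, z_pos), z_pos)
  # zero weights collapse to zero
  m3 <- m
  m3$params$fusion <- list(W1 = matrix(0, 4, 4), b1 = rep(0, 4),
                           W2 = matrix(0, 4, 3), b2 = rep(0, 3))
  expect_true(all(fuse_embeddings(m3, z_e, z_i) == 0))
})

test_that("inner-product decoder reproduces the hand sigmoid matrix", {
  Z <- rbind(c(1, 0), c(0, 1), c(1, 1))
  A <- decode_adjacency(Z)
  sg <- function(x) 1 / (1 + exp(-x))
  expect_equal(unclass(A),
               sg(rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 2))),
               tolerance = 1e-12)
  expect_equal(A[3, 3], 0.881, tolerance = 5e-4)
  expect_equal(A[1, 2], 0.5)
  expect_equal(A[1, 3], 0.731, tolerance = 5e-4)
  # zero embeddings decode to indifference
  expect_true(all(unclass(decode_adjacency(matrix(0, 4, 2))) == 0.5))
})

test_that("decoded adjacency is symmetric with entries strictly inside (0,1)", {
  set.seed(12)
  for (rep in 1:5) {
    Z <- matrix(rnorm(8 * 3, sd = rep), 8)
    A <- unclass(decode_adjacency(Z))
    expect_identical(A, t(A))
    expect_true(all(A > 0 & A < 1))
  }
})

test_that("reconstruction heads equal explicit matrix products", {
  m <- init_model(4, 3, model_config(heads = c(1, 1), dims = c(2, 2),
                                     d_z = 3, d_hidden = 4), seed = 3)
  z_e <- matrix(rnorm(6), 3, 2)
  z_i <- matrix(rnorm(6), 3, 2)
  rec <- reconstruct_features(m, z_e, z_i)
  expect_equal(rec$expr_hat,
               z_e %*% m$params$head_expr$W +
                 matrix(m$params$head_expr$b, 3, 4, byrow = TRUE))
  expect_equal(rec$img_hat,
               z_i %*% m$params$head_img$W +
                 matrix(m$params$head_img$b, 3, 3, byrow = TRUE))
  # zero embeddings + zero-bias heads reconstruct zero
  expect_true(all(reconstruct_features(m, matrix(0, 3, 2),
                                       matrix(0, 3, 2))$expr_hat == 0))
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(31)
  n <- 6
  g <- random_graph_case(n, k = 2)
  x_e <- matrix(rnorm(n * 4), n)
  x_i <- matrix(rnorm(n * 3), n)
  m <- init_model(4, 3, model_config(heads = c(2, 2), dims = c(2, 2),
                                     d_z = 3, d_hidden = 4), seed = 7)
  s <- split_edges(g, 0.5, 0.2, seed = 1)
  mp <- spatialcci:::mp_graph_(g$edges, n)
  w <- loss_weights()
  lg <- spatialcci:::model_loss_grads_(m, x_e, x_i, mp, s$train_pos,
                                       s$train_neg, w)
  loss_of <- function(model) {
    spatialcci:::model_loss_grads_(model, x_e, x_i, mp, s$train_pos,
                                   s$train_neg, w)$losses$total
  }
  eps <- 1e-6
  modify <- function(tree, path, i, delta) {
    if (length(path) == 0) { tree[i] <- tree[i] + delta; return(tree) }
    tree[[path[[1]]]] <- modify(tree[[path[[1]]]], path[-1], i, delta)
    tree
  }
  paths <- list(list("expr", "l1", "W", 1L), list("expr", "l1", "a", 2L),
                list("expr", "l2", "W", 2L), list("img", "l1", "a", 1L),
                list("img", "l2", "W", 1L), list("fusion", "W1"),
                list("fusion", "b2"), list("head_expr", "W"),
                list("head_img", "b"))
  for (p in paths) {
    leaf_grad <- lg$grads
    for (k in p) leaf_grad <- leaf_grad[[k]]
    for (i in sample(length(leaf_grad), min(3, length(leaf_grad)))) {
      mp_ <- m; mp_$params <- modify(m$params, p, i, eps)
      mm_ <- m; mm_$params <- modify(m$params, p, i, -eps)
      num <- (loss_of(mp_) - loss_of(mm_)) / (2 * eps)
      expect_equal(leaf_grad[i], num, tolerance = 1e-4)
    }
  }
})
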
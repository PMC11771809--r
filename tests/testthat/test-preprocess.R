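test_that("gene filter keeps exactly the genes expressed in enough spots", {
  # 3 genes nonzero in 12, 10, 9 of 12 spots
  counts <- cbind(g1 = rep(1, 12),
                  g2 = c(rep(2, 10), 0, 0),
                  g3 = c(rep(1, 9), 0, 0, 0))
  fg <- filter_genes(counts, min_spots = 10)
  expect_equal(fg$kept_gene_ids, c("g1", "g2"))
  expect_equal(colnames(fg$counts), c("g1", "g2"))
})

test_that("gene filter is the identity when nothing violates the threshold", {
  counts <- matrix(rpois(60, 3) + 1, 12, 5)
  expect_equal(filter_genes(counts, min_spots = 0)$counts, counts)
  expect_equal(filter_genes(counts, min_spots = 10)$counts, counts)
})

test_that("gene filter is idempotent", {
  set.seed(1)
  counts <- matrix(rbinom(200, 3, 0.3), 20, 10)
  once <- filter_genes(counts, min_spots = 5)
  twice <- filter_genes(once$counts, min_spots = 5)
  expect_equal(twice$counts, once$counts)
})

test_that("removing every gene raises an advisory error", {
  expect_error(filter_genes(matrix(0, 5, 3), min_spots = 2), "min_spots")
})

test_that("patch extraction equals direct slicing away from borders", {
  set.seed(2)
  img <- matrix(runif(100 * 100), 100, 100)
  p <- extract_patch(img, X = 50, Y = 50, patch_spec(20, 20))
  # loop-based slice oracle over 0-based index range 40..59 on both axes
  oracle <- matrix(0, 20, 20)
  for (r in 1:20) for (c in 1:20) oracle[r, c] <- img[40 + r, 40 + c]
  expect_equal(p, oracle)
  expect_equal(dim(p), c(20L, 20L))
})

test_that("a full-size window centred at the image centre is the identity", {
  img <- matrix(runif(16 * 16), 16, 16)
  p <- extract_patch(img, X = 8, Y = 8, patch_spec(16, 16))
  expect_equal(p, img)
})

test_that("zero padding fills out-of-image quadrants at a corner", {
  img <- matrix(1, 30, 30)
  p <- extract_patch(img, X = 0, Y = 0, patch_spec(20, 20, "pad_zero"))
  expect_equal(dim(p), c(20L, 20L))
  expect_true(all(p[1:10, ] == 0))     # rows above the image
  expect_true(all(p[, 1:10] == 0))     # columns left of the image
  expect_true(all(p[11:20, 11:20] == 1))
})

test_that("clip mode shifts border windows inside; oversize patches error", {
  img <- matrix(seq_len(100) / 100, 10, 10)
  p <- extract_patch(img, X = 0, Y = 0, patch_spec(4, 4, "clip"))
  expect_equal(p, img[1:4, 1:4])
  expect_error(extract_patch(img, 5, 5, patch_spec(20, 20, "clip")), "larger")
})

test_that("patch shape is invariant to border proximity under pad_zero", {
  img <- matrix(runif(64 * 64), 64, 64)
  spec <- patch_spec(17, 11)
  for (xy in list(c(0, 0), c(63.5, 0.2), c(1, 60), c(32, 32))) {
    expect_equal(dim(extract_patch(img, xy[1], xy[2], spec)), c(11L, 17L))
  }
})

test_that("mean-pool featurizer reproduces arithmetic patch means", {
  f1 <- make_meanpool_featurizer(grid = 1)
  p_a <- matrix(0.2, 8, 8)
  p_b <- matrix(0.8, 8, 8)
  fm <- featurize_patches(list(p_a, p_b), f1)
  expect_equal(fm$values, rbind(0.2, 0.8))
  expect_equal(fm$d_img, 1)
  # block means at grid 2
  q <- rbind(cbind(matrix(0, 2, 2), matrix(1, 2, 2)),
             cbind(matrix(2, 2, 2), matrix(3, 2, 2)))
  f2 <- make_meanpool_featurizer(grid = 2)
  expect_setequal(f2(q), c(0, 1, 2, 3))
})

test_that("featurization is deterministic and permutation-equivariant", {
  set.seed(3)
  patches <- replicate(6, matrix(runif(25), 5, 5), simplify = FALSE)
  f <- make_meanpool_featurizer(2)
  v1 <- featurize_patches(patches, f)$values
  v2 <- featurize_patches(patches, f)$values
  expect_identical(v1, v2)
  perm <- c(3, 1, 6, 2, 5, 4)
  vp <- featurize_patches(patches[perm], f)$values
  expect_equal(vp, v1[perm, ])
  expect_equal(featurize_patches(list(matrix(0, 5, 5)), f)$values[1, ],
               rep(0, 4))
})

test_that("ragged featurizer output is rejected", {
  bad <- function(patch) runif(sample(2:3, 1))
  patches <- replicate(5, matrix(runif(16), 4, 4), simplify = FALSE)
  set.seed(1)
  expect_error(featurize_patches(patches, bad), "length varies")
})

test_that("normalized counts equalize library size on the log scale", {
  counts <- rbind(c(10, 0, 10), c(100, 0, 100), c(2, 2, 0))
  x <- normalize_counts(counts)
  expect_equal(x[1, ], x[2, ])  # same composition, different depth
  expect_true(all(x >= 0))
})
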
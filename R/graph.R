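# Contact graph construction, edge splitting, negative sampling and
# false-edge injection.

#' Build the k-nearest-neighbour contact graph
#'
#' Each cell selects its `k` nearest neighbours by Euclidean distance on the
#' raw coordinate units; the directed selections are symmetrized (an edge is
#' present if either endpoint selected the other).  Five neighbours is the
#' standard direct-contact definition for solid tissue.  Ties in distance
#' are broken deterministically by smaller index; duplicate coordinates are
#' allowed.
#'
#' @param coords n x 2 numeric matrix.
#' @param k neighbours per cell, effectively `min(k, n - 1)`.
#' @return list of class `cell_graph` with `n`, `edges` (m x 2 integer
#'   matrix, i < j, sorted), and `k`.
#' @export
build_knn_graph <- function(coords, k = 5) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stopf_("need at least 2 cells to build a graph")
  if (k < 1) stopf_("k must be >= 1")
  k <- min(k, n - 1)
  d <- as.matrix(dist(coords))
  src <- integer(0); dst <- integer(0)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    nb <- order(di, seq_len(n))[seq_len(k)]  # tie-break by smaller index
    src <- c(src, rep.int(i, k)); dst <- c(dst, nb)
  }
  edges <- canon_edges_(cbind(src, dst), n)
  structure(list(n = n, edges = edges, k = k), class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d cells, %d undirected edges (k = %d)\n",
              x$n, nrow(x$edges), x$k))
  invisible(x)
}

#' Dense 0/1 adjacency matrix of a cell graph
#' @param graph a `cell_graph` or an m x 2 edge matrix together with `n`.
#' @param n number of nodes (ignored when `graph` is a `cell_graph`).
#' @return symmetric n x n 0/1 matrix with zero diagonal.
#' @export
as_adjacency <- function(graph, n = NULL) {
  if (inherits(graph, "cell_graph")) {
    edges <- graph$edges; n <- graph$n
  } else {
    edges <- graph
    if (is.null(n)) stopf_("n required when passing a raw edge matrix")
  }
  A <- matrix(0L, n, n)
  if (nrow(edges)) {
    A[edges] <- 1L
    A[edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  A
}

#' Split edges into train/validation/test sets with matched negatives
#'
#' Uniformly partitions the positive edges by seed into train/val/test of
#' sizes `round(|E| * frac)` with the remainder to test, then samples
#' non-edges 1:1 per split, uniformly, without replacement, excluding
#' self-loops, disjoint across splits.  Training on 70% of the edges is the
#' standard protocol; the remaining 30% defaults to 15/15 validation/test.
#'
#' @param graph a `cell_graph`.
#' @param train_frac,val_frac positive fractions with sum < 1.
#' @param seed integer seed controlling the partition and the sampling.
#' @return list of class `edge_split` with fields `train_pos`, `val_pos`,
#'   `test_pos`, `train_neg`, `val_neg`, `test_neg` (m x 2 matrices),
#'   `injected_false` (empty until [inject_false_edges()]), `n`, `seed`.
#' @export
split_edges <- function(graph, train_frac = 0.7, val_frac = 0.15, seed = 0) {
  stopifnot(inherits(graph, "cell_graph"))
  if (train_frac <= 0 || val_frac <= 0 || train_frac + val_frac >= 1) {
    stopf_("need train_frac > 0, val_frac > 0, train_frac + val_frac < 1")
  }
  edges <- graph$edges
  m <- nrow(edges)
  n <- graph$n
  n_train <- round(m * train_frac)
  n_val <- round(m * val_frac)
  n_test <- m - n_train - n_val
  if (n_test < 1) stopf_("test split is empty; reduce train/val fractions")
  if (n_train < 1 || n_val < 1) stopf_("empty train or validation split")
  n_nonedges <- n * (n - 1) / 2 - m
  if (n_nonedges < m) {
    stopf_("graph too dense: only %d non-edges for %d matched negatives",
           n_nonedges, m)
  }
  with_seed_(seed, {
    perm <- sample.int(m)
    train_pos <- edges[perm[seq_len(n_train)], , drop = FALSE]
    val_pos <- edges[perm[n_train + seq_len(n_val)], , drop = FALSE]
    test_pos <- edges[perm[n_train + n_val + seq_len(n_test)], , drop = FALSE]
    negs <- sample_nonedges_(n, m, forbidden_keys = pair_key_(edges[, 1], edges[, 2], n))
    split <- structure(
      list(train_pos = train_pos, val_pos = val_pos, test_pos = test_pos,
           train_neg = negs[seq_len(n_train), , drop = FALSE],
           val_neg = negs[n_train + seq_len(n_val), , drop = FALSE],
           test_neg = negs[n_train + n_val + seq_len(n_test), , drop = FALSE],
           injected_false = matrix(integer(0), ncol = 2),
           n = n, seed = as.integer(seed)),
      class = "edge_split")
    split
  })
}

# Sample `count` distinct non-edges uniformly by rejection, excluding
# self-loops and pairs whose key is in forbidden_keys.
sample_nonedges_ <- function(n, count, forbidden_keys) {
  if (count == 0) return(matrix(integer(0), ncol = 2))
  total_pairs <- n * (n - 1) / 2
  if (total_pairs - length(unique(forbidden_keys)) < count) {
    stopf_("not enough non-edges to sample %d negatives", count)
  }
  got_i <- integer(0); got_j <- integer(0)
  seen <- forbidden_keys
  while (length(got_i) < count) {
    need <- count - length(got_i)
    a <- sample.int(n, 2 * need + 10, replace = TRUE)
    b <- sample.int(n, 2 * need + 10, replace = TRUE)
    ok <- a != b
    a <- a[ok]; b <- b[ok]
    key <- pair_key_(a, b, n)
    fresh <- !(key %in% seen) & !duplicated(key)
    a <- a[fresh]; b <- b[fresh]; key <- key[fresh]
    take <- seq_len(min(length(a), need))
    got_i <- c(got_i, pmin(a, b)[take])
    got_j <- c(got_j, pmax(a, b)[take])
    seen <- c(seen, key[take])
  }
  cbind(i = got_i, j = got_j)
}

#' Inject random false edges into the training set
#'
#' Adds `round(fraction * |train_pos|)` uniformly sampled non-edges to the
#' training adjacency as if they were positives (the noise-robustness
#' protocol), recording them in `injected_false` with hidden ground-truth
#' label 0 so that evaluation can later score the model's ability to assign
#' them low probability.  Injected edges are disjoint from true edges and
#' from all sampled negatives.
#'
#' @param split an `edge_split`.
#' @param graph the `cell_graph` the split came from.
#' @param fraction fraction of training positives to inject, in \[0, 1\].
#' @param seed integer seed.
#' @return The modified `edge_split`.
#' @export
inject_false_edges <- function(split, graph, fraction, seed = 0) {
  stopifnot(inherits(split, "edge_split"), inherits(graph, "cell_graph"))
  if (fraction < 0 || fraction > 1) stopf_("fraction must be in [0, 1]")
  n_inject <- round(fraction * nrow(split$train_pos))
  if (n_inject == 0) {
    split$injected_false <- matrix(integer(0), ncol = 2)
    return(split)
  }
  n <- graph$n
  used <- rbind(graph$edges, split$train_neg, split$val_neg, split$test_neg)
  forbidden <- pair_key_(used[, 1], used[, 2], n)
  split$injected_false <- with_seed_(seed, {
    sample_nonedges_(n, n_inject, forbidden_keys = forbidden)
  })
  split
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf(paste0("<edge_split> pos %d/%d/%d (train/val/test), ",
                     "matched 1:1 negatives, %d injected false edges\n"),
              nrow(x$train_pos), nrow(x$val_pos), nrow(x$test_pos),
              nrow(x$injected_false)))
  invisible(x)
}
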
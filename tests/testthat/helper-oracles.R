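# Independent reference implementations used as oracles: all are written as
# plain double loops over nodes and neighbourhoods, sharing no code with the
# package internals.

# brute-force k-NN graph: all-pairs distances, sort, symmetrize
knn_oracle <- function(coords, k) {
  n <- nrow(coords)
  k <- min(k, n - 1)
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j != i) d[j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
    nb <- order(d, seq_len(n))[seq_len(k)]
    sel[i, nb] <- TRUE
  }
  edges <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && (sel[i, j] || sel[j, i])) edges <- rbind(edges, c(i, j))
    }
  }
  edges
}

leaky_oracle <- function(x, slope) if (x > 0) x else slope * x
elu_oracle <- function(x) ifelse(x > 0, x, exp(x) - 1)

# dense per-node double-loop evaluation of one multi-head GAT layer:
# e_ij = LeakyReLU(a^T [W h_i || W h_j]), alpha by softmax over N(i) (with
# self-loop), h'_i = ELU(sum_j alpha_ij W h_j); heads concatenated after
# activation or pre-activation-averaged then activated.
gat_layer_oracle <- function(h, edges, n, W_list, a_list, combine, slope) {
  K <- length(W_list)
  A <- matrix(FALSE, n, n)
  if (!is.null(edges) && nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      A[edges[r, 1], edges[r, 2]] <- TRUE
      A[edges[r, 2], edges[r, 1]] <- TRUE
    }
  }
  diag(A) <- TRUE
  head_out <- vector("list", K)
  for (k in seq_len(K)) {
    W <- W_list[[k]]; a <- a_list[[k]]
    dh <- ncol(W)
    M <- matrix(0, n, dh)
    for (i in seq_len(n)) {
      nb <- which(A[i, ])
      e <- numeric(length(nb))
      for (t in seq_along(nb)) {
        j <- nb[t]
        gi <- as.vector(h[i, ] %*% W)
        gj <- as.vector(h[j, ] %*% W)
        e[t] <- leaky_oracle(sum(a * c(gi, gj)), slope)
      }
      alpha <- exp(e - max(e)) / sum(exp(e - max(e)))
      for (t in seq_along(nb)) {
        M[i, ] <- M[i, ] + alpha[t] * as.vector(h[nb[t], ] %*% W)
      }
    }
    head_out[[k]] <- M
  }
  if (combine == "concat") {
    do.call(cbind, lapply(head_out, elu_oracle))
  } else {
    elu_oracle(Reduce(`+`, head_out) / K)
  }
}

# a small random cell_graph plus features for property tests
random_graph_case <- function(n, k = 2) {
  coords <- matrix(runif(n * 2), n, 2)
  build_knn_graph(coords, k = k)
}

make_path_graph <- function(n) {
  structure(list(n = n,
                 edges = cbind(i = seq_len(n - 1), j = seq_len(n - 1) + 1),
                 k = 1),
            class = "cell_graph")
}

# a tiny deterministic dataset for io tests
tiny_dataset <- function() {
  spatial_dataset(
    cell_ids = c("c1", "c2", "c3"),
    coords = cbind(x = c(1, 4, 2.5), y = c(1, 1, 3)),
    counts = matrix(c(0:4, 2:6, 1, 0, 3, 0, 5), nrow = 3, byrow = TRUE),
    gene_ids = paste0("g", 1:5)
  )
}
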
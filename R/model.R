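# Dual-stream multi-head graph attention encoder, MLP fusion, inner-product
# adjacency decoder, and feature reconstruction heads.
#
# All forward operations are pure functions of (features, graph, parameters)
# so that a dense reference implementation and finite-difference gradient
# checks can be run against them.

# ---------------------------------------------------------------------------
# message-passing graph: ordered (i, j) pairs with j in N(i), self-loops added
# so every node attends at least to itself.

mp_graph_ <- function(graph, n = NULL) {
  if (inherits(graph, "cell_graph")) {
    edges <- graph$edges; n <- graph$n
  } else {
    edges <- graph
    if (is.null(n)) stopf_("n required with a raw edge matrix")
  }
  pi <- c(edges[, 1], edges[, 2], seq_len(n))
  pj <- c(edges[, 2], edges[, 1], seq_len(n))
  o <- order(pi, pj)
  pi <- pi[o]; pj <- pj[o]
  list(pi = pi, pj = pj, n = n,
       idx = split(seq_along(pi), factor(pi, levels = seq_len(n))))
}

seg_softmax_ <- function(e, mp) {
  mx <- vapply(mp$idx, function(ii) max(e[ii]), numeric(1))
  ex <- exp(e - mx[mp$pi])
  den <- as.vector(rowsum(ex, mp$pi))
  ex / den[mp$pi]
}

# ---------------------------------------------------------------------------
# exported single-head operations (the building blocks, testable in isolation)

#' Raw attention coefficients of one attention head
#'
#' For every ordered pair (i, j) with j in the self-loop-augmented
#' neighbourhood of i, computes
#' `e_ij = LeakyReLU(a^T [W h_i || W h_j])`.
#'
#' @param h n x d_in node feature matrix.
#' @param graph `cell_graph` (self-loops are added internally).
#' @param W d_in x d_head linear transform.
#' @param a attention weight vector of length 2 * d_head.
#' @param slope LeakyReLU negative slope (default 0.2).
#' @return list with `e` (coefficient per pair) and `pairs` (ordered i, j).
#' @export
attention_coefficients <- function(h, graph, W, a, slope = 0.2) {
  h <- as.matrix(h)
  if (ncol(h) != nrow(W)) stopf_("feature width %d != nrow(W) %d", ncol(h), nrow(W))
  if (length(a) != 2 * ncol(W)) stopf_("length(a) must be 2 * ncol(W)")
  mp <- mp_graph_(graph)
  G <- h %*% W
  dh <- ncol(W)
  a1 <- a[seq_len(dh)]; a2 <- a[dh + seq_len(dh)]
  s <- as.vector(G %*% a1)[mp$pi] + as.vector(G %*% a2)[mp$pj]
  list(e = leaky_relu_(s, slope), pairs = cbind(i = mp$pi, j = mp$pj))
}

#' Softmax normalization of attention coefficients
#'
#' Normalizes `e_ij` across each node's neighbourhood,
#' `alpha_ij = exp(e_ij) / sum_k exp(e_ik)`, computed with per-node
#' max-subtraction for numerical stability.  Each node's weights sum to 1.
#'
#' @param e numeric vector of coefficients per ordered pair.
#' @param i integer vector: the centre node of each pair.
#' @return numeric vector `alpha`, same length as `e`.
#' @export
attention_softmax <- function(e, i) {
  if (length(e) != length(i)) stopf_("e and i length mismatch")
  if (length(e) == 0) stopf_("empty neighbourhood")
  nodes <- sort(unique(i))
  fi <- match(i, nodes)
  mx <- vapply(split(e, factor(fi, levels = seq_along(nodes))), max, numeric(1))
  ex <- exp(e - mx[fi])
  den <- as.vector(rowsum(ex, fi))
  unname(ex / den[fi])
}

#' Parameters of one multi-head GAT layer
#'
#' @param W list of K matrices (d_in x d_head), one per head.
#' @param a list of K vectors of length 2 * d_head.
#' @param combine `"concat"` (middle layers) or `"average"` (final layer).
#' @param slope LeakyReLU negative slope.
#' @return list of class `gat_layer_params`.
#' @export
gat_layer_params <- function(W, a, combine = c("concat", "average"),
                             slope = 0.2) {
  combine <- match.arg(combine)
  if (!is.list(W)) W <- list(W)
  if (!is.list(a)) a <- list(a)
  if (length(W) != length(a)) stopf_("need one attention vector per head")
  for (k in seq_along(W)) {
    if (length(a[[k]]) != 2 * ncol(W[[k]])) {
      stopf_("head %d: length(a) != 2 * d_head", k)
    }
  }
  structure(list(W = W, a = a, K = length(W), combine = combine,
                 slope = slope), class = "gat_layer_params")
}

#' One multi-head graph attention layer
#'
#' Per head, aggregates neighbour features with softmax-normalized attention
#' weights and applies ELU: `h'_i = ELU(sum_j alpha_ij W h_j)`.  Head
#' outputs are concatenated after activation (`combine = "concat"`) or the
#' pre-activation aggregates are averaged across heads and then passed
#' through ELU (`combine = "average"`, final layer).
#'
#' @param h n x d_in node features.
#' @param graph `cell_graph` (self-loops added internally).
#' @param params a [gat_layer_params()].
#' @return n x (K * d_head) matrix for concat, n x d_head for average.
#' @export
gat_layer <- function(h, graph, params) {
  stopifnot(inherits(params, "gat_layer_params"))
  mp <- mp_graph_(graph)
  out <- gat_layer_forward_(as.matrix(h), mp, params)$out
  if (!all(is.finite(out))) stopf_("non-finite GAT layer output")
  out
}

# forward with caches (used by both gat_layer and training backprop)
gat_layer_forward_ <- function(h, mp, params) {
  K <- params$K
  heads <- vector("list", K)
  for (k in seq_len(K)) {
    W <- params$W[[k]]; a <- params$a[[k]]
    dh <- ncol(W)
    G <- h %*% W
    f1 <- as.vector(G %*% a[seq_len(dh)])
    f2 <- as.vector(G %*% a[dh + seq_len(dh)])
    s <- f1[mp$pi] + f2[mp$pj]
    e <- leaky_relu_(s, params$slope)
    alpha <- seg_softmax_(e, mp)
    M <- rowsum(alpha * G[mp$pj, , drop = FALSE], mp$pi)
    dimnames(M) <- NULL
    heads[[k]] <- list(G = G, s = s, alpha = alpha, M = M)
  }
  if (params$combine == "concat") {
    out <- do.call(cbind, lapply(heads, function(hd) elu_(hd$M)))
  } else {
    Mavg <- Reduce(`+`, lapply(heads, `[[`, "M")) / K
    out <- elu_(Mavg)
    attr(heads, "Mavg") <- Mavg
  }
  list(out = out, heads = heads, h = h)
}

# backward through one layer: dOut -> (grads for W/a per head, dH)
gat_layer_backward_ <- function(dOut, cache, mp, params) {
  K <- params$K
  h <- cache$h
  n <- mp$n
  fI <- mp$pi; fJ <- mp$pj
  dH <- matrix(0, nrow(h), ncol(h))
  dW <- vector("list", K); da <- vector("list", K)
  if (params$combine == "average") {
    Mavg <- attr(cache$heads, "Mavg")
    dPre <- dOut * elu_grad_(Mavg)
  }
  for (k in seq_len(K)) {
    hd <- cache$heads[[k]]
    W <- params$W[[k]]; a <- params$a[[k]]
    dh_ <- ncol(W)
    a1 <- a[seq_len(dh_)]; a2 <- a[dh_ + seq_len(dh_)]
    dM <- if (params$combine == "concat") {
      cols <- (k - 1) * dh_ + seq_len(dh_)
      dOut[, cols, drop = FALSE] * elu_grad_(hd$M)
    } else {
      dPre / K
    }
    # aggregation backward
    dAlpha <- rowSums(dM[fI, , drop = FALSE] * hd$G[fJ, , drop = FALSE])
    dG <- rowsum2_(hd$alpha * dM[fI, , drop = FALSE], fJ, n)
    # softmax backward
    S <- as.vector(rowsum2_(matrix(hd$alpha * dAlpha), fI, n))
    dE <- hd$alpha * (dAlpha - S[fI])
    dSpre <- dE * ifelse(hd$s > 0, 1, params$slope)
    # attention-score backward
    da1 <- colSums(dSpre * hd$G[fI, , drop = FALSE])
    da2 <- colSums(dSpre * hd$G[fJ, , drop = FALSE])
    sI <- as.vector(rowsum2_(matrix(dSpre), fI, n))
    sJ <- as.vector(rowsum2_(matrix(dSpre), fJ, n))
    dG <- dG + outer(sI, a1) + outer(sJ, a2)
    dW[[k]] <- crossprod(h, dG)
    da[[k]] <- c(da1, da2)
    dH <- dH + dG %*% t(W)
  }
  list(dW = dW, da = da, dH = dH)
}

# rowsum with guaranteed rows 1..n even if a group is absent
rowsum2_ <- function(x, g, n) {
  r <- rowsum(x, g)
  if (nrow(r) == n) { dimnames(r) <- NULL; return(r) }
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(r)), ] <- r
  out
}

# ---------------------------------------------------------------------------
# whole-model construction and forward operations

#' Default model architecture configuration
#'
#' Two GAT layers per stream: layer 1 uses `heads[1]` heads of width
#' `dims[1]` with concatenation, layer 2 uses `heads[2]` heads of width
#' `dims[2]` averaged before the final ELU (so the per-stream embedding
#' width is `dims[2]`).  The fusion MLP maps the concatenated stream
#' embeddings through one hidden layer of width `d_hidden` to `d_z`
#' dimensions.
#'
#' @param heads integer vector of length 2: attention heads per layer.
#' @param dims integer vector of length 2: per-head output widths.
#' @param d_z fused embedding width (must be < 2 * dims\[2\] so that fusion
#'   reduces dimensionality).
#' @param d_hidden fusion MLP hidden width.
#' @param slope LeakyReLU negative slope in the attention mechanism.
#' @return named list.
#' @export
model_config <- function(heads = c(4, 4), dims = c(16, 32), d_z = 32,
                         d_hidden = 64, slope = 0.2) {
  if (d_z >= 2 * dims[2]) stopf_("d_z must be < 2 * dims[2] (dimension reduction)")
  list(heads = as.integer(heads), dims = as.integer(dims),
       d_z = as.integer(d_z), d_hidden = as.integer(d_hidden), slope = slope)
}

init_stream_ <- function(d_in, config) {
  l1 <- gat_layer_params(
    W = lapply(seq_len(config$heads[1]), function(k) glorot_(d_in, config$dims[1])),
    a = lapply(seq_len(config$heads[1]), function(k) {
      as.vector(glorot_(2 * config$dims[1], 1))
    }),
    combine = "concat", slope = config$slope)
  d1 <- config$heads[1] * config$dims[1]
  l2 <- gat_layer_params(
    W = lapply(seq_len(config$heads[2]), function(k) glorot_(d1, config$dims[2])),
    a = lapply(seq_len(config$heads[2]), function(k) {
      as.vector(glorot_(2 * config$dims[2], 1))
    }),
    combine = "average", slope = config$slope)
  list(l1 = l1, l2 = l2)
}

#' Initialize a dual-stream GAT autoencoder
#'
#' Glorot-uniform initialisation of both attention streams, the fusion MLP
#' and the two reconstruction heads, reproducible from `seed`.  When
#' `d_img` is NULL the model is built in expression-only (image-ablation)
#' mode: no image stream, no image head, and the fusion MLP takes only the
#' expression embedding.
#'
#' @param d_expr width of expression node features.
#' @param d_img width of image node features, or NULL for ablation mode.
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return list of class `dual_gat_model`.
#' @export
init_model <- function(d_expr, d_img = NULL, config = model_config(),
                       seed = 0) {
  with_seed_(seed, {
    use_image <- !is.null(d_img)
    d_s <- config$dims[2]
    d_fuse_in <- if (use_image) 2 * d_s else d_s
    params <- list(
      expr = init_stream_(d_expr, config),
      img = if (use_image) init_stream_(d_img, config) else NULL,
      fusion = list(W1 = glorot_(d_fuse_in, config$d_hidden),
                    b1 = rep(0, config$d_hidden),
                    W2 = glorot_(config$d_hidden, config$d_z),
                    b2 = rep(0, config$d_z)),
      head_expr = list(W = glorot_(d_s, d_expr), b = rep(0, d_expr)),
      head_img = if (use_image) list(W = glorot_(d_s, d_img), b = rep(0, d_img))
                 else NULL
    )
    structure(list(params = params, config = config, use_image = use_image,
                   d_expr = d_expr, d_img = d_img, seed = as.integer(seed)),
              class = "dual_gat_model")
  })
}

#' @export
print.dual_gat_model <- function(x, ...) {
  cat(sprintf("<dual_gat_model> %s, heads %s, d_s=%d, d_z=%d\n",
              if (x$use_image) "dual-stream (expression + image)"
              else "expression-only (ablation)",
              paste(x$config$heads, collapse = "/"),
              x$config$dims[2], x$config$d_z))
  invisible(x)
}

stream_forward_ <- function(x, mp, stream) {
  c1 <- gat_layer_forward_(x, mp, stream$l1)
  c2 <- gat_layer_forward_(c1$out, mp, stream$l2)
  list(z = c2$out, c1 = c1, c2 = c2)
}

#' Encode expression and image features into per-stream embeddings
#'
#' Runs the two independently parameterised 2-layer GAT streams over the
#' same graph.  With `x_img = NULL` (or an ablation-mode model) only the
#' expression stream runs and `z_img` is NULL.
#'
#' @param model a `dual_gat_model`.
#' @param x_expr n x d_expr expression node features.
#' @param x_img n x d_img image node features or NULL.
#' @param graph `cell_graph` used for message passing.
#' @return list with `z_expr`, `z_img` (possibly NULL) and `ablation` flag.
#' @export
encode_streams <- function(model, x_expr, x_img, graph) {
  stopifnot(inherits(model, "dual_gat_model"))
  mp <- mp_graph_(graph)
  z_expr <- stream_forward_(as.matrix(x_expr), mp, model$params$expr)$z
  ablation <- is.null(x_img) || !model$use_image
  z_img <- if (!ablation) {
    stream_forward_(as.matrix(x_img), mp, model$params$img)$z
  } else NULL
  list(z_expr = z_expr, z_img = z_img, ablation = ablation)
}

#' Fuse per-stream embeddings through the MLP
#'
#' `Z = ELU([z_expr || z_img] W1 + b1) W2 + b2`; in ablation mode the input
#' is `z_expr` alone.
#'
#' @param model a `dual_gat_model`.
#' @param z_expr,z_img stream embeddings ([encode_streams()]); `z_img` NULL
#'   in ablation mode.
#' @return n x d_z fused embedding matrix Z.
#' @export
fuse_embeddings <- function(model, z_expr, z_img = NULL) {
  f <- model$params$fusion
  zc <- if (is.null(z_img)) z_expr else cbind(z_expr, z_img)
  if (ncol(zc) != nrow(f$W1)) {
    stopf_("fusion input width %d != expected %d", ncol(zc), nrow(f$W1))
  }
  pre1 <- sweep(zc %*% f$W1, 2, f$b1, `+`)
  sweep(elu_(pre1) %*% f$W2, 2, f$b2, `+`)
}

#' Inner-product adjacency decoder
#'
#' `A' = sigmoid(Z Z^T)` elementwise: the predicted edge-probability matrix,
#' symmetric by construction with entries strictly inside (0, 1).  The
#' diagonal (self-communication) is not used by the loss or the evaluation.
#'
#' @param Z n x d_z embedding matrix.
#' @return n x n symmetric probability matrix of class `predicted_adjacency`.
#' @export
decode_adjacency <- function(Z) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stopf_("non-finite embeddings")
  A <- sigmoid_(tcrossprod(Z))
  eps <- 1e-12
  A <- pmin(pmax(A, eps), 1 - eps)
  class(A) <- c("predicted_adjacency", class(A))
  A
}

#' Reconstruct input features from stream embeddings
#'
#' Two independent linear heads map `z_expr` back to the expression feature
#' matrix and `z_img` back to the image feature matrix (their MSE against
#' the inputs are the reconstruction loss terms).  In ablation mode the
#' image reconstruction is NULL and its loss term is skipped.
#'
#' @param model a `dual_gat_model`.
#' @param z_expr,z_img stream embeddings.
#' @return list with `expr_hat` (n x d_expr) and `img_hat` (n x d_img or
#'   NULL).
#' @export
reconstruct_features <- function(model, z_expr, z_img = NULL) {
  he <- model$params$head_expr
  expr_hat <- sweep(z_expr %*% he$W, 2, he$b, `+`)
  img_hat <- NULL
  if (!is.null(z_img) && !is.null(model$params$head_img)) {
    hi <- model$params$head_img
    img_hat <- sweep(z_img %*% hi$W, 2, hi$b, `+`)
  }
  list(expr_hat = expr_hat, img_hat = img_hat)
}

# full forward with caches for backprop (internal)
model_forward_ <- function(model, x_expr, x_img, mp) {
  p <- model$params
  se <- stream_forward_(x_expr, mp, p$expr)
  si <- if (model$use_image && !is.null(x_img)) {
    stream_forward_(x_img, mp, p$img)
  } else NULL
  zc <- if (is.null(si)) se$z else cbind(se$z, si$z)
  pre1 <- sweep(zc %*% p$fusion$W1, 2, p$fusion$b1, `+`)
  Hf <- elu_(pre1)
  Z <- sweep(Hf %*% p$fusion$W2, 2, p$fusion$b2, `+`)
  expr_hat <- sweep(se$z %*% p$head_expr$W, 2, p$head_expr$b, `+`)
  img_hat <- if (!is.null(si)) {
    sweep(si$z %*% p$head_img$W, 2, p$head_img$b, `+`)
  } else NULL
  list(se = se, si = si, zc = zc, pre1 = pre1, Hf = Hf, Z = Z,
       expr_hat = expr_hat, img_hat = img_hat)
}

# scores (probabilities) for a set of unordered pairs given embeddings
pair_scores_ <- function(Z, pairs) {
  logits <- rowSums(Z[pairs[, 1], , drop = FALSE] * Z[pairs[, 2], , drop = FALSE])
  sigmoid_(logits)
}
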
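# Composite loss, analytic backpropagation, optimizers, plateau scheduling
# and the training loop with best-validation-AUC checkpointing.

#' Balanced binary cross-entropy loss
#'
#' `norm * (-1/N) * sum(q log p + (1 - q) log(1 - p))` with probabilities
#' clamped to `[eps, 1 - eps]`, `eps = 1e-7`.  `norm` is the coefficient
#' balancing positive and negative samples; with 1:1 matched sampling the
#' class-balance coefficient `(n_pos + n_neg) / (2 n_pos)` equals 1.
#'
#' @param p predicted probabilities.
#' @param q true 0/1 labels.
#' @param norm balancing coefficient (> 0).
#' @return scalar loss.
#' @export
bce_loss <- function(p, q, norm = 1) {
  if (length(p) != length(q)) stopf_("p and q length mismatch")
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  norm * mean(-(q * log(p) + (1 - q) * log(1 - p)))
}

#' Mean squared error loss
#'
#' Mean of squared differences over all entries.
#'
#' @param x,x_hat equal-shaped numeric arrays.
#' @return scalar loss.
#' @export
mse_loss <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat)) && length(x) != length(x_hat)) {
    stopf_("shape mismatch in mse_loss")
  }
  mean((x - x_hat)^2)
}

#' Weighted total loss
#'
#' `L_total = alpha * L_reg + beta * L_count + gamma * L_feature`, weighing
#' the adjacency reconstruction (BCE) against the expression and image
#' feature reconstruction (MSE) terms.
#'
#' @param l_reg,l_count,l_feature component losses (>= 0).
#' @param weights a [loss_weights()].
#' @return scalar.
#' @export
total_loss <- function(l_reg, l_count, l_feature, weights = loss_weights()) {
  weights$alpha * l_reg + weights$beta * l_count + weights$gamma * l_feature
}

#' Loss weighting factors
#'
#' @param alpha weight of the adjacency (BCE) term.
#' @param beta weight of the expression reconstruction term.
#' @param gamma weight of the image-feature reconstruction term (set 0 for
#'   ablation).
#' @param norm positive/negative balancing coefficient of the BCE, or NULL
#'   to use the class-balance value `(n_pos + n_neg) / (2 n_pos)`.
#' @return named list.
#' @export
loss_weights <- function(alpha = 1, beta = 1, gamma = 1, norm = NULL) {
  if (alpha < 0 || beta < 0 || gamma < 0) stopf_("weights must be >= 0")
  if (!is.null(norm) && norm <= 0) stopf_("norm must be > 0")
  list(alpha = alpha, beta = beta, gamma = gamma, norm = norm)
}

#' Optimization protocol configuration
#'
#' @param optimizer `"sgd"` or `"adam"`.
#' @param lr initial learning rate.
#' @param max_epochs maximum training epochs.
#' @param plateau_patience epochs of non-improving validation loss before
#'   the learning rate is reduced.
#' @param plateau_factor multiplier applied to the learning rate on plateau
#'   (`new_lr = factor * lr`).
#' @param seed integer seed for parameter initialisation order and any
#'   sampling.
#' @return named list of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), lr = 1e-2,
                         max_epochs = 1000, plateau_patience = 10,
                         plateau_factor = 0.05, seed = 0) {
  optimizer <- match.arg(optimizer)
  if (lr <= 0) stopf_("lr must be > 0")
  if (plateau_factor <= 0 || plateau_factor >= 1) {
    stopf_("plateau_factor must be in (0, 1)")
  }
  if (max_epochs < 1) stopf_("max_epochs must be >= 1")
  structure(list(optimizer = optimizer, lr = lr,
                 max_epochs = as.integer(max_epochs),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, seed = as.integer(seed)),
            class = "train_config")
}

#' Resolution presets for the optimization protocol
#'
#' Spot-resolution data use SGD, single-cell-resolution data use Adam; both
#' start at learning rate 1e-2, train for at most 1000 epochs, and reduce
#' the learning rate by a factor of 0.05 after 10 non-improving epochs of
#' validation loss.
#'
#' @param resolution `"single_cell"` or `"spot"`.
#' @param ... overrides passed to [train_config()].
#' @return a `train_config`.
#' @export
train_presets <- function(resolution = c("single_cell", "spot"), ...) {
  resolution <- match.arg(resolution)
  base <- list(optimizer = if (resolution == "spot") "sgd" else "adam",
               lr = 1e-2, max_epochs = 1000, plateau_patience = 10,
               plateau_factor = 0.05)
  do.call(train_config, modifyList(base, list(...)))
}

# ---------------------------------------------------------------------------
# parameter-tree utilities (params are nested lists of numeric arrays)

tree_map_ <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map_, f = f) else if (is.null(x)) NULL else f(x)
}

tree_map2_ <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    # out[k] <- list(...) keeps NULL leaves in place (out[[k]] <- NULL drops)
    for (k in seq_along(x)) out[k] <- list(tree_map2_(x[[k]], y[[k]], f))
    out
  } else if (is.null(x)) NULL else f(x, y)
}

zero_like_ <- function(x) tree_map_(x, function(a) a * 0)

# strip class attributes so tree recursion sees plain lists
as_plain_ <- function(x) {
  if (is.list(x)) { x <- unclass(x); lapply(x, as_plain_) } else x
}

# ---------------------------------------------------------------------------
# loss + gradients for one full-batch epoch

model_loss_grads_ <- function(model, x_expr, x_img, mp, pos_pairs, neg_pairs,
                              weights) {
  p <- model$params
  fw <- model_forward_(model, x_expr, x_img, mp)
  n <- nrow(fw$Z)

  pairs <- rbind(pos_pairs, neg_pairs)
  q <- c(rep(1, nrow(pos_pairs)), rep(0, nrow(neg_pairs)))
  logits <- rowSums(fw$Z[pairs[, 1], , drop = FALSE] *
                      fw$Z[pairs[, 2], , drop = FALSE])
  prob <- sigmoid_(logits)
  norm <- weights$norm %||%
    ((nrow(pos_pairs) + nrow(neg_pairs)) / (2 * nrow(pos_pairs)))
  l_reg <- bce_loss(prob, q, norm)
  l_count <- mse_loss(x_expr, fw$expr_hat)
  l_feature <- if (!is.null(fw$img_hat)) mse_loss(x_img, fw$img_hat) else 0
  ltot <- total_loss(l_reg, l_count, l_feature, weights)

  # --- backward ---
  N <- length(q)
  dlogit <- weights$alpha * norm * (prob - q) / N
  dZ <- matrix(0, n, ncol(fw$Z))
  dZ_i <- dlogit * fw$Z[pairs[, 2], , drop = FALSE]
  dZ_j <- dlogit * fw$Z[pairs[, 1], , drop = FALSE]
  dZ <- dZ + rowsum2_(dZ_i, pairs[, 1], n) + rowsum2_(dZ_j, pairs[, 2], n)

  fus <- p$fusion
  g_fusion <- list(W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL)
  g_fusion$W2 <- crossprod(fw$Hf, dZ)
  g_fusion$b2 <- colSums(dZ)
  dHf <- dZ %*% t(fus$W2)
  dpre1 <- dHf * elu_grad_(fw$pre1)
  g_fusion$W1 <- crossprod(fw$zc, dpre1)
  g_fusion$b1 <- colSums(dpre1)
  dzc <- dpre1 %*% t(fus$W1)
  d_s <- ncol(fw$se$z)
  dz_expr <- dzc[, seq_len(d_s), drop = FALSE]
  dz_img <- if (!is.null(fw$si)) dzc[, d_s + seq_len(d_s), drop = FALSE] else NULL

  # reconstruction heads
  dexpr_hat <- weights$beta * 2 * (fw$expr_hat - x_expr) / length(x_expr)
  g_head_expr <- list(W = crossprod(fw$se$z, dexpr_hat), b = colSums(dexpr_hat))
  dz_expr <- dz_expr + dexpr_hat %*% t(p$head_expr$W)
  g_head_img <- NULL
  if (!is.null(fw$si)) {
    dimg_hat <- weights$gamma * 2 * (fw$img_hat - x_img) / length(x_img)
    g_head_img <- list(W = crossprod(fw$si$z, dimg_hat), b = colSums(dimg_hat))
    dz_img <- dz_img + dimg_hat %*% t(p$head_img$W)
  }

  g_expr <- stream_backward_(dz_expr, fw$se, mp, p$expr)
  g_img <- if (!is.null(fw$si)) stream_backward_(dz_img, fw$si, mp, p$img) else NULL

  grads <- list(expr = g_expr, img = g_img, fusion = g_fusion,
                head_expr = g_head_expr, head_img = g_head_img)
  list(losses = list(l_reg = l_reg, l_count = l_count, l_feature = l_feature,
                     total = ltot),
       grads = grads, forward = fw)
}

stream_backward_ <- function(dz, cache, mp, stream) {
  b2 <- gat_layer_backward_(dz, cache$c2, mp, stream$l2)
  b1 <- gat_layer_backward_(b2$dH, cache$c1, mp, stream$l1)
  list(l1 = list(W = b1$dW, a = b1$da),
       l2 = list(W = b2$dW, a = b2$da))
}

# params tree restricted to trainable leaves, aligned with the grads tree
trainable_ <- function(params) {
  list(expr = list(l1 = list(W = params$expr$l1$W, a = params$expr$l1$a),
                   l2 = list(W = params$expr$l2$W, a = params$expr$l2$a)),
       img = if (!is.null(params$img)) {
         list(l1 = list(W = params$img$l1$W, a = params$img$l1$a),
              l2 = list(W = params$img$l2$W, a = params$img$l2$a))
       } else NULL,
       fusion = params$fusion,
       head_expr = params$head_expr,
       head_img = params$head_img)
}

apply_update_ <- function(params, new_leaves) {
  params$expr$l1$W <- new_leaves$expr$l1$W
  params$expr$l1$a <- new_leaves$expr$l1$a
  params$expr$l2$W <- new_leaves$expr$l2$W
  params$expr$l2$a <- new_leaves$expr$l2$a
  if (!is.null(params$img)) {
    params$img$l1$W <- new_leaves$img$l1$W
    params$img$l1$a <- new_leaves$img$l1$a
    params$img$l2$W <- new_leaves$img$l2$W
    params$img$l2$a <- new_leaves$img$l2$a
  }
  params$fusion <- new_leaves$fusion
  params$head_expr <- new_leaves$head_expr
  params$head_img <- new_leaves$head_img
  params
}

make_optimizer_ <- function(config, params0) {
  if (config$optimizer == "sgd") {
    list(step = function(params, grads, lr) {
      tree_map2_(params, grads, function(p, g) p - lr * g)
    })
  } else {
    m <- zero_like_(params0)
    v <- zero_like_(params0)
    t <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    env <- environment()
    list(step = function(params, grads, lr) {
      env$t <- env$t + 1L
      env$m <- tree_map2_(env$m, grads, function(a, g) b1 * a + (1 - b1) * g)
      env$v <- tree_map2_(env$v, grads, function(a, g) b2 * a + (1 - b2) * g^2)
      mhat <- tree_map_(env$m, function(a) a / (1 - b1^env$t))
      vhat <- tree_map_(env$v, function(a) a / (1 - b2^env$t))
      step_leaf <- function(p, mh, vh) p - lr * mh / (sqrt(vh) + eps)
      rec <- function(p, mh, vh) {
        if (is.list(p)) {
          r <- vector("list", length(p)); names(r) <- names(p)
          for (k in seq_along(p)) r[k] <- list(rec(p[[k]], mh[[k]], vh[[k]]))
          r
        } else if (is.null(p)) NULL else step_leaf(p, mh, vh)
      }
      rec(params, mhat, vhat)
    })
  }
}

# ReduceLROnPlateau: reduce lr by `factor` after `patience` consecutive
# epochs without improvement of the monitored quantity (minimized).
make_plateau_scheduler_ <- function(lr0, patience, factor) {
  best <- Inf
  wait <- 0L
  lr <- lr0
  env <- environment()
  list(
    observe = function(value) {
      if (value < env$best) {
        env$best <- value
        env$wait <- 0L
      } else {
        env$wait <- env$wait + 1L
        if (env$wait >= patience) {
          env$lr <- env$lr * factor
          env$wait <- 0L
        }
      }
      env$lr
    },
    lr = function() env$lr
  )
}

# ---------------------------------------------------------------------------

#' Train the dual-stream GAT autoencoder
#'
#' Full-batch training: each epoch runs a forward pass over the whole graph,
#' computes the balanced BCE on training positives (including any injected
#' false edges, which are presented as positives) and matched negatives plus
#' the two MSE reconstruction terms, backpropagates, and takes an optimizer
#' step.  Validation AUC is computed each epoch on the validation
#' positives/negatives; the parameters are snapshotted whenever it improves,
#' and the returned model carries the best checkpoint.  A
#' reduce-on-plateau scheduler monitors the validation loss.
#'
#' The message-passing graph contains the training positives (and injected
#' false edges) only, so validation and test edges are never seen by the
#' encoder.
#'
#' @param model a `dual_gat_model` from [init_model()].
#' @param x_expr expression node features (n x d_expr).
#' @param x_img image node features (n x d_img) or NULL for ablation.
#' @param split an `edge_split`.
#' @param config a [train_config()] or [train_presets()].
#' @param weights a [loss_weights()].
#' @param verbose print per-epoch progress every `verbose` epochs (0 = quiet).
#' @return list of class `trained_model` with `model` (best checkpoint),
#'   `history` (per-epoch data.frame), `best_epoch`, `best_val_auc`, and
#'   `mp_edges` (the message-passing edge set used).
#' @export
train_model <- function(model, x_expr, x_img, split, config = train_presets(),
                        weights = loss_weights(), verbose = 0) {
  stopifnot(inherits(model, "dual_gat_model"), inherits(split, "edge_split"))
  x_expr <- as.matrix(x_expr)
  if (!is.null(x_img)) x_img <- as.matrix(x_img)
  if (!model$use_image) x_img <- NULL

  n <- split$n
  mp_edges <- canon_edges_(rbind(split$train_pos, split$injected_false), n)
  mp <- mp_graph_(mp_edges, n)

  pos_pairs <- rbind(split$train_pos, split$injected_false)
  neg_pairs <- split$train_neg
  val_pairs <- rbind(split$val_pos, split$val_neg)
  val_labels <- c(rep(1, nrow(split$val_pos)), rep(0, nrow(split$val_neg)))

  params <- model$params
  opt <- make_optimizer_(config, trainable_(as_plain_(params)))
  sched <- make_plateau_scheduler_(config$lr, config$plateau_patience,
                                   config$plateau_factor)
  best_val_auc <- -Inf
  best_params <- params
  best_epoch <- NA_integer_
  hist <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    model$params <- params
    lg <- model_loss_grads_(model, x_expr, x_img, mp, pos_pairs, neg_pairs,
                            weights)
    if (!is.finite(lg$losses$total)) {
      stopf_("non-finite training loss at epoch %d (l_reg=%g l_count=%g l_feature=%g)",
             epoch, lg$losses$l_reg, lg$losses$l_count, lg$losses$l_feature)
    }
    lr <- sched$lr()
    new_leaves <- opt$step(trainable_(as_plain_(params)),
                           as_plain_(lg$grads), lr)
    params <- apply_update_(params, new_leaves)

    # validation with the updated parameters
    model$params <- params
    fw <- model_forward_(model, x_expr, x_img, mp)
    val_scores <- pair_scores_(fw$Z, val_pairs)
    val_loss <- bce_loss(val_scores, val_labels, norm = 1)
    val_auc <- auc_roc_rank_(val_scores, val_labels)
    if (val_auc > best_val_auc) {
      best_val_auc <- val_auc
      best_params <- params
      best_epoch <- epoch
    }
    lr_next <- sched$observe(val_loss)
    hist[[epoch]] <- data.frame(
      epoch = epoch, l_reg = lg$losses$l_reg, l_count = lg$losses$l_count,
      l_feature = lg$losses$l_feature, total = lg$losses$total,
      val_loss = val_loss, val_auc = val_auc, lr = lr)
    if (verbose > 0 && epoch %% verbose == 0) {
      message(sprintf("epoch %4d  loss %.4f  val_loss %.4f  val_auc %.4f  lr %.2g",
                      epoch, lg$losses$total, val_loss, val_auc, lr))
    }
  }
  model$params <- best_params
  structure(list(model = model,
                 history = do.call(rbind, hist),
                 best_epoch = best_epoch,
                 best_val_auc = best_val_auc,
                 mp_edges = mp_edges),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d epochs, best val AUC %.4f at epoch %d\n",
              nrow(x$history), x$best_val_auc, x$best_epoch))
  invisible(x)
}

#' Score cell pairs with a trained model
#'
#' Recomputes the fused embeddings over the stored message-passing graph and
#' returns decoder probabilities for the requested pairs (or the full
#' predicted adjacency when `pairs` is NULL).
#'
#' @param trained a `trained_model`.
#' @param x_expr,x_img the node features used in training.
#' @param pairs m x 2 matrix of cell index pairs, or NULL.
#' @return numeric vector of probabilities, or a `predicted_adjacency`.
#' @export
predict_scores <- function(trained, x_expr, x_img = NULL, pairs = NULL) {
  stopifnot(inherits(trained, "trained_model"))
  model <- trained$model
  if (!model$use_image) x_img <- NULL
  mp <- mp_graph_(trained$mp_edges, n = nrow(as.matrix(x_expr)))
  fw <- model_forward_(model, as.matrix(x_expr),
                       if (is.null(x_img)) NULL else as.matrix(x_img), mp)
  if (is.null(pairs)) decode_adjacency(fw$Z) else pair_scores_(fw$Z, pairs)
}

#' Fused embeddings of a trained model
#' @inheritParams predict_scores
#' @return n x d_z matrix Z.
#' @export
embeddings <- function(trained, x_expr, x_img = NULL) {
  model <- trained$model
  if (!model$use_image) x_img <- NULL
  mp <- mp_graph_(trained$mp_edges, n = nrow(as.matrix(x_expr)))
  model_forward_(model, as.matrix(x_expr),
                 if (is.null(x_img)) NULL else as.matrix(x_img), mp)$Z
}
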
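# Gene filtering, image patch extraction and patch featurization.

#' Filter rarely expressed genes
#'
#' Keeps exactly the genes with nonzero expression in at least `min_spots`
#' cells/spots, preserving column order.  With `min_spots = 10` this is the
#' standard low-abundance filter for sparse spatial counts.
#'
#' @param counts non-negative cells-by-genes matrix.
#' @param min_spots minimum number of cells with nonzero expression.
#' @return list with `counts` (filtered matrix) and `kept_gene_ids`
#'   (column names kept, or kept column indices when unnamed).
#' @export
filter_genes <- function(counts, min_spots = 10) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf_("counts contains negative entries")
  n_expressing <- colSums(counts > 0)
  keep <- n_expressing >= min_spots
  if (!any(keep)) {
    stopf_("all %d genes expressed in fewer than %d spots; lower min_spots",
           ncol(counts), min_spots)
  }
  kept <- counts[, keep, drop = FALSE]
  ids <- if (!is.null(colnames(counts))) colnames(counts)[keep] else which(keep)
  list(counts = kept, kept_gene_ids = ids)
}

#' Library-size normalize and log-transform counts
#'
#' Scales each cell to the median library size and applies `log1p`.  These
#' are the expression-stream node features (and the reconstruction target of
#' the expression head).
#'
#' @param counts non-negative cells-by-genes matrix.
#' @return numeric matrix of the same shape.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  lib <- rowSums(counts)
  target <- median(lib[lib > 0])
  if (!is.finite(target) || target <= 0) target <- 1
  fac <- ifelse(lib > 0, target / lib, 0)
  log1p(counts * fac)
}

#' Patch extraction window specification
#'
#' @param W,H patch width and height in pixels (at least 1).
#' @param border_mode `"pad_zero"` fills out-of-image pixels with 0 so the
#'   patch shape is constant; `"clip"` shifts the window fully inside the
#'   image.
#' @return list of class `patch_spec`.
#' @export
patch_spec <- function(W = 64, H = 64, border_mode = c("pad_zero", "clip")) {
  border_mode <- match.arg(border_mode)
  W <- as.integer(W); H <- as.integer(H)
  if (W < 1 || H < 1) stopf_("patch dimensions must be >= 1")
  structure(list(W = W, H = H, border_mode = border_mode),
            class = "patch_spec")
}

#' Extract a local image patch centred on a coordinate
#'
#' Returns the `W` x `H` window centred at continuous 0-based coordinates
#' `(X, Y)` (x along image columns, y along rows) using half-open pixel
#' index ranges `[X - W/2, X + W/2)` by `[Y - H/2, Y + H/2)`.  Windows
#' crossing the image border are zero-padded or shifted inside per
#' `spec$border_mode`.
#'
#' @param image grayscale matrix or h x w x c array.
#' @param X,Y centre coordinates in pixel units.
#' @param spec a [patch_spec()].
#' @return matrix of dim (H, W) (or array (H, W, c)).
#' @export
extract_patch <- function(image, X, Y, spec = patch_spec()) {
  dims <- dim(image)
  h <- dims[1]; w <- dims[2]
  nc <- if (length(dims) == 3) dims[3] else 1L
  if (X < 0 || X >= w || Y < 0 || Y >= h) {
    stopf_("patch centre (%g, %g) outside image bounds", X, Y)
  }
  x0 <- floor(X - spec$W / 2)  # 0-based first column
  y0 <- floor(Y - spec$H / 2)
  if (spec$border_mode == "clip") {
    if (spec$W > w || spec$H > h) {
      stopf_("patch (%d x %d) larger than image (%d x %d) in clip mode",
             spec$W, spec$H, w, h)
    }
    x0 <- min(max(x0, 0), w - spec$W)
    y0 <- min(max(y0, 0), h - spec$H)
  }
  cols <- x0 + seq_len(spec$W)       # 1-based image columns
  rows <- y0 + seq_len(spec$H)
  ok_c <- cols >= 1 & cols <= w
  ok_r <- rows >= 1 & rows <= h
  out <- array(0, dim = c(spec$H, spec$W, nc))
  img3 <- if (nc == 1L) array(image, dim = c(h, w, 1L)) else image
  out[which(ok_r), which(ok_c), ] <- img3[rows[ok_r], cols[ok_c], , drop = FALSE]
  if (nc == 1L) out <- out[, , 1] else out
  out
}

#' Mean-pool patch featurizer
#'
#' A deterministic, training-free featurizer: the patch is averaged over
#' channels, divided into a `grid` x `grid` block partition, and the block
#' means are flattened into a feature vector of length `grid^2`.  Serves as
#' the default lightweight stand-in satisfying the pluggable featurizer
#' contract (any deterministic patch -> fixed-length-vector map, e.g. a
#' frozen pretrained CNN's penultimate layer).
#'
#' @param grid number of blocks per side.
#' @return function(patch) -> numeric vector of length `grid^2`.
#' @export
make_meanpool_featurizer <- function(grid = 4) {
  grid <- as.integer(grid)
  if (grid < 1) stopf_("grid must be >= 1")
  function(patch) {
    if (length(dim(patch)) == 3) patch <- apply(patch, c(1, 2), mean)
    h <- nrow(patch); w <- ncol(patch)
    if (h < grid || w < grid) {
      stopf_("patch (%d x %d) smaller than pooling grid (%d)", h, w, grid)
    }
    rb <- pmin(ceiling(seq_len(h) / (h / grid)), grid)
    cb <- pmin(ceiling(seq_len(w) / (w / grid)), grid)
    sums <- rowsum(t(rowsum(patch, rb)), cb)  # grid x grid block sums (t)
    cnt <- tabulate(rb, grid) %o% tabulate(cb, grid)
    as.vector(t(sums) / cnt)  # row-major over (row block, col block)
  }
}

#' Featurize a list of patches into an image feature matrix
#'
#' @param patches list of patches (one per cell, in cell order).
#' @param featurizer deterministic function patch -> fixed-length numeric
#'   vector.
#' @return list of class `image_feature_matrix` with `values` (n x d_img),
#'   `d_img` and `featurizer_name`.
#' @export
featurize_patches <- function(patches, featurizer = make_meanpool_featurizer()) {
  feats <- lapply(patches, featurizer)
  lens <- lengths(feats)
  if (length(unique(lens)) > 1) {
    stopf_("featurizer output length varies across patches (%s)",
           paste(unique(lens), collapse = ", "))
  }
  values <- do.call(rbind, feats)
  if (!all(is.finite(values))) stopf_("non-finite image features")
  structure(list(values = values, d_img = ncol(values),
                 featurizer_name = attr(featurizer, "name") %||% "custom"),
            class = "image_feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract and featurize patches for every cell of a dataset
#'
#' @param dataset a [spatial_dataset()] with an image.
#' @param spec a [patch_spec()].
#' @param featurizer see [featurize_patches()].
#' @return an `image_feature_matrix`.
#' @export
image_features <- function(dataset, spec = patch_spec(),
                           featurizer = make_meanpool_featurizer()) {
  if (is.null(dataset$image)) stopf_("dataset has no image")
  patches <- lapply(seq_along(dataset$cell_ids), function(i) {
    extract_patch(dataset$image, dataset$coords[i, "x"],
                  dataset$coords[i, "y"], spec)
  })
  featurize_patches(patches, featurizer)
}
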
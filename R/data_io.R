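# Loading, validation and serialization of spatial datasets and run outputs.

#' Construct a spatial dataset
#'
#' Bundles the modalities of one tissue sample: 2-D coordinates per cell or
#' spot, a cells-by-genes count matrix, an optional aligned tissue image and
#' optional cell-type annotations.  Coordinates share the image pixel unit
#' when an image is present (x maps to image columns, y to rows, both
#' 0-based continuous).
#'
#' @param cell_ids character vector of unique cell/spot identifiers.
#' @param coords numeric matrix with one row per cell and columns x, y.
#' @param counts non-negative integer matrix, cells in rows, genes in columns.
#' @param gene_ids character vector of unique gene identifiers.
#' @param image optional numeric matrix (grayscale) or h x w x 3 array with
#'   intensities in \[0, 1\].
#' @param cell_types optional character/factor vector of per-cell labels.
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(cell_ids, coords, counts, gene_ids,
                            image = NULL, cell_types = NULL) {
  cell_ids <- as.character(cell_ids)
  coords <- as.matrix(coords)
  counts <- as.matrix(counts)
  gene_ids <- as.character(gene_ids)
  n <- length(cell_ids)
  if (nrow(coords) != n || ncol(coords) != 2) {
    stopf_("coords must be a %d x 2 matrix (one row per cell)", n)
  }
  if (nrow(counts) != n) {
    stopf_("counts has %d rows but there are %d cells", nrow(counts), n)
  }
  if (ncol(counts) != length(gene_ids)) {
    stopf_("counts has %d columns but %d gene ids", ncol(counts), length(gene_ids))
  }
  if (anyDuplicated(cell_ids)) stopf_("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stopf_("duplicate gene ids")
  if (any(counts < 0)) stopf_("counts contains negative entries")
  colnames(coords) <- c("x", "y")
  rownames(coords) <- cell_ids
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (!is.null(cell_types)) {
    if (length(cell_types) != n) stopf_("cell_types length mismatch")
    cell_types <- factor(as.character(cell_types))
    names(cell_types) <- cell_ids
  }
  if (!is.null(image)) {
    dims <- dim(image)
    if (!(length(dims) == 2 || (length(dims) == 3 && dims[3] %in% c(3, 4)))) {
      stopf_("image must be a matrix or an h x w x 3 array")
    }
    h <- dims[1]; w <- dims[2]
    bad <- which(coords[, "x"] < 0 | coords[, "x"] >= w |
                   coords[, "y"] < 0 | coords[, "y"] >= h)
    if (length(bad)) {
      stopf_("coordinates outside image bounds for cells: %s",
             paste(cell_ids[bad], collapse = ", "))
    }
  }
  structure(
    list(cell_ids = cell_ids, coords = coords, counts = counts,
         gene_ids = gene_ids, image = image, cell_types = cell_types),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d cells x %d genes\n",
              length(x$cell_ids), length(x$gene_ids)))
  cat(sprintf("  image: %s   cell types: %s\n",
              if (is.null(x$image)) "none" else paste(dim(x$image), collapse = "x"),
              if (is.null(x$cell_types)) "none" else nlevels(x$cell_types)))
  invisible(x)
}

#' Load a spatial dataset from disk
#'
#' Reads a coordinate table, a count matrix (dense CSV or Matrix Market
#' triplet with id sidecars), and optional image and cell-type annotation
#' files.  Cells are ordered as in the coordinate file and the counts are
#' reindexed to that order; id mismatches between files are reported by name.
#'
#' @param coords_path CSV/TSV with columns `cell_id`, `x`, `y`.
#' @param counts_path dense CSV (first column = row ids, header = column ids)
#'   or an `.mtx` Matrix Market file with sidecars `<stem>_rows.txt` and
#'   `<stem>_cols.txt` holding row and column identifiers, one per line.
#' @param image_path optional PNG or TIFF aligned to the coordinate frame.
#' @param types_path optional CSV with columns `cell_id`, `cell_type`.
#' @param orientation `"cells_x_genes"` (default) or `"genes_x_cells"`;
#'   internal canonical form is cells-by-genes.
#' @param flip_y if TRUE, y is interpreted as measured from the bottom of the
#'   image rather than the top and is flipped to image row convention.
#' @return A validated [spatial_dataset()].
#' @export
load_dataset <- function(coords_path, counts_path, image_path = NULL,
                         types_path = NULL,
                         orientation = c("cells_x_genes", "genes_x_cells"),
                         flip_y = FALSE) {
  orientation <- match.arg(orientation)
  for (p in c(coords_path, counts_path, image_path, types_path)) {
    if (!is.null(p) && !file.exists(p)) stopf_("file not found: %s", p)
  }
  sep <- if (grepl("\\.tsv$", coords_path)) "\t" else ","
  ctab <- read.csv(coords_path, sep = sep, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(ctab))) {
    stopf_("coordinate file must have columns cell_id, x, y")
  }
  cell_ids <- as.character(ctab$cell_id)
  coords <- cbind(x = as.numeric(ctab$x), y = as.numeric(ctab$y))

  cm <- read_counts_(counts_path)
  if (orientation == "genes_x_cells") {
    cm$mat <- t(cm$mat)
    tmp <- cm$row_ids; cm$row_ids <- cm$col_ids; cm$col_ids <- tmp
  }
  missing_cells <- setdiff(cell_ids, cm$row_ids)
  extra_cells <- setdiff(cm$row_ids, cell_ids)
  if (length(missing_cells) || length(extra_cells)) {
    stopf_("cell id mismatch between coordinates and counts%s%s",
           if (length(missing_cells))
             paste0("; missing from counts: ",
                    paste(missing_cells, collapse = ", ")) else "",
           if (length(extra_cells))
             paste0("; absent from coordinates: ",
                    paste(extra_cells, collapse = ", ")) else "")
  }
  counts <- cm$mat[match(cell_ids, cm$row_ids), , drop = FALSE]
  if (any(counts < 0)) stopf_("counts contains negative entries")

  image <- if (!is.null(image_path)) read_image_(image_path) else NULL
  if (!is.null(image) && flip_y) {
    coords[, "y"] <- dim(image)[1] - coords[, "y"]
  }

  cell_types <- NULL
  if (!is.null(types_path)) {
    tt <- read.csv(types_path, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "cell_type") %in% names(tt))) {
      stopf_("type annotation file must have columns cell_id, cell_type")
    }
    idx <- match(cell_ids, as.character(tt$cell_id))
    if (anyNA(idx)) {
      stopf_("cells without type annotation: %s",
             paste(cell_ids[is.na(idx)], collapse = ", "))
    }
    cell_types <- tt$cell_type[idx]
  }
  spatial_dataset(cell_ids, coords, counts, cm$col_ids,
                  image = image, cell_types = cell_types)
}

read_counts_ <- function(path) {
  if (grepl("\\.mtx$", path)) {
    mat <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rows_p <- paste0(stem, "_rows.txt")
    cols_p <- paste0(stem, "_cols.txt")
    if (!file.exists(rows_p) || !file.exists(cols_p)) {
      stopf_("MTX sidecars not found: %s / %s", rows_p, cols_p)
    }
    row_ids <- readLines(rows_p)
    col_ids <- readLines(cols_p)
    if (length(row_ids) != nrow(mat) || length(col_ids) != ncol(mat)) {
      stopf_("MTX sidecar lengths do not match matrix dimensions")
    }
    list(mat = mat, row_ids = row_ids, col_ids = col_ids)
  } else {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    row_ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    list(mat = mat, row_ids = row_ids, col_ids = colnames(df)[-1])
  }
}

read_image_ <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stopf_("reading TIFF images requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stopf_("unsupported image format: %s", path)
  }
}

#' Write a spatial dataset to a directory
#'
#' Emits the on-disk formats that [load_dataset()] reads back: `coords.csv`,
#' `counts.mtx` with id sidecars, optionally `image.png` and `types.csv`.
#'
#' @param dataset a [spatial_dataset()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(cell_id = dataset$cell_ids,
                       x = dataset$coords[, "x"],
                       y = dataset$coords[, "y"]),
            file.path(dir, "coords.csv"), row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(dataset$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(dataset$cell_ids, file.path(dir, "counts_rows.txt"))
  writeLines(dataset$gene_ids, file.path(dir, "counts_cols.txt"))
  if (!is.null(dataset$image)) {
    png::writePNG(dataset$image, file.path(dir, "image.png"))
  }
  if (!is.null(dataset$cell_types)) {
    write.csv(data.frame(cell_id = dataset$cell_ids,
                         cell_type = as.character(dataset$cell_types)),
              file.path(dir, "types.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Save run artifacts with a hashed manifest
#'
#' Writes whichever artifacts are supplied — an edge list (CSV), a metrics
#' report (JSON), embeddings and adjacency (dense CSV arrays), a training
#' history (CSV), and a configuration (JSON) — then a `manifest.json`
#' listing every file with its MD5 content hash.  Re-loading with the
#' matching `load_*` helpers reproduces the objects.
#'
#' @param report_dir writable output directory (created if needed).
#' @param edges optional data.frame with columns cell_a, cell_b, score,
#'   label, split, is_injected.
#' @param metrics optional `metrics_report` or plain list.
#' @param embeddings optional numeric matrix.
#' @param adjacency optional numeric matrix.
#' @param history optional data.frame of per-epoch training records.
#' @param config optional list, serialized as JSON.
#' @param mode optional run-mode tag (e.g. `"full"` or `"ablation"`)
#'   recorded in the manifest.
#' @return Invisibly, the manifest as a list with `mode` and `files`
#'   (data.frame of file, md5).
#' @export
save_outputs <- function(report_dir, edges = NULL, metrics = NULL,
                         embeddings = NULL, adjacency = NULL,
                         history = NULL, config = NULL, mode = NULL) {
  ok <- dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(report_dir)) stopf_("cannot create directory %s", report_dir)
  files <- character(0)
  wr <- function(fn) { files[[length(files) + 1]] <<- fn; file.path(report_dir, fn) }
  if (!is.null(edges)) {
    write.csv(edges, wr("edges.csv"), row.names = FALSE)
  }
  if (!is.null(metrics)) {
    writeLines(jsonlite::toJSON(metrics_to_list_(metrics), auto_unbox = TRUE,
                                pretty = TRUE, digits = NA, null = "null",
                                na = "null"),
               wr("metrics.json"))
  }
  if (!is.null(embeddings)) {
    write_array_(embeddings, wr("embeddings.csv"))
  }
  if (!is.null(adjacency)) {
    write_array_(adjacency, wr("adjacency.csv"))
  }
  if (!is.null(history)) {
    write.csv(history, wr("history.csv"), row.names = FALSE)
  }
  if (!is.null(config)) {
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null", force = TRUE),
               wr("config.json"))
  }
  md5 <- unname(tools::md5sum(file.path(report_dir, unlist(files))))
  manifest <- list(mode = mode %||% "full",
                   files = data.frame(file = unlist(files), md5 = md5,
                                      stringsAsFactors = FALSE))
  writeLines(jsonlite::toJSON(manifest, pretty = TRUE, auto_unbox = TRUE),
             file.path(report_dir, "manifest.json"))
  invisible(manifest)
}

metrics_to_list_ <- function(m) {
  keys <- c("auc_roc", "accuracy", "f1", "auc_prc", "average_precision",
            "tp", "fp", "tn", "fn", "n_pos", "n_neg", "threshold")
  out <- setNames(vector("list", length(keys)), keys)
  for (k in keys) out[[k]] <- if (is.null(m[[k]])) NA else m[[k]]
  out
}

write_array_ <- function(x, path) {
  utils::write.table(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' Read back an array written by [save_outputs()]
#' @param path CSV array file.
#' @return numeric matrix.
#' @export
load_array <- function(path) {
  as.matrix(read.csv(path, header = FALSE))
}

#' Read back an edge list written by [save_outputs()]
#' @param path edges.csv path.
#' @return data.frame.
#' @export
load_edge_list <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read back a metrics report written by [save_outputs()]
#' @param path metrics.json path.
#' @return named list.
#' @export
load_metrics <- function(path) {
  jsonlite::fromJSON(path)
}
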
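# Biology-facing summaries of the reconstructed communication network:
# predicted interactions, distal-edge calls, communication strength.

#' Threshold the predicted adjacency into an interaction edge list
#'
#' @param A_prime n x n symmetric probability matrix ([decode_adjacency()]).
#' @param threshold probability cutoff; pairs with `A'_ij >= threshold` are
#'   called interactions.
#' @param exclude_diagonal ignore self-pairs (default TRUE; self-
#'   communication is undefined).
#' @return data.frame with columns i, j (i < j) and score.
#' @export
predict_interactions <- function(A_prime, threshold = 0.5,
                                 exclude_diagonal = TRUE) {
  A_prime <- unclass(A_prime)
  n <- nrow(A_prime)
  ut <- upper.tri(A_prime, diag = !exclude_diagonal)
  hits <- which(ut & A_prime >= threshold, arr.ind = TRUE)
  data.frame(i = hits[, 1], j = hits[, 2],
             score = A_prime[hits])
}

#' Call distal (non-contact) interactions
#'
#' Returns the predicted edges that are not present in the spatial contact
#' graph and whose Euclidean length exceeds the given quantile of the
#' contact-edge length distribution.  Distal calls are the interactions the
#' contact graph could not have supplied and are the candidates for
#' long-range (e.g. cytokine-mediated) communication.
#'
#' @param predicted_edges data.frame from [predict_interactions()].
#' @param graph the spatial contact `cell_graph`.
#' @param coords n x 2 coordinate matrix.
#' @param distance_quantile quantile of contact-edge lengths a distal edge
#'   must exceed (default 0.95); `min_distance` may be given instead.
#' @param min_distance absolute distance cutoff overriding the quantile.
#' @param cell_types optional per-cell labels carried onto the output.
#' @return data.frame with columns i, j, score, distance (and type_i,
#'   type_j when labels are given); a subset of `predicted_edges`.
#' @export
call_distal_edges <- function(predicted_edges, graph, coords,
                              distance_quantile = 0.95, min_distance = NULL,
                              cell_types = NULL) {
  coords <- as.matrix(coords)
  n <- graph$n
  if (nrow(predicted_edges) == 0) {
    return(cbind(predicted_edges, distance = numeric(0)))
  }
  contact_keys <- pair_key_(graph$edges[, 1], graph$edges[, 2], n)
  pred_keys <- pair_key_(predicted_edges$i, predicted_edges$j, n)
  non_contact <- !(pred_keys %in% contact_keys)
  edge_len <- function(i, j) {
    sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
  }
  cutoff <- if (!is.null(min_distance)) {
    min_distance
  } else {
    contact_len <- edge_len(graph$edges[, 1], graph$edges[, 2])
    quantile(contact_len, distance_quantile, names = FALSE)
  }
  d <- edge_len(predicted_edges$i, predicted_edges$j)
  keep <- non_contact & d > cutoff
  out <- predicted_edges[keep, , drop = FALSE]
  out$distance <- d[keep]
  if (!is.null(cell_types)) {
    out$type_i <- as.character(cell_types)[out$i]
    out$type_j <- as.character(cell_types)[out$j]
  }
  rownames(out) <- NULL
  out
}

#' Communication strength between cells and cell types
#'
#' Communication strength of cell i towards type t is the proportion of
#' communication edges between that cell and cells of type t out of all
#' cell-to-type-t edge incidences:
#' `strength(i, t) = n(i, t) / D(t)` with `n(i, t)` the number of edges
#' joining cell i to a cell of type t and `D(t) = sum_i n(i, t)` (so each
#' column sums to 1 whenever type t has any edges; within-type edges count
#' once per endpoint).  Type-level strength aggregates cell strengths over
#' the cells of each type, and the counts matrix tallies edges by unordered
#' endpoint-type pair.
#'
#' @param edges data.frame with columns i, j (e.g. from
#'   [predict_interactions()]).
#' @param cell_types per-cell type labels covering every endpoint.
#' @return list of class `communication_summary` with
#'   `cell_by_type_strength` (n x T), `type_by_type_strength` (T x T),
#'   `type_by_type_counts` (T x T, symmetric), and `n_edges`.
#' @export
communication_strength <- function(edges, cell_types) {
  cell_types <- factor(cell_types)
  n <- length(cell_types)
  types <- levels(cell_types)
  t_n <- length(types)
  untyped <- which(is.na(cell_types))
  if (length(untyped)) {
    stopf_("cells without type label: %s", paste(untyped, collapse = ", "))
  }
  S <- matrix(0, n, t_n, dimnames = list(names(cell_types), types))
  C <- matrix(0L, t_n, t_n, dimnames = list(types, types))
  m <- nrow(edges)
  if (m > 0) {
    ti <- as.integer(cell_types[edges$i])
    tj <- as.integer(cell_types[edges$j])
    # incidences: edge (i, j) joins cell i to type(j) and cell j to type(i)
    for (r in seq_len(m)) {
      S[edges$i[r], tj[r]] <- S[edges$i[r], tj[r]] + 1
      S[edges$j[r], ti[r]] <- S[edges$j[r], ti[r]] + 1
      a <- min(ti[r], tj[r]); b <- max(ti[r], tj[r])
      C[a, b] <- C[a, b] + 1L
      if (a != b) C[b, a] <- C[b, a] + 1L
    }
    D <- colSums(S)
    for (t in seq_len(t_n)) if (D[t] > 0) S[, t] <- S[, t] / D[t]
  }
  TT <- rowsum(S, cell_types)  # type-level aggregation of cell strengths
  structure(list(cell_by_type_strength = S,
                 type_by_type_strength = as.matrix(TT),
                 type_by_type_counts = C,
                 n_edges = m),
            class = "communication_summary")
}

#' @export
print.communication_summary <- function(x, ...) {
  cat(sprintf("<communication_summary> %d edges, %d types\n",
              x$n_edges, ncol(x$cell_by_type_strength)))
  print(x$type_by_type_counts)
  invisible(x)
}
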
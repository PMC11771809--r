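# Internal numerical helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds deterministically, and restores the
#' state on exit so package functions never clobber user RNG streams.
#' @noRd
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

leaky_relu_ <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

elu_ <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

# derivative of ELU wrt its pre-activation
elu_grad_ <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

#' Glorot (fan-balanced) uniform initialisation
#' @noRd
glorot_ <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# unique integer key for an unordered pair, used for edge set algebra
pair_key_ <- function(i, j, n) {
  a <- pmin(i, j)
  b <- pmax(i, j)
  (a - 1) * n + b
}

# canonicalize an m x 2 edge matrix to i < j rows, deduplicated, sorted
canon_edges_ <- function(edges, n) {
  if (length(edges) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- (a - 1) * n + b
  o <- order(key)
  dup <- duplicated(key[o])
  out <- cbind(i = a[o][!dup], j = b[o][!dup])
  out
}

stopf_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
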
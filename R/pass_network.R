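#' Construct a weighted directed pass network
#'
#' A `pass_network` is the package's single source of truth for all metrics:
#' an ordered set of node labels plus a square non-negative weight matrix `W`
#' in which rows index the sender and columns the receiver, so `W[i, j]` is
#' the weight (typically the pass count) of the arc from node `i` to node `j`.
#'
#' Two validation profiles are supported. The default `"sports"` profile
#' additionally requires a zero diagonal, because a player cannot pass to
#' themself; the `"general"` profile admits self-loops, for which every
#' metric remains well defined.
#'
#' @param W A square numeric matrix (or object coercible to one, such as a
#'   data frame with one row per sender) of non-negative weights.
#' @param labels Optional character vector of node labels. Defaults to the
#'   dimnames of `W`, or `"n1"`, `"n2"`, ... when `W` carries none.
#' @param profile Validation profile, `"sports"` (zero diagonal, default) or
#'   `"general"`.
#'
#' @return An object of class `pass_network`: a list with elements `labels`
#'   (character), `W` (matrix with dimnames set to the labels), `n` (node
#'   count) and `profile`.
#'
#' @examples
#' W <- matrix(c(0, 5, 2, 0), 2, 2, byrow = TRUE)
#' g <- pass_network(W, labels = c("a", "b"))
#' total_weight(g)
#' @export
pass_network <- function(W, labels = NULL, profile = c("sports", "general")) {
  profile <- match.arg(profile)
  if (is.data.frame(W)) W <- as.matrix(W)
  if (!is.matrix(W) || !is.numeric(W)) {
    abort("`W` must be a numeric matrix.", class = "passentropy_invalid")
  }
  if (nrow(W) != ncol(W)) {
    abort(
      sprintf("Adjacency matrix must be square; got %d rows and %d columns.",
              nrow(W), ncol(W)),
      class = "passentropy_not_square"
    )
  }
  n <- nrow(W)
  if (n < 2) {
    abort("A pass network needs at least 2 nodes.", class = "passentropy_invalid")
  }
  if (is.null(labels)) {
    labels <- rownames(W) %||% paste0("n", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    abort(
      sprintf("Got %d labels for a %d-node network.", length(labels), n),
      class = "passentropy_invalid"
    )
  }
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1]
    abort(sprintf("Duplicate node label: \"%s\".", dup),
          class = "passentropy_duplicate_label")
  }
  if (anyNA(W)) {
    idx <- which(is.na(W), arr.ind = TRUE)[1, ]
    abort(
      sprintf("Missing weight at cell (%s -> %s).",
              labels[idx[1]], labels[idx[2]]),
      class = "passentropy_missing_value"
    )
  }
  if (any(W < 0)) {
    idx <- which(W < 0, arr.ind = TRUE)[1, ]
    abort(
      sprintf("Negative weight %g at cell (%s -> %s).",
              W[idx[1], idx[2]], labels[idx[1]], labels[idx[2]]),
      class = "passentropy_negative_weight"
    )
  }
  if (profile == "sports" && any(diag(W) != 0)) {
    i <- which(diag(W) != 0)[1]
    abort(
      sprintf(
        "Self-loop weight %g on node \"%s\" (node %d) is not allowed under the sports profile.",
        diag(W)[i], labels[i], i),
      class = "passentropy_self_loop"
    )
  }
  if (sum(W) <= 0) {
    abort("Total network weight must be positive.",
          class = "passentropy_zero_weight")
  }
  dimnames(W) <- list(labels, labels)
  structure(
    list(labels = labels, W = W, n = n, profile = profile),
    class = "pass_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pass_network <- function(x, ...) {
  cat(sprintf("<pass_network: %d nodes, total weight %g, profile \"%s\">\n",
              x$n, sum(x$W), x$profile))
  cat("nodes:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Strengths and total weight of a pass network
#'
#' `out_strength()` and `in_strength()` return the row and column sums of the
#' weight matrix (passes made and received per node); `total_weight()` returns
#' the grand total `L`, the denominator of every probability in the metric
#' formulas.
#'
#' @param G A [pass_network].
#' @return A named numeric vector (strengths) or a scalar (total weight).
#' @export
out_strength <- function(G) {
  stopifnot(inherits(G, "pass_network"))
  rowSums(G$W)
}

#' @rdname out_strength
#' @export
in_strength <- function(G) {
  stopifnot(inherits(G, "pass_network"))
  colSums(G$W)
}

#' @rdname out_strength
#' @export
total_weight <- function(G) {
  stopifnot(inherits(G, "pass_network"))
  sum(G$W)
}

#' Transpose a pass network
#'
#' Reverses every arc: the transposed network has `W[j, i]` passes from `i`
#' to `j`. Under the documented duality every in-metric of `G` equals the
#' corresponding out-metric of `transpose_network(G)`.
#'
#' @param G A [pass_network].
#' @return A [pass_network] with the transposed weight matrix.
#' @export
transpose_network <- function(G) {
  stopifnot(inherits(G, "pass_network"))
  pass_network(t(G$W), labels = G$labels, profile = G$profile)
}

#' Convert a pass network to a tidy arc table
#'
#' @param x A [pass_network].
#' @param drop_zero Drop arcs of weight zero (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `sender`, `receiver`, `weight`.
#' @method tidy pass_network
#' @export
tidy.pass_network <- function(x, drop_zero = TRUE, ...) {
  out <- tibble(
    sender = rep(x$labels, times = x$n),
    receiver = rep(x$labels, each = x$n),
    weight = as.vector(x$W)
  )
  if (drop_zero) out <- out[out$weight > 0, ]
  out
}
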
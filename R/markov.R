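#' Markov transition matrix of a pass network
#'
#' Row-normalizes the weight matrix by out-strength: `M[i, j]` is the
#' probability that the next pass made by node `i` goes to node `j`. Rows
#' with zero out-strength (a player who never passed, e.g. a very late
#' substitute) have no conditional distribution; they are left all-zero and
#' flagged in `defined_rows`, and the `0 * log2(0) = 0` convention keeps
#' every entropy sum finite.
#'
#' @param G A [pass_network].
#' @return An object of class `transition_matrix`: list with `M` (row-
#'   stochastic matrix on defined rows), `defined_rows` (logical mask of
#'   rows with positive out-strength) and `labels`.
#'
#' @examples
#' g <- pass_network(matrix(c(0, 5, 0, 0), 2, 2, byrow = TRUE), c("a", "b"))
#' transition_matrix(g)$M
#' @export
transition_matrix <- function(G) {
  stopifnot(inherits(G, "pass_network"))
  s <- rowSums(G$W)
  defined <- s > 0
  M <- G$W * 0
  if (any(defined)) {
    M[defined, ] <- G$W[defined, , drop = FALSE] / s[defined]
  }
  structure(
    list(M = M, defined_rows = defined, labels = G$labels),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix: %d nodes, %d defined row(s)>\n",
              length(x$labels), sum(x$defined_rows)))
  print(round(x$M, 4))
  invisible(x)
}

#' k-step transition matrix
#'
#' Computes `M^k` by iterated matrix multiplication (`k` is small in
#' practice; no eigendecomposition is used). Rows that were defined remain
#' substochastic; their sums stay 1 as long as no undefined row is reachable.
#'
#' @param MT A `transition_matrix` from [transition_matrix()], or a plain
#'   square numeric matrix.
#' @param k Positive integer number of steps.
#' @return The `k`-step transition matrix (plain matrix).
#' @export
k_step <- function(MT, k) {
  M <- if (inherits(MT, "transition_matrix")) MT$M else MT
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != as.integer(k)) {
    abort("`k` must be a positive integer.", class = "passentropy_invalid")
  }
  out <- M
  for (step in seq_len(k - 1)) out <- out %*% M
  out
}

#' Propagate a state distribution k steps
#'
#' Returns `p0 %*% M^k`, the probability of each node holding the ball after
#' `k` passes, starting from distribution `p0`. If probability mass reaches
#' an undefined (zero out-strength) row before the final step, the result
#' sums to less than one and a warning reports the lost mass.
#'
#' @param p0 Numeric vector of length `n`; non-negative, summing to 1
#'   (within 1e-9).
#' @param MT A `transition_matrix` or plain stochastic matrix.
#' @param k Positive integer number of steps.
#' @return Numeric state vector of length `n` (named when labels are known).
#' @export
propagate <- function(p0, MT, k) {
  M <- if (inherits(MT, "transition_matrix")) MT$M else MT
  if (!is.numeric(p0) || length(p0) != nrow(M) || any(p0 < 0) ||
      abs(sum(p0) - 1) > 1e-9) {
    abort("`p0` must be a probability vector over the network's nodes.",
          class = "passentropy_invalid")
  }
  p <- as.vector(p0 %*% k_step(M, k))
  if (sum(p) < 1 - 1e-9) {
    warn(sprintf("Probability mass %.6g lost to zero out-strength nodes.",
                 1 - sum(p)))
  }
  if (inherits(MT, "transition_matrix")) names(p) <- MT$labels
  p
}
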
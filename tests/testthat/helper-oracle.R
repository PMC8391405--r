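# Independent brute-force implementations of every metric, written as the
# literal sums over the joint distribution w_ij / L with explicit loops.
# These deliberately share no code with the package internals.

oracle_xlog2 <- function(x) if (x > 0) x * log2(x) else 0

oracle_trans <- function(W) {
  n <- nrow(W)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + W[i, j]
    if (s > 0) for (j in seq_len(n)) M[i, j] <- W[i, j] / s
  }
  M
}

oracle_node_rate_out <- function(W, i) {
  L <- sum(W)
  M <- oracle_trans(W)
  si <- 0
  for (j in seq_len(ncol(W))) si <- si + W[i, j]
  acc <- 0
  for (j in seq_len(ncol(W))) acc <- acc + (si / L) * oracle_xlog2(M[i, j])
  -acc
}

# literal reading of the reception substitution: w_ij -> w_ji, m_ij -> m_ji
# with M still the row-stochastic matrix of W
oracle_node_rate_in_literal <- function(W, i) {
  L <- sum(W)
  M <- oracle_trans(W)
  ti <- 0
  for (j in seq_len(nrow(W))) ti <- ti + W[j, i]
  acc <- 0
  for (j in seq_len(nrow(W))) acc <- acc + (ti / L) * oracle_xlog2(M[j, i])
  -acc
}

# conditional reading: row-normalize the transposed matrix first
oracle_node_rate_in_conditional <- function(W, i) {
  oracle_node_rate_out(t(W), i)
}

oracle_en_out <- function(W) {
  L <- sum(W)
  n <- nrow(W)
  acc <- 0
  for (i in seq_len(n)) {
    si <- 0
    for (j in seq_len(n)) si <- si + W[i, j]
    for (j in seq_len(n)) {
      if (W[i, j] > 0) acc <- acc + (W[i, j] / L) * log2(si / L)
    }
  }
  -acc
}

oracle_en_in <- function(W) oracle_en_out(t(W))

oracle_rn_out <- function(W) {
  acc <- 0
  for (i in seq_len(nrow(W))) acc <- acc + oracle_node_rate_out(W, i)
  acc
}

oracle_rn_in <- function(W, variant = "literal") {
  f <- if (variant == "literal") oracle_node_rate_in_literal
       else oracle_node_rate_in_conditional
  acc <- 0
  for (i in seq_len(nrow(W))) acc <- acc + f(W, i)
  acc
}

oracle_cn_out <- function(W, variant = "literal") {
  oracle_en_out(W) - oracle_rn_in(W, variant)
}

oracle_cn_in <- function(W, variant = "literal") {
  oracle_en_in(W) - oracle_rn_out(W)
}

# textbook mutual information of the sender-receiver joint w_ij / L
oracle_mutual_information <- function(W) {
  L <- sum(W)
  n <- nrow(W)
  p <- rowSums(W) / L
  q <- colSums(W) / L
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pij <- W[i, j] / L
      if (pij > 0) acc <- acc + pij * log2(pij / (p[i] * q[j]))
    }
  }
  acc
}

# random sports-profile pass matrix with every node active
random_pass_matrix <- function(n, max_count = 9) {
  repeat {
    W <- matrix(sample(0:max_count, n * n, replace = TRUE), n, n)
    diag(W) <- 0
    if (sum(W) > 0 && all(rowSums(W) > 0) && all(colSums(W) > 0)) return(W)
  }
}

# random matrix allowed to contain silent rows/columns
random_sparse_matrix <- function(n, max_count = 6, p_zero = 0.5) {
  repeat {
    W <- matrix(sample(0:max_count, n * n, replace = TRUE) *
                  rbinom(n * n, 1, 1 - p_zero), n, n)
    diag(W) <- 0
    if (sum(W) > 0) return(W)
  }
}
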
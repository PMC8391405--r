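#' Entropy-based variability metrics
#'
#' @description
#' These functions implement the family of variability metrics for weighted
#' directed networks derived from the Markov transition matrix `M` of the
#' weight matrix `W`. Writing `s_i` for node `i`'s out-strength, `t_i` for
#' its in-strength, `L` for the total weight, `p_i = s_i / L` and
#' `q_i = t_i / L`:
#'
#' * `node_rate_out(G, i)` — the rate of passing of node `i`,
#'   `R_out(i) = p_i * H(M[i, ])` in bits, where `H` is the base-2 Shannon
#'   entropy: the node's share of all passes times the entropy of its
#'   outgoing target distribution.
#' * `node_rate_in(G, i, variant)` — the rate of reception. The dual
#'   substitution (swap `w_ij` with `w_ji`, `m_ij` with `m_ji`) admits two
#'   readings, both provided:
#'   `"literal"` (default) keeps `M` as the row-stochastic matrix of `W` and
#'   sums column `i`: `R_in(i) = -q_i * sum_j m_ji log2 m_ji`;
#'   `"conditional"` row-normalizes the transposed matrix first, so
#'   `R_in(i) = q_i * H(C[i, ])` with `C = transition_matrix(t(W))`, which
#'   makes the network rate of reception a conditional entropy `H(X|Y)`.
#' * `node_index_out()` / `node_index_in()` — the same rates divided by
#'   `log2 n`, mapping them onto a `[0, 1]` scale.
#' * `network_rate_out()` / `network_rate_in()` — sums of the node rates.
#' * `network_index_out()` / `network_index_in()` — network rates over
#'   `log2 n`.
#' * `total_entropy_out()` / `total_entropy_in()` — marginal entropies of
#'   the sender / receiver distributions, `H(p)` and `H(q)`.
#' * `capacity_out(G, variant)` — `CN_out = EN_out - RN_in`; under the
#'   literal variant this is signed (negative values indicate passing
#'   patterns more stable than reception patterns), under the conditional
#'   variant it equals the transmitter–receiver mutual information
#'   `I(X; Y) >= 0`.
#' * `capacity_in(G, variant)` — `CN_in = EN_in - RN_out`.
#' * `capacity_index_out()` / `capacity_index_in()` — `|CN| / log2 n`.
#'
#' Throughout, `0 * log2(0) = 0`, so nodes with zero out- (or in-) strength
#' contribute nothing, and `n` in every `log2 n` denominator is the
#' dimension of the supplied matrix — substitutes included — never the
#' number of active nodes.
#'
#' @param G A [pass_network].
#' @param i Node index (1-based) or node label.
#' @param variant Reception variant, `"literal"` (default) or
#'   `"conditional"`.
#' @return A numeric scalar, in bits for rates/entropies/capacities and
#'   dimensionless in `[0, 1]` for indexes (capacities may be negative under
#'   the literal variant; their indexes take the absolute value).
#'
#' @examples
#' g <- uniform_complete(4)
#' node_rate_out(g, 1)        # log2(3) / 4
#' network_index_out(g)       # log2(3) / log2(4)
#' capacity_out(g)            # log2(4) - log2(3)
#' @name variability-metrics
NULL

resolve_node <- function(G, i) {
  if (is.character(i)) {
    j <- match(i, G$labels)
    if (is.na(j)) {
      abort(sprintf("Unknown node label \"%s\".", i),
            class = "passentropy_invalid")
    }
    return(j)
  }
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > G$n || i != as.integer(i)) {
    abort(sprintf("Node index %s out of range 1..%d.", format(i), G$n),
          class = "passentropy_invalid")
  }
  as.integer(i)
}

check_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1 ||
      !variant %in% c("literal", "conditional")) {
    abort("`variant` must be \"literal\" or \"conditional\".",
          class = "passentropy_invalid")
  }
  variant
}

# All per-node rates in one pass; every exported metric reads from here.
node_rates_core <- function(G, variant = "literal") {
  W <- G$W
  L <- sum(W)
  p <- rowSums(W) / L
  q <- colSums(W) / L
  M <- transition_matrix(G)$M
  r_out <- p * apply(M, 1, shannon2)
  r_in <- if (variant == "literal") {
    q * apply(M, 2, shannon2)
  } else {
    C <- transition_matrix(transpose_network(G))$M
    q * apply(C, 1, shannon2)
  }
  list(R_out = unname(r_out), R_in = unname(r_in), p = unname(p),
       q = unname(q), L = L)
}

#' @rdname variability-metrics
#' @export
node_rate_out <- function(G, i) {
  stopifnot(inherits(G, "pass_network"))
  i <- resolve_node(G, i)
  node_rates_core(G)$R_out[i]
}

#' @rdname variability-metrics
#' @export
node_rate_in <- function(G, i, variant = c("literal", "conditional")) {
  stopifnot(inherits(G, "pass_network"))
  variant <- check_variant(match.arg(variant))
  i <- resolve_node(G, i)
  node_rates_core(G, variant)$R_in[i]
}

#' @rdname variability-metrics
#' @export
node_index_out <- function(G, i) {
  node_rate_out(G, i) / log2(G$n)
}

#' @rdname variability-metrics
#' @export
node_index_in <- function(G, i, variant = c("literal", "conditional")) {
  node_rate_in(G, i, variant) / log2(G$n)
}

#' @rdname variability-metrics
#' @export
network_rate_out <- function(G) {
  stopifnot(inherits(G, "pass_network"))
  sum(node_rates_core(G)$R_out)
}

#' @rdname variability-metrics
#' @export
network_rate_in <- function(G, variant = c("literal", "conditional")) {
  stopifnot(inherits(G, "pass_network"))
  variant <- check_variant(match.arg(variant))
  sum(node_rates_core(G, variant)$R_in)
}

#' @rdname variability-metrics
#' @export
network_index_out <- function(G) {
  network_rate_out(G) / log2(G$n)
}

#' @rdname variability-metrics
#' @export
network_index_in <- function(G, variant = c("literal", "conditional")) {
  network_rate_in(G, variant) / log2(G$n)
}

#' @rdname variability-metrics
#' @export
total_entropy_out <- function(G) {
  stopifnot(inherits(G, "pass_network"))
  shannon2(rowSums(G$W) / sum(G$W))
}

#' @rdname variability-metrics
#' @export
total_entropy_in <- function(G) {
  stopifnot(inherits(G, "pass_network"))
  shannon2(colSums(G$W) / sum(G$W))
}

#' @rdname variability-metrics
#' @export
capacity_out <- function(G, variant = c("literal", "conditional")) {
  variant <- check_variant(match.arg(variant))
  total_entropy_out(G) - network_rate_in(G, variant)
}

#' @rdname variability-metrics
#' @export
capacity_in <- function(G, variant = c("literal", "conditional")) {
  variant <- check_variant(match.arg(variant))
  total_entropy_in(G) - network_rate_out(G)
}

#' @rdname variability-metrics
#' @export
capacity_index_out <- function(G, variant = c("literal", "conditional")) {
  abs(capacity_out(G, variant)) / log2(G$n)
}

#' @rdname variability-metrics
#' @export
capacity_index_in <- function(G, variant = c("literal", "conditional")) {
  abs(capacity_in(G, variant)) / log2(G$n)
}

#' Per-node metric table
#'
#' Computes the rate and index of passing and reception for every node in
#' one pass.
#'
#' @inheritParams variability-metrics
#' @return A tibble with one row per node, in label order: columns `node`,
#'   `R_out`, `R_in`, `IndR_out`, `IndR_in` (rates in bits, indexes in
#'   `[0, 1]`).
#' @export
node_metrics <- function(G, variant = c("literal", "conditional")) {
  stopifnot(inherits(G, "pass_network"))
  variant <- check_variant(match.arg(variant))
  core <- node_rates_core(G, variant)
  ln <- log2(G$n)
  tibble(
    node = G$labels,
    R_out = core$R_out,
    R_in = core$R_in,
    IndR_out = core$R_out / ln,
    IndR_in = core$R_in / ln
  )
}

#' Network-level metric table
#'
#' @inheritParams variability-metrics
#' @return A one-row tibble with columns `RN_out`, `RN_in`, `IndRN_out`,
#'   `IndRN_in`, `EN_out`, `EN_in`, `CN_out`, `CN_in`, `IndCN_out`,
#'   `IndCN_in`, `L`, `n`. `CN_out`/`CN_in` are signed; their indexes take
#'   the absolute value.
#' @export
network_metrics <- function(G, variant = c("literal", "conditional")) {
  stopifnot(inherits(G, "pass_network"))
  variant <- check_variant(match.arg(variant))
  core <- node_rates_core(G, variant)
  ln <- log2(G$n)
  RN_out <- sum(core$R_out)
  RN_in <- sum(core$R_in)
  EN_out <- shannon2(core$p)
  EN_in <- shannon2(core$q)
  CN_out <- EN_out - RN_in
  CN_in <- EN_in - RN_out
  tibble(
    RN_out = RN_out, RN_in = RN_in,
    IndRN_out = RN_out / ln, IndRN_in = RN_in / ln,
    EN_out = EN_out, EN_in = EN_in,
    CN_out = CN_out, CN_in = CN_in,
    IndCN_out = abs(CN_out) / ln, IndCN_in = abs(CN_in) / ln,
    L = core$L, n = G$n
  )
}
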
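# Frozen oracle values for the fixed asymmetric 3x3 matrix
# W = [[0,3,1],[2,0,2],[1,1,0]], computed with the brute-force helpers
# (helper-oracle.R) before the main implementation.
ASYM3 <- list(
  node2_rate_in_literal     = 0.324511249783653,
  node2_rate_in_conditional = 0.324511249783653,
  node2_rate_out            = 0.400000000000000,
  EN_out = 1.521928094887362,
  EN_in  = 1.570950594454669,
  RN_out = 0.924511249783653,
  RN_in_literal = 0.924511249783653,
  CN_out_literal = 0.597416845103709,
  CN_in_literal  = 0.646439344671015,
  mutual_information = 0.646439344671015
)

test_that("node and network metrics reproduce frozen brute-force values on the 3x3 fixture", {
  g <- canonical_fixtures()$asym_3
  expect_equal(node_rate_out(g, 2), ASYM3$node2_rate_out, tolerance = 1e-12)
  expect_equal(node_rate_in(g, 2, "literal"), ASYM3$node2_rate_in_literal,
               tolerance = 1e-12)
  expect_equal(node_rate_in(g, 2, "conditional"),
               ASYM3$node2_rate_in_conditional, tolerance = 1e-12)
  expect_equal(total_entropy_out(g), ASYM3$EN_out, tolerance = 1e-12)
  expect_equal(total_entropy_in(g), ASYM3$EN_in, tolerance = 1e-12)
  expect_equal(network_rate_out(g), ASYM3$RN_out, tolerance = 1e-12)
  expect_equal(network_rate_in(g, "literal"), ASYM3$RN_in_literal,
               tolerance = 1e-12)
  expect_equal(capacity_out(g, "literal"), ASYM3$CN_out_literal,
               tolerance = 1e-12)
  expect_equal(capacity_in(g, "literal"), ASYM3$CN_in_literal,
               tolerance = 1e-12)
  expect_equal(capacity_out(g, "conditional"), ASYM3$mutual_information,
               tolerance = 1e-12)
  expect_equal(capacity_in(g, "conditional"), ASYM3$mutual_information,
               tolerance = 1e-12)
})

test_that("uniform complete digraphs match their closed forms", {
  for (n in c(3, 4, 8, 16)) {
    g <- uniform_complete(n)
    ln <- log2(n)
    for (i in c(1, n)) {
      expect_equal(node_rate_out(g, i), log2(n - 1) / n, tolerance = 1e-12)
      expect_equal(node_rate_in(g, i, "literal"), log2(n - 1) / n,
                   tolerance = 1e-12)
      expect_equal(node_index_out(g, i), log2(n - 1) / (n * ln),
                   tolerance = 1e-12)
    }
    expect_equal(network_rate_out(g), log2(n - 1), tolerance = 1e-12)
    expect_equal(network_index_out(g), log2(n - 1) / ln, tolerance = 1e-12)
    expect_equal(total_entropy_out(g), ln, tolerance = 1e-12)
    expect_equal(capacity_out(g, "literal"), ln - log2(n - 1),
                 tolerance = 1e-12)
    expect_equal(capacity_out(g, "conditional"), ln - log2(n - 1),
                 tolerance = 1e-12)
    expect_equal(capacity_index_out(g), 1 - log2(n - 1) / ln,
                 tolerance = 1e-12)
  }
  # the network index approaches 1 from below as n grows
  idx <- vapply(c(4, 8, 16), function(n) network_index_out(uniform_complete(n)),
                numeric(1))
  expect_true(all(diff(idx) > 0) && all(idx < 1))
})

test_that("degenerate graphs: single arc and 2-cycle", {
  fx <- canonical_fixtures()
  g1 <- fx$single_arc
  expect_equal(node_rate_out(g1, 1), 0)       # deterministic row
  expect_equal(node_rate_out(g1, 2), 0)       # silent row
  expect_equal(network_rate_out(g1), 0)
  expect_equal(total_entropy_out(g1), 0)      # single sender
  expect_equal(total_entropy_in(g1), 0)       # single receiver
  expect_equal(capacity_out(g1), 0)
  expect_equal(capacity_in(g1), 0)
  expect_equal(capacity_index_out(g1), 0)

  g2 <- fx$two_cycle
  expect_equal(network_rate_out(g2), 0)
  expect_equal(network_rate_in(g2, "literal"), 0)
  expect_equal(total_entropy_out(g2), 1)
  expect_equal(capacity_out(g2), 1)
  expect_equal(capacity_index_out(g2), 1)
  expect_equal(node_rate_in(g2, 1, "literal"), 0)
})

test_that("stars expose the literal variant's sign behaviour", {
  fx <- canonical_fixtures()
  # out-star: one sender, EN_out = 0, but receivers' literal rates are positive
  so <- fx$star_out_5
  expect_equal(total_entropy_out(so), 0)
  expect_equal(capacity_out(so, "literal"), -0.5)
  expect_true(capacity_out(so, "conditional") >= 0)
  expect_equal(capacity_index_out(so, "literal"), 0.5 / log2(5))
  # in-star: EN_out = log2 4 over leaves, RN_in = 0
  si <- fx$star_in_5
  expect_equal(total_entropy_out(si), 2)
  expect_equal(network_rate_in(si, "literal"), 0)
  expect_equal(capacity_out(si, "literal"), 2)
})

test_that("library agrees with the brute-force oracle on random graphs, both variants", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    W <- if (rep %% 3 == 0) random_sparse_matrix(n) else random_pass_matrix(n)
    g <- pass_network(W, as.character(seq_len(n)))
    i <- sample(n, 1)
    expect_equal(node_rate_out(g, i), oracle_node_rate_out(W, i),
                 tolerance = 1e-12)
    expect_equal(node_rate_in(g, i, "literal"),
                 oracle_node_rate_in_literal(W, i), tolerance = 1e-12)
    expect_equal(node_rate_in(g, i, "conditional"),
                 oracle_node_rate_in_conditional(W, i), tolerance = 1e-12)
    expect_equal(total_entropy_out(g), oracle_en_out(W), tolerance = 1e-12)
    expect_equal(total_entropy_in(g), oracle_en_in(W), tolerance = 1e-12)
    expect_equal(capacity_out(g, "literal"), oracle_cn_out(W, "literal"),
                 tolerance = 1e-12)
    expect_equal(capacity_in(g, "conditional"),
                 oracle_cn_in(W, "conditional"), tolerance = 1e-12)
  }
})

test_that("decomposition identity: rate equals strength share times row entropy", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    W <- random_pass_matrix(n)
    g <- pass_network(W, as.character(seq_len(n)))
    M <- transition_matrix(g)$M
    for (i in seq_len(n)) {
      row <- M[i, ]
      h <- -sum(row[row > 0] * log2(row[row > 0]))
      expect_equal(node_rate_out(g, i), (sum(W[i, ]) / sum(W)) * h,
                   tolerance = 1e-12)
    }
  }
})

test_that("in-metrics equal out-metrics of the transposed network", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    W <- random_pass_matrix(n)
    g <- pass_network(W, as.character(seq_len(n)))
    gt <- transpose_network(g)
    # conditional variant: full duality
    expect_equal(network_rate_in(g, "conditional"), network_rate_out(gt),
                 tolerance = 1e-12)
    expect_equal(total_entropy_in(g), total_entropy_out(gt), tolerance = 1e-12)
    expect_equal(capacity_in(g, "conditional"),
                 capacity_out(gt, "conditional"), tolerance = 1e-12)
    # double transpose: conditional reception on the transpose recovers
    # the out-rate of the original
    for (i in sample(n, 2)) {
      expect_equal(node_rate_in(gt, i, "conditional"), node_rate_out(g, i),
                   tolerance = 1e-12)
    }
  }
})

test_that("every metric is scale invariant", {
  set.seed(8)
  W <- random_pass_matrix(9)
  g <- pass_network(W, as.character(1:9))
  gs <- pass_network(7.3 * W, as.character(1:9))
  for (variant in c("literal", "conditional")) {
    expect_equal(network_metrics(gs, variant)[, 1:10],
                 network_metrics(g, variant)[, 1:10], tolerance = 1e-12)
    expect_equal(node_metrics(gs, variant)[, -1],
                 node_metrics(g, variant)[, -1], tolerance = 1e-12)
  }
})

test_that("node lookup by label, index validation and variant validation", {
  g <- canonical_fixtures()$asym_3
  expect_equal(node_rate_out(g, "2"), node_rate_out(g, 2))
  expect_error(node_rate_out(g, 4), class = "passentropy_invalid")
  expect_error(node_rate_out(g, "z"), class = "passentropy_invalid")
  expect_error(node_rate_in(g, 1, "bogus"))
})

test_that("full_report satisfies its internal consistency contracts", {
  g <- simulate_pass_network(n = 14, total_passes = 500, seed = 42)
  for (variant in c("literal", "conditional")) {
    rep <- full_report(g, variant)
    pn <- rep$per_node
    nw <- rep$network
    expect_equal(nrow(pn), 14)
    expect_identical(pn$node, g$labels)
    expect_equal(nw$RN_out, sum(pn$R_out))
    expect_equal(nw$RN_in, sum(pn$R_in))
    expect_equal(nw$CN_out, nw$EN_out - nw$RN_in)
    expect_equal(nw$CN_in, nw$EN_in - nw$RN_out)
    expect_equal(pn$IndR_out, pn$R_out / log2(14))
    expect_equal(nw$IndCN_out, abs(nw$CN_out) / log2(14))
    expect_equal(nw$L, 500)
    expect_identical(rep$variant, variant)
  }
  # tidy/glance surfaces
  td <- tidy(full_report(g))
  expect_identical(sort(unique(td$metric)),
                   sort(c("R_out", "R_in", "IndR_out", "IndR_in")))
  gl <- glance(full_report(g, "conditional"))
  expect_identical(gl$variant, "conditional")
})

test_that("compare_networks puts capacities first and is zero against itself", {
  g <- canonical_fixtures()$uniform_complete_4
  tab <- compare_networks(g, g, names = c("x", "y"))
  expect_identical(tab$metric[1:4], c("CN_out", "CN_in", "IndCN_out", "IndCN_in"))
  expect_true(all(tab$diff == 0))
  tab2 <- compare_networks(g, canonical_fixtures()$two_cycle)
  expect_equal(tab2$A[tab2$metric == "IndCN_out"], 0.2075187496,
               tolerance = 1e-9)
  expect_equal(tab2$B[tab2$metric == "IndCN_out"], 1)
})
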
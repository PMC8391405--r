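# Version tag written into generator metadata; bump when the sampling
# algorithm changes so stored seeds remain interpretable.
GENERATOR_VERSION <- "1"

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rdirichlet1 <- function(k, concentration) {
  g <- rgamma(k, shape = concentration, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)  # guard against underflow at tiny concentration
  g / sum(g)
}

#' Generate a synthetic match-like pass network
#'
#' Draws a random weighted digraph with the statistical structure of a
#' single-match football pass matrix: a Dirichlet-multinomial allocation of
#' a fixed number of completed passes over sender-receiver pairs, with a
#' zero diagonal. Sender activity (how often each node passes) is either
#' supplied or drawn from a symmetric Dirichlet; each sender's preferences
#' over the other `n - 1` receivers are drawn from an independent symmetric
#' Dirichlet. The `concentration` parameter interpolates between spiky
#' (low values: a few dominant arcs) and uniform (high values) passing
#' structure — the axis the variability metrics measure.
#'
#' Defaults emulate a full-match squad: 14 nodes (11 starters plus 3
#' substitutes) and 500 completed passes.
#'
#' @param n Node count (players, including substitutes). Default 14.
#' @param total_passes Total completed passes to allocate. Default 500.
#' @param concentration Positive Dirichlet concentration for both the
#'   activity and the receiver-preference draws. Default 1 (uniform over
#'   the simplex).
#' @param activity Optional length-`n` non-negative vector of relative
#'   sender activity (at least two entries positive); use near-zero entries
#'   to emulate a goalkeeper or late substitute. When `NULL`, activity is
#'   drawn from `Dirichlet(concentration)`.
#' @param seed Integer seed; the draw is fully reproducible from it and the
#'   caller's RNG state is left untouched.
#' @param labels Optional node labels (default `"1"` ... `"n"`, shirt-number
#'   style).
#' @return A [pass_network] with integer weights summing exactly to
#'   `total_passes`, carrying a `generator` attribute (version, parameters,
#'   seed).
#'
#' @examples
#' g <- simulate_pass_network(n = 14, total_passes = 500, seed = 42)
#' total_weight(g)
#' @export
simulate_pass_network <- function(n = 14, total_passes = 500,
                                  concentration = 1, activity = NULL,
                                  seed = 1, labels = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != as.integer(n)) {
    abort("`n` must be an integer >= 2.", class = "passentropy_invalid")
  }
  if (!is.numeric(total_passes) || length(total_passes) != 1 ||
      total_passes < 1 || total_passes != as.integer(total_passes)) {
    abort("`total_passes` must be a positive integer.",
          class = "passentropy_invalid")
  }
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      concentration <= 0) {
    abort("`concentration` must be a positive real.",
          class = "passentropy_invalid")
  }
  if (!is.null(activity)) {
    if (!is.numeric(activity) || length(activity) != n || any(activity < 0) ||
        sum(activity > 0) < 2) {
      abort("`activity` must be length-n, non-negative, with at least two positive entries.",
            class = "passentropy_invalid")
    }
  }
  labels <- labels %||% as.character(seq_len(n))
  W <- with_local_seed(seed, {
    act <- if (is.null(activity)) rdirichlet1(n, concentration)
           else activity / sum(activity)
    prob <- matrix(0, n, n)
    for (i in seq_len(n)) {
      pref <- rdirichlet1(n - 1, concentration)
      prob[i, -i] <- act[i] * pref
    }
    counts <- rmultinom(1, size = total_passes, prob = as.vector(prob))
    matrix(as.numeric(counts), n, n)
  })
  G <- pass_network(W, labels = labels, profile = "sports")
  attr(G, "generator") <- list(
    version = GENERATOR_VERSION, n = n, total_passes = total_passes,
    concentration = concentration,
    activity = if (is.null(activity)) "dirichlet" else activity,
    seed = seed
  )
  G
}

#' Canonical fixture networks
#'
#' A named list of small networks with known closed-form metrics, used
#' throughout the test suite and handy for exploring the metric family:
#' uniform complete digraphs (`uniform_complete_3/4/8/16`), the 2-cycle
#' (`two_cycle`), a single-arc 2-node graph (`single_arc`), 5-node in- and
#' out-stars (`star_in_5`, `star_out_5`: the centre receives from / sends
#' one pass to each leaf) and a fixed asymmetric 3-node matrix (`asym_3`).
#'
#' @return Named list of [pass_network] objects.
#' @export
canonical_fixtures <- function() {
  star_in <- matrix(0, 5, 5)
  star_in[2:5, 1] <- 1
  star_out <- t(star_in)
  list(
    uniform_complete_3 = uniform_complete(3),
    uniform_complete_4 = uniform_complete(4),
    uniform_complete_8 = uniform_complete(8),
    uniform_complete_16 = uniform_complete(16),
    two_cycle = pass_network(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE),
                             labels = c("1", "2")),
    single_arc = pass_network(matrix(c(0, 5, 0, 0), 2, 2, byrow = TRUE),
                              labels = c("1", "2")),
    star_in_5 = pass_network(star_in, labels = as.character(1:5)),
    star_out_5 = pass_network(star_out, labels = as.character(1:5)),
    asym_3 = pass_network(matrix(c(0, 3, 1,
                                   2, 0, 2,
                                   1, 1, 0), 3, 3, byrow = TRUE),
                          labels = c("1", "2", "3"))
  )
}

#' Uniform complete digraph
#'
#' Every ordered pair of distinct nodes carries weight 1. Closed forms:
#' `R_out(i) = log2(n - 1) / n`, `RN_out = log2(n - 1)`,
#' `EN_out = log2 n`, `CN_out = log2 n - log2(n - 1)`.
#'
#' @param n Node count, at least 2.
#' @return A [pass_network].
#' @export
uniform_complete <- function(n) {
  W <- matrix(1, n, n) - diag(n)
  pass_network(W, labels = as.character(seq_len(n)))
}

#' Simulate a pass sequence as a random walk on the transition matrix
#'
#' Samples `length` consecutive passes: from the current holder `i`, the
#' next receiver is drawn from row `i` of the transition matrix. If the
#' walk reaches a node with zero out-strength before completing, the
#' sequence truncates there with a warning. Aggregating the returned events
#' recovers the transition proportions as `length` grows.
#'
#' @param G A [pass_network].
#' @param length Number of passes to simulate.
#' @param start Starting node (index or label); must have positive
#'   out-strength.
#' @param seed Integer seed (caller RNG state untouched).
#' @return A tibble of events with columns `sender`, `receiver`,
#'   `timestamp` (pass number, 1-based).
#' @export
simulate_pass_sequence <- function(G, length, start = 1, seed = 1) {
  stopifnot(inherits(G, "pass_network"))
  if (!is.numeric(length) || length(length) != 1 || length < 1) {
    abort("`length` must be a positive integer.", class = "passentropy_invalid")
  }
  start <- resolve_node(G, start)
  MT <- transition_matrix(G)
  if (!MT$defined_rows[start]) {
    abort(sprintf("Start node \"%s\" has zero out-strength.", G$labels[start]),
          class = "passentropy_invalid")
  }
  senders <- integer(length)
  receivers <- integer(length)
  made <- with_local_seed(seed, {
    cur <- start
    k <- 0L
    while (k < length) {
      if (!MT$defined_rows[cur]) break
      nxt <- sample.int(G$n, 1, prob = MT$M[cur, ])
      k <- k + 1L
      senders[k] <- cur
      receivers[k] <- nxt
      cur <- nxt
    }
    k
  })
  if (made < length) {
    warn(sprintf(
      "Pass sequence truncated after %d of %d passes: node \"%s\" has zero out-strength.",
      made, length, G$labels[receivers[made]]))
  }
  tibble(
    sender = G$labels[senders[seq_len(made)]],
    receiver = G$labels[receivers[seq_len(made)]],
    timestamp = as.numeric(seq_len(made))
  )
}
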
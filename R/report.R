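#' Full metric report for a pass network
#'
#' Computes every per-node and network-level metric in one pass and bundles
#' them with provenance metadata. This is the object the CLI serializes and
#' the plotting functions consume.
#'
#' @inheritParams variability-metrics
#' @param source Optional character tag recording where the network came
#'   from (file path, generator call, ...).
#' @return An object of class `metric_report`: list with `per_node`
#'   (tibble, one row per node in label order), `network` (one-row tibble),
#'   `variant` and `meta` (list with `source`, `n`, `L`).
#'
#' @examples
#' rep <- full_report(uniform_complete(4))
#' glance(rep)
#' @export
full_report <- function(G, variant = c("literal", "conditional"),
                        source = NULL) {
  stopifnot(inherits(G, "pass_network"))
  variant <- check_variant(match.arg(variant))
  per_node <- node_metrics(G, variant)
  network <- network_metrics(G, variant)
  structure(
    list(
      per_node = per_node,
      network = network,
      variant = variant,
      meta = list(source = source %||% "in-memory", n = G$n, L = sum(G$W))
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: %d nodes, L = %g, variant = \"%s\">\n",
              x$meta$n, x$meta$L, x$variant))
  cat("\nPer-node metrics:\n")
  print(x$per_node, n = nrow(x$per_node))
  cat("\nNetwork metrics:\n")
  print(tidyr::pivot_longer(x$network, dplyr::everything(),
                            names_to = "metric", values_to = "value"),
        n = 12)
  invisible(x)
}

#' Tidy a metric report into a long per-node table
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `metric`
#'   (`R_out`/`R_in`/`IndR_out`/`IndR_in`) and `value`.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) {
  tidyr::pivot_longer(x$per_node, -"node",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return The network-level metrics as a one-row tibble, plus the variant.
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  dplyr::mutate(x$network, variant = x$variant)
}

#' Compare two networks side by side
#'
#' Produces the team-comparison table: network metrics of both inputs in
#' adjacent columns plus their difference, capacities and capacity indexes
#' first.
#'
#' @param G_a,G_b Two [pass_network] objects.
#' @param variant Reception variant applied to both (must be the same for a
#'   meaningful comparison).
#' @param names Length-2 character vector naming the two networks.
#' @return A tibble with columns `metric`, the two team columns, and `diff`.
#' @export
compare_networks <- function(G_a, G_b,
                             variant = c("literal", "conditional"),
                             names = c("A", "B")) {
  variant <- check_variant(match.arg(variant))
  stopifnot(length(names) == 2)
  na <- network_metrics(G_a, variant)
  nb <- network_metrics(G_b, variant)
  ord <- c("CN_out", "CN_in", "IndCN_out", "IndCN_in",
           "RN_out", "RN_in", "IndRN_out", "IndRN_in",
           "EN_out", "EN_in", "L", "n")
  out <- tibble(
    metric = ord,
    a = as.numeric(na[1, ord]),
    b = as.numeric(nb[1, ord])
  )
  out$diff <- out$a - out$b
  names(out)[2:3] <- names
  out
}
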
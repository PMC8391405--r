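#' Read a labelled adjacency matrix from CSV
#'
#' The expected layout is a square matrix with a header row of receiver
#' labels and a first column of sender labels: cell `(i, j)` holds the
#' weight of passes from row node `i` to column node `j`. Row and column
#' labels must agree in order.
#'
#' @param path Path to a CSV file (comma separated, `.` decimal point,
#'   header row mandatory).
#' @param profile Validation profile passed to [pass_network()].
#' @return A [pass_network].
#' @seealso [write_adjacency_csv()]
#' @export
read_adjacency_csv <- function(path, profile = c("sports", "general")) {
  profile <- match.arg(profile)
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  if (ncol(df) < 3) {
    abort("Adjacency CSV needs a label column plus at least 2 weight columns.",
          class = "passentropy_invalid")
  }
  labels <- as.character(df[[1]])
  body <- as.matrix(df[, -1])
  if (!is.numeric(body)) {
    bad <- colnames(df[, -1])[!vapply(df[, -1], is.numeric, logical(1))][1]
    abort(sprintf("Non-numeric entries in column \"%s\".", bad),
          class = "passentropy_invalid")
  }
  header <- colnames(df)[-1]
  if (nrow(body) == ncol(body) && !identical(header, labels)) {
    abort("Row labels and header labels disagree.",
          class = "passentropy_invalid")
  }
  pass_network(body, labels = labels, profile = profile)
}

#' Write a pass network as a labelled adjacency CSV
#'
#' Inverse of [read_adjacency_csv()]: the round trip preserves labels exactly
#' and weights to 15 significant digits.
#'
#' @param G A [pass_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(G, path) {
  stopifnot(inherits(G, "pass_network"))
  df <- as.data.frame(signif(G$W, 15))
  df <- cbind(node = G$labels, df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Aggregate pass events into a pass network
#'
#' Counts completed passes per (sender, receiver) pair. The node set is the
#' supplied `labels` when given; otherwise the sorted distinct identifiers
#' seen in the events, or their first-appearance order with
#' `order = "appearance"`.
#'
#' @param events A data frame with character columns `sender` and `receiver`
#'   (a `timestamp` column, if present, is carried along by
#'   [simulate_pass_sequence()] but ignored here).
#' @param labels Optional ordered character vector of node labels; every
#'   sender and receiver must appear in it.
#' @param order Label ordering when `labels` is not given: `"sorted"`
#'   (default) or `"appearance"`.
#' @param profile Validation profile passed to [pass_network()]; the sports
#'   profile rejects self-passes.
#' @return A [pass_network] whose total weight equals `nrow(events)`.
#'
#' @examples
#' ev <- tibble::tibble(sender = c("a", "a", "b"), receiver = c("b", "b", "a"))
#' aggregate_events(ev)$W
#' @export
aggregate_events <- function(events, labels = NULL,
                             order = c("sorted", "appearance"),
                             profile = c("sports", "general")) {
  order <- match.arg(order)
  profile <- match.arg(profile)
  if (!is.data.frame(events) || !all(c("sender", "receiver") %in% names(events))) {
    abort("`events` must be a data frame with columns `sender` and `receiver`.",
          class = "passentropy_invalid")
  }
  if (nrow(events) == 0) {
    abort("Cannot aggregate an empty event list.",
          class = "passentropy_empty_events")
  }
  snd <- as.character(events$sender)
  rcv <- as.character(events$receiver)
  if (profile == "sports" && any(snd == rcv)) {
    i <- which(snd == rcv)[1]
    abort(
      sprintf("Event %d is a self-pass (%s -> %s), not allowed under the sports profile.",
              i, snd[i], rcv[i]),
      class = "passentropy_self_loop"
    )
  }
  if (is.null(labels)) {
    seen <- unique(c(rbind(snd, rcv)))
    labels <- if (order == "sorted") sort(seen) else seen
  } else {
    labels <- as.character(labels)
    missing <- setdiff(unique(c(snd, rcv)), labels)
    if (length(missing) > 0) {
      abort(sprintf("Event node(s) not in `labels`: %s.",
                    paste(missing, collapse = ", ")),
            class = "passentropy_invalid")
    }
  }
  n <- length(labels)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  tab <- table(factor(snd, levels = labels), factor(rcv, levels = labels))
  W[] <- as.numeric(tab)
  pass_network(W, labels = labels, profile = profile)
}

#' Read a pass-event log from CSV
#'
#' Expects columns `sender,receiver[,timestamp]`.
#'
#' @param path Path to the event CSV.
#' @return A tibble of events.
#' @export
read_events_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  if (!all(c("sender", "receiver") %in% names(df))) {
    abort("Event CSV must have columns `sender` and `receiver`.",
          class = "passentropy_invalid")
  }
  df$sender <- as.character(df$sender)
  df$receiver <- as.character(df$receiver)
  as_tibble(df)
}

#' Read a weighted edge list (TSV)
#'
#' Imports a three-column tab-separated file `source, target, weight` and
#' assembles the adjacency matrix over the union of endpoint labels
#' (sorted order).
#'
#' @param path Path to the TSV file.
#' @param profile Validation profile passed to [pass_network()].
#' @return A [pass_network].
#' @export
read_edgelist_tsv <- function(path, profile = c("sports", "general")) {
  profile <- match.arg(profile)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  if (ncol(df) < 3) {
    abort("Edge-list TSV must have columns source, target, weight.",
          class = "passentropy_invalid")
  }
  names(df)[1:3] <- c("source", "target", "weight")
  labels <- sort(unique(c(as.character(df$source), as.character(df$target))))
  n <- length(labels)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (k in seq_len(nrow(df))) {
    W[as.character(df$source[k]), as.character(df$target[k])] <-
      W[as.character(df$source[k]), as.character(df$target[k])] + df$weight[k]
  }
  pass_network(W, labels = labels, profile = profile)
}

#' Write a metric report to JSON or CSV
#'
#' The JSON document has a stable schema with four top-level fields:
#' `meta` (source, `n`, total weight `L`, variant, generator version when
#' synthetic), `per_node` (array of per-node records in label order),
#' `network` (the network-level record) and `variant`. Numbers are written
#' with 15 significant digits. The CSV format writes the per-node table,
#' a blank line, then the network table.
#'
#' @param report A `metric_report` from [full_report()].
#' @param path Output path. For `format = "csv"` a single file holds both
#'   tables.
#' @param format `"json"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [read_report_json()]
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "metric_report"))
  if (format == "json") {
    payload <- list(
      meta = report$meta,
      variant = report$variant,
      per_node = report$per_node,
      network = as.list(report$network)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    node_tab <- report$per_node
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("node,R_out,R_in,IndR_out,IndR_in", con)
    for (i in seq_len(nrow(node_tab))) {
      writeLines(paste(
        node_tab$node[i],
        format(signif(node_tab$R_out[i], 15), digits = 15),
        format(signif(node_tab$R_in[i], 15), digits = 15),
        format(signif(node_tab$IndR_out[i], 15), digits = 15),
        format(signif(node_tab$IndR_in[i], 15), digits = 15),
        sep = ","), con)
    }
    writeLines("", con)
    net <- report$network
    writeLines(paste(names(net), collapse = ","), con)
    writeLines(paste(vapply(net, function(v)
      format(signif(v, 15), digits = 15), character(1)), collapse = ","), con)
  }
  invisible(path)
}

#' Read back a JSON metric report
#'
#' @param path Path to a JSON file written by [write_report()].
#' @return A `metric_report`.
#' @export
read_report_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      meta = payload$meta,
      variant = payload$variant,
      per_node = as_tibble(payload$per_node),
      network = as_tibble(as.list(payload$network))
    ),
    class = "metric_report"
  )
}
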
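# Network topology: degree centrality (DC), betweenness centrality (BC)
# via Brandes' accumulation, per-class summary statistics, and the two
# node-selection rules used on pharmacology networks (hub rule: DC and BC
# above 2x the median; above-average rule: above the class mean).

#' Degree centrality
#'
#' DC of a node is its number of incident edges (equivalently, of adjacent
#' nodes, since the graph is simple).
#'
#' @param net A `typed_network`.
#' @return `data.frame` with columns `node_id`, `class`, `dc`.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  d <- node_degrees(net)
  data.frame(node_id = net$nodes$id, class = net$nodes$class,
             dc = as.integer(d[net$nodes$id]), stringsAsFactors = FALSE)
}

# Brandes' algorithm for unweighted betweenness: one BFS per source with
# back-propagation of pair dependencies. Raw values are halved (each
# unordered pair is counted from both endpoints on an undirected graph).
.brandes <- function(adj) {
  n <- length(adj)
  cb <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- c(s); head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb / 2
}

#' Betweenness centrality
#'
#' Exact unweighted betweenness by Brandes' dependency accumulation:
#' for each node v, the sum over node pairs (s, t) of the fraction of
#' shortest s-t paths passing through v (endpoints excluded). With
#' `normalized = TRUE` (default) raw values are divided by
#' (n-1)(n-2)/2 — the number of node pairs excluding v — giving values in
#' \[0, 1\]; this is the NetworkAnalyzer/Cytoscape convention. For n < 3
#' the normalized BC is 0. On disconnected graphs dependencies accumulate
#' within components only, while normalization still uses the full node
#' count n, so fragmenting a network deflates all BC values.
#'
#' @param net A `typed_network`.
#' @param normalized Divide by (n-1)(n-2)/2 (default `TRUE`).
#' @return `data.frame` with columns `node_id`, `class`, `bc`.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  stopifnot(inherits(net, "typed_network"))
  ids <- net$nodes$id
  n <- length(ids)
  adj <- rep(list(integer(0)), n)
  if (nrow(net$edges)) {
    fi <- match(net$edges$from, ids)
    ti <- match(net$edges$to, ids)
    for (k in seq_along(fi)) {
      adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
      adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k])
    }
  }
  bc <- if (n) .brandes(adj) else numeric(0)
  if (normalized) {
    bc <- if (n < 3) rep(0, n) else bc / ((n - 1) * (n - 2) / 2)
  }
  data.frame(node_id = ids, class = net$nodes$class, bc = bc,
             stringsAsFactors = FALSE)
}

#' Degree and betweenness table for a network
#'
#' Convenience wrapper computing both centralities in one table, the
#' standard input for [class_summary()] and [select_nodes()].
#'
#' @inheritParams betweenness_centrality
#' @return `data.frame` with columns `node_id`, `class`, `dc`, `bc`.
#' @export
centrality_table <- function(net, normalized = TRUE) {
  dc <- degree_centrality(net)
  bc <- betweenness_centrality(net, normalized = normalized)
  cbind(dc, bc = bc$bc)
}

#' Per-class centrality summary
#'
#' Median or mean of DC and BC per node class. Medians of even-sized
#' classes are the midpoint of the two central order statistics.
#'
#' @param table A centrality `data.frame` (`node_id`, `class`, `dc`,
#'   `bc`).
#' @param statistic `"median"` or `"mean"`.
#' @param classes Optional character vector of classes that must be
#'   present; an absent (empty) class raises an error naming it.
#' @return `data.frame` with columns `class`, `dc_stat`, `bc_stat`.
#' @export
class_summary <- function(table, statistic = c("median", "mean"),
                          classes = NULL) {
  statistic <- match.arg(statistic)
  if (!nrow(table)) stop("empty centrality table")
  if (!is.null(classes)) {
    absent <- setdiff(classes, unique(table$class))
    if (length(absent)) stop("empty node class: ", paste(absent, collapse = ", "))
  }
  fun <- if (statistic == "median") stats::median else mean
  cls <- sort(unique(table$class))
  data.frame(
    class = cls,
    dc_stat = vapply(cls, function(k) fun(table$dc[table$class == k]), 0),
    bc_stat = vapply(cls, function(k) fun(table$bc[table$class == k]), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Node-selection rule
#'
#' Describes a threshold rule of the form "DC and/or BC greater than
#' `multiplier` x class `statistic`". The hub rule is
#' `selection_rule("median", 2, "AND")`; the above-average rule is
#' `selection_rule("mean", 1, "AND")`. `combine = "DC_ONLY"` thresholds on
#' degree alone.
#'
#' @param statistic `"median"` or `"mean"` — the per-class (or global)
#'   location statistic thresholds are based on.
#' @param multiplier Positive multiplier applied to the statistic
#'   (2 for the hub rule, 1 for above-average).
#' @param combine `"AND"` (both DC and BC must pass), `"OR"` (either), or
#'   `"DC_ONLY"`.
#' @param strict `TRUE` (default) for strictly greater, `FALSE` for
#'   greater-or-equal.
#' @param per_class Compute thresholds per node class (default `TRUE`);
#'   `FALSE` uses one network-wide threshold pair.
#' @return A `selection_rule` object.
#' @export
selection_rule <- function(statistic = c("median", "mean"), multiplier = 2,
                           combine = c("AND", "OR", "DC_ONLY"),
                           strict = TRUE, per_class = TRUE) {
  statistic <- match.arg(statistic)
  combine <- match.arg(combine)
  stopifnot(is.numeric(multiplier), length(multiplier) == 1, multiplier > 0,
            is.logical(strict), is.logical(per_class))
  structure(list(statistic = statistic, multiplier = multiplier,
                 combine = combine, strict = strict, per_class = per_class),
            class = "selection_rule")
}

#' Select important nodes by a threshold rule
#'
#' Applies a [selection_rule()] to a centrality table: thresholds are
#' `multiplier` x the chosen statistic of DC and BC, computed from the
#' same table (per class when `per_class`). Selected node ids are returned
#' sorted by DC descending, ties by BC descending then node id.
#'
#' @param table A centrality `data.frame` (`node_id`, `class`, `dc`,
#'   `bc`).
#' @param rule A [selection_rule()].
#' @return Character vector of selected node ids, with the threshold table
#'   attached as attribute `"thresholds"`.
#' @export
#' @examples
#' net <- typed_network(
#'   data.frame(id = c("a", "b", "c", "d"), class = "protein"),
#'   data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"))
#' )
#' select_nodes(centrality_table(net), selection_rule("median", 1, "AND"))
select_nodes <- function(table, rule = selection_rule()) {
  stopifnot(inherits(rule, "selection_rule"))
  if (!nrow(table)) return(character(0))
  if (rule$per_class) {
    thr <- class_summary(table, rule$statistic)
    i <- match(table$class, thr$class)
    dc_thr <- rule$multiplier * thr$dc_stat[i]
    bc_thr <- rule$multiplier * thr$bc_stat[i]
  } else {
    fun <- if (rule$statistic == "median") stats::median else mean
    thr <- data.frame(class = "(all)", dc_stat = fun(table$dc),
                      bc_stat = fun(table$bc))
    dc_thr <- rep(rule$multiplier * thr$dc_stat, nrow(table))
    bc_thr <- rep(rule$multiplier * thr$bc_stat, nrow(table))
  }
  gt <- if (rule$strict) `>` else `>=`
  pass_dc <- gt(table$dc, dc_thr)
  pass_bc <- gt(table$bc, bc_thr)
  sel <- switch(rule$combine,
                AND = pass_dc & pass_bc,
                OR = pass_dc | pass_bc,
                DC_ONLY = pass_dc)
  picked <- table[sel, , drop = FALSE]
  picked <- picked[order(-picked$dc, -picked$bc, picked$node_id), , drop = FALSE]
  structure(picked$node_id, thresholds = thr)
}
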
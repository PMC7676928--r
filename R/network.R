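# Typed undirected networks: the C-T (compound-target), C-OT
# (compound-overlapping-target), C-T-P (compound-target-pathway) and PPI
# graphs are all simple undirected graphs whose nodes carry a class label.

.node_classes <- c("compound", "target", "pathway", "protein")

#' Construct a typed network
#'
#' A `typed_network` is a simple undirected graph whose nodes carry a class
#' label in `compound | target | pathway | protein`. Self-loops are
#' rejected, duplicate (unordered) edges collapsed, and every edge endpoint
#' must be a declared node. Extra columns on `nodes` (e.g. centrality
#' values) are carried along and exported where the output format allows.
#'
#' @param nodes `data.frame` with columns `id` (unique, non-empty) and
#'   `class`.
#' @param edges `data.frame` with columns `from` and `to`.
#' @return A `typed_network` object: `list(nodes = ..., edges = ...)` with
#'   edges stored in canonical order (`from < to`, sorted, deduplicated).
#' @export
#' @examples
#' typed_network(
#'   data.frame(id = c("c1", "T1"), class = c("compound", "target")),
#'   data.frame(from = "c1", to = "T1")
#' )
typed_network <- function(nodes, edges = data.frame(from = character(0),
                                                    to = character(0))) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "class") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  nodes$id <- as.character(nodes$id)
  nodes$class <- as.character(nodes$class)
  if (any(!nzchar(nodes$id))) stop("empty node id")
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  bad <- setdiff(unique(nodes$class), .node_classes)
  if (length(bad)) stop("unknown node class: ", paste(bad, collapse = ", "))
  if (nrow(edges)) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")
    miss <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(miss)) stop("edge endpoint(s) not in node set: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    e <- data.frame(from = pmin(edges$from, edges$to),
                    to = pmax(edges$from, edges$to), stringsAsFactors = FALSE)
    e <- unique(e)
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
    edges <- e
  } else {
    edges <- data.frame(from = character(0), to = character(0))
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "typed_network")
}

#' @export
print.typed_network <- function(x, ...) {
  tab <- table(x$nodes$class)
  cat("typed_network: ", nrow(x$nodes), " nodes (",
      paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
      "), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Number of nodes / edges in a typed network
#' @param net A `typed_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

# Degree of every node (named integer vector, zero for isolates).
node_degrees <- function(net) {
  d <- stats::setNames(integer(nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges)) {
    t1 <- table(net$edges$from); t2 <- table(net$edges$to)
    d[names(t1)] <- d[names(t1)] + as.integer(t1)
    d[names(t2)] <- d[names(t2)] + as.integer(t2)
  }
  d
}

#' Convert a typed network to an igraph object
#'
#' Node class and any extra node columns become vertex attributes.
#'
#' @param net A `typed_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  v <- net$nodes
  names(v)[names(v) == "id"] <- "name"
  igraph::graph_from_data_frame(net$edges, directed = FALSE, vertices = v)
}

#' Build a compound-target (C-T or C-OT) network
#'
#' Constructs the bipartite compound-target graph from a compound->target
#' map. With `restrict_targets = NULL` this is the C-T network over all
#' mapped targets; with `restrict_targets` set to the drug/disease
#' overlapping-target set it is the C-OT network over therapeutic targets
#' only. Compounds whose targets are all filtered out are dropped with a
#' warning, so node count = kept compounds + kept targets and edge count =
#' kept pairs.
#'
#' @param map `data.frame` with columns `compound_id`, `target`
#'   (normalized symbols, deduplicated pairs).
#' @param restrict_targets Optional character vector of target symbols to
#'   keep (e.g. the therapeutic-target overlap), or `NULL` for no
#'   restriction.
#' @return A bipartite `typed_network` with classes `compound` / `target`.
#' @export
build_ct_network <- function(map, restrict_targets = NULL) {
  map <- unique(as.data.frame(map, stringsAsFactors = FALSE)[, c("compound_id", "target")])
  if (!is.null(restrict_targets)) {
    map <- map[map$target %in% restrict_targets, , drop = FALSE]
  }
  if (!nrow(map)) {
    return(typed_network(data.frame(id = character(0), class = character(0))))
  }
  compounds <- unique(map$compound_id)
  targets <- unique(map$target)
  clash <- intersect(compounds, targets)
  if (length(clash)) stop("compound ids collide with target symbols: ",
                          paste(clash, collapse = ", "))
  nodes <- data.frame(
    id = c(compounds, targets),
    class = c(rep("compound", length(compounds)), rep("target", length(targets))),
    stringsAsFactors = FALSE
  )
  typed_network(nodes, data.frame(from = map$compound_id, to = map$target,
                                  stringsAsFactors = FALSE))
}

#' Build a protein-protein interaction network
#'
#' Filters a scored edge list to edges with both endpoints in `members` and
#' confidence `score >= min_score` (the STRING "high confidence" convention
#' is 0.7). Members left without any surviving edge are excluded from the
#' node set by default, mirroring how STRING/Cytoscape workflows end up
#' with fewer network nodes than query proteins; set `keep_isolates = TRUE`
#' to retain them with degree 0.
#'
#' @param edges `data.frame` with columns `node_a`, `node_b`, `score` in
#'   \[0, 1\] (see [read_scored_edges()]).
#' @param members Character vector of protein symbols to admit.
#' @param min_score Minimum confidence in \[0, 1\]; default 0.7.
#' @param keep_isolates Keep members with no surviving edge as isolated
#'   nodes (default `FALSE`).
#' @return A `typed_network` with class `protein`.
#' @export
build_ppi <- function(edges, members, min_score = 0.7, keep_isolates = FALSE) {
  stopifnot(min_score >= 0, min_score <= 1)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  keep <- edges$node_a %in% members & edges$node_b %in% members &
    edges$score >= min_score
  e <- edges[keep, , drop = FALSE]
  ids <- if (keep_isolates) unique(members) else unique(c(e$node_a, e$node_b))
  typed_network(
    data.frame(id = ids, class = rep("protein", length(ids)),
               stringsAsFactors = FALSE),
    data.frame(from = e$node_a, to = e$node_b, stringsAsFactors = FALSE)
  )
}

#' Build a compound-target-pathway (C-T-P) network
#'
#' Extends a C-OT network into the tripartite graph over a selection of
#' enriched pathways: target-pathway edges are added for every membership
#' of a kept target in a selected pathway; targets belonging to no selected
#' pathway are dropped, and compounds that lose all their targets are
#' dropped too. Compounds never connect to pathways directly, so every edge
#' has exactly one target endpoint.
#'
#' @param ct A compound-target `typed_network` (typically the C-OT
#'   network).
#' @param pathway_membership A `gene_set_collection` giving pathway member
#'   genes.
#' @param selected_pathways Character vector of term ids to include (e.g.
#'   the top 20 enriched pathways); must all exist in
#'   `pathway_membership`.
#' @return A tripartite `typed_network` with classes
#'   `compound`/`target`/`pathway`.
#' @export
build_ctp_network <- function(ct, pathway_membership, selected_pathways) {
  stopifnot(inherits(ct, "typed_network"))
  unknown <- setdiff(selected_pathways, names(pathway_membership))
  if (length(unknown)) stop("unknown pathway term id(s): ",
                            paste(unknown, collapse = ", "))
  targets <- ct$nodes$id[ct$nodes$class == "target"]
  tp <- do.call(rbind, lapply(selected_pathways, function(term) {
    hit <- intersect(pathway_membership[[term]]$genes, targets)
    if (!length(hit)) return(NULL)
    data.frame(from = hit, to = term, stringsAsFactors = FALSE)
  }))
  kept_targets <- if (is.null(tp)) character(0) else unique(tp$from)
  ce <- ct$edges[ct$edges$from %in% kept_targets | ct$edges$to %in% kept_targets, ,
                 drop = FALSE]
  cls <- stats::setNames(ct$nodes$class, ct$nodes$id)
  kept_compounds <- unique(c(ce$from, ce$to))
  kept_compounds <- kept_compounds[cls[kept_compounds] == "compound"]
  kept_pathways <- if (is.null(tp)) character(0) else unique(tp$to)
  nodes <- data.frame(
    id = c(kept_compounds, kept_targets, kept_pathways),
    class = c(rep("compound", length(kept_compounds)),
              rep("target", length(kept_targets)),
              rep("pathway", length(kept_pathways))),
    stringsAsFactors = FALSE
  )
  edges <- rbind(ce, if (!is.null(tp)) tp)
  if (is.null(edges)) edges <- data.frame(from = character(0), to = character(0))
  typed_network(nodes, edges)
}
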
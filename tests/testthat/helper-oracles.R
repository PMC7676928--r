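# Independent oracles used across the suite. These deliberately take the
# slow, literal route (path enumeration, term-by-term combinatorial sums,
# exhaustive filters) so they stay independent of the implementations they
# check.

# Brute-force betweenness: for every node pair, enumerate *all* shortest
# paths by recursion over the BFS-distance DAG and count pass-throughs.
# adj: list of integer neighbor vectors. Returns raw (unnormalized) BC.
bf_betweenness <- function(adj) {
  n <- length(adj)
  cb <- numeric(n)
  bfs_dist <- function(s) {
    d <- rep(NA_integer_, n); d[s] <- 0L
    q <- c(s); h <- 1L
    while (h <= length(q)) {
      v <- q[h]; h <- h + 1L
      for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
    }
    d
  }
  for (s in seq_len(n)) {
    d <- bfs_dist(s)
    for (t in seq_len(n)) {
      if (t <= s || is.na(d[t]) || d[t] == 0) next
      # all shortest s->t paths, walking back from t
      walk <- function(v) {
        if (v == s) return(list(s))
        out <- list()
        for (u in adj[[v]]) {
          if (!is.na(d[u]) && d[u] == d[v] - 1L) {
            for (p in walk(u)) out <- c(out, list(c(p, v)))
          }
        }
        out
      }
      paths <- walk(t)
      tot <- length(paths)
      for (p in paths) {
        interior <- p[-c(1, length(p))]
        for (v in interior) cb[v] <- cb[v] + 1 / tot
      }
    }
  }
  cb
}

# Random simple undirected graph as a typed_network plus adjacency list.
random_graph <- function(n, p, class = "protein") {
  ids <- paste0("v", seq_len(n))
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) { from <- c(from, ids[i]); to <- c(to, ids[j]) }
  }
  net <- typed_network(data.frame(id = ids, class = class),
                       data.frame(from = from, to = to))
  adj <- rep(list(integer(0)), n)
  for (k in seq_along(from)) {
    i <- match(from[k], ids); j <- match(to[k], ids)
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  list(net = net, adj = adj, ids = ids)
}

# Hypergeometric upper tail by direct combinatorial summation (choose(),
# not distribution functions).
bf_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Exhaustive row-by-row selection filter mirroring a selection rule.
bf_select <- function(table, statistic, multiplier, combine, strict) {
  fun <- if (statistic == "median") stats::median else mean
  out <- character(0)
  for (i in seq_len(nrow(table))) {
    rows <- table[table$class == table$class[i], ]
    dt <- multiplier * fun(rows$dc); bt <- multiplier * fun(rows$bc)
    gd <- if (strict) table$dc[i] > dt else table$dc[i] >= dt
    gb <- if (strict) table$bc[i] > bt else table$bc[i] >= bt
    ok <- switch(combine, AND = gd && gb, OR = gd || gb, DC_ONLY = gd)
    if (ok) out <- c(out, table$node_id[i])
  }
  out
}

# Small C-OT-style fixture: 2 compounds, 3 targets.
tiny_cot <- function() {
  map <- data.frame(compound_id = c("c1", "c1", "c2", "c2"),
                    target = c("T1", "T2", "T2", "T3"))
  build_ct_network(map)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
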
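# Readers and writers for the external formats the pipeline touches:
# TSV tables (compounds, compound->target maps, scored PPI edges), plain
# gene lists, GMT gene-set collections, and network exports (GraphML via
# igraph, SIF, edge-TSV). All readers skip lines starting with '#' and
# validate eagerly, reporting the offending file line where possible.

# Read a TSV keeping track of original line numbers (comment lines and
# blank lines are dropped but line numbering refers to the file on disk).
# Returns list(df = data.frame of character columns, lines = integer vector
# mapping data rows to file line numbers).
.read_tsv_lines <- function(path, comment_char = "#") {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl(paste0("^\\s*", comment_char), raw) & nzchar(trimws(raw))
  idx <- which(keep)
  if (!length(idx)) stop("'", path, "': no header line found")
  fields <- strsplit(raw[idx], "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  n <- length(fields) - 1L
  df <- as.data.frame(
    matrix("", nrow = n, ncol = length(header), dimnames = list(NULL, header)),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    length(row) <- length(header)
    df[i, ] <- trimws(row)
  }
  list(df = df, lines = if (n) idx[-1L] else integer(0))
}

# Strict TSV reader used for simple tables: requires the named columns
# (case-insensitively) and returns them under their canonical names.
read_tsv_checked <- function(path, required) {
  parsed <- .read_tsv_lines(path)
  df <- parsed$df
  lc <- tolower(names(df))
  pos <- match(tolower(required), lc)
  if (anyNA(pos)) {
    stop("'", path, "': missing required column(s): ",
         paste(required[is.na(pos)], collapse = ", "))
  }
  out <- df[, pos, drop = FALSE]
  names(out) <- required
  attr(out, "file_lines") <- parsed$lines
  out
}

.as_numeric_checked <- function(x, lines, path, column, lo = -Inf, hi = Inf) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v < lo | v > hi
  if (any(bad)) {
    stop("'", path, "', line ", lines[which(bad)[1]], ": column '", column,
         "' has invalid value '", x[which(bad)[1]], "' (expected number in [",
         lo, ", ", hi, "])")
  }
  v
}

#' Read a compound table with pharmacokinetic scores
#'
#' Reads a tab-separated compound table carrying an identifier, a name, an
#' oral bioavailability (OB, percent) and a drug-likeness (DL, unitless in
#' \[0, 1\]) column — the shape of a TCMSP ingredient export.
#'
#' @param path Path to a TSV file with a header. Lines starting with `#`
#'   are skipped.
#' @param dialect Optional named character vector mapping the canonical
#'   column roles `id`, `name`, `ob`, `dl` to the column names used in the
#'   file. Unmapped roles are matched case-insensitively against common
#'   spellings (`compound_id`/`id`/`number`, `name`/`compound_name`,
#'   `ob`/`ob_pct`, `dl`/`drug_likeness`).
#' @return A `data.frame` with columns `compound_id`, `name`, `ob`, `dl`;
#'   one row per compound, `compound_id` unique.
#' @export
read_compound_table <- function(path, dialect = NULL) {
  parsed <- .read_tsv_lines(path)
  df <- parsed$df
  synonyms <- list(
    id   = c("compound_id", "id", "mol_id", "number", "compound id"),
    name = c("name", "compound", "compound_name", "compound name"),
    ob   = c("ob", "ob_pct", "ob (%)", "ob_percent", "oral_bioavailability"),
    dl   = c("dl", "drug_likeness", "drug-likeness")
  )
  col_for <- function(role) {
    if (!is.null(dialect) && role %in% names(dialect)) {
      j <- match(tolower(dialect[[role]]), tolower(names(df)))
      if (is.na(j)) stop("'", path, "': declared ", role, " column '",
                         dialect[[role]], "' not found")
      return(j)
    }
    j <- match(synonyms[[role]], tolower(names(df)))
    j <- j[!is.na(j)]
    if (!length(j)) stop("'", path, "': missing column for ", role,
                         " (looked for: ", paste(synonyms[[role]], collapse = ", "), ")")
    j[1]
  }
  out <- data.frame(
    compound_id = df[[col_for("id")]],
    name = df[[col_for("name")]],
    ob = .as_numeric_checked(df[[col_for("ob")]], parsed$lines, path, "ob", 0, 100),
    dl = .as_numeric_checked(df[[col_for("dl")]], parsed$lines, path, "dl", 0, 1),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$compound_id))) {
    stop("'", path, "', line ", parsed$lines[which(!nzchar(out$compound_id))[1]],
         ": empty compound_id")
  }
  if (anyDuplicated(out$compound_id)) {
    stop("'", path, "': duplicate compound_id: ",
         paste(unique(out$compound_id[duplicated(out$compound_id)]), collapse = ", "))
  }
  out
}

#' Read a gene list
#'
#' Reads gene symbols either one per line, or from a named column of a TSV.
#' Symbols are normalized (see [normalize_symbol()]), blank lines ignored,
#' and duplicates (after normalization) collapsed.
#'
#' @param path Path to the file.
#' @param column If `NULL` (default) the file is treated as one symbol per
#'   line; otherwise the name of the TSV column holding the symbols.
#' @param aliases Alias table passed to [normalize_symbol()].
#' @return A character vector of unique normalized symbols, sorted.
#' @export
read_gene_list <- function(path, column = NULL, aliases = read_alias_table()) {
  if (is.null(column)) {
    if (!file.exists(path)) stop("cannot read '", path, "': no such file")
    raw <- readLines(path, warn = FALSE)
    raw <- raw[!grepl("^\\s*#", raw)]
    raw <- trimws(raw)
    raw <- raw[nzchar(raw)]
  } else {
    raw <- read_tsv_checked(path, required = column)[[column]]
    raw <- raw[nzchar(raw)]
  }
  sort(unique(normalize_symbol(raw, aliases)))
}

#' Read a compound-to-target mapping
#'
#' Reads the bipartite compound/target relation as a two-column TSV
#' (`compound_id`, `target`). Target symbols are normalized and duplicate
#' pairs collapsed.
#'
#' @inheritParams read_gene_list
#' @return A `data.frame` with columns `compound_id` and `target`, one row
#'   per distinct pair.
#' @export
read_target_map <- function(path, aliases = read_alias_table()) {
  df <- read_tsv_checked(path, required = c("compound_id", "target"))
  out <- data.frame(
    compound_id = df$compound_id,
    target = normalize_symbol(df$target, aliases),
    stringsAsFactors = FALSE
  )
  unique(out[nzchar(out$compound_id) & nzchar(out$target), , drop = FALSE])
}

#' Read confidence-scored interaction edges
#'
#' Reads a STRING-style protein-protein edge list: two node columns and a
#' confidence score. Scores are mapped to \[0, 1\]; STRING exports use
#' 0-999 integers, declared with `score_scale = "thousand"` (the scale is
#' never guessed from the data, since silent misscaling would corrupt any
#' downstream confidence cutoff). Self-loops are dropped with a message and
#' duplicate unordered pairs collapsed keeping the maximum score.
#'
#' @param path Path to a TSV with columns `node_a`, `node_b`, `score`
#'   (case-insensitive; `protein1`/`protein2`/`combined_score` also
#'   accepted).
#' @param score_scale `"unit"` for scores already in \[0, 1\], or
#'   `"thousand"` for 0-999/0-1000 integer scores which are divided by 1000.
#' @param aliases Alias table passed to [normalize_symbol()].
#' @return A `data.frame` with columns `node_a`, `node_b`, `score`
#'   (`node_a < node_b` lexicographically, one row per unordered pair).
#' @export
read_scored_edges <- function(path, score_scale = c("unit", "thousand"),
                              aliases = read_alias_table()) {
  score_scale <- match.arg(score_scale)
  parsed <- .read_tsv_lines(path)
  df <- parsed$df
  lc <- tolower(names(df))
  pick <- function(cands, what) {
    j <- match(cands, lc); j <- j[!is.na(j)]
    if (!length(j)) stop("'", path, "': missing ", what, " column (looked for: ",
                         paste(cands, collapse = ", "), ")")
    j[1]
  }
  a <- normalize_symbol(df[[pick(c("node_a", "protein1", "node1", "from"), "node_a")]], aliases)
  b <- normalize_symbol(df[[pick(c("node_b", "protein2", "node2", "to"), "node_b")]], aliases)
  hi <- if (score_scale == "thousand") 1000 else 1
  s <- .as_numeric_checked(df[[pick(c("score", "combined_score", "confidence"), "score")]],
                           parsed$lines, path, "score", 0, hi)
  if (score_scale == "thousand") s <- s / 1000
  loop <- a == b
  if (any(loop)) message("read_scored_edges: dropped ", sum(loop), " self-loop(s)")
  edges <- data.frame(node_a = pmin(a[!loop], b[!loop]),
                      node_b = pmax(a[!loop], b[!loop]),
                      score = s[!loop], stringsAsFactors = FALSE)
  if (!nrow(edges)) return(edges)
  key <- paste(edges$node_a, edges$node_b, sep = "\r")
  agg <- tapply(edges$score, key, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(parts, `[`, "", 1L),
                    node_b = vapply(parts, `[`, "", 2L),
                    score = as.numeric(agg), stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `term_id`, `description`,
#' then member symbols. Members are normalized and deduplicated; empty sets
#' and duplicate term ids are rejected.
#'
#' @inheritParams read_gene_list
#' @return A `gene_set_collection`: a named list (names = term ids) whose
#'   elements are `list(name = <description>, genes = <character vector>)`.
#' @export
read_gmt <- function(path, aliases = read_alias_table()) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  sets <- list()
  for (i in which(keep)) {
    f <- trimws(strsplit(raw[i], "\t", fixed = TRUE)[[1]])
    if (length(f) < 3) stop("'", path, "', line ", i,
                            ": GMT line needs >= 3 tab-separated fields")
    id <- f[1]
    if (id %in% names(sets)) stop("'", path, "', line ", i,
                                  ": duplicate term id '", id, "'")
    genes <- unique(normalize_symbol(f[-(1:2)], aliases))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("'", path, "', line ", i, ": empty gene set '", id, "'")
    sets[[id]] <- list(name = f[2], genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#'
#' @param collection A `gene_set_collection` as returned by [read_gmt()] or
#'   [simulate_gene_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    s <- collection[[id]]
    paste(c(id, s$name, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_target_map
#' @param map A compound-target map `data.frame` to write.
#' @export
write_target_map <- function(map, path) {
  utils::write.table(map[, c("compound_id", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_compound_table
#' @param compounds A compound `data.frame` to write.
#' @export
write_compound_table <- function(compounds, path) {
  utils::write.table(compounds[, c("compound_id", "name", "ob", "dl")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_scored_edges
#' @param edges A scored-edge `data.frame` to write (unit-scale scores).
#' @export
write_scored_edges <- function(edges, path) {
  utils::write.table(edges[, c("node_a", "node_b", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a typed network to disk
#'
#' Exports a [typed_network()] in one of three Cytoscape-compatible
#' formats. GraphML carries node classes and any numeric node attributes
#' (e.g. centrality columns); edge-TSV carries node classes; SIF carries
#' structure only (interaction type `"interacts"`, isolated nodes written
#' as single-field lines).
#'
#' @param net A `typed_network`.
#' @param path Output path.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "sif", "tsv")) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unknown network format '", format[1],
         "'; supported: graphml, sif, tsv"))
  stopifnot(inherits(net, "typed_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    deg <- node_degrees(net)
    iso <- net$nodes$id[deg[net$nodes$id] == 0]
    lines <- character(0)
    if (nrow(net$edges)) {
      lines <- paste(net$edges$from, "interacts", net$edges$to, sep = "\t")
    }
    writeLines(c(lines, iso), path)
  } else {
    cls <- stats::setNames(net$nodes$class, net$nodes$id)
    if (nrow(net$edges)) {
      df <- data.frame(from = net$edges$from, to = net$edges$to,
                       from_class = cls[net$edges$from],
                       to_class = cls[net$edges$to], stringsAsFactors = FALSE)
    } else {
      df <- data.frame(from = character(0), to = character(0),
                       from_class = character(0), to_class = character(0))
    }
    deg <- node_degrees(net)
    iso <- net$nodes$id[deg[net$nodes$id] == 0]
    if (length(iso)) {
      df <- rbind(df, data.frame(from = iso, to = "", from_class = cls[iso],
                                 to_class = "", stringsAsFactors = FALSE))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a typed network written by [write_network()]
#'
#' @param path Input path.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @param classes For SIF input only (which carries no attributes): an
#'   optional named character vector of node classes; nodes not named get
#'   class `"protein"`.
#' @return A `typed_network`.
#' @export
read_network <- function(path, format = c("graphml", "sif", "tsv"),
                         classes = NULL) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unknown network format '", format[1],
         "'; supported: graphml, sif, tsv"))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    attrs <- igraph::vertex_attr(g)
    nodes <- data.frame(id = attrs$name, class = attrs$class,
                        stringsAsFactors = FALSE)
    for (a in setdiff(names(attrs), c("name", "class", "id"))) {
      nodes[[a]] <- attrs[[a]]
    }
    el <- igraph::as_edgelist(g, names = TRUE)
    return(typed_network(nodes, data.frame(from = el[, 1], to = el[, 2],
                                           stringsAsFactors = FALSE)))
  }
  if (format == "sif") {
    raw <- readLines(path, warn = FALSE)
    raw <- raw[nzchar(trimws(raw))]
    parts <- strsplit(raw, "\t", fixed = TRUE)
    from <- character(0); to <- character(0); iso <- character(0)
    for (p in parts) {
      if (length(p) == 1) iso <- c(iso, p) else {
        from <- c(from, rep(p[1], length(p) - 2L))
        to <- c(to, p[-(1:2)])
      }
    }
    ids <- unique(c(from, to, iso))
    cl <- rep("protein", length(ids))
    if (!is.null(classes)) {
      hit <- ids %in% names(classes)
      cl[hit] <- unname(classes[ids[hit]])
    }
    return(typed_network(data.frame(id = ids, class = cl, stringsAsFactors = FALSE),
                         data.frame(from = from, to = to, stringsAsFactors = FALSE)))
  }
  df <- read_tsv_checked(path, required = c("from", "to", "from_class", "to_class"))
  is_edge <- nzchar(df$to)
  ids <- c(df$from, df$to[is_edge])
  cl <- c(df$from_class, df$to_class[is_edge])
  keep <- !duplicated(ids)
  typed_network(data.frame(id = ids[keep], class = cl[keep], stringsAsFactors = FALSE),
                data.frame(from = df$from[is_edge], to = df$to[is_edge],
                           stringsAsFactors = FALSE))
}
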
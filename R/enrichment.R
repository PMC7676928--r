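# Hypergeometric over-representation analysis (ORA) of gene-set
# collections, with BH adjustment, significance screening and top-N
# reporting. This is the in-package replacement for web-service
# annotation-enrichment steps: the statistic is the plain hypergeometric
# upper tail (no EASE-style modification).

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` are annotated. Computed via
#' `stats::phyper` (log-space internally, numerically stable); `k = 0`
#' returns exactly 1.
#'
#' @param k Observed overlap count, `0 <= k <= min(K, n)`.
#' @param K Annotated-set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The upper-tail probability in (0, 1\].
#' @export
#' @examples
#' hypergeom_tail(5, 5, 5, 10)  # 1 / choose(10, 5)
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  v <- c(k = k, K = K, n = n, N = N)
  if (any(v != round(v)) || any(v < 0)) {
    stop("hypergeom_tail: arguments must be non-negative integers")
  }
  if (K > N || n > N || k > min(K, n)) {
    stop("hypergeom_tail: require k <= min(K, n) and K, n <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (capped at 1, monotone
#' in p-rank). A thin validating wrapper over `stats::p.adjust(method =
#' "BH")`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("bh_adjust: p-values must be in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set in a collection for over-representation of the
#' query genes within a universe, using the hypergeometric upper tail.
#' Query genes outside the universe are dropped with a message; set
#' members are intersected with the universe before counting. One row is
#' returned per set with at least one query member (`k >= 1`), sorted by
#' p ascending with ties broken by term id. When `alpha` is non-`NULL`
#' rows failing the screen are removed (on raw p by default, on BH-
#' adjusted p with `use_adjusted = TRUE`); adjusted p-values are always
#' computed across all tested sets before any screening.
#'
#' @param query Character vector of query gene symbols (e.g. therapeutic
#'   targets).
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param universe Character vector of background gene symbols; defaults
#'   to all genes annotated in the collection.
#' @param alpha Significance screen, or `NULL` to keep all rows. Default
#'   0.05.
#' @param use_adjusted Screen on BH-adjusted p instead of raw p (default
#'   `FALSE`).
#' @return `data.frame` with columns `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p`, `p_adj`, `members` (comma-joined overlap genes).
#' @export
enrich <- function(query, collection, universe = NULL, alpha = 0.05,
                   use_adjusted = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection") || is.list(collection))
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(collection, `[[`, "genes"),
                              use.names = FALSE))
  }
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("enrich: empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message("enrich: dropped ", length(outside),
            " query gene(s) outside the universe")
  }
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(sort(names(collection)), function(id) {
    members <- intersect(collection[[id]]$genes, universe)
    hit <- intersect(query, members)
    k <- length(hit)
    if (k < 1) return(NULL)
    data.frame(term_id = id, term_name = collection[[id]]$name,
               k = k, K = length(members), n = n, N = N,
               p = hypergeom_tail(k, length(members), n, N),
               members = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), p_adj = numeric(0),
                      members = character(0)))
  }
  rows$p_adj <- bh_adjust(rows$p)
  rows <- rows[order(rows$p, rows$term_id), , drop = FALSE]
  if (!is.null(alpha)) {
    stopifnot(alpha > 0, alpha <= 1)
    keep <- if (use_adjusted) rows$p_adj < alpha else rows$p < alpha
    rows <- rows[keep, , drop = FALSE]
  }
  rownames(rows) <- NULL
  rows[, c("term_id", "term_name", "k", "K", "n", "N", "p", "p_adj", "members")]
}

#' Keep the top enriched terms after blocklist removal
#'
#' Removes rows whose term names match any blocklist pattern
#' (case-insensitive substring — the screen for manually curated
#' "uncorrelated" pathways such as unrelated cancers), then keeps the
#' first `top_n` rows. Input is assumed sorted by p (as [enrich()]
#' returns).
#'
#' @param rows Enrichment `data.frame` from [enrich()].
#' @param top_n Number of rows to keep.
#' @param blocklist Character vector of substrings to remove; default
#'   empty.
#' @return The filtered, truncated `data.frame`.
#' @export
screen_top <- function(rows, top_n, blocklist = character(0)) {
  stopifnot(is.numeric(top_n), top_n >= 0)
  if (length(blocklist)) {
    hit <- Reduce(`|`, lapply(blocklist, function(b) {
      grepl(b, rows$term_name, fixed = TRUE, ignore.case = FALSE) |
        grepl(tolower(b), tolower(rows$term_name), fixed = TRUE)
    }), init = rep(FALSE, nrow(rows)))
    rows <- rows[!hit, , drop = FALSE]
  }
  out <- utils::head(rows, top_n)
  rownames(out) <- NULL
  out
}
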
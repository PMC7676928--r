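# Target-set algebra: deduplicate the compound->target relation, merge
# disease gene sources, and intersect drug targets with disease targets to
# obtain the therapeutic-target set. All operations assume symbols already
# normalized (see normalize_symbol); they are plain set operations on
# character vectors so results compose with base R.

#' Distinct targets of a compound-target map
#'
#' Collapses the compound->target relation to the set of distinct target
#' symbols across all compounds (e.g. raw per-compound target rows
#' deduplicate to the drug-target set).
#'
#' @param map `data.frame` with columns `compound_id`, `target`.
#' @return Sorted character vector of unique targets.
#' @export
union_targets <- function(map) {
  if (!nrow(map)) return(character(0))
  sort(unique(as.character(map$target)))
}

#' Merge disease-gene sources
#'
#' Unions gene sets retrieved from several sources/keyword queries (e.g.
#' GeneCards and OMIM under multiple disease synonyms), removing
#' duplicates. Per-source counts are reported via `message()` so the
#' raw-to-distinct reduction is visible.
#'
#' @param sources A list of character vectors (optionally named by
#'   source).
#' @return Sorted character vector: the deduplicated union.
#' @export
merge_disease_sources <- function(sources) {
  stopifnot(is.list(sources), length(sources) >= 1)
  labs <- names(sources)
  if (is.null(labs)) labs <- paste0("source", seq_along(sources))
  n_raw <- sum(lengths(sources))
  merged <- sort(unique(unlist(sources, use.names = FALSE)))
  message("merge_disease_sources: ",
          paste(sprintf("%s=%d", labs, lengths(sources)), collapse = ", "),
          "; ", n_raw, " raw -> ", length(merged), " distinct")
  merged
}

#' Intersect drug targets with disease targets
#'
#' The intersection of compound targets and disease targets is the
#' therapeutic-target set. Both inputs must be normalized symbol vectors;
#' the result is a subset of each.
#'
#' @param drug Character vector of drug (compound) target symbols.
#' @param disease Character vector of disease-associated gene symbols.
#' @return Sorted character vector of overlapping symbols.
#' @export
#' @examples
#' intersect_targets(c("TP53", "IL6", "TNF"), c("TNF", "IL6", "EGFR"))
intersect_targets <- function(drug, disease) {
  sort(intersect(as.character(drug), as.character(disease)))
}

#' Report near-miss symbols between two sets
#'
#' Lists symbol pairs that differ only by normalization/alias rules —
#' i.e. raw symbols from either side that would have matched the other
#' side after [normalize_symbol()] but do not match verbatim. Useful for
#' spotting curation gaps when intersections look suspiciously small.
#'
#' @param raw_drug,raw_disease Character vectors of *raw* (unnormalized)
#'   symbols.
#' @param aliases Alias table passed to [normalize_symbol()].
#' @return `data.frame` with columns `raw`, `normalized`, `side`.
#' @export
near_miss_report <- function(raw_drug, raw_disease, aliases = read_alias_table()) {
  nd <- normalize_symbol(raw_drug, aliases)
  ns <- normalize_symbol(raw_disease, aliases)
  mk <- function(raw, norm, other_raw, other_norm, side) {
    hit <- norm %in% other_norm & !(raw %in% other_raw)
    changed <- raw != norm
    idx <- which(hit & changed)
    if (!length(idx)) return(NULL)
    data.frame(raw = raw[idx], normalized = norm[idx], side = side,
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(raw_drug, nd, raw_disease, ns, "drug"),
               mk(raw_disease, ns, raw_drug, nd, "disease"))
  if (is.null(out)) {
    out <- data.frame(raw = character(0), normalized = character(0),
                      side = character(0))
  }
  unique(out)
}
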
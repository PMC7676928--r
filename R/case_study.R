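# Curated case-study tables: the Prunella vulgaris / subacute thyroiditis
# (SAT) single-herb study that this pipeline's defaults are shaped after.
# The tables are small published summaries (active ingredients with C-OT
# degrees; PPI hub centralities; the full C-T-P centrality table) shipped
# as plain TSV under inst/extdata.

#' Active ingredients of Prunella vulgaris
#'
#' The 11 compounds of *Prunella vulgaris* passing the ADME screen
#' (OB >= 30%, DL >= 0.18), with their degree in the compound-overlapping-
#' target (C-OT) network against subacute thyroiditis. The degrees sum to
#' the C-OT edge count (231); together with the 83 overlapping targets the
#' C-OT network has 94 nodes.
#'
#' @return `data.frame` with columns `compound_id`, `name`, `ob`, `dl`,
#'   `cot_degree`.
#' @export
#' @examples
#' sum(prunella_compounds()$cot_degree)  # C-OT edge count
prunella_compounds <- function() {
  path <- system.file("extdata", "prunella_compounds.tsv", package = "herbnet")
  df <- read_tsv_checked(path, c("compound_id", "name", "ob", "dl", "cot_degree"))
  df$ob <- as.numeric(df$ob)
  df$dl <- as.numeric(df$dl)
  df$cot_degree <- as.integer(df$cot_degree)
  attr(df, "file_lines") <- NULL
  df
}

#' Hub targets of the P. vulgaris / SAT PPI network
#'
#' Degree and normalized betweenness of the 18 hub targets selected from
#' the 77-node / 383-edge PPI network over the 83 therapeutic targets
#' (network medians: DC 7, BC 0.00287026). Symbols are normalized (the
#' published table mixes styles, e.g. "IL-1β").
#'
#' @return `data.frame` with columns `node_id`, `dc`, `bc`.
#' @export
prunella_ppi_hubs <- function() {
  path <- system.file("extdata", "prunella_ppi_hubs.tsv", package = "herbnet")
  df <- read_tsv_checked(path, c("node_id", "dc", "bc"))
  df$node_id <- normalize_symbol(df$node_id)
  df$dc <- as.integer(df$dc)
  df$bc <- as.numeric(df$bc)
  attr(df, "file_lines") <- NULL
  df
}

#' Centrality table of the P. vulgaris / SAT C-T-P network
#'
#' Degree and normalized betweenness for every node of the tripartite
#' compound-target-pathway network (65 nodes: 11 compounds, 34 targets,
#' 20 pathways; 239 edges), with node classes. This is the input for the
#' above-class-mean selection of 4 compounds, 15 targets and 5 pathways.
#'
#' @return `data.frame` with columns `node_id`, `class`, `dc`, `bc`.
#' @export
#' @examples
#' ct <- prunella_ctp_centrality()
#' class_summary(ct, "mean")
prunella_ctp_centrality <- function() {
  path <- system.file("extdata", "prunella_ctp_centrality.tsv", package = "herbnet")
  df <- read_tsv_checked(path, c("node_id", "class", "dc", "bc"))
  df$dc <- as.integer(df$dc)
  df$bc <- as.numeric(df$bc)
  attr(df, "file_lines") <- NULL
  df
}
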
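# Gene-symbol normalization.
#
# Target-set intersections are only as good as symbol identity: database
# exports mix "IL-6", "IL6", "IL-1β" and "TNF-α" styles. All symbols
# entering the pipeline pass through normalize_symbol().

# Greek letters commonly embedded in cytokine/protein names, mapped to the
# Latin letter used in official HGNC symbols (IL-1β -> IL1B).
.greek_map <- c(
  "α" = "A", "Α" = "A",
  "β" = "B", "Β" = "B",
  "γ" = "G", "Γ" = "G",
  "δ" = "D", "Δ" = "D",
  "κ" = "K", "Κ" = "K",
  "λ" = "L", "Λ" = "L",
  "σ" = "S", "Σ" = "S",
  "ω" = "O", "Ω" = "O"
)

#' Load a symbol alias table
#'
#' Reads a two-column tab-separated table mapping non-standard gene names to
#' the symbol the pipeline should use. Aliases are applied after case,
#' whitespace, hyphen and Greek-letter normalization, so entries should be
#' written in already-normalized form (e.g. `TNFA` -> `TNF`, not
#' `TNF-α` -> `TNF`). A small default table ships with the package;
#' users extend it by concatenating their own rows.
#'
#' @param path Path to a TSV with columns `alias` and `symbol`. Lines
#'   starting with `#` are skipped. Defaults to the built-in table.
#' @return A named character vector: `names()` are aliases, values are the
#'   replacement symbols.
#' @export
#' @examples
#' al <- read_alias_table()
#' al[["TNFA"]]
read_alias_table <- function(path = system.file("extdata", "symbol_aliases.tsv",
                                                package = "herbnet")) {
  df <- read_tsv_checked(path, required = c("alias", "symbol"))
  if (anyDuplicated(df$alias)) {
    stop("duplicate alias entries: ",
         paste(unique(df$alias[duplicated(df$alias)]), collapse = ", "))
  }
  stats::setNames(as.character(df$symbol), as.character(df$alias))
}

#' Normalize gene symbols
#'
#' Canonicalizes gene symbols so that set algebra (union, intersection)
#' operates on identity rather than formatting: trims whitespace,
#' transliterates embedded Greek letters (`IL-1β` -> `IL1B`), removes
#' hyphens (`IL-6` -> `IL6`), uppercases, and finally applies the alias
#' table.
#'
#' @param x Character vector of raw symbols.
#' @param aliases Named character vector as returned by
#'   [read_alias_table()], or `NULL` to skip alias replacement.
#' @return Character vector of normalized symbols (same length as `x`).
#' @export
#' @examples
#' normalize_symbol(c(" tp53 ", "IL-6", "IL-1β"))
normalize_symbol <- function(x, aliases = read_alias_table()) {
  x <- trimws(as.character(x))
  for (g in names(.greek_map)) {
    x <- gsub(g, .greek_map[[g]], x, fixed = TRUE)
  }
  x <- toupper(gsub("-", "", x, fixed = TRUE))
  if (!is.null(aliases) && length(aliases)) {
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  x
}
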
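# ADME screening: candidate compounds become "active ingredients" when
# both pharmacokinetic scores pass their cutoffs (OB >= 30%, DL >= 0.18 by
# convention for TCMSP-style screens).

#' ADME screening criteria
#'
#' @param ob_min Minimum oral bioavailability in percent (default 30).
#' @param dl_min Minimum drug-likeness, unitless in \[0, 1\] (default
#'   0.18).
#' @param inclusive If `TRUE` (default) the cutoffs are inclusive (`>=`),
#'   the usual convention; `FALSE` gives strict `>` for sensitivity
#'   analysis.
#' @return An `adme_criteria` object.
#' @export
#' @examples
#' adme_criteria()            # OB >= 30, DL >= 0.18
#' adme_criteria(ob_min = 40)
adme_criteria <- function(ob_min = 30, dl_min = 0.18, inclusive = TRUE) {
  stopifnot(is.numeric(ob_min), length(ob_min) == 1, ob_min >= 0, ob_min <= 100,
            is.numeric(dl_min), length(dl_min) == 1, dl_min >= 0, dl_min <= 1,
            is.logical(inclusive), length(inclusive) == 1)
  structure(list(ob_min = ob_min, dl_min = dl_min, inclusive = inclusive),
            class = "adme_criteria")
}

#' Screen compounds by oral bioavailability and drug-likeness
#'
#' Partitions a compound table into active ingredients (both OB and DL
#' pass) and rejected compounds. Compounds with a missing OB or DL are
#' rejected with a message, never silently kept. Input row order is
#' preserved within each part; optionally the active part is re-sorted by
#' OB descending.
#'
#' @param compounds `data.frame` with columns `compound_id`, `name`, `ob`,
#'   `dl` (see [read_compound_table()]).
#' @param criteria An [adme_criteria()] object.
#' @param sort_by_ob Sort the active part by OB descending (default
#'   `FALSE`).
#' @return `list(active = <data.frame>, rejected = <data.frame>)`; the two
#'   parts partition the input.
#' @export
filter_compounds <- function(compounds, criteria = adme_criteria(),
                             sort_by_ob = FALSE) {
  stopifnot(inherits(criteria, "adme_criteria"),
            all(c("ob", "dl") %in% names(compounds)))
  miss <- is.na(compounds$ob) | is.na(compounds$dl)
  if (any(miss)) {
    message("filter_compounds: rejected ", sum(miss),
            " compound(s) with missing OB/DL")
  }
  pass <- if (criteria$inclusive) {
    compounds$ob >= criteria$ob_min & compounds$dl >= criteria$dl_min
  } else {
    compounds$ob > criteria$ob_min & compounds$dl > criteria$dl_min
  }
  pass <- !miss & !is.na(pass) & pass
  active <- compounds[pass, , drop = FALSE]
  if (sort_by_ob) active <- active[order(-active$ob), , drop = FALSE]
  rejected <- compounds[!pass, , drop = FALSE]
  rownames(active) <- rownames(rejected) <- NULL
  list(active = active, rejected = rejected)
}
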
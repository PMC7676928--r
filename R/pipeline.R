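# End-to-end pipeline driver: filter -> overlap -> networks -> topology ->
# selection -> enrichment -> C-T-P, from a single config (YAML file or R
# list), writing every artifact plus a machine-readable JSON report whose
# counts are mutually consistent by construction.

.default_params <- function() {
  list(ob_min = 30, dl_min = 0.18, inclusive = TRUE,
       ppi_min_score = 0.7, keep_isolates = FALSE,
       alpha = 0.05, use_adjusted = FALSE,
       universe = "collection",            # or "targets"
       hub_statistic = "median", hub_multiplier = 2, hub_combine = "AND",
       hub_strict = TRUE,
       ctp_compound_combine = "AND", ctp_target_combine = "DC_ONLY",
       ctp_pathway_combine = "AND",
       top_n = 20, blocklist = character(0), normalized_bc = TRUE)
}

.validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  inputs <- config$inputs
  need <- c("compounds", "target_map", "disease", "ppi", "gmt")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("config validation: missing input(s): ",
                         paste(miss, collapse = ", "))
  for (f in unlist(inputs[need], use.names = FALSE)) {
    if (!file.exists(f)) stop("config validation: input file not found: ", f)
  }
  params <- utils::modifyList(.default_params(), config$params %||% list())
  if (!is.null(params$alpha) && params$alpha <= 0) {
    stop("config validation: alpha must be > 0")
  }
  if (params$ppi_min_score < 0 || params$ppi_min_score > 1) {
    stop("config validation: ppi_min_score must be in [0, 1]")
  }
  if (params$top_n < 0) stop("config validation: top_n must be >= 0")
  list(inputs = inputs, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full network-pharmacology pipeline
#'
#' Executes, in order: compound ADME filtering; compound-target map
#' restriction to active compounds and target deduplication; disease-
#' source merging; drug/disease target intersection; C-T, C-OT and PPI
#' network construction; PPI topology with hub selection (DC and BC above
#' `hub_multiplier` x the median by default); hypergeometric pathway
#' enrichment of the overlapping targets with top-N screening; C-T-P
#' network construction over the selected pathways with above-class-mean
#' node selection. Each stage aborts with its name on failure; all
#' artifacts (TSV tables, GraphML networks, JSON report) are written under
#' `out_dir`.
#'
#' @param config Path to a YAML config, or an equivalent list, with
#'   elements `inputs` (paths `compounds`, `target_map`, `disease` — one
#'   path or a vector, `ppi`, `gmt`, optional `aliases`, optional
#'   `ppi_score_scale`) and optional `params` overriding the defaults
#'   (ob_min 30, dl_min 0.18, ppi_min_score 0.7, alpha 0.05,
#'   hub_multiplier 2, top_n 20, ...).
#' @param out_dir Directory for artifacts (created if needed), or `NULL`
#'   to skip writing files.
#' @return Invisibly, `list(report = <list>, objects = <list of
#'   intermediate R objects>)`. The report is what `report.json`
#'   contains.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- .validate_config(config)
  inputs <- cfg$inputs; params <- cfg$params
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  aliases <- if (!is.null(inputs$aliases)) {
    read_alias_table(inputs$aliases)
  } else read_alias_table()
  warnings <- character(0)

  ## 1. compounds + ADME screen
  compounds <- stage("read_compounds", read_compound_table(inputs$compounds))
  flt <- stage("adme_filter", filter_compounds(
    compounds, adme_criteria(params$ob_min, params$dl_min, params$inclusive)))
  active <- flt$active

  ## 2. target sets
  map <- stage("read_target_map", read_target_map(inputs$target_map, aliases))
  n_pairs_raw <- nrow(map)
  map <- map[map$compound_id %in% active$compound_id, , drop = FALSE]
  drug_targets <- union_targets(map)
  disease_sources <- stage("read_disease", lapply(inputs$disease, read_gene_list,
                                                  aliases = aliases))
  disease_targets <- suppressMessages(merge_disease_sources(disease_sources))
  overlap <- intersect_targets(drug_targets, disease_targets)

  ## 3. networks
  ct <- stage("build_ct", build_ct_network(map))
  cot <- stage("build_cot", suppressWarnings(build_ct_network(map, overlap)))
  scale <- inputs$ppi_score_scale %||% "unit"
  ppi_edges <- stage("read_ppi", suppressMessages(
    read_scored_edges(inputs$ppi, score_scale = scale, aliases = aliases)))
  ppi <- stage("build_ppi", build_ppi(ppi_edges, overlap,
                                      min_score = params$ppi_min_score,
                                      keep_isolates = params$keep_isolates))

  ## 4. PPI topology + hub selection
  ppi_cent <- stage("ppi_topology", centrality_table(ppi, params$normalized_bc))
  hub_rule <- selection_rule(params$hub_statistic, params$hub_multiplier,
                             params$hub_combine, params$hub_strict)
  hubs <- select_nodes(ppi_cent, hub_rule)
  hubs_dc_only <- select_nodes(ppi_cent, selection_rule(
    params$hub_statistic, params$hub_multiplier, "DC_ONLY", params$hub_strict))
  if (!setequal(hubs, hubs_dc_only)) {
    warnings <- c(warnings, sprintf(
      "hub rule sensitivity: %d nodes pass '%s' but %d pass 'DC_ONLY'; the BC threshold excludes %d node(s)",
      length(hubs), params$hub_combine, length(hubs_dc_only),
      length(setdiff(hubs_dc_only, hubs))))
  }

  ## 5. enrichment of overlapping targets
  gmt <- stage("read_gmt", read_gmt(inputs$gmt, aliases))
  universe <- if (identical(params$universe, "targets")) drug_targets else NULL
  enr <- stage("enrich", suppressMessages(
    enrich(overlap, gmt, universe = universe, alpha = params$alpha,
           use_adjusted = params$use_adjusted)))
  top <- screen_top(enr, params$top_n, params$blocklist)

  ## 6. C-T-P over selected pathways
  ctp <- NULL; ctp_cent <- NULL
  ctp_selected <- list(compound = character(0), target = character(0),
                       pathway = character(0))
  if (params$top_n == 0 || !nrow(top)) {
    message("run_pipeline: C-T-P stage skipped (no selected pathways)")
  } else {
    ctp <- stage("build_ctp", build_ctp_network(cot, gmt, top$term_id))
    ctp_cent <- stage("ctp_topology", centrality_table(ctp, params$normalized_bc))
    for (k in c("compound", "target", "pathway")) {
      comb <- params[[paste0("ctp_", k, "_combine")]]
      sel <- select_nodes(ctp_cent[ctp_cent$class == k, , drop = FALSE],
                          selection_rule("mean", 1, comb, strict = TRUE))
      ctp_selected[[k]] <- as.character(sel)
    }
  }

  report <- list(
    tool = paste0("herbnet ", as.character(utils::packageVersion("herbnet"))),
    params = params,
    compounds = list(retrieved = nrow(compounds), active = nrow(active),
                     active_ids = active$compound_id),
    targets = list(pairs_raw = n_pairs_raw, pairs_active = nrow(map),
                   drug_distinct = length(drug_targets),
                   disease_raw = sum(lengths(disease_sources)),
                   disease_distinct = length(disease_targets),
                   overlap = length(overlap)),
    networks = list(
      ct = list(nodes = n_nodes(ct), edges = n_edges(ct)),
      cot = list(nodes = n_nodes(cot), edges = n_edges(cot)),
      ppi = list(nodes = n_nodes(ppi), edges = n_edges(ppi)),
      ctp = if (!is.null(ctp)) list(nodes = n_nodes(ctp), edges = n_edges(ctp))
    ),
    ppi_summary = if (nrow(ppi_cent)) {
      s <- class_summary(ppi_cent, "median")
      list(median_dc = s$dc_stat[1], median_bc = s$bc_stat[1])
    },
    hubs = list(rule = unclass(hub_rule), selected = as.character(hubs),
                n = length(hubs),
                pct_of_overlap = if (length(overlap)) {
                  round(100 * length(hubs) / length(overlap), 2)
                } else NA),
    enrichment = list(tested = nrow(enr), kept_top = nrow(top),
                      top_terms = top$term_id),
    ctp_class_means = if (!is.null(ctp_cent)) {
      s <- class_summary(ctp_cent, "mean")
      stats::setNames(lapply(seq_len(nrow(s)), function(i) {
        list(dc = s$dc_stat[i], bc = s$bc_stat[i])
      }), s$class)
    },
    ctp_selected = ctp_selected,
    warnings = warnings
  )

  if (!is.null(out_dir)) {
    write_compound_table(active, file.path(out_dir, "active_compounds.tsv"))
    writeLines(overlap, file.path(out_dir, "overlap_targets.tsv"))
    write_network(ct, file.path(out_dir, "ct_network.graphml"), "graphml")
    write_network(cot, file.path(out_dir, "cot_network.graphml"), "graphml")
    write_network(ppi, file.path(out_dir, "ppi_network.graphml"), "graphml")
    utils::write.table(format(ppi_cent, digits = 8),
                       file.path(out_dir, "ppi_centrality.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(ctp)) {
      write_network(ctp, file.path(out_dir, "ctp_network.graphml"), "graphml")
      utils::write.table(format(ctp_cent, digits = 8),
                         file.path(out_dir, "ctp_centrality.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(report = report,
                 objects = list(active = active, map = map,
                                drug_targets = drug_targets,
                                disease_targets = disease_targets,
                                overlap = overlap, ct = ct, cot = cot,
                                ppi = ppi, ppi_centrality = ppi_cent,
                                hubs = as.character(hubs), enrichment = enr,
                                top = top, ctp = ctp,
                                ctp_centrality = ctp_cent,
                                ctp_selected = ctp_selected)))
}
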
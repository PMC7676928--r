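# Synthetic database exports with controlled statistical structure, so the
# whole pipeline runs and is testable offline: a compound table with an
# exact number of ADME-passing rows, a compound->target map with an exact
# drug/disease target overlap, a scored PPI edge list with an exact count
# of high-confidence edges, and GMT gene sets with planted enrichment.
# Every generator is an exact construction (counts hold by construction,
# not in expectation) and a pure function of (config, seed): each draws
# from its own RNG stream derived from the master seed, so adding one
# generator never perturbs another.

# Run expr under a private RNG stream derived from (seed, offset),
# restoring the caller's RNG state afterwards.
.with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) %% 1000000L) * 1009L + offset)
  force(expr)
}

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic-data generators. The defaults
#' emulate the scale of a single-herb network-pharmacology study: 60
#' candidate compounds of which 11 pass the ADME screen, 126 drug targets,
#' 2207 disease targets with an overlap of 83, a scored PPI list in which
#' exactly half of 766 edges reach high confidence (383 survive the 0.7
#' cutoff), and 90 pathway gene sets with one planted enriched term.
#'
#' @param seed Master seed; every generator derives its own stream from
#'   it.
#' @param n_compounds Number of candidate compounds.
#' @param frac_active Fraction passing OB >= 30 and DL >= 0.18; exactly
#'   `round(frac_active * n_compounds)` rows pass, by construction.
#' @param degree_spec Integer vector of per-active-compound target counts
#'   (defaults to the degree profile of a flavonoid-rich herb: one
#'   dominant compound and a long tail).
#' @param n_drug_targets,n_disease_targets,n_overlap Distinct drug
#'   targets, distinct disease targets, and their exact intersection
#'   size.
#' @param ppi_edge_count Number of distinct scored protein pairs
#'   generated.
#' @param ppi_frac_high Fraction of edges with score >= 0.7 (exact count
#'   `round(ppi_frac_high * ppi_edge_count)`).
#' @param n_pathways Number of gene sets.
#' @param pathway_size_range Length-2 integer vector: min/max set size.
#' @param planted_terms `data.frame` with columns `index` (which set) and
#'   `strength` (probability that each member is drawn from the query
#'   rather than the universe); `NULL` for a fully null collection.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_compounds = 60,
                       frac_active = 11 / 60,
                       degree_spec = c(68, 37, 32, 27, 24, 16, 11, 5, 4, 4, 3),
                       n_drug_targets = 126,
                       n_disease_targets = 2207,
                       n_overlap = 83,
                       ppi_edge_count = 766,
                       ppi_frac_high = 0.5,
                       n_pathways = 90,
                       pathway_size_range = c(10, 60),
                       planted_terms = data.frame(index = 1, strength = 0.75)) {
  stopifnot(n_compounds >= 0, frac_active >= 0, frac_active <= 1,
            n_overlap <= min(n_drug_targets, n_disease_targets),
            all(degree_spec >= 0), ppi_edge_count >= 0,
            ppi_frac_high >= 0, ppi_frac_high <= 1,
            n_pathways >= 0, length(pathway_size_range) == 2,
            pathway_size_range[1] >= 1,
            pathway_size_range[1] <= pathway_size_range[2])
  if (!is.null(planted_terms) && nrow(planted_terms)) {
    stopifnot(all(planted_terms$index >= 1),
              all(planted_terms$index <= n_pathways),
              all(planted_terms$strength >= 0),
              all(planted_terms$strength <= 1))
  }
  structure(list(seed = seed, n_compounds = n_compounds,
                 frac_active = frac_active, degree_spec = degree_spec,
                 n_drug_targets = n_drug_targets,
                 n_disease_targets = n_disease_targets, n_overlap = n_overlap,
                 ppi_edge_count = ppi_edge_count, ppi_frac_high = ppi_frac_high,
                 n_pathways = n_pathways,
                 pathway_size_range = pathway_size_range,
                 planted_terms = planted_terms),
            class = "sim_config")
}

#' Simulate a compound table
#'
#' Generates `n_compounds` rows of which exactly
#' `round(frac_active * n_compounds)` satisfy OB >= 30 and DL >= 0.18.
#' Actives draw OB ~ U\[30, 60\] and DL ~ U\[0.18, 0.8\]; each inactive
#' fails at least one criterion (OB below 30, DL below 0.18, or both).
#' Active rows are placed at random positions in the table.
#'
#' @param cfg A [sim_config()].
#' @return A compound `data.frame` (`compound_id`, `name`, `ob`, `dl`).
#' @export
simulate_compound_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_stream(cfg$seed, 11L, {
    n <- cfg$n_compounds
    n_act <- round(cfg$frac_active * n)
    act_pos <- sort(sample.int(n, n_act))
    ob <- dl <- numeric(n)
    ob[act_pos] <- stats::runif(n_act, 30, 60)
    dl[act_pos] <- stats::runif(n_act, 0.18, 0.8)
    inact <- setdiff(seq_len(n), act_pos)
    mode <- sample(1:3, length(inact), replace = TRUE)  # fail OB / DL / both
    for (j in seq_along(inact)) {
      i <- inact[j]
      ob[i] <- if (mode[j] %in% c(1, 3)) stats::runif(1, 0, 29.9) else stats::runif(1, 30, 100)
      dl[i] <- if (mode[j] %in% c(2, 3)) stats::runif(1, 0, 0.17) else stats::runif(1, 0.18, 1)
    }
    data.frame(compound_id = sprintf("CMP%04d", seq_len(n)),
               name = sprintf("compound_%04d", seq_len(n)),
               ob = round(ob, 2), dl = round(dl, 3), stringsAsFactors = FALSE)
  })
}

#' Simulate the drug/disease target universe and compound-target map
#'
#' Constructs, exactly: `n_drug_targets` distinct drug targets all hit by
#' at least one compound, `n_disease_targets` distinct disease targets,
#' and a drug/disease intersection of exactly `n_overlap` symbols. Each
#' active compound receives the number of targets given by `degree_spec`
#' (distinct per compound). Symbols are synthetic `G000001`-style tokens,
#' chosen to never collide with real gene aliases.
#'
#' @param cfg A [sim_config()].
#' @param compound_ids Ids of the active compounds the map should cover;
#'   defaults to the ADME-passing rows of [simulate_compound_table()]
#'   under the same config. Length must match `degree_spec`.
#' @return `list(map = <compound_id/target data.frame>, drug = <character>,
#'   disease = <character>)`.
#' @export
simulate_target_universe <- function(cfg, compound_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(compound_ids)) {
    tab <- simulate_compound_table(cfg)
    compound_ids <- filter_compounds(tab)$active$compound_id
  }
  deg <- as.integer(cfg$degree_spec)
  if (length(deg) != length(compound_ids)) {
    stop("degree_spec has ", length(deg), " entries but there are ",
         length(compound_ids), " active compounds")
  }
  if (any(deg > cfg$n_drug_targets)) {
    stop("degree_spec entries exceed n_drug_targets (", cfg$n_drug_targets, ")")
  }
  if (sum(deg) < cfg$n_drug_targets) {
    stop("sum(degree_spec) = ", sum(deg), " cannot cover all ",
         cfg$n_drug_targets, " drug targets")
  }
  .with_stream(cfg$seed, 23L, {
    drug <- sprintf("G%06d", seq_len(cfg$n_drug_targets))
    overlap <- sample(drug, cfg$n_overlap)
    n_extra <- cfg$n_disease_targets - cfg$n_overlap
    disease <- c(overlap,
                 sprintf("G%06d", cfg$n_drug_targets + seq_len(n_extra)))
    # coverage pass: hand each drug target to a compound with spare degree,
    # preferring those with the most capacity left; then fill remaining
    # degree with random extra targets.
    remaining <- deg
    assigned <- rep(list(character(0)), length(compound_ids))
    for (t in sample(drug)) {
      i <- sample(rep(which(remaining > 0), 2), 1,
                  prob = rep(remaining[remaining > 0], 2))
      assigned[[i]] <- c(assigned[[i]], t)
      remaining[i] <- remaining[i] - 1L
    }
    for (i in seq_along(compound_ids)) {
      if (remaining[i] > 0) {
        pool <- setdiff(drug, assigned[[i]])
        assigned[[i]] <- c(assigned[[i]], sample(pool, remaining[i]))
      }
    }
    map <- data.frame(
      compound_id = rep(compound_ids, lengths(assigned)),
      target = unlist(assigned, use.names = FALSE), stringsAsFactors = FALSE
    )
    list(map = map, drug = sort(drug), disease = sort(disease))
  })
}

#' Simulate a scored protein-protein edge list
#'
#' Draws `ppi_edge_count` distinct unordered pairs among `members`
#' (no self-loops) and assigns confidence scores such that exactly
#' `round(ppi_frac_high * ppi_edge_count)` of them are >= 0.7: high-
#' confidence scores are `0.7 + 0.3 * Beta(1.2, 3)` (mass near the
#' cutoff, as in evidence-combined scores), the rest `0.7 * Beta(2, 2)`.
#'
#' @param cfg A [sim_config()].
#' @param members Character vector of protein symbols.
#' @return A scored-edge `data.frame` (`node_a`, `node_b`, `score`).
#' @export
simulate_ppi <- function(cfg, members) {
  stopifnot(inherits(cfg, "sim_config"), length(members) >= 2)
  members <- sort(unique(as.character(members)))
  m <- length(members)
  n_pairs <- m * (m - 1) / 2
  if (cfg$ppi_edge_count > n_pairs) {
    stop("ppi_edge_count = ", cfg$ppi_edge_count, " exceeds the ", n_pairs,
         " possible pairs among ", m, " members")
  }
  .with_stream(cfg$seed, 37L, {
    idx <- sort(sample.int(n_pairs, cfg$ppi_edge_count))
    # map linear index to unordered pair (i < j), row-major over i
    i <- findInterval(idx - 1, cumsum(c(0, (m - 1):1)), rightmost.closed = FALSE)
    offset <- idx - c(0, cumsum((m - 1):1))[i]
    j <- i + offset
    e <- cfg$ppi_edge_count
    n_high <- round(cfg$ppi_frac_high * e)
    score <- numeric(e)
    hi <- if (n_high > 0) sample.int(e, n_high) else integer(0)
    score[hi] <- 0.7 + 0.3 * stats::rbeta(n_high, 1.2, 3)
    score[-hi] <- 0.7 * stats::rbeta(e - n_high, 2, 2)
    if (n_high == 0) score <- 0.7 * stats::rbeta(e, 2, 2)
    data.frame(node_a = members[i], node_b = members[j], score = score,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Generates `n_pathways` gene sets with sizes uniform in
#' `pathway_size_range`. Members of non-planted sets are sampled
#' uniformly from `universe`; each member of a planted set is drawn from
#' `query` with probability equal to the planted `strength`, otherwise
#' from outside the query, so `strength = length(query) /
#' length(universe)` recovers (approximately) the central null.
#'
#' @param cfg A [sim_config()].
#' @param universe Character vector of background gene symbols.
#' @param query Character vector of query genes (must be within
#'   `universe`).
#' @return A `gene_set_collection` with term ids `PW001`, `PW002`, ...
#' @export
simulate_gene_sets <- function(cfg, universe, query = character(0)) {
  stopifnot(inherits(cfg, "sim_config"))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (length(setdiff(query, universe))) stop("query must be within universe")
  planted <- cfg$planted_terms
  .with_stream(cfg$seed, 53L, {
    sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                    cfg$n_pathways, replace = TRUE)
    sets <- vector("list", cfg$n_pathways)
    names(sets) <- sprintf("PW%03d", seq_len(cfg$n_pathways))
    for (t in seq_len(cfg$n_pathways)) {
      m <- min(sizes[t], length(universe))
      strength <- if (!is.null(planted) && t %in% planted$index) {
        planted$strength[match(t, planted$index)]
      } else NA_real_
      if (!is.na(strength) && length(query)) {
        # overlap with the query is exactly the Binomial(m, strength) count:
        # the remaining members come from outside the query, so strength =
        # |query| / |universe| reduces to (approximately) the central null.
        pool <- setdiff(universe, query)
        n_q <- stats::rbinom(1, m, strength)
        n_q <- min(n_q, length(query))
        n_q <- max(n_q, m - length(pool))
        from_q <- if (n_q) sample(query, n_q) else character(0)
        genes <- c(from_q, if (m - n_q) sample(pool, m - n_q) else character(0))
      } else {
        genes <- sample(universe, m)
      }
      sets[[t]] <- list(name = sprintf("pathway_%03d", t), genes = sort(genes))
    }
    structure(sets, class = "gene_set_collection")
  })
}

#' Write all simulated inputs to a directory
#'
#' Materializes one complete synthetic study — compounds, compound-target
#' map, disease gene list, scored PPI edges, GMT pathways — plus the
#' config echoed as JSON, so the pipeline can be exercised purely from
#' files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_to_files <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  compounds <- simulate_compound_table(cfg)
  uni <- simulate_target_universe(
    cfg, filter_compounds(compounds)$active$compound_id)
  overlap <- intersect_targets(uni$drug, uni$disease)
  ppi <- simulate_ppi(cfg, overlap)
  gmt <- simulate_gene_sets(cfg, unique(c(uni$drug, uni$disease)), overlap)
  paths <- c(
    compounds = file.path(out_dir, "compounds.tsv"),
    target_map = file.path(out_dir, "target_map.tsv"),
    disease = file.path(out_dir, "disease_genes.txt"),
    ppi = file.path(out_dir, "ppi_edges.tsv"),
    gmt = file.path(out_dir, "pathways.gmt"),
    config = file.path(out_dir, "sim_config.json")
  )
  write_compound_table(compounds, paths[["compounds"]])
  write_target_map(uni$map, paths[["target_map"]])
  writeLines(uni$disease, paths[["disease"]])
  write_scored_edges(ppi, paths[["ppi"]])
  write_gmt(gmt, paths[["gmt"]])
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
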
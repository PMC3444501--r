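# End-to-end orchestration: enrichment -> key pathways -> candidate
# universe -> putative targets (docking hits restricted to the universe) ->
# bipartite networks -> minimal PPI sub-network -> module decomposition ->
# machine-readable report. Also houses the report arithmetic: coverage
# percentages and potency ratios, both rounded half-up as conventionally
# printed.

#' Coverage percentage
#'
#' `100 * numerator / denominator`, rounded half-up.
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @param digits Decimal digits to keep (default 0).
#' @return The percentage on the 0-100 scale.
#' @export
#' @examples
#' coverage_percentage(129, 133)  # 97
#' coverage_percentage(33, 120)   # 28
coverage_percentage <- function(numerator, denominator, digits = 0) {
  numerator <- check_count(numerator, "numerator")
  denominator <- check_count(denominator, "denominator")
  if (denominator == 0L) np_stop("domain error: denominator must be positive")
  if (numerator > denominator) {
    np_stop("domain error: numerator must not exceed denominator")
  }
  round_half_up(100 * numerator / denominator, digits)
}

#' Potency ratio of a test compound versus a reference
#'
#' Ratio of half-maximal concentrations (IC50 or EC50, same units), rounded
#' half-up to one decimal. Values above 1 mean the test compound is that
#' many fold less potent than the reference.
#'
#' @param test_value,reference_value Positive concentrations in the same
#'   unit.
#' @param digits Decimal digits to keep (default 1).
#' @return The rounded ratio.
#' @export
#' @examples
#' potency_ratio(403, 8.3)    # 48.6
#' potency_ratio(268, 1.94)   # 138.1
potency_ratio <- function(test_value, reference_value, digits = 1) {
  if (!is.numeric(test_value) || !is.numeric(reference_value) ||
      test_value <= 0 || reference_value <= 0) {
    np_stop("domain error: concentrations must be positive")
  }
  round_half_up(test_value / reference_value, digits)
}

#' Read a potency assay table
#'
#' TSV with columns `assay`, `test_value`, `reference_value` (same unit per
#' row) and optionally `level` and `reference_name`.
#'
#' @param path Path to a TSV file.
#' @return Data frame with an added `ratio` column from [potency_ratio].
#' @export
read_potency_table <- function(path) {
  df <- read_tsv_checked(path, c("assay", "test_value", "reference_value"))
  df$test_value <- as.numeric(df$test_value)
  df$reference_value <- as.numeric(df$reference_value)
  df$ratio <- mapply(potency_ratio, df$test_value, df$reference_value)
  df
}

load_analysis_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) np_stop(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(alpha = 0.05, correction = "none")
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out_dir)) np_stop("config must name out_dir")
  if (is.null(config$simulate) && is.null(config$inputs)) {
    np_stop("config must provide either 'simulate' settings or 'inputs' paths")
  }
  config
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    np_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full network-pharmacology analysis
#'
#' Sequences all stages over the configured inputs (real tables or seeded
#' synthetic data), writes every stage artifact under `out_dir`, and
#' returns the analysis report. Reruns with the same config are
#' bit-identical.
#'
#' Config fields (YAML/JSON file or list): `out_dir`; either `simulate`
#' (arguments of [synth_config]) or `inputs` with paths `drug_target`,
#' `pathways`, `ppi`, `docking`; optional `background` (drug-target TSV for
#' Type III enrichment), `alpha` (default 0.05), `correction`
#' (`"none"`/`"bh"`), `sa` (arguments of [sa_params]), `potency` (path to a
#' potency assay TSV).
#'
#' @param config Path to a YAML/JSON config file, or an equivalent list.
#' @return An `analysis_report` list (also serialized to
#'   `out_dir/report.json`).
#' @export
run_full_analysis <- function(config) {
  cfg <- load_analysis_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  created <- character()
  track <- function(path) { created <<- c(created, path); path }
  tryCatch(
    run_full_analysis_impl(cfg, out, track),
    error = function(e) {
      unlink(created)  # remove partial artifacts
      stop(e)
    })
}

run_full_analysis_impl <- function(cfg, out, track) {
  log_lines <- character()
  logf <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # --- inputs ----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    scfg <- run_stage("simulate", do.call(synth_config, cfg$simulate))
    sim_dir <- file.path(out, "inputs")
    objs <- run_stage("simulate", write_synthetic_inputs(scfg, sim_dir))
    for (f in c("drug_target.tsv", "pathways.tsv", "ppi.tsv", "docking.tsv",
                "ground_truth.json")) {
      track(file.path(sim_dir, f))
    }
    drugs <- objs$drug_target
    collection <- objs$pathways$collection
    ppi <- objs$ppi$network
    docking <- objs$docking
    logf("inputs: simulated with seed %d", scfg$seed)
  } else {
    drugs <- run_stage("read_inputs", read_drug_target_table(cfg$inputs$drug_target))
    collection <- run_stage("read_inputs", read_pathway_collection(cfg$inputs$pathways))
    ppi <- run_stage("read_inputs", read_ppi_edgelist(cfg$inputs$ppi))
    docking <- run_stage("read_inputs", read_docking_hit_table(cfg$inputs$docking))
    logf("inputs: read from configured paths")
  }
  background <- if (!is.null(cfg$background)) {
    run_stage("read_inputs", read_drug_target_table(cfg$background))
  } else NULL

  targets <- sort(unique(drugs$target_gene))
  pathway_genes <- unique(collection$gene_id)
  targets_mapped <- intersect(targets, pathway_genes)
  drug_hits <- drug_pathway_hits(drugs, collection)
  drugs_mapped <- names(drug_hits)[vapply(drug_hits, length, 1L) > 0L]
  pathways_with_targets <- sort(unique(
    collection$pathway_id[collection$gene_id %in% targets_mapped]))

  # --- enrichment and key pathways ------------------------------------
  enr <- run_stage("enrichment", suppressWarnings(
    enrich_pathways(collection, targets, drugs = drugs,
                    background = background, alpha = cfg$alpha)))
  utils::write.table(as.data.frame(unclass(enr)),
                     track(file.path(out, "enrichment.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  key <- run_stage("key_pathways",
                   select_key_pathways(enr, alpha = cfg$alpha,
                                       correction = cfg$correction))
  writeLines(key, track(file.path(out, "key_pathways.txt")))
  universe <- run_stage("candidate_universe",
                        candidate_protein_universe(key, collection))
  logf("enrichment: %d key pathway(s), candidate universe %d gene(s)",
       length(key), length(universe))

  # --- putative targets ------------------------------------------------
  hit_genes <- sort(unique(docking$target_gene))
  putative <- intersect(hit_genes, universe)
  outside <- setdiff(hit_genes, universe)
  if (length(outside)) {
    logf("docking: %d hit gene(s) outside the candidate universe", length(outside))
  }
  logf("putative targets: %d of %d docking hit gene(s)",
       length(putative), length(hit_genes))

  # --- coverage arithmetic ---------------------------------------------
  key_collection <- collection[collection$pathway_id %in% key, , drop = FALSE]
  class(key_collection) <- class(collection)
  targets_covered <- intersect(targets_mapped, unique(key_collection$gene_id))
  drugs_covered <- drugs_mapped[vapply(drug_hits[drugs_mapped],
                                       function(p) any(p %in% key), TRUE)]

  # --- bipartite networks ----------------------------------------------
  nets <- run_stage("bipartite_networks", {
    dt_net <- if (length(putative)) {
      suppressWarnings(build_drug_target(drugs, restrict_targets = putative))
    } else {
      build_drug_target(drugs)
    }
    tp_net <- build_target_pathway(
      if (length(putative)) putative else targets_mapped,
      if (nrow(key_collection)) key_collection else collection)
    dp_net <- build_drug_pathway(drugs, collection)
    list(dt = dt_net, tp = tp_net, dp = dp_net)
  })
  for (nm in names(nets)) {
    fn <- c(dt = "drug_target", tp = "target_pathway", dp = "drug_pathway")[nm]
    lb <- c(dt = "dt", tp = "tp", dp = "tp")[nm]
    if (length(nets[[nm]]$left_nodes) || length(nets[[nm]]$right_nodes)) {
      g <- bipartite_to_igraph(nets[[nm]])
      write_network(g, track(file.path(out, paste0(fn, ".graphml"))), "graphml")
      write_network(g, track(file.path(out, paste0(fn, ".sif"))), "sif",
                    sif_label = lb)
    }
  }
  fits <- run_stage("degree_fits", {
    rows <- lapply(names(nets), function(nm) {
      net <- nets[[nm]]
      sides <- c("left", "right")
      do.call(rbind, lapply(sides, function(s) {
        nodes <- if (s == "left") net$left_nodes else net$right_nodes
        if (!length(nodes)) return(NULL)
        f <- degree_fit(net, s)
        data.frame(network = nm, side = s,
                   gamma = f$exponent, r2 = f$r2, stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
  utils::write.table(fits, track(file.path(out, "degree_fits.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- steiner sub-network and modules ---------------------------------
  steiner_summary <- list(n_mapped = 0L, n_linked = 0L, n_connectors = 0L)
  module_summary <- data.frame()
  partition <- NULL
  if (length(putative) == 0L) {
    np_warn("no putative target inside the candidate universe; sub-network and module stages skipped")
    logf("steiner/modules: skipped (no putative targets)")
  } else {
    sub <- run_stage("steiner", suppressWarnings(
      min_connector_subnetwork(ppi, putative)))
    steiner_summary <- coverage_summary(sub, putative)
    sg <- steiner_to_igraph(sub)
    if (igraph::vcount(sg)) {
      write_network(sg, track(file.path(out, "steiner_subnetwork.graphml")),
                    "graphml")
    }
    jsonlite::write_json(
      list(n_mapped = steiner_summary$n_mapped,
           n_linked = steiner_summary$n_linked,
           connectors = sub$connector_nodes,
           excluded_targets = sub$excluded_targets),
      track(file.path(out, "steiner_report.json")),
      auto_unbox = TRUE, pretty = TRUE)
    if (igraph::ecount(sg) > 0L) {
      sa_cfg <- do.call(sa_params, if (is.null(cfg$sa)) list() else cfg$sa)
      partition <- run_stage("modules", sa_partition(sg, sa_cfg))
      roles <- stats::setNames(igraph::V(sg)$role, igraph::V(sg)$name)
      module_summary <- run_stage("modules",
                                  annotate_modules(partition, sg, roles))
      part_df <- data.frame(node = names(partition$assignment),
                            module = unname(partition$assignment),
                            stringsAsFactors = FALSE)
      part_df$is_hub <- part_df$node %in% module_summary$hub
      utils::write.table(part_df, track(file.path(out, "partition.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logf("modules: %d module(s), Q = %.4f", partition$r, partition$q)
    } else {
      logf("modules: skipped (sub-network has no edges)")
    }
  }

  # --- potency ratios ---------------------------------------------------
  potency <- if (!is.null(cfg$potency)) {
    run_stage("potency", read_potency_table(cfg$potency))
  } else NULL

  report <- list(
    n_drugs_total = length(unique(drugs$drug_id)),
    n_targets_total = length(targets),
    n_targets_pathway_mapped = length(targets_mapped),
    n_drugs_pathway_mapped = length(drugs_mapped),
    n_pathways_with_targets = length(pathways_with_targets),
    key_pathway_ids = key,
    pct_pathways_selected = if (length(pathways_with_targets)) {
      coverage_percentage(sum(key %in% pathways_with_targets),
                          length(pathways_with_targets))
    } else 0,
    n_drugs_covered = length(drugs_covered),
    n_targets_covered = length(targets_covered),
    pct_drugs_covered = if (length(drugs_mapped)) {
      coverage_percentage(length(drugs_covered), length(drugs_mapped))
    } else 0,
    pct_targets_covered = if (length(targets_mapped)) {
      coverage_percentage(length(targets_covered), length(targets_mapped))
    } else 0,
    candidate_universe_size = length(universe),
    putative_target_count = length(putative),
    docking_hits_outside_universe = outside,
    steiner_summary = steiner_summary,
    n_modules = if (!is.null(partition)) partition$r else 0L,
    modularity = if (!is.null(partition)) partition$q else NA,
    module_summary = module_summary,
    potency_ratios = if (!is.null(potency)) {
      potency[c("assay", "test_value", "reference_value", "ratio")]
    } else NULL
  )
  class(report) <- "analysis_report"
  jsonlite::write_json(unclass(report), track(file.path(out, "report.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  writeLines(log_lines, track(file.path(out, "run_log.txt")))
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("network-pharmacology analysis report\n")
  cat(sprintf("  drugs: %d (%d mapped to pathways)\n",
              x$n_drugs_total, x$n_drugs_pathway_mapped))
  cat(sprintf("  targets: %d (%d mapped to pathways)\n",
              x$n_targets_total, x$n_targets_pathway_mapped))
  cat(sprintf("  key pathways: %d of %d with targets (%s%%)\n",
              length(x$key_pathway_ids), x$n_pathways_with_targets,
              x$pct_pathways_selected))
  cat(sprintf("  coverage: %s%% of mapped drugs, %s%% of mapped targets\n",
              x$pct_drugs_covered, x$pct_targets_covered))
  cat(sprintf("  candidate universe: %d genes; putative targets: %d\n",
              x$candidate_universe_size, x$putative_target_count))
  cat(sprintf("  sub-network: %d mapped, %d linked, %d connector(s)\n",
              x$steiner_summary$n_mapped, x$steiner_summary$n_linked,
              x$steiner_summary$n_connectors))
  if (x$n_modules > 0) {
    cat(sprintf("  modules: %d, Q = %.4f\n", x$n_modules, x$modularity))
  }
  invisible(x)
}
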
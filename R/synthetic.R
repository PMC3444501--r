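# Seeded generators producing drug/target/pathway/PPI/docking inputs with
# known ground truth, so every downstream stage is testable without
# database downloads. One global seed expands to per-generator child seeds
# by fixed offsets, so stages can be regenerated independently.

SEED_OFFSETS <- c(drug_target = 1L, pathways = 2L, ppi = 3L, docking = 4L)

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate a desk-scale version of a drug/target/pathway study:
#' a drug class of 174 compounds, 50 therapeutic target genes inside a
#' 2,000-gene pathway universe, 200 pathways of 20-120 members with 10
#' planted target-enriched pathways at 10:1 inclusion odds, small geometric
#' node multiplicity ("regulating points"), and a 4-module stochastic block
#' model PPI graph (15 proteins per module, within/between edge
#' probabilities 0.6/0.05).
#'
#' @param seed Integer master seed; each generator derives a child seed from
#'   it by a fixed offset.
#' @param n_drugs Number of drugs.
#' @param n_targets Number of therapeutic target genes (the first
#'   `n_targets` genes of the universe).
#' @param n_proteins Size of the gene universe from which pathways draw
#'   members.
#' @param n_pathways Number of pathways.
#' @param pathway_size_range Length-2 integer vector (min, max) of pathway
#'   member counts.
#' @param n_enriched_pathways Number of pathways with planted target
#'   enrichment.
#' @param enrichment_odds Ratio (> 0) of target-inclusion weight in enriched
#'   vs background pathways; 1 means no planted signal.
#' @param node_count_geometric_p Probability in (0, 1] of the geometric law
#'   behind per-member node multiplicity: node_count = 1 + Geom(p). With
#'   p = 1 every node_count is 1.
#' @param sbm_modules Number of planted PPI modules.
#' @param sbm_module_size Proteins per planted module.
#' @param p_in,p_out Within/between-module edge probabilities, `p_in > p_out`.
#' @param drug_degree_alpha Power-law exponent (> 1) of the per-drug target
#'   count distribution.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_drugs = 174L,
                         n_targets = 50L,
                         n_proteins = 2000L,
                         n_pathways = 200L,
                         pathway_size_range = c(20L, 120L),
                         n_enriched_pathways = 10L,
                         enrichment_odds = 10,
                         node_count_geometric_p = 0.6,
                         sbm_modules = 4L,
                         sbm_module_size = 15L,
                         p_in = 0.6,
                         p_out = 0.05,
                         drug_degree_alpha = 2.5) {
  cfg <- list(seed = check_count(seed, "seed"),
              n_drugs = check_count(n_drugs, "n_drugs"),
              n_targets = check_count(n_targets, "n_targets"),
              n_proteins = check_count(n_proteins, "n_proteins"),
              n_pathways = check_count(n_pathways, "n_pathways"),
              pathway_size_range = as.integer(pathway_size_range),
              n_enriched_pathways = check_count(n_enriched_pathways,
                                                "n_enriched_pathways"),
              enrichment_odds = enrichment_odds,
              node_count_geometric_p = node_count_geometric_p,
              sbm_modules = check_count(sbm_modules, "sbm_modules"),
              sbm_module_size = check_count(sbm_module_size, "sbm_module_size"),
              p_in = p_in, p_out = p_out,
              drug_degree_alpha = drug_degree_alpha)
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2] ||
      cfg$pathway_size_range[1] < 1L) {
    np_stop("pathway_size_range must be (min, max) with 1 <= min <= max")
  }
  if (cfg$n_enriched_pathways > cfg$n_pathways) {
    np_stop("n_enriched_pathways must not exceed n_pathways")
  }
  if (cfg$enrichment_odds <= 0) np_stop("enrichment_odds must be > 0")
  if (cfg$node_count_geometric_p <= 0 || cfg$node_count_geometric_p > 1) {
    np_stop("node_count_geometric_p must be in (0, 1]")
  }
  if (cfg$p_in < 0 || cfg$p_in > 1 || cfg$p_out < 0 || cfg$p_out > 1) {
    np_stop("p_in and p_out must be probabilities")
  }
  if (cfg$p_in <= cfg$p_out) {
    np_stop("p_in must exceed p_out (planted modules undetectable otherwise)")
  }
  if (cfg$drug_degree_alpha <= 1) np_stop("drug_degree_alpha must be > 1")
  if (cfg$n_targets > cfg$n_proteins) np_stop("n_targets must not exceed n_proteins")
  class(cfg) <- "synth_config"
  cfg
}

#' Gene universe of a synthetic configuration
#'
#' @param cfg A [synth_config].
#' @return Character vector `g0001 ... g<n_proteins>`.
#' @export
synth_gene_universe <- function(cfg) {
  sprintf("g%04d", seq_len(cfg$n_proteins))
}

#' Planted therapeutic target genes
#'
#' The first `n_targets` genes of the universe, so targets are shared
#' between the pathway, PPI and docking generators by construction.
#'
#' @param cfg A [synth_config].
#' @return Character vector of target gene symbols.
#' @export
synth_target_genes <- function(cfg) {
  synth_gene_universe(cfg)[seq_len(cfg$n_targets)]
}

# Discrete power law on support 1..kmax by inverse CDF: P(k) proportional
# to k^-alpha, truncated.
sample_power_law <- function(n, alpha, kmax) {
  k <- seq_len(kmax)
  w <- k^(-alpha)
  cdf <- cumsum(w) / sum(w)
  findInterval(stats::runif(n), cdf) + 1L
}

#' Generate a drug-target table with power-law drug degrees
#'
#' Each drug's target count is drawn from a discrete power law with exponent
#' `drug_degree_alpha` truncated to `[1, n_targets]`; targets are then
#' sampled with mild rank-biased weights so the target side of the bipartite
#' graph is heavy-tailed as well. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config].
#' @return A [drug_target_table]; empty when `n_drugs = 0`.
#' @export
gen_drug_target_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_targets == 0L) np_stop("config error: n_targets must be positive")
  if (cfg$n_drugs == 0L) {
    return(drug_target_table(character(), character()))
  }
  targets <- synth_target_genes(cfg)
  with_seed(cfg$seed + SEED_OFFSETS[["drug_target"]], {
    deg <- sample_power_law(cfg$n_drugs, cfg$drug_degree_alpha, cfg$n_targets)
    target_w <- seq_along(targets)^(-1)
    drug_ids <- sprintf("d%03d", seq_len(cfg$n_drugs))
    atc <- sprintf("C%02dA%s", 1L + (seq_len(cfg$n_drugs) %% 10L),
                   LETTERS[1L + (seq_len(cfg$n_drugs) %% 6L)])
    rows_drug <- rep(drug_ids, deg)
    rows_atc <- rep(atc, deg)
    rows_gene <- unlist(lapply(deg, function(k) {
      sample(targets, k, replace = FALSE, prob = target_w)
    }))
    drug_target_table(rows_drug, rows_gene, rows_atc)
  })
}

#' Generate pathways with planted target enrichment
#'
#' Draws `n_pathways` member sets from the gene universe; in the
#' `n_enriched_pathways` planted pathways each target gene's sampling weight
#' is multiplied by `enrichment_odds`. Every member receives a node
#' multiplicity `1 + Geom(node_count_geometric_p)`.
#'
#' @param cfg A [synth_config].
#' @param targets Character vector of target genes (defaults to
#'   [synth_target_genes]).
#' @return List with elements `collection` (a [pathway_collection]) and
#'   `enriched_ids` (character vector of planted pathway ids).
#' @export
gen_pathways <- function(cfg, targets = synth_target_genes(cfg)) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!length(targets)) np_stop("targets must be nonempty")
  if (cfg$pathway_size_range[1] > cfg$n_proteins) {
    np_stop("config error: pathway_size_range minimum exceeds n_proteins")
  }
  universe <- synth_gene_universe(cfg)
  is_target <- universe %in% targets
  with_seed(cfg$seed + SEED_OFFSETS[["pathways"]], {
    ids <- sprintf("pw%03d", seq_len(cfg$n_pathways))
    enriched <- if (cfg$n_enriched_pathways > 0) {
      sort(sample(ids, cfg$n_enriched_pathways))
    } else character()
    sizes <- sample(seq(cfg$pathway_size_range[1],
                        min(cfg$pathway_size_range[2], cfg$n_proteins)),
                    cfg$n_pathways, replace = TRUE)
    rows <- lapply(seq_len(cfg$n_pathways), function(i) {
      w <- rep(1, cfg$n_proteins)
      if (ids[i] %in% enriched) w[is_target] <- cfg$enrichment_odds
      members <- sample(universe, sizes[i], replace = FALSE, prob = w)
      nc <- 1L + stats::rgeom(sizes[i], cfg$node_count_geometric_p)
      data.frame(pathway_id = ids[i], gene_id = members, node_count = nc,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    coll <- pathway_collection(rows$pathway_id, rows$gene_id,
                               pathway_name = paste0("pathway ", rows$pathway_id),
                               node_count = rows$node_count)
    list(collection = coll, enriched_ids = enriched)
  })
}

#' Generate a PPI network from a stochastic block model
#'
#' Nodes are the first `sbm_modules * sbm_module_size` genes of the
#' universe; edges appear independently with probability `p_in` within a
#' planted module and `p_out` between modules.
#'
#' @param cfg A [synth_config].
#' @return List with `network` (undirected simple `igraph`) and
#'   `true_partition` (named integer vector gene -> module).
#' @export
gen_ppi_sbm <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$sbm_modules < 1L) np_stop("config error: sbm_modules must be >= 1")
  n <- cfg$sbm_modules * cfg$sbm_module_size
  if (n > cfg$n_proteins) np_stop("config error: SBM larger than gene universe")
  genes <- synth_gene_universe(cfg)[seq_len(n)]
  membership <- rep(seq_len(cfg$sbm_modules), each = cfg$sbm_module_size)
  with_seed(cfg$seed + SEED_OFFSETS[["ppi"]], {
    pref <- matrix(cfg$p_out, cfg$sbm_modules, cfg$sbm_modules)
    diag(pref) <- cfg$p_in
    g <- igraph::sample_sbm(n, pref.matrix = pref,
                            block.sizes = rep(cfg$sbm_module_size,
                                              cfg$sbm_modules))
    g <- igraph::set_vertex_attr(g, "name", value = genes)
    list(network = g,
         true_partition = stats::setNames(membership, genes))
  })
}

#' Generate a docking-hit table over planted targets and decoys
#'
#' Every gene in `targets` and `decoys` appears; each gene receives 1-3
#' structure identifiers, so the distinct-gene count never exceeds the row
#' count.
#'
#' @param cfg A [synth_config].
#' @param targets Character vector of planted hit genes.
#' @param decoys Character vector of decoy hit genes (disjoint from
#'   `targets`).
#' @param compound_id Compound identifier for all rows.
#' @return A [docking_hit_table].
#' @export
gen_docking_hits <- function(cfg, targets, decoys = character(),
                             compound_id = "cmpd1") {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(intersect(targets, decoys))) {
    np_stop("targets and decoys must be disjoint")
  }
  genes <- c(sort(unique(targets)), sort(unique(decoys)))
  if (!length(genes)) {
    return(docking_hit_table(character(), character(), character()))
  }
  with_seed(cfg$seed + SEED_OFFSETS[["docking"]], {
    mult <- sample(1:3, length(genes), replace = TRUE)
    rows_gene <- rep(genes, mult)
    structure_id <- sprintf("STR%04d", seq_along(rows_gene))
    docking_hit_table(rep(compound_id, length(rows_gene)), rows_gene,
                      structure_id)
  })
}

#' Write all synthetic inputs plus ground truth to a directory
#'
#' Produces the four pipeline input tables (`drug_target.tsv`,
#' `pathways.tsv`, `ppi.tsv`, `docking.tsv`) and `ground_truth.json` holding
#' the planted enriched pathway ids, PPI partition and docking target genes.
#'
#' @param cfg A [synth_config].
#' @param dir Output directory (created if absent).
#' @param n_docking_targets Number of planted docking-hit genes, sampled
#'   deterministically from the target genes present in the PPI network.
#' @return Invisibly, a list of generated objects.
#' @export
write_synthetic_inputs <- function(cfg, dir, n_docking_targets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dt <- gen_drug_target_table(cfg)
  pw <- gen_pathways(cfg)
  ppi <- gen_ppi_sbm(cfg)
  ppi_targets <- intersect(synth_target_genes(cfg), igraph::V(ppi$network)$name)
  if (is.null(n_docking_targets)) n_docking_targets <- length(ppi_targets)
  planted <- with_seed(cfg$seed + 5L, {
    sort(sample(ppi_targets, min(n_docking_targets, length(ppi_targets))))
  })
  dock <- gen_docking_hits(cfg, planted)

  write_drug_target_table(dt, file.path(dir, "drug_target.tsv"))
  write_pathway_collection(pw$collection, file.path(dir, "pathways.tsv"))
  write_ppi_edgelist(ppi$network, file.path(dir, "ppi.tsv"))
  write_docking_hit_table(dock, file.path(dir, "docking.tsv"))
  truth <- list(enriched_pathways = pw$enriched_ids,
                planted_partition = as.list(ppi$true_partition),
                planted_targets = planted)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(drug_target = dt, pathways = pw, ppi = ppi, docking = dock,
                 planted_targets = planted))
}

#' @rdname write_synthetic_inputs
#' @param table,collection,network Objects to serialize.
#' @param path Output file path.
#' @export
write_drug_target_table <- function(table, path) {
  utils::write.table(as.data.frame(unclass(table)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_synthetic_inputs
#' @export
write_pathway_collection <- function(collection, path) {
  utils::write.table(as.data.frame(unclass(collection)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_synthetic_inputs
#' @export
write_ppi_edgelist <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_synthetic_inputs
#' @export
write_docking_hit_table <- function(table, path) {
  utils::write.table(as.data.frame(unclass(table)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
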
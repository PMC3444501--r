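# Seeded generators: determinism, planted-signal contracts, marginal laws.

test_that("generators are deterministic given the seed and independent of caller RNG", {
  cfg <- synth_config(seed = 1)
  set.seed(999)
  a <- gen_drug_target_table(cfg)
  runif(10)  # disturb the caller stream
  b <- gen_drug_target_table(cfg)
  expect_identical(a, b)
  expect_identical(gen_pathways(cfg), gen_pathways(cfg))
  g1 <- gen_ppi_sbm(cfg)
  g2 <- gen_ppi_sbm(cfg)
  expect_identical(igraph::as_edgelist(g1$network), igraph::as_edgelist(g2$network))
  expect_identical(g1$true_partition, g2$true_partition)
})

test_that("drug-target generator honors size parameters and degenerate cases", {
  cfg0 <- synth_config(seed = 2, n_drugs = 0)
  expect_equal(nrow(gen_drug_target_table(cfg0)), 0L)
  cfg <- synth_config(seed = 2, n_drugs = 40, n_targets = 12)
  tab <- gen_drug_target_table(cfg)
  expect_equal(length(unique(tab$drug_id)), 40L)
  expect_true(all(tab$target_gene %in% synth_target_genes(cfg)))
  expect_true(all(table(tab$drug_id) >= 1))
})

test_that("degree_fit agrees with a direct lm oracle on a generated sample", {
  cfg <- synth_config(seed = 5, n_drugs = 2000, n_targets = 50)
  tab <- gen_drug_target_table(cfg)
  net <- build_drug_target(tab)
  fit <- degree_fit(net, "left")
  # independent fit straight from the association table
  hist <- table(table(tab$drug_id))
  k <- as.integer(names(hist)); cnt <- as.integer(hist)
  oracle <- stats::lm(log(cnt / 2000) ~ log(k))
  expect_equal(fit$exponent, -unname(coef(oracle)[2]), tolerance = 1e-12)
  expect_equal(fit$r2, summary(oracle)$r.squared, tolerance = 1e-12)
})

test_that("log-log OLS slope recovers the planted drug-degree exponent on a large sample", {
  cfg <- synth_config(seed = 5, n_drugs = 20000, n_targets = 50,
                      drug_degree_alpha = 2.5)
  net <- build_drug_target(gen_drug_target_table(cfg))
  fit <- degree_fit(net, "left")
  expect_lt(abs(fit$exponent - 2.5), 0.3)
})

test_that("pathway generator plants enrichment only when odds exceed 1", {
  # null case: enriched and background pathways indistinguishable
  cfg_null <- synth_config(seed = 11, enrichment_odds = 1,
                           n_enriched_pathways = 20)
  pw <- gen_pathways(cfg_null)
  targets <- synth_target_genes(cfg_null)
  frac <- vapply(pathway_members(pw$collection),
                 function(m) mean(names(m) %in% targets), 1)
  is_enr <- names(frac) %in% pw$enriched_ids
  tt <- stats::t.test(frac[is_enr], frac[!is_enr])
  expect_gt(tt$p.value, 0.01)

  # planted case: enriched target fraction strictly greater
  cfg_sig <- synth_config(seed = 11, enrichment_odds = 10,
                          n_enriched_pathways = 10)
  pw2 <- gen_pathways(cfg_sig)
  frac2 <- vapply(pathway_members(pw2$collection),
                  function(m) mean(names(m) %in% targets), 1)
  is_enr2 <- names(frac2) %in% pw2$enriched_ids
  expect_gt(mean(frac2[is_enr2]), mean(frac2[!is_enr2]))
})

test_that("node multiplicity collapses to 1 when the geometric parameter is 1", {
  cfg <- synth_config(seed = 3, node_count_geometric_p = 1)
  pw <- gen_pathways(cfg)
  expect_true(all(pw$collection$node_count == 1L))
})

test_that("SBM generator produces planted blocks at the configured densities", {
  # degenerate: p_in = 1, p_out ~ 0 gives two disjoint cliques
  cfg <- synth_config(seed = 4, sbm_modules = 2, sbm_module_size = 5,
                      p_in = 1, p_out = 1e-9)
  g <- gen_ppi_sbm(cfg)
  expect_equal(igraph::ecount(g$network), 2 * choose(5, 2))
  comp <- igraph::components(g$network)$membership
  expect_equal(unname(comp[names(g$true_partition)]),
               unname(g$true_partition))

  # density check under the default 4x15 block model
  cfg2 <- synth_config(seed = 4, sbm_modules = 4, sbm_module_size = 15,
                       p_in = 0.6, p_out = 0.05)
  g2 <- gen_ppi_sbm(cfg2)
  el <- igraph::as_edgelist(g2$network)
  part <- g2$true_partition
  within <- part[el[, 1]] == part[el[, 2]]
  dens_in <- sum(within) / (4 * choose(15, 2))
  expect_gte(dens_in, 0.5)
  expect_lte(dens_in, 0.7)
  expect_error(synth_config(p_in = 0.05, p_out = 0.6), "p_in")
})

test_that("docking generator covers every planted gene with 1-3 structures", {
  cfg <- synth_config(seed = 6)
  targets <- sprintf("g%04d", 1:39)
  hits <- gen_docking_hits(cfg, targets)
  expect_setequal(unique(hits$target_gene), targets)
  expect_gte(nrow(hits), 39L)
  expect_true(all(table(hits$target_gene) <= 3))
  expect_false(any(duplicated(hits$structure_id)))
  # decoys appear alongside targets and stay disjoint
  hits2 <- gen_docking_hits(cfg, targets[1:5], decoys = c("zz1", "zz2"))
  expect_setequal(unique(hits2$target_gene), c(targets[1:5], "zz1", "zz2"))
  expect_error(gen_docking_hits(cfg, "a", decoys = "a"), "disjoint")
})

test_that("planted-enrichment detection rate is monotone in the odds", {
  odds_levels <- c(1.5, 3, 10)
  recall <- vapply(odds_levels, function(od) {
    mean(vapply(1:20, function(s) {
      cfg <- synth_config(seed = 1000 + s, n_pathways = 100,
                          n_enriched_pathways = 10, enrichment_odds = od)
      pw <- gen_pathways(cfg)
      enr <- suppressWarnings(
        enrich_pathways(pw$collection, synth_target_genes(cfg)))
      key <- select_key_pathways(enr, alpha = 0.05)
      mean(pw$enriched_ids %in% key)
    }, 1))
  }, 1)
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[3], recall[1])
})
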
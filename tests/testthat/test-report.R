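# Report arithmetic and the end-to-end pipeline.

test_that("coverage percentages round half-up from printed counts", {
  expect_equal(coverage_percentage(129, 133), 97)
  expect_equal(coverage_percentage(103, 131), 79)
  expect_equal(coverage_percentage(33, 120), 28)   # 27.5 rounds up
  expect_equal(coverage_percentage(0, 10), 0)
  expect_equal(coverage_percentage(1, 3, digits = 1), 33.3)
  expect_error(coverage_percentage(1, 0), "denominator")
  expect_error(coverage_percentage(5, 3), "numerator")
})

test_that("potency ratios round half-up to one decimal", {
  expect_equal(potency_ratio(403, 8.3), 48.6)
  expect_equal(potency_ratio(268, 1.94), 138.1)
  expect_equal(potency_ratio(1357, 365), 3.7)
  expect_equal(potency_ratio(1.357, 0.365), 3.7)   # unit-consistent pairs
  expect_error(potency_ratio(-1, 2), "positive")
  expect_error(potency_ratio(1, 0), "positive")
})

test_that("shipped potency table reproduces the published ratios", {
  path <- system.file("extdata", "agsiv_potency.tsv", package = "netpharm")
  tab <- read_potency_table(path)
  expect_equal(tab$ratio, c(48.6, 138.1, 3.7))
})

test_that("the full pipeline is deterministic and self-consistent", {
  cfgl <- list(simulate = list(seed = 42, n_drugs = 60, n_targets = 30,
                               n_proteins = 600, n_pathways = 80,
                               n_enriched_pathways = 8),
               sa = list(seed = 7),
               potency = system.file("extdata", "agsiv_potency.tsv",
                                     package = "netpharm"),
               out_dir = withr::local_tempdir())
  rep1 <- suppressWarnings(run_full_analysis(cfgl))
  json1 <- readLines(file.path(cfgl$out_dir, "report.json"))
  cfgl$out_dir <- withr::local_tempdir()
  rep2 <- suppressWarnings(run_full_analysis(cfgl))
  json2 <- readLines(file.path(cfgl$out_dir, "report.json"))
  expect_identical(json1, json2)

  # percentage fields recompute from their numerator/denominator fields
  expect_equal(rep1$pct_drugs_covered,
               coverage_percentage(rep1$n_drugs_covered,
                                   rep1$n_drugs_pathway_mapped))
  expect_equal(rep1$pct_targets_covered,
               coverage_percentage(rep1$n_targets_covered,
                                   rep1$n_targets_pathway_mapped))
  expect_equal(rep1$pct_pathways_selected,
               coverage_percentage(length(rep1$key_pathway_ids),
                                   rep1$n_pathways_with_targets))
  expect_equal(rep1$potency_ratios$ratio, c(48.6, 138.1, 3.7))
  # expected artifacts on disk
  for (f in c("enrichment.tsv", "key_pathways.txt", "report.json",
              "degree_fits.tsv", "run_log.txt")) {
    expect_true(file.exists(file.path(cfgl$out_dir, f)))
  }
})

test_that("putative targets are the docking hits inside the candidate universe", {
  cfg <- synth_config(seed = 42)
  pw <- gen_pathways(cfg)
  dt <- gen_drug_target_table(cfg)
  enr <- suppressWarnings(enrich_pathways(pw$collection,
                                          synth_target_genes(cfg), drugs = dt))
  key <- select_key_pathways(enr)
  uni <- candidate_protein_universe(key, pw$collection)
  ppi <- gen_ppi_sbm(cfg)
  planted <- intersect(synth_target_genes(cfg), igraph::V(ppi$network)$name)
  hits <- gen_docking_hits(cfg, planted)
  cfgl <- list(simulate = list(seed = 42), sa = list(seed = 7),
               out_dir = withr::local_tempdir())
  rep <- suppressWarnings(run_full_analysis(cfgl))
  oracle <- length(intersect(unique(hits$target_gene), uni))
  expect_equal(rep$putative_target_count, oracle)
})

test_that("docking hits outside the universe skip downstream stages gracefully", {
  dir <- withr::local_tempdir()
  # hand-built inputs: docking genes absent from every pathway
  write_drug_target_table(tiny_drugs(), file.path(dir, "dt.tsv"))
  write_pathway_collection(
    pathway_collection(c("P1", "P1", "P2"), c("g1", "g2", "g3")),
    file.path(dir, "pw.tsv"))
  write_ppi_edgelist(ppi_network(c("g1", "g2"), c("g2", "g3")),
                     file.path(dir, "ppi.tsv"))
  write_docking_hit_table(docking_hit_table("c1", "zzz", "s1"),
                          file.path(dir, "dock.tsv"))
  cfgl <- list(inputs = list(drug_target = file.path(dir, "dt.tsv"),
                             pathways = file.path(dir, "pw.tsv"),
                             ppi = file.path(dir, "ppi.tsv"),
                             docking = file.path(dir, "dock.tsv")),
               alpha = 0.9999,   # force some key pathways on the tiny fixture
               out_dir = file.path(dir, "out"))
  expect_warning(rep <- run_full_analysis(cfgl), "no putative target")
  expect_equal(rep$putative_target_count, 0L)
  expect_equal(rep$n_modules, 0L)
  expect_false(file.exists(file.path(dir, "out", "partition.tsv")))
})

test_that("a failing stage removes its partial artifacts", {
  dir <- withr::local_tempdir()
  cfgl <- list(inputs = list(drug_target = file.path(dir, "missing.tsv"),
                             pathways = "x", ppi = "x", docking = "x"),
               out_dir = file.path(dir, "out"))
  expect_error(run_full_analysis(cfgl), "read_inputs")
  expect_false(file.exists(file.path(dir, "out", "report.json")))
})
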
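# Hypergeometric upper tail against enumeration, the three enrichment
# types, key-pathway selection and the candidate universe.

test_that("hypergeometric upper tail matches hand-enumerated probabilities", {
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(6, 4, 5, 10), 0)    # k > min(K, n)
  # C(4,3)C(6,2) + C(4,4)C(6,1) = 60 + 6 = 66 of C(10,5) = 252 draws
  expect_equal(hypergeom_upper_tail(3, 4, 5, 10), 66 / 252, tolerance = 1e-14)
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "domain")
  expect_error(hypergeom_upper_tail(1, 4, 11, 10), "domain")
})

test_that("upper tail agrees with the enumeration oracle and is monotone in k", {
  set.seed(42)
  for (rep in 1:60) {
    N <- sample(2:40, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    ks <- 0:min(K, n)
    p <- vapply(ks, hypergeom_upper_tail, 1, K = K, n = n, N = N)
    p_oracle <- vapply(ks, hyper_enum, 1, K = K, n = n, N = N)
    expect_equal(p, p_oracle, tolerance = 1e-12)
    expect_true(all(diff(p) <= 1e-12))           # non-increasing in k
    # symmetry: drawing K and marking n gives the same tail
    p_swap <- vapply(ks, hypergeom_upper_tail, 1, K = n, n = K, N = N)
    expect_equal(p, p_swap, tolerance = 1e-12)
  }
})

test_that("Type I enrichment counts distinct targets against the pathway universe", {
  coll <- tiny_pathways()   # P1: g1,g2,g5; P2: g2,g3 (universe g1,g2,g3,g5)
  r <- enrich_type1("P2", targets = c("g1", "g5"), coll)
  expect_equal(r[c("k", "K", "n", "N")], list(k = 0L, K = 2L, n = 2L, N = 4L))
  expect_equal(r$p, 1)

  # pathway = universe makes the event certain
  uni <- pathway_collection(rep("P1", 3), c("a", "b", "c"))
  r2 <- enrich_type1("P1", targets = c("a", "b"), uni)
  expect_equal(r2$k, r2$n)
  expect_equal(r2$p, 1)

  # 100-gene universe, 20-gene pathway, 10 targets with 6 in the pathway
  genes <- sprintf("x%03d", 1:100)
  coll3 <- pathway_collection(c(rep("P1", 20), rep("P2", 80)),
                              c(genes[1:20], genes[21:100]))
  targets <- c(genes[1:6], genes[50:53])
  r3 <- enrich_type1("P1", targets, coll3)
  expect_equal(r3$k, 6L)
  expect_equal(r3$p, hyper_enum(6, 20, 10, 100), tolerance = 1e-12)
})

test_that("Type II counts node occurrences and reduces to Type I structure", {
  # single-membership genes with unit counts: p2 equals p1
  coll <- pathway_collection(c("P1", "P1", "P2", "P2", "P2"),
                             c("a", "b", "c", "d", "e"))
  t1 <- enrich_type1("P1", c("a", "c"), coll)
  t2 <- enrich_type2("P1", c("a", "c"), coll)
  expect_equal(t2[c("k", "K", "n", "N", "p")], t1[c("k", "K", "n", "N", "p")])

  # counting contract: one target at 5 of 10 occurrences
  coll2 <- pathway_collection(c("P1", "P1", "P2"), c("a", "b", "c"),
                              node_count = c(5, 5, 7))
  r <- enrich_type2("P1", "a", coll2)
  expect_equal(r$k, 5L)
  expect_equal(r$K, 10L)
  expect_equal(r$n, 5L)
  expect_equal(r$N, 17L)
  expect_equal(r$p, hyper_enum(5, 10, 5, 17), tolerance = 1e-12)
})

test_that("Type II p-values match the enumeration oracle on geometric multiplicities", {
  cfg <- synth_config(seed = 8, n_proteins = 30, n_pathways = 4,
                      pathway_size_range = c(4, 8), n_targets = 6,
                      n_enriched_pathways = 0, enrichment_odds = 1,
                      node_count_geometric_p = 0.5)
  pw <- gen_pathways(cfg)
  coll <- pw$collection
  expect_lte(sum(coll$node_count), 60)   # keeps enumeration cheap
  targets <- synth_target_genes(cfg)
  for (pid in unique(coll$pathway_id)) {
    r <- suppressWarnings(enrich_type2(pid, targets, coll))
    expect_equal(r$p, hyper_enum(r$k, r$K, r$n, r$N), tolerance = 1e-12)
  }
})

test_that("Type III scores drug membership against a background table", {
  coll <- pathway_collection(c("P1", "P1", "P2"), c("g1", "g2", "g3"))
  drugs <- tiny_drugs()  # d1: g1,g2; d2: g1,g3; d3: g4 (unmapped)
  # pathway hit by every mapped drug: certain event
  r <- enrich_type3("P1", drugs, coll)
  expect_equal(r$k, r$n)
  expect_equal(r$p, 1)
  # pathway hit by no drug
  coll2 <- pathway_collection(c("P1", "P2"), c("g1", "zz"))
  r2 <- enrich_type3("P2", drugs, coll2)
  expect_equal(r2$k, 0L)
  expect_equal(r2$p, 1)
  # 50 background drugs, 10-drug class, 20 vs 8 pathway hits
  bg <- drug_target_table(sprintf("b%02d", 1:50),
                          c(rep("g1", 20), rep("g3", 30)))
  cl <- drug_target_table(sprintf("b%02d", 1:10),
                          c(rep("g1", 8), rep("g3", 2)))
  coll3 <- pathway_collection(c("P1", "P2"), c("g1", "g3"))
  r3 <- enrich_type3("P1", cl, coll3, background = bg)
  expect_equal(r3[c("k", "K", "n", "N")], list(k = 8L, K = 20L, n = 10L, N = 50L))
  expect_equal(r3$p, hyper_enum(8, 20, 10, 50), tolerance = 1e-12)
  expect_error(enrich_type3("P1", drug_target_table("d", "none"), coll),
               "no drug maps")
})

test_that("key-pathway selection applies the any-type threshold with deterministic order", {
  res <- data.frame(pathway_id = c("B", "A", "C"),
                    p1 = c(0.04, 1, 0.04), p2 = c(0.5, 1, 0.2),
                    p3 = c(0.5, 1, 0.9))
  expect_equal(select_key_pathways(res, alpha = 0.05), c("B", "C"))
  res_tie <- data.frame(pathway_id = c("B", "A"), p1 = c(0.01, 0.01),
                        p2 = 1, p3 = 1)
  expect_equal(select_key_pathways(res_tie, alpha = 0.05), c("A", "B"))
  all_null <- data.frame(pathway_id = "A", p1 = 1, p2 = 1, p3 = 1)
  expect_equal(select_key_pathways(all_null, alpha = 0.05), character())
  expect_error(select_key_pathways(res, alpha = 1.5), "alpha")
  # BH correction is at least as strict as raw thresholding
  many <- data.frame(pathway_id = sprintf("P%02d", 1:20),
                     p1 = seq(0.001, 0.5, length.out = 20), p2 = 1, p3 = 1)
  expect_true(all(select_key_pathways(many, 0.05, "bh") %in%
                  select_key_pathways(many, 0.05, "none")))
})

test_that("planted pathways are fully recovered at odds 10", {
  cfg <- synth_config(seed = 21, n_pathways = 200, n_targets = 50,
                      n_enriched_pathways = 10, enrichment_odds = 10)
  pw <- gen_pathways(cfg)
  enr <- suppressWarnings(enrich_pathways(pw$collection, synth_target_genes(cfg)))
  key <- select_key_pathways(enr, alpha = 0.05)
  expect_true(all(pw$enriched_ids %in% key))
})

test_that("candidate universe is the union of selected pathway members", {
  coll <- tiny_pathways()
  expect_equal(candidate_protein_universe("P1", coll), c("g1", "g2", "g5"))
  expect_equal(length(candidate_protein_universe(c("P1", "P2"), coll)), 4L)
  expect_error(candidate_protein_universe("nope", coll), "unknown pathway")
  # brute-force union oracle on a synthetic selection
  cfg <- synth_config(seed = 9, n_pathways = 40)
  pw <- gen_pathways(cfg)
  ids <- unique(pw$collection$pathway_id)[1:15]
  uni <- candidate_protein_universe(ids, pw$collection)
  brute <- sort(unique(unlist(lapply(ids, function(i) {
    pw$collection$gene_id[pw$collection$pathway_id == i]
  }))))
  expect_equal(uni, brute)
})
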
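# Independent oracles and fixture builders used across the suite. Each
# oracle is deliberately naive (enumeration, brute force, linear scan) and
# shares no code with the implementation it checks.

# Upper-tail hypergeometric by explicit enumeration of favorable draws:
# sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n).
hyper_enum <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# All set partitions of n elements as restricted-growth strings (rows of a
# matrix). Bell(8) = 4140, Bell(10) = 115975.
set_partitions <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  out <- vector("list", 4200L)
  cnt <- 0L
  a <- rep(1L, n)
  b <- rep(1L, n)  # b[i] = 1 + max(a[1..i-1]) = highest label allowed at i
  for (i in 2:n) b[i] <- max(b[i - 1L], a[i - 1L] + 1L)
  repeat {
    cnt <- cnt + 1L
    if (cnt > length(out)) out <- c(out, vector("list", length(out)))
    out[[cnt]] <- a
    j <- n
    while (j > 1L && a[j] == b[j]) j <- j - 1L
    if (j == 1L) break
    a[j] <- a[j] + 1L
    if (j < n) {
      for (i in (j + 1L):n) {
        a[i] <- 1L
        b[i] <- max(b[i - 1L], a[i - 1L] + 1L)
      }
    }
  }
  do.call(rbind, out[seq_len(cnt)])
}

# Modularity of a membership vector computed straight from the definition,
# independent of the package implementation.
q_direct <- function(edges, deg, L, memb) {
  within <- memb[edges[, 1]] == memb[edges[, 2]]
  d_s <- tapply(deg, memb, sum)
  sum(within) / L - sum((d_s / (2 * L))^2)
}

# Brute-force maximum modularity over all set partitions (vectorized over
# partitions; feasible to n = 10).
best_modularity_brute <- function(graph) {
  n <- igraph::vcount(graph)
  L <- igraph::ecount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  deg <- igraph::degree(graph)
  parts <- set_partitions(n)
  within <- matrix(0L, nrow(parts), nrow(el))
  for (e in seq_len(nrow(el))) {
    within[, e] <- parts[, el[e, 1]] == parts[, el[e, 2]]
  }
  term1 <- rowSums(within) / L
  term2 <- numeric(nrow(parts))
  for (m in seq_len(n)) {
    d_s <- (parts == m) %*% deg
    term2 <- term2 + (d_s / (2 * L))^2
  }
  q <- term1 - term2
  list(q = max(q), assignment = parts[which.max(q), ])
}

# Exhaustive minimum-connector search. Candidates are non-targets adjacent
# to >= 2 targets; a subset is feasible when direct target-target edges
# plus the subset's connector-target stars link every achievable target
# group. Returns the minimum total connector count over the instance
# (summed over components of the direct-or-shared target graph).
exhaustive_min_connectors <- function(ppi, targets) {
  targets <- intersect(targets, igraph::V(ppi)$name)
  nodes <- igraph::V(ppi)$name
  non_targets <- setdiff(nodes, targets)
  nbrs <- igraph::adjacent_vertices(ppi, non_targets)
  cand_t <- list()
  for (i in seq_along(non_targets)) {
    tn <- intersect(nbrs[[i]]$name, targets)
    if (length(tn) >= 2L) cand_t[[non_targets[i]]] <- tn
  }
  sub <- igraph::induced_subgraph(ppi, targets)
  dir_el <- igraph::as_edgelist(sub, names = TRUE)
  # target graph with shared edges to find achievable components
  extra <- do.call(rbind, lapply(cand_t, function(tn) t(utils::combn(tn, 2L))))
  all_el <- rbind(dir_el, extra)
  tg <- igraph::graph_from_data_frame(
    as.data.frame(all_el, stringsAsFactors = FALSE),
    directed = FALSE, vertices = targets)
  comp <- igraph::components(tg)$membership
  total <- 0L
  for (cid in unique(comp)) {
    members <- names(comp)[comp == cid]
    if (length(members) < 2L) next
    cand <- names(cand_t)[vapply(cand_t, function(tn) any(tn %in% members), TRUE)]
    de <- dir_el[dir_el[, 1] %in% members & dir_el[, 2] %in% members, ,
                 drop = FALSE]
    feasible <- function(subset) {
      el2 <- de
      for (x in subset) {
        tn <- intersect(cand_t[[x]], members)
        el2 <- rbind(el2, cbind(x, tn))
      }
      g <- igraph::graph_from_data_frame(
        as.data.frame(el2, stringsAsFactors = FALSE),
        directed = FALSE, vertices = c(members, subset))
      cmp <- igraph::components(g)$membership
      length(unique(cmp[members])) == 1L
    }
    found <- NA_integer_
    for (sz in 0:length(cand)) {
      if (sz == 0L) {
        if (feasible(character())) { found <- 0L; break }
        next
      }
      combos <- utils::combn(cand, sz, simplify = FALSE)
      for (ss in combos) {
        if (feasible(ss)) { found <- sz; break }
      }
      if (!is.na(found)) break
    }
    total <- total + found
  }
  total
}

# Check the one-intermediate constraint on a steiner sub-network output:
# no path between two targets may traverse two consecutive connectors,
# which holds iff no edge joins two connectors.
satisfies_alternation <- function(sub) {
  conn <- sub$connector_nodes
  !any(sub$edges$from %in% conn & sub$edges$to %in% conn)
}

# Random PPI instance with a bounded candidate-connector count, for the
# greedy-vs-exhaustive battery.
rand_connector_instance <- function(seed) {
  set.seed(seed)
  n_t <- sample(4:8, 1)
  n_c <- sample(3:9, 1)   # non-targets
  targets <- sprintf("T%02d", seq_len(n_t))
  others <- sprintf("x%02d", seq_len(n_c))
  from <- character(); to <- character()
  # sparse direct target edges
  tp <- t(utils::combn(targets, 2))
  keep <- runif(nrow(tp)) < 0.12
  from <- c(from, tp[keep, 1]); to <- c(to, tp[keep, 2])
  # connector-target edges
  for (x in others) {
    tn <- sample(targets, sample(0:min(4, n_t), 1))
    from <- c(from, rep(x, length(tn))); to <- c(to, tn)
  }
  if (!length(from)) { from <- targets[1]; to <- targets[2] }
  g <- suppressWarnings(ppi_network(from, to, nodes = c(targets, others)))
  list(ppi = g, targets = targets)
}

# Tiny drug-target fixture: 3 drugs x assorted targets.
tiny_drugs <- function() {
  drug_target_table(
    drug_id = c("d1", "d1", "d2", "d2", "d3"),
    target_gene = c("g1", "g2", "g1", "g3", "g4"),
    atc_codes = c("C01AA05", "C01AA05", "C07AB02", "C07AB02", "C08CA01"))
}

# Tiny pathway fixture: two pathways sharing one gene, explicit node counts.
tiny_pathways <- function() {
  pathway_collection(
    pathway_id = c("P1", "P1", "P1", "P2", "P2"),
    gene_id = c("g1", "g2", "g5", "g2", "g3"),
    node_count = c(2, 1, 1, 1, 3))
}

# Connected-graph battery for exhaustive modularity checks (n <= 8).
small_graph_battery <- function() {
  g <- list(
    path5 = igraph::make_ring(5, circular = FALSE),
    ring6 = igraph::make_ring(6),
    star7 = igraph::make_star(7, mode = "undirected"),
    full5 = igraph::make_full_graph(5),
    two_triangles = igraph::add_edges(
      igraph::make_full_graph(3) + igraph::make_full_graph(3), c(1, 4)),
    barbell44 = igraph::add_edges(
      igraph::make_full_graph(4) + igraph::make_full_graph(4), c(1, 5)),
    tree8 = igraph::make_tree(8, children = 2, mode = "undirected")
  )
  for (s in 1:3) {
    set.seed(100 + s)
    repeat {
      gr <- igraph::sample_gnp(8, 0.35)
      if (igraph::is_connected(gr)) break
    }
    g[[paste0("gnp8_", s)]] <- gr
  }
  g
}
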
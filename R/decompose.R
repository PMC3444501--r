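# Modularity and its maximization by simulated annealing. The metric is the
# standard undirected Newman modularity: the gap between the observed
# fraction of within-module edges and its expectation under degree-
# preserving random rewiring,
#     Q = sum_s [ l_s / L - (d_s / 2L)^2 ],
# with L the edge count, l_s the edges inside module s and d_s the degree
# sum of module s.

#' Modularity of a partition
#'
#' @param graph An undirected `igraph` graph with at least one edge.
#' @param assignment Module membership: an integer vector named by vertex
#'   name, or positional in vertex order.
#' @return Modularity Q in `[-1, 1)`.
#' @export
#' @examples
#' g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
#' g <- igraph::add_edges(g, c(1, 4))
#' modularity_q(g, rep(1:2, each = 3))  # 5/14
modularity_q <- function(graph, assignment) {
  L <- igraph::ecount(graph)
  if (L == 0L) np_stop("domain error: modularity undefined for edgeless graph")
  n <- igraph::vcount(graph)
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  if (!is.null(names(assignment))) {
    if (!all(vnames %in% names(assignment))) {
      np_stop("assignment must cover every vertex")
    }
    assignment <- assignment[vnames]
  }
  if (length(assignment) != n) np_stop("assignment must cover every vertex")
  assignment <- as.integer(factor(assignment))
  el <- igraph::as_edgelist(graph, names = FALSE)
  within <- assignment[el[, 1]] == assignment[el[, 2]]
  deg <- igraph::degree(graph)
  d_s <- tapply(deg, assignment, sum)
  l_s <- tapply(within, assignment[el[, 1]], sum)  # only within edges counted
  sum_l <- sum(within) / L
  sum_d <- sum((d_s / (2 * L))^2)
  sum_l - sum_d
}

#' Simulated-annealing parameters
#'
#' Controls the anneal of [sa_partition]. At each temperature,
#' `move_factor * n^2` single-node reassignment moves and `move_factor * n`
#' collective merge/split moves are attempted; worsening moves are accepted
#' with probability `exp(dQ / T)`. The temperature cools geometrically and
#' the anneal stops after `frozen_threshold` consecutive temperature steps
#' without improvement of the best seen partition.
#'
#' @param seed Integer seed; the anneal is deterministic given the seed.
#' @param t0 Initial temperature; `NULL` calibrates it from the typical
#'   `|dQ|` of a short sample of random moves.
#' @param cooling_factor Geometric cooling factor in (0, 1).
#' @param move_factor Scales the number of moves per temperature.
#' @param frozen_threshold Improvement-free temperature steps before
#'   stopping.
#' @param t_min Hard floor on the temperature.
#' @return An `sa_params` list.
#' @export
sa_params <- function(seed = 1L, t0 = NULL, cooling_factor = 0.995,
                      move_factor = 1, frozen_threshold = 50L,
                      t_min = 1e-8) {
  if (!is.null(t0) && t0 <= 0) np_stop("t0 must be positive")
  if (cooling_factor <= 0 || cooling_factor >= 1) {
    np_stop("cooling_factor must be in (0, 1)")
  }
  if (move_factor <= 0) np_stop("move_factor must be positive")
  structure(list(seed = check_count(seed, "seed"), t0 = t0,
                 cooling_factor = cooling_factor, move_factor = move_factor,
                 frozen_threshold = check_count(frozen_threshold,
                                                "frozen_threshold"),
                 t_min = t_min),
            class = "sa_params")
}

# Anneal one connected component. adj: list of integer neighbor vectors;
# deg: degrees; L: global edge count. Returns integer assignment 1..r.
sa_anneal_component <- function(adj, deg, L, params) {
  n <- length(adj)
  if (n == 1L) return(1L)
  twoL <- 2 * L
  # state: membership vector, per-module degree sums
  memb <- seq_len(n)
  d_mod <- deg
  ki_to <- function(i, m) {
    nb <- adj[[i]]
    if (!length(nb)) return(0)
    sum(memb[nb] == m)
  }
  q_of <- function(mb) {
    l_s <- 0
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (length(nb)) l_s <- l_s + sum(mb[nb] == mb[i])
    }
    l_s <- l_s / 2
    d_s <- tapply(deg, mb, sum)
    l_s / L - sum((d_s / twoL)^2)
  }
  delta_single <- function(i, a, b) {
    ka <- ki_to(i, a) # i currently in a; no self loop so excludes i
    kb <- ki_to(i, b)
    (kb - ka) / L -
      ((d_mod[b] + deg[i])^2 - d_mod[b]^2 +
         (d_mod[a] - deg[i])^2 - d_mod[a]^2) / twoL^2
  }
  apply_single <- function(i, a, b) {
    memb[i] <<- b
    d_mod[a] <<- d_mod[a] - deg[i]
    d_mod[b] <<- d_mod[b] + deg[i]
  }
  cur_q <- q_of(memb)
  best_q <- cur_q
  best_memb <- memb
  # calibrate T0 from the |dQ| scale of sampled random moves
  t0 <- params$t0
  if (is.null(t0)) {
    dqs <- replicate(min(100L, 10L * n), {
      i <- sample.int(n, 1L)
      b <- sample.int(n, 1L)
      abs(delta_single(i, memb[i], b))
    })
    t0 <- max(mean(dqs), 1e-6)
  }
  temp <- t0
  n_single <- max(1L, ceiling(params$move_factor * n^2))
  n_collective <- max(1L, ceiling(params$move_factor * n))
  frozen <- 0L
  while (frozen < params$frozen_threshold && temp > params$t_min) {
    improved <- FALSE
    # single-node reassignment moves
    nodes <- sample.int(n, n_single, replace = TRUE)
    dests <- sample.int(n, n_single, replace = TRUE)
    accept_u <- stats::runif(n_single)
    for (s in seq_len(n_single)) {
      i <- nodes[s]
      a <- memb[i]
      b <- dests[s]  # module label space = 1..n (empty labels allowed)
      if (a == b) next
      dq <- delta_single(i, a, b)
      if (dq >= 0 || accept_u[s] < exp(dq / temp)) {
        apply_single(i, a, b)
        cur_q <- cur_q + dq
        if (cur_q > best_q + 1e-12) {
          best_q <- cur_q
          best_memb <- memb
          improved <- TRUE
        }
      }
    }
    # collective moves: merge two modules or split one
    for (s in seq_len(n_collective)) {
      mods <- unique(memb)
      if (stats::runif(1) < 0.5 && length(mods) >= 2L) {
        ab <- sample(mods, 2L)
        a <- ab[1]; b <- ab[2]
        ia <- which(memb == a)
        l_ab <- sum(vapply(ia, function(i) sum(memb[adj[[i]]] == b), 1))
        dq <- l_ab / L - 2 * d_mod[a] * d_mod[b] / twoL^2
        if (dq >= 0 || stats::runif(1) < exp(dq / temp)) {
          memb[ia] <- b
          d_mod[b] <- d_mod[b] + d_mod[a]
          d_mod[a] <- 0
          cur_q <- cur_q + dq
        }
      } else {
        a <- sample(mods, 1L)
        ia <- which(memb == a)
        if (length(ia) < 2L) next
        free <- setdiff(seq_len(n), mods)
        if (!length(free)) next
        b <- free[1]
        half <- ia[stats::runif(length(ia)) < 0.5]
        if (!length(half) || length(half) == length(ia)) next
        old_memb <- memb; old_d <- d_mod
        dq <- 0
        for (i in half) {
          dq <- dq + delta_single(i, a, b)
          apply_single(i, a, b)
        }
        # one refinement sweep between the two halves
        for (i in ia) {
          from <- memb[i]; to <- if (from == a) b else a
          dq_i <- delta_single(i, from, to)
          if (dq_i > 0) {
            apply_single(i, from, to)
            dq <- dq + dq_i
          }
        }
        if (dq >= 0 || stats::runif(1) < exp(dq / temp)) {
          cur_q <- cur_q + dq
        } else {
          memb <- old_memb
          d_mod <- old_d
        }
      }
      if (cur_q > best_q + 1e-12) {
        best_q <- cur_q
        best_memb <- memb
        improved <- TRUE
      }
    }
    frozen <- if (improved) 0L else frozen + 1L
    temp <- temp * params$cooling_factor
  }
  as.integer(factor(best_memb))
}

#' Partition a graph by simulated-annealing modularity maximization
#'
#' Anneals each connected component independently from a singleton start:
#' single-node reassignments plus collective merge/split moves, Metropolis
#' acceptance `exp(dQ/T)` for worsening moves, geometric cooling, and
#' returns the best partition seen with its modularity recomputed from
#' scratch. Deterministic given `params$seed`.
#'
#' @param graph An undirected `igraph` graph with at least one edge.
#' @param params An [sa_params] object.
#' @return A `partition` list: `assignment` (named integer vector, module
#'   ids contiguous from 1), `r` (number of modules), `q` (modularity).
#' @export
sa_partition <- function(graph, params = sa_params()) {
  stopifnot(inherits(params, "sa_params"))
  if (igraph::ecount(graph) == 0L) {
    np_stop("domain error: modularity undefined for edgeless graph")
  }
  if (is.null(igraph::V(graph)$name)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
  }
  L <- igraph::ecount(graph)
  deg_all <- igraph::degree(graph)
  comp <- igraph::components(graph)$membership
  assignment <- integer(igraph::vcount(graph))
  names(assignment) <- igraph::V(graph)$name
  next_id <- 0L
  with_seed(params$seed, {
    for (cid in sort(unique(comp))) {
      idx <- which(comp == cid)
      sub_names <- igraph::V(graph)$name[idx]
      sub <- igraph::induced_subgraph(graph, idx)
      # neighbor lists in sub-vertex order, but degrees/L are global
      adj <- lapply(igraph::adjacent_vertices(sub, igraph::V(sub)),
                    as.integer)
      sub_deg <- deg_all[match(igraph::V(sub)$name, names(deg_all))]
      memb <- sa_anneal_component(adj, unname(sub_deg), L, params)
      assignment[match(igraph::V(sub)$name, names(assignment))] <-
        memb + next_id
      next_id <- next_id + max(memb)
    }
  })
  assignment <- stats::setNames(as.integer(factor(assignment)),
                                names(assignment))
  structure(list(assignment = assignment,
                 r = length(unique(assignment)),
                 q = modularity_q(graph, assignment)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d module(s), Q = %.4f\n", x$r, x$q))
  invisible(x)
}

#' Per-module report with hubs and node-role composition
#'
#' @param partition A `partition` from [sa_partition].
#' @param graph The partitioned `igraph` graph.
#' @param node_roles Optional named character vector (e.g. `"target"` /
#'   `"connector"`) for role composition.
#' @return Data frame with one row per module: `module`, `size`, `hub`
#'   (highest within-module degree, ties to the lexicographically smaller
#'   name), `members` (semicolon-joined), and when roles are given,
#'   `frac_target` and `frac_connector`.
#' @export
annotate_modules <- function(partition, graph, node_roles = NULL) {
  stopifnot(inherits(partition, "partition"))
  assignment <- partition$assignment
  rows <- lapply(sort(unique(assignment)), function(m) {
    nodes <- sort(names(assignment)[assignment == m])
    sub <- igraph::induced_subgraph(graph, nodes)
    wdeg <- igraph::degree(sub)
    hub <- sort(names(wdeg)[wdeg == max(wdeg)])[1]
    row <- data.frame(module = m, size = length(nodes), hub = hub,
                      members = paste(nodes, collapse = ";"),
                      stringsAsFactors = FALSE)
    if (!is.null(node_roles)) {
      roles <- node_roles[nodes]
      row$frac_target <- mean(roles == "target", na.rm = TRUE)
      row$frac_connector <- mean(roles == "connector", na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
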
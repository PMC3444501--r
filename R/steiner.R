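# Minimal PPI sub-network over putative targets under the one-intermediate
# rule: two targets may be linked directly or through at most one shared
# non-target ("connector") protein. Because intermediates are bounded to a
# single non-target, connector selection at graph distance <= 2 replaces
# general Steiner-tree machinery: within each achievable target group we
# pick connectors by greedy set cover over the target adjacencies they
# realize (direct edges cost nothing).

#' Target adjacency under the one-intermediate rule
#'
#' For every pair of targets, records a `"direct"` edge when the PPI
#' contains the edge itself, otherwise a `"shared"` edge labeled with the
#' non-target proteins adjacent to both. Targets at PPI distance greater
#' than 2 get no edge. Targets absent from the PPI are dropped with a
#' warning and reported in `unmapped`.
#'
#' @param ppi An undirected `igraph` PPI network.
#' @param targets Character vector of target genes.
#' @return A `target_adjacency` list: `targets` (mapped), `unmapped`,
#'   `edges` (data frame `t1`, `t2`, `type`, `connectors` --
#'   semicolon-joined shared neighbors, `""` for direct edges).
#' @export
target_adjacency <- function(ppi, targets) {
  targets <- unique(as.character(targets))
  nodes <- igraph::V(ppi)$name
  unmapped <- setdiff(targets, nodes)
  if (length(unmapped)) {
    np_warn(sprintf("%d target(s) absent from the PPI network", length(unmapped)))
  }
  mapped <- sort(intersect(targets, nodes))
  edges <- data.frame(t1 = character(), t2 = character(), type = character(),
                      connectors = character(), stringsAsFactors = FALSE)
  if (length(mapped) >= 2L) {
    sub <- igraph::induced_subgraph(ppi, mapped)
    el <- igraph::as_edgelist(sub, names = TRUE)
    direct <- if (nrow(el)) {
      data.frame(t1 = pmin(el[, 1], el[, 2]), t2 = pmax(el[, 1], el[, 2]),
                 type = "direct", connectors = "", stringsAsFactors = FALSE)
    } else edges
    # shared non-target neighbors
    pair_conn <- list()
    non_targets <- setdiff(nodes, mapped)
    nbrs <- igraph::adjacent_vertices(ppi, non_targets)
    for (i in seq_along(non_targets)) {
      tn <- intersect(nbrs[[i]]$name, mapped)
      if (length(tn) >= 2L) {
        tn <- sort(tn)
        pairs <- utils::combn(tn, 2L)
        for (j in seq_len(ncol(pairs))) {
          key <- paste(pairs[1, j], pairs[2, j], sep = "\r")
          pair_conn[[key]] <- c(pair_conn[[key]], non_targets[i])
        }
      }
    }
    if (length(pair_conn)) {
      dkey <- paste(direct$t1, direct$t2, sep = "\r")
      skey <- setdiff(names(pair_conn), dkey)
      if (length(skey)) {
        parts <- strsplit(skey, "\r", fixed = TRUE)
        shared <- data.frame(
          t1 = vapply(parts, `[[`, "", 1L),
          t2 = vapply(parts, `[[`, "", 2L),
          type = "shared",
          connectors = vapply(pair_conn[skey],
                              function(x) paste(sort(x), collapse = ";"), ""),
          stringsAsFactors = FALSE)
        direct <- rbind(direct, shared)
      }
    }
    edges <- direct[order(direct$t1, direct$t2), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(targets = mapped, unmapped = sort(unmapped), edges = edges),
            class = "target_adjacency")
}

#' Minimal connector sub-network linking the targets
#'
#' Primary objective: link as many targets as possible into connected
#' groups under the one-intermediate rule; secondary objective: use as few
#' connector proteins as possible. Achievable groupings are the connected
#' components of the direct-or-shared target adjacency; within each
#' component connectors are chosen greedily, each step picking the candidate
#' that merges the most currently disconnected target groups (ties: more
#' target neighbors, then lexicographically smaller id). Direct target-target
#' edges cost nothing. Targets linkable to no other target stay as singleton
#' components and are reported in `excluded_targets` together with targets
#' absent from the PPI.
#'
#' @param ppi An undirected `igraph` PPI network.
#' @param targets Character vector of target genes.
#' @return A `steiner_subnetwork` list: `target_nodes`, `connector_nodes`,
#'   `edges` (data frame `from`, `to`), `excluded_targets`, `components`
#'   (list of node-name vectors), `unmapped`.
#' @export
min_connector_subnetwork <- function(ppi, targets) {
  if (!length(targets)) np_stop("targets must be nonempty")
  adj <- target_adjacency(ppi, targets)
  mapped <- adj$targets
  if (!length(mapped)) {
    np_warn("no target maps onto the PPI network; empty sub-network")
    return(structure(list(target_nodes = character(),
                          connector_nodes = character(),
                          edges = data.frame(from = character(), to = character(),
                                             stringsAsFactors = FALSE),
                          excluded_targets = sort(unique(targets)),
                          components = list(), unmapped = adj$unmapped),
                     class = "steiner_subnetwork"))
  }
  # components of the direct-or-shared target graph
  tg <- igraph::graph_from_data_frame(adj$edges[c("t1", "t2")],
                                      directed = FALSE, vertices = mapped)
  comp <- igraph::components(tg)$membership
  # candidate connectors per component: shared neighbors with their target sets
  conn_targets <- list()
  shared <- adj$edges[adj$edges$type == "shared", , drop = FALSE]
  if (nrow(shared)) {
    for (i in seq_len(nrow(shared))) {
      for (x in strsplit(shared$connectors[i], ";", fixed = TRUE)[[1]]) {
        conn_targets[[x]] <- unique(c(conn_targets[[x]],
                                      shared$t1[i], shared$t2[i]))
      }
    }
  }
  selected <- character()
  for (cid in sort(unique(comp))) {
    members <- sort(names(comp)[comp == cid])
    if (length(members) < 2L) next
    # union-find over direct edges
    parent <- stats::setNames(members, members)
    find <- function(x) {
      while (parent[[x]] != x) {
        parent[[x]] <<- parent[[parent[[x]]]]
        x <- parent[[x]]
      }
      x
    }
    union2 <- function(a, b) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[[ra]] <<- rb
    }
    dir_e <- adj$edges[adj$edges$type == "direct" & adj$edges$t1 %in% members, ,
                       drop = FALSE]
    for (i in seq_len(nrow(dir_e))) union2(dir_e$t1[i], dir_e$t2[i])
    n_groups <- length(unique(vapply(members, find, "")))
    cand <- names(conn_targets)[vapply(conn_targets,
                                       function(tn) any(tn %in% members), TRUE)]
    cand <- sort(setdiff(cand, selected))
    while (n_groups > 1L) {
      roots <- lapply(cand, function(x) {
        unique(vapply(intersect(conn_targets[[x]], members), find, ""))
      })
      gain <- vapply(roots, length, 1L) - 1L
      cover <- vapply(cand, function(x) {
        length(intersect(conn_targets[[x]], members))
      }, 1L)
      if (!length(cand) || max(gain) < 1L) break  # unreachable by construction
      ord <- order(-gain, -cover, cand)
      best <- ord[1]
      x <- cand[best]
      tn <- intersect(conn_targets[[x]], members)
      for (t in tn[-1]) union2(tn[1], t)
      n_groups <- n_groups - gain[best]
      selected <- c(selected, x)
      cand <- setdiff(cand, x)
    }
  }
  selected <- sort(selected)
  # assemble edges: direct target-target plus connector-target
  dir_e <- adj$edges[adj$edges$type == "direct", , drop = FALSE]
  edges <- data.frame(from = dir_e$t1, to = dir_e$t2, stringsAsFactors = FALSE)
  for (x in selected) {
    tn <- sort(conn_targets[[x]])
    edges <- rbind(edges, data.frame(from = x, to = tn, stringsAsFactors = FALSE))
  }
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = c(mapped, selected))
  cm <- igraph::components(g)$membership
  comps <- split(names(cm), cm)
  names(comps) <- NULL
  singleton <- vapply(comps, function(nodes) {
    sum(nodes %in% mapped) < 2L
  }, TRUE)
  excluded <- sort(c(adj$unmapped,
                     unlist(lapply(comps[singleton],
                                   function(nodes) intersect(nodes, mapped)))))
  structure(list(target_nodes = mapped, connector_nodes = selected,
                 edges = edges, excluded_targets = excluded,
                 components = comps, unmapped = adj$unmapped),
            class = "steiner_subnetwork")
}

#' @export
print.steiner_subnetwork <- function(x, ...) {
  cat(sprintf(
    "steiner sub-network: %d target(s), %d connector(s), %d edge(s), %d component(s)\n",
    length(x$target_nodes), length(x$connector_nodes), nrow(x$edges),
    length(x$components)))
  invisible(x)
}

#' Coverage summary of a target sub-network
#'
#' @param sub A `steiner_subnetwork`.
#' @param targets The original target gene vector.
#' @return List with `n_mapped` (targets present in the PPI), `n_linked`
#'   (targets in the largest linked component) and `n_connectors`.
#' @export
coverage_summary <- function(sub, targets) {
  stopifnot(inherits(sub, "steiner_subnetwork"))
  targets <- unique(as.character(targets))
  n_mapped <- length(intersect(targets, sub$target_nodes))
  n_linked <- if (length(sub$components)) {
    max(vapply(sub$components, function(nodes) {
      length(intersect(nodes, sub$target_nodes))
    }, 1L))
  } else 0L
  list(n_mapped = n_mapped, n_linked = n_linked,
       n_connectors = length(sub$connector_nodes))
}

#' Convert a steiner sub-network to igraph
#'
#' Vertices carry a `role` attribute, `"target"` or `"connector"`.
#'
#' @param sub A `steiner_subnetwork`.
#' @return An undirected `igraph` graph.
#' @export
steiner_to_igraph <- function(sub) {
  stopifnot(inherits(sub, "steiner_subnetwork"))
  verts <- data.frame(
    name = c(sub$target_nodes, sub$connector_nodes),
    role = c(rep("target", length(sub$target_nodes)),
             rep("connector", length(sub$connector_nodes))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(sub$edges, directed = FALSE, vertices = verts)
}
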
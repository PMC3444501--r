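# Bipartite drug-target, target-pathway and drug-pathway networks and
# their power-law degree diagnostics.

new_bipartite <- function(left, right, edges, left_role, right_role,
                          node_attrs = list()) {
  left <- sort(unique(as.character(left)))
  right <- sort(unique(as.character(right)))
  overlap <- intersect(left, right)
  if (length(overlap)) {
    np_stop(sprintf("left and right node sets must be disjoint (%s)",
                    paste(utils::head(overlap, 3), collapse = ", ")))
  }
  if (nrow(edges)) {
    stopifnot(all(edges[[1]] %in% left), all(edges[[2]] %in% right))
    edges <- unique(data.frame(left = as.character(edges[[1]]),
                               right = as.character(edges[[2]]),
                               stringsAsFactors = FALSE))
    edges <- edges[order(edges$left, edges$right), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(left = character(), right = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(left_nodes = left, right_nodes = right, edges = edges,
                 left_role = left_role, right_role = right_role,
                 node_attrs = node_attrs),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite network: %d %s node(s), %d %s node(s), %d edge(s)\n",
              length(x$left_nodes), x$left_role,
              length(x$right_nodes), x$right_role, nrow(x$edges)))
  invisible(x)
}

#' Build the drug-target bipartite network
#'
#' One edge per drug-target association. With `restrict_targets`, only drugs
#' sharing at least one target with the restriction set are kept, together
#' with *all* their targets — the construction used to relate a query
#' compound's putative targets to the approved drugs acting on them.
#' Node attributes carry each drug's ATC codes truncated to the 4th level.
#'
#' @param drugs A [drug_target_table].
#' @param restrict_targets Optional character vector of target genes.
#' @return A `bipartite_network` with drug (left) and target (right) nodes.
#' @export
build_drug_target <- function(drugs, restrict_targets = NULL) {
  stopifnot(inherits(drugs, "drug_target_table"))
  df <- as.data.frame(unclass(drugs), stringsAsFactors = FALSE)
  if (!is.null(restrict_targets)) {
    keep <- unique(df$drug_id[df$target_gene %in% restrict_targets])
    if (!length(keep)) {
      np_warn("target restriction matches no drug; returning empty network")
      return(new_bipartite(character(), character(),
                           data.frame(left = character(), right = character()),
                           "drug", "target"))
    }
    df <- df[df$drug_id %in% keep, , drop = FALSE]
  }
  atc4 <- function(codes) {
    parts <- unlist(strsplit(codes, ";", fixed = TRUE))
    paste(unique(substr(parts[nzchar(parts)], 1, 5)), collapse = ";")
  }
  atc_map <- vapply(split(df$atc_codes, df$drug_id),
                    function(x) atc4(x[1]), "")
  new_bipartite(df$drug_id, df$target_gene,
                data.frame(left = df$drug_id, right = df$target_gene),
                "drug", "target",
                node_attrs = list(atc_level4 = atc_map))
}

#' Build the target-pathway bipartite network
#'
#' An edge links a target to every pathway it belongs to. Targets belonging
#' to no pathway are retained as isolated nodes.
#'
#' @param targets Character vector of target genes.
#' @param collection A [pathway_collection].
#' @return A `bipartite_network` with target (left) and pathway (right)
#'   nodes.
#' @export
build_target_pathway <- function(targets, collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  targets <- unique(as.character(targets))
  hit <- collection[collection$gene_id %in% targets, , drop = FALSE]
  pw_ids <- sort(unique(collection$pathway_id))
  new_bipartite(targets, pw_ids,
                data.frame(left = hit$gene_id, right = hit$pathway_id),
                "target", "pathway")
}

#' Build the drug-pathway bipartite network
#'
#' A drug links to a pathway when at least one of its targets is a member;
#' multiple supporting targets still yield a single edge.
#'
#' @param drugs A [drug_target_table].
#' @param collection A [pathway_collection].
#' @return A `bipartite_network` with drug (left) and pathway (right) nodes.
#' @export
build_drug_pathway <- function(drugs, collection) {
  stopifnot(inherits(drugs, "drug_target_table"),
            inherits(collection, "pathway_collection"))
  hits <- drug_pathway_hits(drugs, collection)
  edges <- data.frame(
    left = rep(names(hits), vapply(hits, length, 1L)),
    right = unlist(hits, use.names = FALSE),
    stringsAsFactors = FALSE)
  new_bipartite(unique(drugs$drug_id), sort(unique(collection$pathway_id)),
                edges, "drug", "pathway")
}

#' Degree histogram and power-law fit for one side of a bipartite network
#'
#' Builds the degree histogram of the chosen side (isolated nodes included
#' in the histogram as degree 0) and fits an ordinary least-squares line to
#' `(log k, log p(k))` over degrees `k >= 1` with nonzero counts. The
#' returned `exponent` is the magnitude of the fitted slope; it is `NA` when
#' fewer than 3 distinct positive degrees are observed.
#'
#' @param network A `bipartite_network`.
#' @param side `"left"` or `"right"`.
#' @return A `degree_fit` list: `degrees` (named count vector), `exponent`,
#'   `r2`.
#' @export
degree_fit <- function(network, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(network, "bipartite_network"))
  nodes <- if (side == "left") network$left_nodes else network$right_nodes
  col <- if (side == "left") "left" else "right"
  if (!length(nodes)) np_stop(sprintf("%s side is empty", side))
  deg <- stats::setNames(rep(0L, length(nodes)), nodes)
  tab <- table(network$edges[[col]])
  deg[names(tab)] <- as.integer(tab)
  hist <- table(deg)
  fit <- fit_power_law_hist(as.integer(names(hist)), as.integer(hist),
                            length(nodes))
  structure(list(degrees = hist, exponent = fit$exponent, r2 = fit$r2),
            class = "degree_fit")
}

# OLS fit of log p(k) ~ log k over positive degrees with nonzero counts.
fit_power_law_hist <- function(k, count, n_nodes) {
  keep <- k >= 1L & count > 0L
  k <- k[keep]; count <- count[keep]
  if (length(k) < 3L) {
    return(list(exponent = NA_real_, r2 = NA_real_))
  }
  p <- count / n_nodes
  fit <- stats::lm(log(p) ~ log(k))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(exponent = -unname(stats::coef(fit)[2]), r2 = r2)
}

#' Convert a bipartite network to igraph
#'
#' Vertices carry `role` (the side's role label) and `type` (`FALSE` for
#' left, `TRUE` for right) attributes, suitable for GraphML export.
#'
#' @param network A `bipartite_network`.
#' @return An undirected `igraph` graph.
#' @export
bipartite_to_igraph <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  verts <- data.frame(
    name = c(network$left_nodes, network$right_nodes),
    role = c(rep(network$left_role, length(network$left_nodes)),
             rep(network$right_role, length(network$right_nodes))),
    type = c(rep(FALSE, length(network$left_nodes)),
             rep(TRUE, length(network$right_nodes))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = verts)
  if (length(network$node_attrs)) {
    for (attr in names(network$node_attrs)) {
      vals <- network$node_attrs[[attr]]
      m <- vals[igraph::V(g)$name]
      g <- igraph::set_vertex_attr(g, attr,
                                   value = ifelse(is.na(m), "", m))
    }
  }
  g
}
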
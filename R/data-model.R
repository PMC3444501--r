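# Domain types and readers/writers for the tabular and graph formats the
# pipeline touches. Gene identity is a case-sensitive string symbol
# throughout; callers harmonize identifiers before loading.

#' Construct a drug-target association table
#'
#' One row per (drug, target) association. ATC codes are carried as a
#' semicolon-separated string per row (a drug's codes are repeated across its
#' rows). Duplicate (drug_id, target_gene) pairs collapse to one association,
#' as database exports commonly repeat rows per evidence line.
#'
#' @param drug_id Character vector of drug identifiers.
#' @param target_gene Character vector of target gene symbols.
#' @param atc_codes Character vector of semicolon-separated ATC codes
#'   (optional; defaults to empty strings).
#' @param warn_duplicates Emit a warning when duplicate associations are
#'   collapsed.
#' @return A `drug_target_table`, a data frame with columns `drug_id`,
#'   `atc_codes`, `target_gene`.
#' @export
#' @examples
#' drug_target_table(c("d1", "d1", "d2"), c("g1", "g2", "g1"))
drug_target_table <- function(drug_id, target_gene, atc_codes = NULL,
                              warn_duplicates = FALSE) {
  drug_id <- as.character(drug_id)
  target_gene <- as.character(target_gene)
  if (is.null(atc_codes)) atc_codes <- rep("", length(drug_id))
  atc_codes <- as.character(atc_codes)
  if (length(target_gene) != length(drug_id) ||
      length(atc_codes) != length(drug_id)) {
    np_stop("drug_id, atc_codes and target_gene must have equal length")
  }
  if (length(drug_id) && (any(!nzchar(drug_id)) || any(!nzchar(target_gene)))) {
    np_stop("drug_id and target_gene must be non-empty strings")
  }
  df <- data.frame(drug_id = drug_id, atc_codes = atc_codes,
                   target_gene = target_gene, stringsAsFactors = FALSE)
  dup <- duplicated(df[c("drug_id", "target_gene")])
  if (any(dup)) {
    if (warn_duplicates) {
      np_warn(sprintf("collapsed %d duplicate drug-target row(s)", sum(dup)))
    }
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$drug_id, df$target_gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("drug_target_table", "data.frame")
  df
}

#' Construct a pathway membership collection
#'
#' Long-format membership table: one row per (pathway, gene) with a positive
#' `node_count` giving the number of distinct nodes ("regulating points") the
#' gene occupies on the pathway map. Repeated (pathway, gene) rows sum their
#' node counts.
#'
#' @param pathway_id,gene_id Character vectors.
#' @param pathway_name Character vector of display names (optional).
#' @param node_count Positive integer vector (default 1).
#' @return A `pathway_collection` data frame with columns `pathway_id`,
#'   `pathway_name`, `gene_id`, `node_count`.
#' @export
pathway_collection <- function(pathway_id, gene_id, pathway_name = NULL,
                               node_count = NULL) {
  pathway_id <- as.character(pathway_id)
  gene_id <- as.character(gene_id)
  n <- length(pathway_id)
  if (is.null(pathway_name)) pathway_name <- pathway_id
  if (is.null(node_count)) node_count <- rep(1L, n)
  if (length(gene_id) != n || length(pathway_name) != n ||
      length(node_count) != n) {
    np_stop("pathway_id, pathway_name, gene_id, node_count must have equal length")
  }
  node_count <- as.numeric(node_count)
  if (n && (any(is.na(node_count)) || any(node_count < 1) ||
            any(node_count != floor(node_count)))) {
    np_stop("node_count must be a positive integer for every member")
  }
  df <- data.frame(pathway_id = pathway_id,
                   pathway_name = as.character(pathway_name),
                   gene_id = gene_id,
                   node_count = as.integer(node_count),
                   stringsAsFactors = FALSE)
  if (n) {
    agg <- stats::aggregate(node_count ~ pathway_id + gene_id, data = df, FUN = sum)
    names_map <- df$pathway_name[!duplicated(df$pathway_id)]
    names(names_map) <- df$pathway_id[!duplicated(df$pathway_id)]
    df <- data.frame(pathway_id = agg$pathway_id,
                     pathway_name = unname(names_map[agg$pathway_id]),
                     gene_id = agg$gene_id,
                     node_count = as.integer(agg$node_count),
                     stringsAsFactors = FALSE)
    df <- df[order(df$pathway_id, df$gene_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("pathway_collection", "data.frame")
  df
}

#' Pathway members as a named list
#'
#' @param collection A `pathway_collection`.
#' @return Named list mapping pathway_id to a named integer vector of
#'   node counts (names are gene ids).
#' @export
pathway_members <- function(collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  split_counts <- split(stats::setNames(collection$node_count, collection$gene_id),
                        collection$pathway_id)
  split_counts
}

#' Construct an undirected PPI network
#'
#' Self-loops are dropped (with a warning) and duplicate/reciprocal edges
#' collapse, yielding a simple undirected [igraph][igraph::graph] graph.
#'
#' @param from,to Character vectors of interacting gene symbols.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   nodes to include.
#' @return An undirected simple `igraph` graph with vertex `name` attributes.
#' @export
ppi_network <- function(from, to, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  stopifnot(length(from) == length(to))
  loops <- from == to
  if (any(loops)) {
    np_warn(sprintf("dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]
    to <- to[!loops]
  }
  verts <- sort(unique(c(from, to, as.character(nodes))))
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = FALSE,
                                     vertices = verts)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Construct a docking-hit table
#'
#' Stand-in container for inverse-docking output: one row per docked
#' structure, so a gene with several solved structures repeats across rows.
#'
#' @param compound_id,target_gene,structure_id Character vectors of equal
#'   length.
#' @return A `docking_hit_table` data frame.
#' @export
docking_hit_table <- function(compound_id, target_gene, structure_id) {
  compound_id <- as.character(compound_id)
  target_gene <- as.character(target_gene)
  structure_id <- as.character(structure_id)
  stopifnot(length(target_gene) == length(compound_id),
            length(structure_id) == length(compound_id))
  df <- data.frame(compound_id = compound_id, target_gene = target_gene,
                   structure_id = structure_id, stringsAsFactors = FALSE)
  df <- df[order(df$compound_id, df$target_gene, df$structure_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("docking_hit_table", "data.frame")
  df
}

# Shared TSV reader: UTF-8, tab-separated, '#' comments.
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) np_stop(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                      colClasses = "character", stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8", check.names = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        np_stop(sprintf("empty input file: %s", path))
      }
      stop(e)
    })
  if (nrow(df) == 0 && ncol(df) == 0) np_stop(sprintf("empty input file: %s", path))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    np_stop(sprintf("format error in %s: missing column(s) %s",
                    path, paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) np_stop(sprintf("empty input file (no data rows): %s", path))
  df
}

#' Read a drug-target TSV
#'
#' Expects a header `drug_id`, `atc_codes` (semicolon-separated, may be
#' empty), `target_gene`. Duplicate rows collapse to one association with a
#' warning.
#'
#' @param path Path to a TSV file.
#' @return A [drug_target_table].
#' @export
read_drug_target_table <- function(path) {
  df <- read_tsv_checked(path, c("drug_id", "atc_codes", "target_gene"))
  drug_target_table(df$drug_id, df$target_gene, df$atc_codes,
                    warn_duplicates = TRUE)
}

#' Read a pathway membership TSV
#'
#' Expects header `pathway_id`, `pathway_name`, `gene_id`, `node_count`.
#' Repeated (pathway, gene) rows sum their node counts.
#'
#' @param path Path to a TSV file.
#' @return A [pathway_collection].
#' @export
read_pathway_collection <- function(path) {
  df <- read_tsv_checked(path, c("pathway_id", "pathway_name", "gene_id", "node_count"))
  nc <- suppressWarnings(as.numeric(df$node_count))
  if (any(is.na(nc))) np_stop(sprintf("non-numeric node_count in %s", path))
  if (any(nc < 1)) np_stop(sprintf("node_count < 1 in %s", path))
  pathway_collection(df$pathway_id, df$gene_id, df$pathway_name, nc)
}

#' Read a PPI edge list
#'
#' Two-column TSV of gene pairs (header `gene_a`, `gene_b`, or any two
#' columns). Reciprocal duplicates collapse; self-loops are dropped with a
#' warning.
#'
#' @param path Path to a TSV file.
#' @return An undirected simple `igraph` graph.
#' @export
read_ppi_edgelist <- function(path) {
  if (!file.exists(path)) np_stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (!length(lines)) np_stop(sprintf("empty input file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    np_stop(sprintf("format error in %s at line %d: expected 2 tab-separated fields",
                    path, bad[1]))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  # tolerate a header line
  if (identical(tolower(a[1]), "gene_a") || identical(tolower(a[1]), "from")) {
    a <- a[-1]; b <- b[-1]
  }
  if (!length(a)) np_stop(sprintf("empty input file (no data rows): %s", path))
  ppi_network(a, b)
}

#' Read a docking-hit TSV
#'
#' Expects header `compound_id`, `target_gene`, `structure_id`; one row per
#' docked structure.
#'
#' @param path Path to a TSV file.
#' @return A [docking_hit_table].
#' @export
read_docking_hit_table <- function(path) {
  df <- read_tsv_checked(path, c("compound_id", "target_gene", "structure_id"))
  docking_hit_table(df$compound_id, df$target_gene, df$structure_id)
}

#' Write a network to GraphML or SIF
#'
#' GraphML output preserves all vertex attributes (including the `role`
#' attribute set by pipeline stages). SIF output writes one interaction per
#' line with the given interaction label; isolated vertices are written as
#' single-field lines.
#'
#' @param graph An `igraph` graph.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @param sif_label Interaction label for SIF output (e.g. `"pp"`, `"dt"`,
#'   `"tp"`); ignored for GraphML. If the graph has an edge attribute
#'   `interaction` it takes precedence.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("graphml", "sif"),
                          sif_label = "pp") {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph, names = TRUE)
    lab <- if ("interaction" %in% igraph::edge_attr_names(graph)) {
      igraph::edge_attr(graph, "interaction")
    } else {
      rep(sif_label, nrow(el))
    }
    lines <- if (nrow(el)) paste(el[, 1], lab, el[, 2], sep = "\t") else character()
    iso <- setdiff(igraph::V(graph)$name,
                   unique(c(el[, 1], el[, 2])))
    writeLines(c(lines, iso), path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a network written by [write_network]
#'
#' @param path File path.
#' @param format `"graphml"` or `"sif"`.
#' @return An undirected `igraph` graph.
#' @export
read_network <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) np_stop(sprintf("file not found: %s", path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g)
    return(g)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(!nf %in% c(1L, 3L))) {
    np_stop(sprintf("format error in %s at line %d: SIF lines have 1 or 3 fields",
                    path, which(!nf %in% c(1L, 3L))[1]))
  }
  edges <- fields[nf == 3L]
  iso <- unlist(fields[nf == 1L])
  a <- vapply(edges, `[[`, "", 1L)
  b <- vapply(edges, `[[`, "", 3L)
  lab <- vapply(edges, `[[`, "", 2L)
  g <- ppi_network(a, b, nodes = iso)
  if (igraph::ecount(g)) {
    el <- igraph::as_edgelist(g)
    key <- function(x, y) paste(pmin(x, y), pmax(x, y))
    m <- match(key(el[, 1], el[, 2]), key(a, b))
    g <- igraph::set_edge_attr(g, "interaction", value = lab[m])
  }
  g
}
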
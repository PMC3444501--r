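# Three hypergeometric pathway-enrichment statistics over a drug class and
# its targets, key-pathway selection, and the candidate protein universe
# the selected pathways define.
#
# All three types score the upper tail P(X >= k) of a hypergeometric
# distribution with population N, K marked items, and n draws:
#   Type I   - distinct target genes among pathway members;
#   Type II  - target node occurrences ("regulating points") among all node
#              occurrences, so a pathway hit by few targets at many map
#              positions can still score;
#   Type III - drugs (a drug is "in" a pathway if >= 1 of its targets is a
#              member), scored against a background drug table.

#' Upper-tail hypergeometric probability
#'
#' Returns `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` marked items when drawing `n` items without
#' replacement from a population of `N` containing `K` marked ones.
#'
#' @param k Observed count of marked items.
#' @param K Number of marked items in the population.
#' @param n Number of draws.
#' @param N Population size.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_upper_tail(3, 4, 5, 10)  # 66/252
hypergeom_upper_tail <- function(k, K, n, N) {
  k <- check_count(k, "k"); K <- check_count(K, "K")
  n <- check_count(n, "n"); N <- check_count(N, "N")
  if (K > N || n > N) np_stop("domain error: K and n must not exceed N")
  if (k == 0L) return(1)
  if (k > min(K, n)) return(0)
  stats::phyper(k - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
}

enrich_counts_p <- function(k, K, n, N) {
  list(k = k, K = K, n = n, N = N, p = hypergeom_upper_tail(k, K, n, N))
}

#' Type I enrichment: distinct targets in a pathway
#'
#' Population is the gene universe (by default every gene appearing in any
#' pathway of the collection); marked items are the pathway's members; draws
#' are the target genes. Targets outside the universe are dropped with a
#' warning.
#'
#' @param pathway_id Pathway identifier.
#' @param targets Character vector of target genes.
#' @param collection A [pathway_collection].
#' @param universe Optional character vector overriding the gene universe.
#' @return List with `k`, `K`, `n`, `N`, `p`.
#' @export
enrich_type1 <- function(pathway_id, targets, collection, universe = NULL) {
  members <- pathway_members(collection)
  if (!pathway_id %in% names(members)) {
    np_stop(sprintf("unknown pathway id: %s", pathway_id))
  }
  if (is.null(universe)) universe <- unique(collection$gene_id)
  if (!length(universe)) np_stop("domain error: empty gene universe")
  universe <- unique(universe)
  targets <- unique(targets)
  outside <- setdiff(targets, universe)
  if (length(outside)) {
    np_warn(sprintf("%d target(s) outside the pathway universe dropped",
                    length(outside)))
    targets <- intersect(targets, universe)
  }
  memb <- intersect(names(members[[pathway_id]]), universe)
  enrich_counts_p(k = length(intersect(memb, targets)),
                  K = length(memb),
                  n = length(targets),
                  N = length(universe))
}

#' Type II enrichment: target node occurrences in a pathway
#'
#' Counts node occurrences rather than distinct genes: the population is the
#' total node count over the whole collection, marked items are this
#' pathway's node occurrences, and draws are the node occurrences of target
#' genes anywhere in the collection.
#'
#' @inheritParams enrich_type1
#' @return List with `k`, `K`, `n`, `N`, `p`.
#' @export
enrich_type2 <- function(pathway_id, targets, collection) {
  if (!pathway_id %in% collection$pathway_id) {
    np_stop(sprintf("unknown pathway id: %s", pathway_id))
  }
  targets <- unique(targets)
  universe <- unique(collection$gene_id)
  outside <- setdiff(targets, universe)
  if (length(outside)) {
    np_warn(sprintf("%d target(s) outside the pathway universe dropped",
                    length(outside)))
    targets <- intersect(targets, universe)
  }
  in_pw <- collection$pathway_id == pathway_id
  is_t <- collection$gene_id %in% targets
  enrich_counts_p(k = sum(collection$node_count[in_pw & is_t]),
                  K = sum(collection$node_count[in_pw]),
                  n = sum(collection$node_count[is_t]),
                  N = sum(collection$node_count))
}

# Map each drug to the set of pathways at least one of its targets belongs to.
drug_pathway_hits <- function(drugs, collection) {
  gene_pw <- split(collection$pathway_id, collection$gene_id)
  per_drug <- split(drugs$target_gene, drugs$drug_id)
  lapply(per_drug, function(genes) {
    unique(unlist(gene_pw[intersect(genes, names(gene_pw))], use.names = FALSE))
  })
}

#' Type III enrichment: drugs acting on a pathway
#'
#' A drug acts on a pathway when at least one of its targets is a member.
#' The population is the background drug table (drugs with >= 1 target in
#' any pathway); the draws are the study drug class. When no background is
#' supplied the class itself is the background, in which case the statistic
#' is degenerate (`p = 1` for every pathway) and only becomes informative
#' with an explicit background, mirroring a disease-class-vs-all-drugs
#' comparison.
#'
#' @param pathway_id Pathway identifier.
#' @param drugs A [drug_target_table] for the study drug class.
#' @param collection A [pathway_collection].
#' @param background Optional [drug_target_table] for the background drug
#'   set.
#' @return List with `k`, `K`, `n`, `N`, `p`.
#' @export
enrich_type3 <- function(pathway_id, drugs, collection, background = NULL) {
  if (!pathway_id %in% collection$pathway_id) {
    np_stop(sprintf("unknown pathway id: %s", pathway_id))
  }
  if (is.null(background)) background <- drugs
  bg_hits <- drug_pathway_hits(background, collection)
  bg_mapped <- names(bg_hits)[vapply(bg_hits, length, 1L) > 0L]
  if (!length(bg_mapped)) {
    np_stop("domain error: no drug maps to any pathway of the collection")
  }
  cl_hits <- drug_pathway_hits(drugs, collection)
  cl_mapped <- names(cl_hits)[vapply(cl_hits, length, 1L) > 0L]
  hits_pw <- function(hits, ids) {
    if (!length(ids)) return(0L)
    sum(vapply(hits[ids], function(p) pathway_id %in% p, TRUE))
  }
  enrich_counts_p(k = hits_pw(cl_hits, cl_mapped),
                  K = hits_pw(bg_hits, bg_mapped),
                  n = length(cl_mapped),
                  N = length(bg_mapped))
}

#' Run all three enrichment types over a pathway collection
#'
#' @param collection A [pathway_collection].
#' @param targets Character vector of target genes.
#' @param drugs Optional [drug_target_table] for Type III; when `NULL`,
#'   `p3` is reported as 1 for every pathway.
#' @param background Optional background [drug_target_table] for Type III.
#' @param alpha Significance level in (0, 1).
#' @return An `enrichment_result` data frame with one row per pathway:
#'   counts `k*`, `K*`, `n*`, `N*` and p-values `p1`, `p2`, `p3` per type,
#'   plus `significant = min(p1, p2, p3) < alpha`.
#' @export
enrich_pathways <- function(collection, targets, drugs = NULL,
                            background = NULL, alpha = 0.05) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (alpha <= 0 || alpha >= 1) np_stop("domain error: alpha must be in (0, 1)")
  ids <- sort(unique(collection$pathway_id))
  universe <- unique(collection$gene_id)
  if (!length(universe)) np_stop("domain error: empty pathway collection")
  targets <- unique(targets)
  dropped <- setdiff(targets, universe)
  if (length(dropped)) {
    np_warn(sprintf("%d target(s) not in any pathway dropped from enrichment",
                    length(dropped)))
  }
  targets_in <- intersect(targets, universe)

  members <- pathway_members(collection)[ids]
  # Type I: distinct genes
  N1 <- length(universe)
  n1 <- length(targets_in)
  K1 <- vapply(members, length, 1L)
  k1 <- vapply(members, function(m) sum(names(m) %in% targets_in), 1L)
  # Type II: node occurrences
  N2 <- sum(collection$node_count)
  n2 <- sum(collection$node_count[collection$gene_id %in% targets_in])
  K2 <- vapply(members, function(m) sum(m), 1L)
  k2 <- vapply(members, function(m) sum(m[names(m) %in% targets_in]), 1L)
  p1 <- mapply(hypergeom_upper_tail, k1, K1, MoreArgs = list(n = n1, N = N1))
  p2 <- mapply(hypergeom_upper_tail, k2, K2, MoreArgs = list(n = n2, N = N2))

  # Type III: drugs
  if (!is.null(drugs)) {
    if (is.null(background)) background <- drugs
    bg_hits <- drug_pathway_hits(background, collection)
    bg_mapped <- names(bg_hits)[vapply(bg_hits, length, 1L) > 0L]
    if (!length(bg_mapped)) {
      np_stop("domain error: no drug maps to any pathway of the collection")
    }
    cl_hits <- drug_pathway_hits(drugs, collection)
    cl_mapped <- names(cl_hits)[vapply(cl_hits, length, 1L) > 0L]
    N3 <- length(bg_mapped)
    n3 <- length(cl_mapped)
    count_pw <- function(hits, idset) {
      tab <- table(unlist(hits[idset], use.names = FALSE))
      out <- stats::setNames(rep(0L, length(ids)), ids)
      out[names(tab)] <- as.integer(tab)
      out
    }
    K3 <- count_pw(bg_hits, bg_mapped)
    k3 <- count_pw(cl_hits, cl_mapped)
    p3 <- mapply(hypergeom_upper_tail, k3, K3, MoreArgs = list(n = n3, N = N3))
  } else {
    N3 <- 0L; n3 <- 0L
    K3 <- rep(0L, length(ids)); k3 <- rep(0L, length(ids))
    p3 <- rep(1, length(ids))
  }

  res <- data.frame(pathway_id = ids,
                    k1 = k1, K1 = K1, n1 = n1, N1 = N1, p1 = unname(p1),
                    k2 = k2, K2 = K2, n2 = n2, N2 = N2, p2 = unname(p2),
                    k3 = unname(k3), K3 = unname(K3),
                    n3 = n3, N3 = N3, p3 = unname(p3),
                    stringsAsFactors = FALSE)
  res$significant <- pmin(res$p1, res$p2, res$p3) < alpha
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Select key pathways from enrichment results
#'
#' A pathway is key when at least one of its three enrichment p-values falls
#' below `alpha`. With `correction = "bh"`, Benjamini-Hochberg adjustment is
#' applied per enrichment type before thresholding. Results are ordered by
#' the minimum (adjusted) p-value, ties broken by pathway id.
#'
#' @param results An `enrichment_result` from [enrich_pathways].
#' @param alpha Significance threshold in (0, 1).
#' @param correction `"none"` (raw p-values) or `"bh"`.
#' @return Character vector of selected pathway ids, most significant first.
#' @export
select_key_pathways <- function(results, alpha = 0.05,
                                correction = c("none", "bh")) {
  correction <- match.arg(correction)
  stopifnot(inherits(results, "data.frame"), nrow(results) > 0)
  if (alpha <= 0 || alpha >= 1) np_stop("domain error: alpha must be in (0, 1)")
  p1 <- results$p1; p2 <- results$p2; p3 <- results$p3
  if (correction == "bh") {
    p1 <- stats::p.adjust(p1, "BH")
    p2 <- stats::p.adjust(p2, "BH")
    p3 <- stats::p.adjust(p3, "BH")
  }
  minp <- pmin(p1, p2, p3)
  sel <- which(minp < alpha)
  ord <- sel[order(minp[sel], results$pathway_id[sel])]
  results$pathway_id[ord]
}

#' Candidate protein universe of a key-pathway selection
#'
#' The union of all member genes of the selected pathways; downstream
#' docking hits are intersected with this set to define putative targets.
#'
#' @param key_pathways Character vector of pathway ids.
#' @param collection A [pathway_collection].
#' @return Sorted character vector of gene symbols.
#' @export
candidate_protein_universe <- function(key_pathways, collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  unknown <- setdiff(key_pathways, unique(collection$pathway_id))
  if (length(unknown)) {
    np_stop(sprintf("unknown pathway id(s): %s",
                    paste(utils::head(unknown, 5), collapse = ", ")))
  }
  sort(unique(collection$gene_id[collection$pathway_id %in% key_pathways]))
}
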
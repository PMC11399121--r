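#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper hypergeometric tail
#' `p = sum_{j >= k} C(K, j) C(N - K, n - j) / C(N, n)` of the overlap `k`
#' between the query and the term within the universe; BH adjustment across
#' all tested terms. The universe is the intersection of the supplied
#' background with the genes annotated in the collection; query genes
#' outside it are dropped.
#'
#' @param query Character vector of gene ids.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Character vector: background gene ids.
#' @param enrich_alpha Threshold on `padj` for the `significant` flag.
#' @return Data frame: `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`,
#'   `padj`, `significant`, `overlap_genes`, sorted by `p`.
#' @export
ora <- function(query, gene_sets, universe, enrich_alpha = 0.05) {
  universe <- intersect(universe, unique(unlist(gene_sets)))
  query <- intersect(unique(query), universe)
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query after universe intersection")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], universe)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    desc <- attr(gene_sets[[term]], "description")
    data.frame(term_id = term,
               term_name = if (is.null(desc)) term else desc,
               k = k, K = K, n = n, N = N, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out$significant <- out$padj < enrich_alpha
  out <- out[order(out$p, out$term_id),
             c("term_id", "term_name", "k", "K", "n", "N", "p", "padj",
               "significant", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Jaccard similarity matrix between gene sets
#'
#' `J(A, B) = |A n B| / |A u B|`; the diagonal is 1, and an empty set has
#' similarity 0 with everything (flagged via the `empty_sets` attribute).
#'
#' @param sets Named list of character vectors.
#' @return Symmetric numeric matrix.
#' @export
jaccard_matrix <- function(sets) {
  sets <- lapply(sets, unique)
  m <- length(sets)
  J <- matrix(0, m, m, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(m)) for (j in seq_len(i)) {
    u <- length(union(sets[[i]], sets[[j]]))
    J[i, j] <- J[j, i] <- if (u == 0) 0 else
      length(intersect(sets[[i]], sets[[j]])) / u
  }
  diag(J) <- 1
  attr(J, "empty_sets") <- names(sets)[lengths(sets) == 0]
  J
}

#' Cluster enriched terms on their similarity
#'
#' Terms are connected when their Jaccard similarity reaches `edge_min`;
#' communities are found by deterministic greedy modularity maximization
#' (fast-greedy agglomeration), so the partition is reproducible across
#' runs. Singletons are allowed. Each cluster's representative is the term
#' with the largest member set, ties broken by lexicographic id.
#'
#' @param similarity Symmetric matrix from [jaccard_matrix()].
#' @param edge_min Similarity threshold for graph edges.
#' @param sets Optional named list (for representative-by-size selection;
#'   defaults to degree in the similarity graph).
#' @return Data frame: `term_id`, `cluster_id`, `representative`.
#' @export
cluster_terms <- function(similarity, edge_min = 0.2, sets = NULL) {
  stopifnot(nrow(similarity) == ncol(similarity))
  ids <- rownames(similarity)
  adj <- similarity >= edge_min
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- if (igraph::ecount(g) > 0)
    igraph::membership(igraph::cluster_fast_greedy(g))
  else seq_along(ids)
  memb <- as.integer(memb)
  size_of <- if (is.null(sets)) stats::setNames(rowSums(adj), ids) else
    stats::setNames(lengths(sets)[ids], ids)
  out <- data.frame(term_id = ids, cluster_id = memb,
                    stringsAsFactors = FALSE)
  reps <- vapply(split(out$term_id, out$cluster_id), function(members) {
    members[order(-size_of[members], members)][1]
  }, character(1))
  out$representative <- reps[as.character(out$cluster_id)]
  # renumber clusters deterministically by their representative
  lev <- sort(unique(out$representative))
  out$cluster_id <- match(out$representative, lev)
  out[order(out$cluster_id, out$term_id), ]
}

#' Partition modularity
#'
#' Newman modularity of a partition on the unweighted graph defined by
#' `similarity >= edge_min`; used by the test-suite oracle and reported for
#' diagnostics.
#'
#' @param similarity Symmetric matrix.
#' @param membership Integer vector of cluster labels.
#' @param edge_min Edge threshold.
#' @export
partition_modularity <- function(similarity, membership, edge_min = 0.2) {
  adj <- similarity >= edge_min
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::ecount(g) == 0) return(0)
  igraph::modularity(g, membership)
}
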
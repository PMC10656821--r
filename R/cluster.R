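#' k-nearest-neighbor lists over gene expression profiles
#'
#' For each gene (row), finds its k nearest other genes under Euclidean
#' distance between row vectors. Ties in distance are broken by gene id,
#' making the lists deterministic.
#'
#' @param matrix complete genes x samples numeric matrix (standardized
#'   profiles).
#' @param k number of neighbors (< number of genes).
#' @return named list: gene id -> character vector of its k neighbors.
#' @export
build_knn_graph <- function(matrix, k = 30L) {
  check_matrix(matrix)
  if (anyNA(matrix)) stop("kNN graph requires a complete matrix")
  n <- nrow(matrix)
  if (k >= n) stop("k must be smaller than the number of genes")
  ids <- rownames(matrix)
  d <- as.matrix(stats::dist(matrix))
  out <- vector("list", n)
  names(out) <- ids
  for (i in seq_len(n)) {
    di <- d[i, -i]
    ord <- order(di, names(di), method = "radix")
    out[[i]] <- names(di)[ord[seq_len(k)]]
  }
  out
}

#' Shared-nearest-neighbor Jaccard graph from kNN lists
#'
#' Connects u and v when either lists the other as a neighbor, weighting
#' the edge by the Jaccard index of their neighbor sets
#' \code{|N(u) n N(v)| / |N(u) u N(v)|}; zero-weight edges are dropped.
#' This is the shared-neighbor refinement used by Phenograph-style
#' clustering.
#'
#' @param knn named list from [build_knn_graph()].
#' @return an undirected weighted [igraph::graph] whose vertex set equals
#'   the input gene set.
#' @export
jaccard_graph <- function(knn) {
  ids <- names(knn)
  k <- lengths(knn)
  src <- rep(seq_along(ids), k)
  dst <- match(unlist(knn, use.names = FALSE), ids)
  a <- pmin(src, dst); b <- pmax(src, dst)
  uniq <- !duplicated(as.numeric(a) * (length(ids) + 1) + b)
  from <- a[uniq]; to <- b[uniq]
  w <- numeric(length(from))
  for (e in seq_along(from)) {
    nu <- knn[[from[e]]]
    nv <- knn[[to[e]]]
    w[e] <- length(intersect(nu, nv)) / length(union(nu, nv))
  }
  keep <- w > 0
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(from[keep], to[keep]),
                           weight = w[keep])
  g
}

#' Louvain community detection on a gene graph
#'
#' Modularity-maximizing Louvain partition of the weighted gene graph;
#' the number of clusters is emergent, not preset. The seed fixes the
#' (vertex-order) randomness of the algorithm so repeated runs on the
#' same graph are identical. An edgeless graph degenerates to singleton
#' clusters with a warning.
#'
#' @param graph an [igraph::graph] with a \code{weight} edge attribute.
#' @param seed integer seed.
#' @return list: \code{membership} (named integer vector, gene ->
#'   cluster id), \code{modularity}, \code{n_clusters}, \code{sizes}.
#' @export
louvain_communities <- function(graph, seed = 1L) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph")
  if (igraph::ecount(graph) == 0) {
    warning("graph has no edges; every gene is its own cluster")
    memb <- stats::setNames(seq_len(n), igraph::V(graph)$name)
    return(list(membership = memb, modularity = NA_real_,
                n_clusters = n, sizes = table(memb)))
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph,
                                weights = igraph::E(graph)$weight)
  memb <- stats::setNames(igraph::membership(cl),
                          igraph::V(graph)$name)
  list(membership = memb,
       modularity = max(igraph::modularity(cl)),
       n_clusters = length(unique(memb)),
       sizes = table(memb))
}

#' Cluster prognostic genes by co-expression across the compendium
#'
#' The Phenograph-style pipeline applied to a prognostic gene list:
#' assemble the complete cross-study matrix (samples must cover >= 80%
#' of the genes; only complete gene rows survive), build the kNN graph on
#' gene profiles, weight edges by shared-neighbor Jaccard, and extract
#' Louvain communities. Clusters are annotated with the majority
#' pro/anti direction of their member genes; genes dropped by the
#' complete-data rule are reported.
#'
#' @param studies list of \code{study_dataset} objects.
#' @param genes prognostic gene ids to cluster.
#' @param labels optional named character vector gene -> "pro"/"anti"
#'   used for the cluster direction annotation.
#' @param policy a [threshold_policy()] (supplies the coverage rule).
#' @param k kNN neighborhood size (default 30).
#' @param seed integer seed for the Louvain stage.
#' @return object of class \code{cluster_assignment}: \code{membership}
#'   (gene -> cluster id), \code{direction} (per-cluster majority label),
#'   \code{modularity}, \code{sizes}, \code{dropped_genes},
#'   \code{retention_pct}, \code{n_samples}.
#' @export
cluster_prognostic_genes <- function(studies, genes, labels = NULL,
                                     policy = threshold_policy(),
                                     k = 30L, seed = 1L) {
  if (!length(genes)) stop("prognostic gene list is empty")
  genes <- sort(unique(genes))  # input-order invariance
  mat <- assemble_complete_matrix(studies, genes,
                                  coverage = policy$clustering_coverage)
  if (nrow(mat) < 2 * k)
    stop(sprintf("only %d genes survive the complete-data rule; need >= %d",
                 nrow(mat), 2 * k))
  knn <- build_knn_graph(mat, k = k)
  graph <- jaccard_graph(knn)
  comm <- louvain_communities(graph, seed = seed)
  direction <- NULL
  if (!is.null(labels)) {
    direction <- vapply(split(names(comm$membership), comm$membership),
                        function(members) {
                          lab <- labels[members]
                          lab <- lab[!is.na(lab)]
                          if (!length(lab)) return(NA_character_)
                          names(sort(table(lab), decreasing = TRUE))[1]
                        }, "")
  }
  structure(list(membership = comm$membership,
                 direction = direction,
                 modularity = comm$modularity,
                 sizes = comm$sizes,
                 n_clusters = comm$n_clusters,
                 dropped_genes = setdiff(genes, rownames(mat)),
                 retention_pct = attr(mat, "retention_pct"),
                 n_samples = ncol(mat)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Co-expression clustering: %d genes in %d clusters (modularity %.3f)\n",
              length(x$membership), x$n_clusters, x$modularity))
  cat(sprintf("  %d genes dropped by the complete-data rule (retention %d%%)\n",
              length(x$dropped_genes), x$retention_pct))
  sizes <- as.integer(x$sizes)
  dir <- if (is.null(x$direction)) rep("", length(sizes))
         else paste0(" (", x$direction, ")")
  cat("  sizes:", paste0(sizes, dir, collapse = ", "), "\n")
  invisible(x)
}
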
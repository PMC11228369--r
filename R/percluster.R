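#' Cluster one scRNA-seq dataset
#'
#' Louvain community detection on a shared-nearest-neighbor graph built from
#' the top principal components of log1p, library-size-normalized counts
#' (the usual Seurat-style recipe: 10k scaling, 50 PCs, k = 20 SNN,
#' resolution-free Louvain). Deterministic given `seed`. Precomputed labels
#' may be supplied instead, in which case they are validated and relabeled
#' to contiguous 0..n-1.
#'
#' @param em An [expression_matrix()] with `unit == "counts"`.
#' @param knn_k Neighbors for the SNN graph. Default 20.
#' @param resolution Louvain resolution; values below 1 favor coarser
#'   communities. Default 0.8.
#' @param n_pcs Number of principal components. Default 50 (capped by the
#'   data dimensions).
#' @param seed Integer seed for the Louvain pass.
#' @param precomputed Optional integer vector of per-cell labels (named by
#'   cell id or in matrix column order) that bypasses clustering.
#' @return A list of class `cluster_assignment` with fields `dataset_id`,
#'   `cell_ids`, `labels` (0-based, contiguous) and `n_clusters`.
#' @export
cluster_dataset <- function(em, knn_k = 20, resolution = 0.8, n_pcs = 50,
                            seed = 1L, precomputed = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  n <- ncol(em$values)
  if (n < 2L) stop("need at least 2 cells to cluster")

  if (!is.null(precomputed)) {
    if (!is.null(names(precomputed))) {
      if (!setequal(names(precomputed), em$cell_or_sample_ids)) {
        stop("precomputed labels do not cover the dataset's cells")
      }
      precomputed <- precomputed[em$cell_or_sample_ids]
    }
    if (length(precomputed) != n) stop("one label per cell required")
    labels <- match(precomputed, sort(unique(precomputed))) - 1L
  } else {
    if (em$unit != "counts") stop("clustering expects raw counts")
    if (n <= knn_k) {
      stop("dataset has ", n, " cells but knn_k = ", knn_k,
           "; use a smaller k")
    }
    x <- em$values
    libs <- colSums(x)
    libs[libs == 0] <- 1
    x <- log1p(t(x) * (1e4 / libs))            # cells x genes
    if (all(apply(x, 2, stats::sd) == 0)) {
      labels <- rep(0L, n)
    } else {
      npc <- min(n_pcs, n - 1L, ncol(x) - 1L)
      pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = npc)$x
      g <- .snn_graph(pcs, k = knn_k)
      set.seed(seed)
      comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                      resolution = resolution)
      labels <- as.integer(igraph::membership(comm))
      labels <- .group_singletons(labels, g, pcs)
      labels <- match(labels, sort(unique(labels))) - 1L
    }
  }
  structure(
    list(
      dataset_id = em$dataset_id,
      cell_ids = em$cell_or_sample_ids,
      labels = labels,
      n_clusters = length(unique(labels))
    ),
    class = "cluster_assignment"
  )
}

# Singleton communities are merged into the cluster they are best connected
# to (sum of SNN edge weights; nearest cluster centroid in PC space when a
# node has no edges) — the usual Seurat-style behavior.
.group_singletons <- function(labels, g, pcs) {
  sizes <- table(labels)
  single <- as.integer(names(sizes)[sizes == 1L])
  if (!length(single) || length(sizes) == length(single)) return(labels)
  adj <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  for (lab in single) {
    node <- which(labels == lab)
    other <- labels != lab & !(labels %in% single)
    if (!any(other)) next
    w <- tapply(adj[node, other], labels[other], sum)
    if (max(w) > 0) {
      labels[node] <- as.integer(names(which.max(w)))
    } else {
      cent <- vapply(split(seq_len(nrow(pcs))[other], labels[other]),
                     function(ix) {
                       sqrt(sum((colMeans(pcs[ix, , drop = FALSE]) -
                                   pcs[node, ])^2))
                     }, numeric(1))
      labels[node] <- as.integer(names(which.min(cent)))
    }
  }
  labels
}

# Shared-nearest-neighbor graph: kNN by Euclidean distance, edge weight =
# Jaccard overlap of neighbor lists (neighborhoods include the point itself).
.snn_graph <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nb <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ], decreasing = FALSE)
    ord <- ord[ord != i][seq_len(min(k, n - 1L))]
    c(i, ord)
  })
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) {
    for (j in nb[[i]][-1]) {
      if (j > i) {
        ov <- length(intersect(nb[[i]], nb[[j]]))
        jac <- ov / (2L * (k + 1L) - ov)
        if (jac > 0) {
          from <- c(from, i); to <- c(to, j); w <- c(w, jac)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  g
}

#' Rank-normalize cells
#'
#' Within each cell, genes are ranked ascending by expression (highest
#' expression gets rank G). Ties, including the zero block, receive average
#' ranks, so every cell's mean rank is (G+1)/2. Rank normalization is
#' invariant to any strictly monotone per-cell transform, which is what
#' makes the downstream centroids comparable across platforms.
#'
#' @param em An [expression_matrix()] with counts or TPM values.
#' @return An [expression_matrix()] with `unit == "rank"`.
#' @export
rank_normalize_cells <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!em$unit %in% c("counts", "TPM")) {
    stop("rank normalization expects counts or TPM, got ", em$unit)
  }
  ranked <- apply(em$values, 2, rank, ties.method = "average")
  rownames(ranked) <- em$gene_ids
  out <- em
  out$values <- ranked
  out$unit <- "rank"
  out
}

#' Compute a cluster's rank centroid
#'
#' Per-gene arithmetic mean of the member cells' ranks. A warning is logged
#' when the cluster has fewer than `min_cells` members: subsampling
#' experiments show centroid stability saturates around 50 cells.
#'
#' @param ranked A rank-normalized [expression_matrix()].
#' @param member_cell_ids Cell ids belonging to the cluster.
#' @param cluster_uid Unique id, conventionally `"<dataset_id>.<cluster>"`.
#' @param min_cells Robustness threshold for the size warning. Default 50.
#' @return A list of class `rank_centroid` with `cluster_uid`, `dataset_id`,
#'   `gene_ids`, `avg_rank` and `n_cells`.
#' @export
compute_rank_centroid <- function(ranked, member_cell_ids,
                                  cluster_uid = "cluster",
                                  min_cells = 50) {
  stopifnot(inherits(ranked, "expression_matrix"))
  if (ranked$unit != "rank") stop("centroid expects a rank-normalized matrix")
  if (length(member_cell_ids) == 0L) stop("empty member set")
  missing <- setdiff(member_cell_ids, ranked$cell_or_sample_ids)
  if (length(missing)) {
    stop("member cells not in matrix: ", paste(missing, collapse = ", "))
  }
  sub <- ranked$values[, member_cell_ids, drop = FALSE]
  if (length(member_cell_ids) < min_cells) {
    warning("cluster ", cluster_uid, " has only ", length(member_cell_ids),
            " cells (< ", min_cells, "); centroid may be unstable")
  }
  structure(
    list(
      cluster_uid = cluster_uid,
      dataset_id = ranked$dataset_id,
      gene_ids = ranked$gene_ids,
      avg_rank = rowMeans(sub),
      n_cells = length(member_cell_ids)
    ),
    class = "rank_centroid"
  )
}

#' Rank centroids for every cluster of a dataset
#'
#' Convenience wrapper: rank-normalizes the dataset and computes one
#' centroid per cluster label.
#'
#' @param em Counts [expression_matrix()].
#' @param assignment A `cluster_assignment` from [cluster_dataset()].
#' @param min_cells Passed to [compute_rank_centroid()].
#' @return A list of `rank_centroid` objects.
#' @export
dataset_centroids <- function(em, assignment, min_cells = 50) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ranked <- rank_normalize_cells(em)
  lapply(sort(unique(assignment$labels)), function(lab) {
    members <- assignment$cell_ids[assignment$labels == lab]
    compute_rank_centroid(
      ranked, members,
      cluster_uid = paste0(em$dataset_id, ".", lab),
      min_cells = min_cells
    )
  })
}
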
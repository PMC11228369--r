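#' 2-D layout of samples by exemplar-score similarity
#'
#' Builds a k-nearest-neighbor graph (default k = 15) on the Pearson
#' correlation between samples' exemplar-score vectors and runs a seeded
#' force-directed (Fruchterman-Reingold) layout initialized from classical
#' MDS of the correlation distance. Identical score vectors therefore land
#' on near-coincident points, and blocks of samples with disjoint active
#' exemplars separate. Deterministic given `seed`.
#'
#' @param scores Numeric matrix, samples x exemplars (>= 10 samples).
#' @param seed Layout seed.
#' @param knn_k Neighbors per sample in the layout graph. Default 15.
#' @param niter Force-directed iterations. Default 500.
#' @return A list of class `map_layout`: `sample_ids`, `x`, `y`, `seed`,
#'   `knn_k`.
#' @export
layout_samples <- function(scores, seed = 1L, knn_k = 15, niter = 500) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 10L) stop("need at least 10 samples for a map layout")
  if (is.null(rownames(scores))) rownames(scores) <- paste0("s", seq_len(n))
  sds <- apply(scores, 1, stats::sd)
  if (all(sds == 0)) stop("constant score matrix: no structure to lay out")
  # correlation between sample score vectors; constant rows get 0
  cc <- suppressWarnings(stats::cor(t(scores)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  k <- min(knn_k, n - 1L)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) {
    nb <- setdiff(order(cc[i, ], decreasing = TRUE), i)[seq_len(k)]
    from <- c(from, rep(i, k)); to <- c(to, nb)
    w <- c(w, (cc[i, nb] + 1) / 2)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  g <- igraph::simplify(g, edge.attr.comb = "max")
  dmat <- stats::as.dist(1 - cc)
  init <- stats::cmdscale(dmat, k = 2)
  if (ncol(init) < 2) init <- cbind(init, 0)[, 1:2, drop = FALSE]
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, coords = init, niter = niter,
                               weights = igraph::E(g)$weight)
  # vertices were added in index order, so rows align with samples
  structure(
    list(sample_ids = rownames(scores), x = xy[, 1], y = xy[, 2],
         seed = seed, knn_k = k),
    class = "map_layout"
  )
}

#' Spatial clusters on the map
#'
#' HDBSCAN on the layout coordinates; noise points are reported as
#' `"unassigned"`.
#'
#' @param layout A `map_layout`.
#' @param min_cluster_size Minimum cluster size. Default 20 for the primary
#'   map (50 is conventional for comparison maps).
#' @return A list of class `spatial_clustering`: `sample_ids`, `cluster`
#'   (character; `"c1"`, `"c2"`, ... or `"unassigned"`),
#'   `min_cluster_size`.
#' @export
spatial_clusters <- function(layout, min_cluster_size = 20) {
  stopifnot(inherits(layout, "map_layout"))
  labs <- hdbscan_points(cbind(layout$x, layout$y),
                         min_cluster_size = min_cluster_size)
  cl <- ifelse(labs == 0L, "unassigned", paste0("c", labs))
  structure(
    list(sample_ids = layout$sample_ids,
         cluster = stats::setNames(cl, layout$sample_ids),
         min_cluster_size = min_cluster_size),
    class = "spatial_clustering"
  )
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement. Samples labeled
#' `"unassigned"` (or NA) in either labeling are excluded before the
#' computation. When both labelings place every retained sample in a
#' single cluster the partitions agree trivially and the ARI is defined
#' as 1.
#'
#' @param labels_a,labels_b Vectors of labels over the same samples.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must cover the same samples")
  }
  keep <- !is.na(labels_a) & !is.na(labels_b) &
    labels_a != "unassigned" & labels_b != "unassigned"
  a <- labels_a[keep]; b <- labels_b[keep]
  if (length(a) == 0L) stop("no co-assigned samples")
  if (length(unique(a)) == 1L && length(unique(b)) == 1L) return(1)
  mclust::adjustedRandIndex(a, b)
}

#' Per-disease survival comparisons between map clusters
#'
#' For each disease, the main cluster is the spatial cluster holding the
#' most samples of that disease; every other cluster with at least 5
#' samples of the disease is compared to it with a subtype-corrected Cox
#' model (comparison cluster = "up"). When `per_subtype` is TRUE the
#' comparison is repeated inside each subtype level without the covariate.
#'
#' @param clustering A `spatial_clustering`.
#' @param disease Named character vector (names = sample ids).
#' @param survival_df Survival data frame (`sample_id`, `time`, `event`).
#' @param subtypes Named character vector of subtype labels.
#' @param min_disease_samples Qualification threshold. Default 5.
#' @param per_subtype Also run within-subtype comparisons. Default TRUE.
#' @return Data frame of `sos_result` rows (one per comparison), with
#'   `cohort` = disease (or disease/subtype) and `exemplar` =
#'   "cluster_vs_main" identifiers.
#' @export
cluster_survival_comparisons <- function(clustering, disease, survival_df,
                                         subtypes = NULL,
                                         min_disease_samples = 5,
                                         per_subtype = TRUE) {
  stopifnot(inherits(clustering, "spatial_clustering"))
  cl <- clustering$cluster
  ids <- clustering$sample_ids
  assigned <- ids[cl[ids] != "unassigned"]
  out <- list()
  for (dz in unique(disease[assigned])) {
    dz_ids <- assigned[disease[assigned] == dz]
    tab <- table(cl[dz_ids])
    qual <- names(tab)[tab >= min_disease_samples]
    if (length(qual) < 2L) next
    main <- names(tab)[which.max(tab)]
    for (other in setdiff(qual, main)) {
      grp <- .cluster_pair_groups(cl, dz_ids, other, main)
      res <- if (!is.null(subtypes)) {
        fit_subtype_corrected_sos(grp, survival_df, subtypes,
                                  cohort = dz,
                                  exemplar = paste0(other, "_vs_", main))
      } else {
        fit_sos(grp, survival_df, cohort = dz,
                exemplar = paste0(other, "_vs_", main))
      }
      out[[length(out) + 1L]] <- res
      if (per_subtype && !is.null(subtypes)) {
        for (st in unique(stats::na.omit(subtypes[dz_ids]))) {
          st_ids <- dz_ids[!is.na(subtypes[dz_ids]) & subtypes[dz_ids] == st]
          if (sum(cl[st_ids] == other) >= min_disease_samples &&
              sum(cl[st_ids] == main) >= min_disease_samples) {
            grp_st <- .cluster_pair_groups(cl, st_ids, other, main)
            out[[length(out) + 1L]] <- fit_sos(
              grp_st, survival_df, cohort = paste0(dz, "/", st),
              exemplar = paste0(other, "_vs_", main)
            )
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame())
  }
  do.call(rbind, out)
}

.cluster_pair_groups <- function(cl, ids, up_cluster, down_cluster) {
  keep <- ids[cl[ids] %in% c(up_cluster, down_cluster)]
  lab <- ifelse(cl[keep] == up_cluster, "up", "down")
  structure(
    list(sample_ids = keep, label = stats::setNames(lab, keep),
         rule = "map_cluster", cutpoints = numeric(0)),
    class = "group_assignment"
  )
}

#' Differential exemplars between two sample clusters
#'
#' Per-exemplar two-sample Student t statistic (cluster a vs cluster b,
#' pooled variance); reports the 3 most positive and 3 most negative
#' statistics with p-values. Exemplars with zero variance in both clusters
#' are skipped. Ties are broken lexicographically by exemplar id.
#'
#' @param scores Samples x exemplars matrix.
#' @param cluster_a_ids,cluster_b_ids Sample ids (>= 3 each).
#' @param n_top Number reported per direction. Default 3.
#' @return List with `highest` and `lowest` data frames (exemplar_id,
#'   t_stat, p) and the full `table`.
#' @export
differential_exemplars <- function(scores, cluster_a_ids, cluster_b_ids,
                                   n_top = 3) {
  scores <- as.matrix(scores)
  if (length(cluster_a_ids) < 3L || length(cluster_b_ids) < 3L) {
    stop("both clusters need at least 3 samples")
  }
  a <- scores[cluster_a_ids, , drop = FALSE]
  b <- scores[cluster_b_ids, , drop = FALSE]
  res <- lapply(colnames(scores), function(ex) {
    va <- a[, ex]; vb <- b[, ex]
    if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
      message("exemplar ", ex, " has zero variance in both clusters; skipped")
      return(NULL)
    }
    tt <- tryCatch(stats::t.test(va, vb, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(tt)) return(NULL)
    data.frame(exemplar_id = ex, t_stat = unname(tt$statistic),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  if (is.null(tab) || nrow(tab) == 0L) stop("no testable exemplars")
  hi <- tab[order(-tab$t_stat, tab$exemplar_id), ]
  lo <- tab[order(tab$t_stat, tab$exemplar_id), ]
  list(
    highest = utils::head(hi, n_top),
    lowest = utils::head(lo, n_top),
    table = tab
  )
}
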
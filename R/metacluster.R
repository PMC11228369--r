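#' Build the supra-threshold similarity graph
#'
#' Nodes are all cluster centroids; undirected edges connect pairs whose
#' RTKE score is strictly above the threshold, weighted by the score.
#' Isolated nodes are kept — a centroid with no sufficiently similar partner
#' becomes a singleton exemplar downstream.
#'
#' @param sm A `similarity_matrix` from [pairwise_rtke()].
#' @param threshold Finite edge threshold, typically from
#'   [empirical_threshold()].
#' @return An igraph graph with vertex names = cluster uids.
#' @export
build_cluster_graph <- function(sm, threshold) {
  stopifnot(inherits(sm, "similarity_matrix"), is.finite(threshold))
  n <- length(sm$cluster_uids)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- sm$cluster_uids
  idx <- which(upper.tri(sm$scores) & sm$scores > threshold, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    g <- igraph::add_edges(g, t(idx))
    igraph::E(g)$weight <- sm$scores[idx]
  }
  g
}

#' Meta-cluster centroids into exemplars
#'
#' Louvain community detection on the weighted cluster graph. Isolated
#' nodes become singleton exemplars. Exemplar ids are assigned X1..Xn in
#' order of decreasing member count, ties broken by the smallest member
#' uid; the numbering is a presentation convention, not a biological claim.
#'
#' @param g Graph from [build_cluster_graph()].
#' @param seed Seed for the Louvain pass.
#' @return Named character vector mapping cluster_uid -> exemplar id.
#' @export
metacluster <- function(g, seed = 1L) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  set.seed(seed)
  w <- if (igraph::ecount(g) > 0L) igraph::E(g)$weight else NULL
  comm <- igraph::cluster_louvain(g, weights = w)
  mem <- igraph::membership(comm)
  uids <- igraph::V(g)$name
  groups <- split(uids, as.integer(mem))
  ord <- order(-lengths(groups),
               vapply(groups, function(u) min(u), character(1)))
  groups <- groups[ord]
  out <- character(length(uids))
  names(out) <- uids
  for (i in seq_along(groups)) out[groups[[i]]] <- paste0("X", i)
  out
}

#' Exemplar signature from member centroids
#'
#' Unweighted per-gene mean of the member centroids' average ranks (every
#' member cluster counts once, regardless of its cell count). The mean-rank
#' invariant (G+1)/2 is preserved by linearity.
#'
#' @param members List of `rank_centroid` objects on a common gene universe.
#' @param exemplar_id Identifier, e.g. `"X1"`.
#' @param weighted If TRUE, members are weighted by their cell counts.
#' @return A list of class `exemplar_signature` with `exemplar_id`,
#'   `member_cluster_uids`, `gene_ids`, `avg_rank`, `n_datasets` and an
#'   empty `annotation` slot.
#' @export
exemplar_centroid <- function(members, exemplar_id = "X1", weighted = FALSE) {
  stopifnot(length(members) >= 1L)
  universe <- members[[1]]$gene_ids
  for (m in members) {
    if (!identical(m$gene_ids, universe)) {
      stop("member centroids disagree on the gene universe")
    }
  }
  ranks <- vapply(members, `[[`, numeric(length(universe)), "avg_rank")
  ranks <- matrix(ranks, nrow = length(universe))
  w <- if (weighted) {
    vapply(members, `[[`, numeric(1), "n_cells")
  } else {
    rep(1, length(members))
  }
  avg <- as.numeric(ranks %*% (w / sum(w)))
  names(avg) <- universe
  structure(
    list(
      exemplar_id = exemplar_id,
      member_cluster_uids = vapply(members, `[[`, character(1), "cluster_uid"),
      gene_ids = universe,
      avg_rank = avg,
      n_datasets = length(unique(vapply(members, `[[`, character(1),
                                        "dataset_id"))),
      annotation = NULL
    ),
    class = "exemplar_signature"
  )
}

#' Derive exemplars from a set of cluster centroids
#'
#' End-to-end convenience: shared-universe restriction, all-pairs RTKE,
#' empirical threshold, graph construction, Louvain meta-clustering and
#' exemplar centroid computation.
#'
#' @param centroids List of `rank_centroid` objects.
#' @param config A [run_config()].
#' @param seed Seed for the meta-clustering pass; defaults to the config's.
#' @return A list with `exemplars` (list of `exemplar_signature`),
#'   `membership` (cluster_uid -> exemplar id), `similarity`
#'   (`similarity_matrix`) and `threshold`.
#' @export
derive_exemplars <- function(centroids, config = run_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$rng_seed
  centroids <- restrict_to_shared_genes(centroids)
  sm <- pairwise_rtke(centroids, fraction = config$top_k_fraction)
  thr <- empirical_threshold(sm, quantile = config$edge_quantile)
  g <- build_cluster_graph(sm, thr)
  membership <- metacluster(g, seed = seed)
  by_ex <- split(names(membership), membership)
  cent_by_uid <- stats::setNames(centroids,
                                 vapply(centroids, `[[`, character(1),
                                        "cluster_uid"))
  exemplars <- lapply(names(by_ex), function(ex) {
    exemplar_centroid(cent_by_uid[by_ex[[ex]]], exemplar_id = ex)
  })
  names(exemplars) <- names(by_ex)
  ord <- order(as.integer(sub("^X", "", names(exemplars))))
  list(
    exemplars = exemplars[ord],
    membership = membership,
    similarity = sm,
    threshold = thr
  )
}

#' Exemplar matrix (genes x exemplars)
#'
#' @param exemplars List of `exemplar_signature` objects on one universe.
#' @return Numeric matrix of average ranks, genes x exemplars.
#' @export
exemplar_matrix <- function(exemplars) {
  stopifnot(length(exemplars) >= 1L)
  universe <- exemplars[[1]]$gene_ids
  m <- vapply(exemplars, `[[`, numeric(length(universe)), "avg_rank")
  m <- matrix(m, nrow = length(universe),
              dimnames = list(universe,
                              vapply(exemplars, `[[`, character(1),
                                     "exemplar_id")))
  m
}
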
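#' Restrict centroids to a common gene universe
#'
#' Cross-dataset comparisons operate on the intersection of the centroids'
#' gene ids. Ranks are recomputed on the restricted universe so the mean
#' rank invariant (G+1)/2 holds after restriction.
#'
#' @param centroids List of `rank_centroid` objects.
#' @return The list with every centroid restricted to the shared universe
#'   and re-ranked.
#' @export
restrict_to_shared_genes <- function(centroids) {
  stopifnot(length(centroids) >= 1L)
  universe <- Reduce(intersect, lapply(centroids, `[[`, "gene_ids"))
  if (length(universe) < 10L) {
    stop("gene intersection across centroids has ", length(universe),
         " genes (< 10): insufficient overlap")
  }
  lapply(centroids, function(ct) {
    keep <- match(universe, ct$gene_ids)
    ct$gene_ids <- universe
    ct$avg_rank <- rank(ct$avg_rank[keep], ties.method = "average")
    ct
  })
}

#' Top-k genes of a centroid
#'
#' The `ceiling(fraction * G)` genes with the largest average rank.
#' Boundary ties are broken lexicographically by gene id so selection is
#' deterministic.
#'
#' @param centroid A `rank_centroid` (or any object with `gene_ids` and
#'   `avg_rank`).
#' @param fraction Fraction of the universe to keep, in (0, 1]. Default 0.10.
#' @return Character vector of gene ids.
#' @export
top_k_genes <- function(centroid, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  g <- length(centroid$gene_ids)
  if (g == 0L) stop("empty centroid")
  k <- ceiling(fraction * g)
  ord <- order(-centroid$avg_rank, centroid$gene_ids)
  centroid$gene_ids[ord[seq_len(k)]]
}

#' Reciprocal top-K enrichment score
#'
#' Similarity between two rank centroids on a shared gene universe of size
#' G: with top-k sets T_a and T_b and overlap m, the score is
#' `-log10 P(X >= m)` for X ~ Hypergeometric(G, |T_a|, |T_b|). The tail is
#' evaluated in log space (`phyper(..., log.p = TRUE)`), so large overlaps
#' never underflow to a zero p-value. The construction is symmetric — both
#' centroids contribute their top-k sets — hence "reciprocal".
#'
#' @param a,b `rank_centroid` objects on the same gene universe.
#' @param fraction Top-k fraction. Default 0.10.
#' @param variant `"overlap"` (default, hypergeometric tail of the top-k
#'   overlap) or `"rank_sum"` (mutual average rank of the other centroid's
#'   top-k set, scaled to [0, 1]) for sensitivity analysis.
#' @return Non-negative, finite score.
#' @export
rtke_score <- function(a, b, fraction = 0.10,
                       variant = c("overlap", "rank_sum")) {
  variant <- match.arg(variant)
  if (!identical(a$gene_ids, b$gene_ids)) {
    stop("centroids must share an identical gene universe; ",
         "see restrict_to_shared_genes()")
  }
  g <- length(a$gene_ids)
  if (g < 10L) stop("gene universe has ", g, " genes (< 10)")
  ta <- top_k_genes(a, fraction)
  tb <- top_k_genes(b, fraction)
  if (variant == "rank_sum") {
    # mean normalized rank of b's top set under a, and vice versa
    ra <- mean(a$avg_rank[match(tb, a$gene_ids)]) / g
    rb <- mean(b$avg_rank[match(ta, b$gene_ids)]) / g
    return((ra + rb) / 2)
  }
  m <- length(intersect(ta, tb))
  if (m == 0L) return(0)
  logp <- stats::phyper(m - 1L, length(ta), g - length(ta), length(tb),
                        lower.tail = FALSE, log.p = TRUE)
  score <- -logp / log(10)
  min(score, .Machine$double.xmax)
}

#' All-pairs RTKE similarity matrix
#'
#' Maps all centroids to the common gene intersection, then scores every
#' pair (including within-dataset pairs). The diagonal holds each
#' centroid's self-score, the maximum attainable value for the universe.
#'
#' @param centroids List of two or more `rank_centroid` objects.
#' @param fraction Top-k fraction. Default 0.10.
#' @param variant See [rtke_score()].
#' @return A list of class `similarity_matrix` with `cluster_uids`,
#'   symmetric `scores`, `top_k_fraction` and `gene_universe_size`.
#' @export
pairwise_rtke <- function(centroids, fraction = 0.10,
                          variant = c("overlap", "rank_sum")) {
  variant <- match.arg(variant)
  if (length(centroids) < 2L) stop("need at least 2 centroids")
  centroids <- restrict_to_shared_genes(centroids)
  uids <- vapply(centroids, `[[`, character(1), "cluster_uid")
  if (anyDuplicated(uids)) stop("duplicate cluster_uids")
  n <- length(centroids)
  s <- matrix(0, n, n, dimnames = list(uids, uids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s[i, j] <- s[j, i] <- rtke_score(centroids[[i]], centroids[[j]],
                                       fraction, variant)
    }
  }
  structure(
    list(
      cluster_uids = uids,
      scores = s,
      top_k_fraction = fraction,
      gene_universe_size = length(centroids[[1]]$gene_ids)
    ),
    class = "similarity_matrix"
  )
}

#' Empirical edge threshold
#'
#' Quantile of the off-diagonal, upper-triangle score distribution. The
#' default keeps the upper 0.006 tail (`quantile = 0.994`), the protocol's
#' empirically screened setting. Uses the standard linear-interpolation
#' quantile (type 7).
#'
#' @param sm A `similarity_matrix`.
#' @param quantile Probability in (0, 1]; edges above the returned value
#'   survive. Default 0.994.
#' @return The threshold score.
#' @export
empirical_threshold <- function(sm, quantile = 0.994) {
  stopifnot(inherits(sm, "similarity_matrix"), quantile > 0, quantile <= 1)
  off <- sm$scores[upper.tri(sm$scores)]
  if (length(off) < 1L) stop("no off-diagonal scores")
  if (length(unique(off)) == 1L) {
    warning("degenerate similarity distribution: all off-diagonal scores equal ",
            off[1])
    return(off[1])
  }
  unname(stats::quantile(off, probs = quantile, type = 7))
}
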
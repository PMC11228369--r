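#' Read a GMT gene-set collection
#'
#' @param path GMT file path.
#' @param source_tag Label recorded on the collection.
#' @return A list of class `gene_set_collection`: `sets` (name -> gene
#'   character vector) and `source`.
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  sets <- fgsea::gmtPathways(path)
  structure(list(sets = sets, source = source_tag),
            class = "gene_set_collection")
}

#' Gene-set collection from a list
#'
#' @param sets Named list of gene id character vectors.
#' @param source_tag Label recorded on the collection.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source_tag = "custom") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  structure(list(sets = sets, source = source_tag),
            class = "gene_set_collection")
}

#' Filter gene sets by size
#'
#' Keeps sets with strictly more than `min_size` and strictly fewer than
#' `max_size` genes — sizes of exactly 50 or 100 are removed under the
#' defaults. Genes are deduplicated, and when a `universe` is supplied each
#' set is intersected with it before sizing, so the filter reflects the
#' genes actually available for enrichment.
#'
#' @param collection A `gene_set_collection`.
#' @param universe Optional character vector of usable gene ids.
#' @param min_size,max_size Strict size bounds. Defaults 50 and 100.
#' @return The filtered `gene_set_collection`.
#' @export
filter_gene_sets <- function(collection, universe = NULL,
                             min_size = 50, max_size = 100) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sets <- lapply(collection$sets, unique)
  if (!is.null(universe)) sets <- lapply(sets, intersect, y = universe)
  sizes <- lengths(sets)
  keep <- sizes > min_size & sizes < max_size
  if (!any(keep)) {
    stop("no gene sets with size in (", min_size, ", ", max_size,
         "); try a different collection")
  }
  collection$sets <- sets[keep]
  collection
}

#' Annotate an exemplar with its top-ranked gene sets
#'
#' Scores every gene set with a preranked weighted running-sum enrichment
#' statistic (weight exponent 1) over the exemplar's gene ordering. The
#' statistic is computed on the rank of the exemplar's average-rank vector
#' rather than the raw values, so it is invariant to monotone transforms
#' of the profile. Sets are ranked by enrichment score (ties broken
#' lexicographically by set name) and the top `n_top` recorded.
#'
#' @param exemplar An `exemplar_signature`.
#' @param collection A filtered `gene_set_collection`.
#' @param n_top Number of gene sets recorded. Default 5.
#' @param classic If TRUE, an unweighted (classic) running sum is used
#'   (weight exponent 0).
#' @return Data frame: exemplar_id, rank (1..n_top), set_name, score.
#' @export
annotate_exemplar <- function(exemplar, collection, n_top = 5,
                              classic = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(collection$sets)) stop("empty gene set collection")
  stats_vec <- rank(exemplar$avg_rank, ties.method = "average")
  names(stats_vec) <- exemplar$gene_ids
  ord <- order(stats_vec, decreasing = TRUE)
  sorted_stats <- stats_vec[ord]
  param <- if (classic) 0 else 1
  scores <- vapply(names(collection$sets), function(nm) {
    idx <- which(names(sorted_stats) %in% collection$sets[[nm]])
    if (length(idx) == 0L) return(NA_real_)
    fgsea::calcGseaStat(sorted_stats, selectedStats = idx,
                        gseaParam = param)
  }, numeric(1))
  ok <- !is.na(scores)
  if (!any(ok)) stop("no gene set overlaps the exemplar's gene universe")
  tab <- data.frame(set_name = names(scores)[ok], score = scores[ok],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score, tab$set_name), ]
  top <- utils::head(tab, n_top)
  data.frame(
    exemplar_id = exemplar$exemplar_id,
    rank = seq_len(nrow(top)),
    set_name = top$set_name,
    score = top$score,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
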
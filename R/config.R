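#' Run configuration
#'
#' Central container for the tunable parameters of the exemplar workflow.
#' Defaults follow the published protocol: top 10% of genes per centroid for
#' RTKE, the upper 0.006 quantile of the empirical similarity distribution as
#' the graph edge threshold, the top 20% of genes by gap score as signature
#' genes, a 1% normalized deconvolution score as the detection threshold, and
#' an HDBSCAN minimum cluster size of 20 on the sample map.
#'
#' @param top_k_fraction Fraction of the gene universe taken as each
#'   centroid's top gene set for RTKE. Default 0.10.
#' @param edge_quantile Quantile of the off-diagonal similarity distribution
#'   used as the graph edge threshold (0.994 keeps the upper 0.006 tail).
#' @param signature_gene_fraction Fraction of genes retained in the
#'   deconvolution signature matrix, ranked by gap score. Default 0.20.
#' @param detection_threshold Normalized deconvolution score at or above
#'   which a signature counts as detected in a sample. Default 0.01.
#' @param min_cells_per_cluster Cluster size below which a rank centroid is
#'   flagged as potentially unstable (centroid quality saturates around 50
#'   cells). Default 50.
#' @param hdbscan_min_cluster_size Minimum spatial cluster size on the
#'   sample map. Default 20 (50 is used for comparison maps).
#' @param mixture_count Number of in-silico bulk mixtures simulated by
#'   default. Default 200.
#' @param rng_seed Integer seed used by seeded operations when none is
#'   passed explicitly.
#'
#' @return A list of class `scex_config`.
#' @export
run_config <- function(top_k_fraction = 0.10,
                       edge_quantile = 0.994,
                       signature_gene_fraction = 0.20,
                       detection_threshold = 0.01,
                       min_cells_per_cluster = 50,
                       hdbscan_min_cluster_size = 20,
                       mixture_count = 200,
                       rng_seed = 1L) {
  stopifnot(
    top_k_fraction > 0, top_k_fraction <= 1,
    edge_quantile > 0, edge_quantile <= 1,
    signature_gene_fraction > 0, signature_gene_fraction <= 1,
    detection_threshold >= 0, detection_threshold < 1,
    min_cells_per_cluster >= 1,
    hdbscan_min_cluster_size >= 2,
    mixture_count >= 1
  )
  structure(
    list(
      top_k_fraction = top_k_fraction,
      edge_quantile = edge_quantile,
      signature_gene_fraction = signature_gene_fraction,
      detection_threshold = detection_threshold,
      min_cells_per_cluster = min_cells_per_cluster,
      hdbscan_min_cluster_size = hdbscan_min_cluster_size,
      mixture_count = mixture_count,
      rng_seed = as.integer(rng_seed)
    ),
    class = "scex_config"
  )
}

#' Read a flat key=value configuration file
#'
#' Each non-blank, non-comment line is `key = value`. Unknown keys error.
#' Values override the defaults of [run_config()].
#'
#' @param path Path to the configuration file.
#' @return A `scex_config` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    if (!key %in% names(formals(run_config))) stop("unknown config key: ", key)
    args[[key]] <- as.numeric(trimws(kv[2]))
  }
  do.call(run_config, args)
}
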
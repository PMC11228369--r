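# Shared fixtures and independent oracles for the test suite.

# A rank_centroid built directly from an avg_rank vector.
make_centroid <- function(avg_rank, uid = "ds.0", dataset_id = "ds",
                          n_cells = 100) {
  if (is.null(names(avg_rank))) {
    names(avg_rank) <- sprintf("g%03d", seq_along(avg_rank))
  }
  structure(
    list(cluster_uid = uid, dataset_id = dataset_id,
         gene_ids = names(avg_rank), avg_rank = avg_rank,
         n_cells = n_cells),
    class = "rank_centroid"
  )
}

# Centroid whose top-k genes are exactly `top_genes` within universe 1..G.
centroid_with_top <- function(G, top_genes, uid = "ds.0",
                              dataset_id = "ds") {
  genes <- sprintf("g%03d", seq_len(G))
  r <- seq_len(G)
  names(r) <- genes
  # move requested genes to the top ranks, keep relative order elsewhere
  rest <- setdiff(genes, top_genes)
  r[c(rest, top_genes)] <- seq_len(G)
  make_centroid(r, uid = uid, dataset_id = dataset_id)
}

# Exhaustive hypergeometric upper-tail oracle: P(|draw ∩ fixed| >= m) when
# a kb-subset is drawn uniformly from G elements and the fixed set has ka.
hyper_tail_enum <- function(G, ka, kb, m) {
  draws <- utils::combn(G, kb)
  fixed <- seq_len(ka)
  hits <- apply(draws, 2, function(cols) sum(cols %in% fixed) >= m)
  mean(hits)
}

# Product-limit (Kaplan-Meier) estimate at each requested time, computed
# from first principles.
km_oracle <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- stats::setNames(numeric(length(at)), at)
  for (i in seq_along(at)) {
    s_i <- 1
    for (t in ut[ut <= at[i]]) {
      n_risk <- sum(time >= t)
      d <- sum(time == t & event == 1)
      s_i <- s_i * (1 - d / n_risk)
    }
    surv[i] <- s_i
  }
  unname(surv)
}

# A group_assignment built directly from labels.
make_groups <- function(sample_ids, labels, rule = "median") {
  structure(
    list(sample_ids = sample_ids,
         label = stats::setNames(labels, sample_ids),
         rule = rule, cutpoints = numeric(0)),
    class = "group_assignment"
  )
}

# Score matrix of two sample populations with disjoint active exemplars.
two_block_scores <- function(n_per = 40, k_per = 3, seed = 2) {
  set.seed(seed)
  sc <- rbind(
    cbind(matrix(runif(n_per * k_per, 5, 10), n_per),
          matrix(runif(n_per * k_per, 0, 0.1), n_per)),
    cbind(matrix(runif(n_per * k_per, 0, 0.1), n_per),
          matrix(runif(n_per * k_per, 5, 10), n_per))
  )
  dimnames(sc) <- list(paste0("s", seq_len(2 * n_per)),
                       paste0("X", seq_len(2 * k_per)))
  sc
}

# Cluster a full compendium and return centroids plus per-centroid majority
# truth labels and the design-derived edge quantile.
compendium_centroids <- function(comp, seed) {
  cents <- list()
  truth <- c()
  for (d in names(comp$datasets)) {
    em <- comp$datasets[[d]]
    ca <- cluster_dataset(em, seed = seed)
    cents <- c(cents,
               suppressWarnings(dataset_centroids(em, ca, min_cells = 1)))
    for (lab in sort(unique(ca$labels))) {
      tt <- comp$truth$cell_types[[d]][ca$cell_ids[ca$labels == lab]]
      truth[paste0(d, ".", lab)] <- names(which.max(table(tt)))
    }
  }
  same <- outer(truth, truth, "==")
  ut <- upper.tri(same)
  list(centroids = cents, truth = truth,
       edge_quantile = 1 - sum(same & ut) / sum(ut))
}
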
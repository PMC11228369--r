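#' Simulate a multi-dataset single-cell compendium with planted cell types
#'
#' Emulates the situation the exemplar workflow is built for: several
#' scRNA-seq datasets share a set of true cell types, but each dataset sees
#' them through its own platform lens. Type profiles are log-normal
#' baselines with disjoint marker blocks upregulated per type; each dataset
#' applies a dataset-specific strictly monotone distortion (x -> x^a,
#' a in `distortion_range` — rank-preserving by design, which is exactly
#' the invariance the rank centroids exploit) plus gene-wise multiplicative
#' factors, and counts are drawn from a negative binomial.
#'
#' @param n_types Number of planted cell types T (>= 2). Default 3.
#' @param n_datasets Number of datasets D. Default 4.
#' @param n_genes Gene universe size G (>= 200). Default 600.
#' @param cells_per_type Cells per type per dataset. Default 60.
#' @param marker_frac Fraction of genes forming each type's marker block.
#'   Default 0.10: marker breadth matches the RTKE top-gene fraction, so
#'   type identity dominates the top of each centroid ranking.
#' @param marker_fold Fold upregulation of marker genes. Default 8.
#' @param distortion_range Range of the per-dataset power-law exponent.
#'   Default c(0.5, 2); use c(1, 1) for no distortion.
#' @param gene_factor_sd SD (log scale) of gene-wise per-dataset
#'   multiplicative factors. Default 0.3.
#' @param dispersion Negative binomial dispersion (size = 1/dispersion).
#'   Default 0.3.
#' @param types_per_dataset How many of the T types each dataset contains;
#'   defaults to all.
#' @param lib_size Expected library size per cell. Default 20000.
#' @param seed Seed; regeneration with the same seed is byte-identical.
#' @return List with `datasets` (list of counts [expression_matrix()]) and
#'   `truth` (per-dataset cell-to-type assignments, the type mean profiles,
#'   per-dataset distortion parameters, and the seed).
#' @export
simulate_compendium <- function(n_types = 3, n_datasets = 4, n_genes = 600,
                                cells_per_type = 60, marker_frac = 0.10,
                                marker_fold = 8,
                                distortion_range = c(0.5, 2),
                                gene_factor_sd = 0.3, dispersion = 0.3,
                                types_per_dataset = n_types,
                                lib_size = 20000, seed = 1L) {
  stopifnot(n_types >= 2, n_datasets >= 1, n_genes >= 200,
            types_per_dataset >= 1, types_per_dataset <= n_types)
  n_marker <- ceiling(marker_frac * n_genes)
  if (n_types * n_marker > n_genes) {
    stop("marker blocks (", n_types, " x ", n_marker,
         ") exceed the gene universe (", n_genes, ")")
  }
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, meanlog = log(2), sdlog = 1)
  profiles <- matrix(base, n_genes, n_types,
                     dimnames = list(genes, paste0("type", seq_len(n_types))))
  marker_blocks <- split(seq_len(n_types * n_marker),
                         rep(seq_len(n_types), each = n_marker))
  for (t in seq_len(n_types)) {
    profiles[marker_blocks[[t]], t] <- profiles[marker_blocks[[t]], t] *
      marker_fold
  }

  datasets <- vector("list", n_datasets)
  cell_types <- vector("list", n_datasets)
  distortion <- numeric(n_datasets)
  for (d in seq_len(n_datasets)) {
    ds_id <- sprintf("ds%02d", d)
    a <- stats::runif(1, distortion_range[1], distortion_range[2])
    distortion[d] <- a
    gene_fac <- stats::rlnorm(n_genes, 0, gene_factor_sd)
    types <- if (types_per_dataset < n_types) {
      sort(sample(seq_len(n_types), types_per_dataset))
    } else {
      seq_len(n_types)
    }
    n_cells <- cells_per_type * length(types)
    counts <- matrix(0L, n_genes, n_cells)
    truth <- character(n_cells)
    col <- 1L
    for (t in types) {
      mu <- (profiles[, t]^a) * gene_fac
      mu <- mu / sum(mu) * lib_size
      for (i in seq_len(cells_per_type)) {
        counts[, col] <- stats::rnbinom(n_genes, mu = mu,
                                        size = 1 / dispersion)
        truth[col] <- paste0("type", t)
        col <- col + 1L
      }
    }
    dimnames(counts) <- list(genes,
                             paste0(ds_id, "_c", seq_len(n_cells)))
    datasets[[d]] <- expression_matrix(counts, unit = "counts",
                                       dataset_id = ds_id)
    cell_types[[d]] <- stats::setNames(truth, colnames(counts))
  }
  names(datasets) <- names(cell_types) <-
    sprintf("ds%02d", seq_len(n_datasets))
  list(
    datasets = datasets,
    truth = list(cell_types = cell_types, profiles = profiles,
                 distortion = distortion, seed = seed)
  )
}

#' Simulate in-silico bulk mixtures with a dominant tumor component
#'
#' Reproduces the validation protocol for deconvolution: a designated
#' tumor component receives an integer percentage drawn uniformly from
#' 50..90, the remainder is split across the other components in
#' non-negative integer percentages (symmetric Dirichlet draw rounded with
#' largest-remainder correction so every proportion vector sums to exactly
#' 100). Components are quantile-normalized to a common reference before
#' mixing; optional multiplicative log-normal noise with coefficient of
#' variation `noise_cv` is applied to each mixture.
#'
#' @param components Genes x components numeric matrix (expression scale),
#'   >= 2 columns.
#' @param n Number of mixtures. Default 200.
#' @param tumor_id Column name of the tumor component; defaults to the
#'   first column.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#'   Default 0.1; 0 disables noise.
#' @param seed Seed.
#' @return List with `bulk` (an [expression_matrix()], unit TPM) and
#'   `truth` (mixtures x components integer percentage matrix, `tumor_id`,
#'   `seed`).
#' @export
simulate_mixtures <- function(components, n = 200, tumor_id = NULL,
                              noise_cv = 0.1, seed = 1L) {
  components <- as.matrix(components)
  if (ncol(components) < 2L) stop("need at least 2 components")
  if (is.null(colnames(components))) {
    colnames(components) <- paste0("comp", seq_len(ncol(components)))
  }
  if (is.null(tumor_id)) tumor_id <- colnames(components)[1]
  if (!tumor_id %in% colnames(components)) {
    stop("tumor component ", tumor_id, " not found")
  }
  set.seed(seed)
  qn <- limma::normalizeQuantiles(components)
  others <- setdiff(colnames(components), tumor_id)
  props <- matrix(0L, n, ncol(components),
                  dimnames = list(sprintf("mix%04d", seq_len(n)),
                                  colnames(components)))
  for (i in seq_len(n)) {
    tf <- sample(50:90, 1L)
    props[i, tumor_id] <- tf
    props[i, others] <- .integer_partition(100L - tf, length(others))
  }
  mix <- qn %*% t(props / 100)
  if (noise_cv > 0) {
    slog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(stats::rlnorm(length(mix), -slog^2 / 2, slog),
                    nrow(mix), ncol(mix))
    mix <- mix * noise
  }
  list(
    bulk = expression_matrix(mix, unit = "TPM", dataset_id = "mixtures"),
    truth = list(proportions = props, tumor_id = tumor_id, seed = seed)
  )
}

# Symmetric Dirichlet draw scaled to `total`, rounded with the
# largest-remainder method so the integer parts sum exactly to `total`.
.integer_partition <- function(total, k) {
  if (k == 0L) {
    if (total != 0L) stop("no components to absorb the remainder")
    return(integer(0))
  }
  if (total == 0L) return(rep(0L, k))
  w <- stats::rgamma(k, shape = 1)
  x <- total * w / sum(w)
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Simulate survival records with a planted hazard ratio
#'
#' Exponential event times whose hazard is multiplied by `hr` for
#' patients-up samples (and optionally by per-subtype multipliers), with
#' independent uniform censoring C ~ U(0, b) where b is solved so the
#' expected censoring fraction equals `censor_frac`.
#'
#' @param groups Data frame with `sample_id` and `group` ("up"/"down"),
#'   optionally `subtype`.
#' @param baseline_hazard Hazard of the down group. Default 0.01 per day.
#' @param hr Hazard ratio of up vs down. Default 3.
#' @param censor_frac Target censoring fraction in [0, 1). Default 0.2.
#' @param subtype_hr Optional named vector of per-subtype hazard
#'   multipliers.
#' @param cohort Cohort label on the output. Default "synthetic".
#' @param seed Seed.
#' @return Survival data frame: sample_id, time, event, subtype, cohort.
#' @export
simulate_survival <- function(groups, baseline_hazard = 0.01, hr = 3,
                              censor_frac = 0.2, subtype_hr = NULL,
                              cohort = "synthetic", seed = 1L) {
  stopifnot(hr > 0, censor_frac >= 0, censor_frac < 1,
            all(c("sample_id", "group") %in% colnames(groups)))
  set.seed(seed)
  rate <- baseline_hazard * ifelse(groups$group == "up", hr, 1)
  if (!is.null(subtype_hr)) {
    if (!"subtype" %in% colnames(groups)) stop("groups lacks a subtype column")
    rate <- rate * unname(subtype_hr[as.character(groups$subtype)])
  }
  t_event <- stats::rexp(nrow(groups), rate = rate)
  if (censor_frac > 0) {
    # P(censored | rate h, C ~ U(0, b)) = E[exp(-hC)] = (1 - exp(-hb))/(hb),
    # decreasing in b
    cens_prob <- function(b) {
      mean((1 - exp(-rate * b)) / (rate * b)) - censor_frac
    }
    b <- stats::uniroot(cens_prob, lower = 1e-8, upper = 1e8,
                        extendInt = "downX")$root
    c_time <- stats::runif(nrow(groups), 0, b)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
  } else {
    time <- t_event
    event <- rep(1L, nrow(groups))
  }
  data.frame(
    sample_id = groups$sample_id,
    time = time,
    event = event,
    subtype = if ("subtype" %in% colnames(groups)) groups$subtype else NA,
    cohort = cohort,
    stringsAsFactors = FALSE
  )
}
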
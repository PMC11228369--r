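#' Deconvolve bulk samples against a signature matrix
#'
#' CIBERSORT-style absolute-mode work-alike. For each sample the bulk
#' profile and every signature column are restricted to their shared genes
#' and z-scored over those genes, and non-negative coefficients are fitted
#' (default: non-negative least squares; optionally nu-support-vector
#' regression with nu in \{0.25, 0.5, 0.75\}, keeping the lowest-RMSE fit
#' and clipping negative coefficients to zero). Fitted z-space coefficients
#' are mapped back to mixture-proportion units by `w_i = c_i * sd(y) /
#' sd(x_i)`, so a noiseless convex combination of signature columns is
#' recovered exactly. Raw scores are not forced to sum to one
#' ("no.sumto1"); no quantile normalization is applied. The per-sample
#' 0-1 normalization used for detection divides raw scores by their sum.
#'
#' @param bulk An [expression_matrix()] of bulk samples (TPM recommended).
#' @param sig Genes x exemplars signature matrix.
#' @param method `"nnls"` (default) or `"nu_svr"`.
#' @param rank_bulk If TRUE, the bulk samples are within-sample
#'   rank-transformed before fitting (the signature is rank-based; this
#'   puts both sides on the rank scale).
#' @return A list of class `deconvolution_result`: `sample_ids`,
#'   `exemplar_ids`, `raw_scores` and `normalized_scores` (samples x
#'   exemplars), `detected` (NULL until [detect()]), and `fit_stats`
#'   (per-sample reconstruction RMSE and Pearson r in z-space).
#' @export
deconvolve <- function(bulk, sig, method = c("nnls", "nu_svr"),
                       rank_bulk = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(bulk, "expression_matrix"), is.matrix(sig))
  shared <- intersect(bulk$gene_ids, rownames(sig))
  if (length(shared) < 50L) {
    stop("bulk and signature share ", length(shared), " genes (< 50)")
  }
  b <- bulk$values[shared, , drop = FALSE]
  if (rank_bulk) b <- apply(b, 2, rank, ties.method = "average")
  x <- sig[shared, , drop = FALSE]

  sx <- apply(x, 2, stats::sd)
  mx <- colMeans(x)
  xz <- sweep(sweep(x, 2, mx, "-"), 2, ifelse(sx > 0, sx, 1), "/")

  n_s <- ncol(b)
  n_e <- ncol(x)
  raw <- matrix(0, n_s, n_e, dimnames = list(colnames(b), colnames(x)))
  stats_df <- data.frame(sample_id = colnames(b), rmse = NA_real_,
                         pearson_r = NA_real_, stringsAsFactors = FALSE)

  for (s in seq_len(n_s)) {
    y <- b[, s]
    sy <- stats::sd(y)
    if (all(y == 0) || sy == 0) {
      warning("sample ", colnames(b)[s], " is constant; scores set to zero")
      next
    }
    yz <- (y - mean(y)) / sy
    co <- switch(method,
      nnls = pracma::lsqnonneg(xz, yz)$x,
      nu_svr = .fit_nu_svr(xz, yz)
    )
    co[co < 0] <- 0
    fit <- as.numeric(xz %*% co)
    stats_df$rmse[s] <- sqrt(mean((yz - fit)^2))
    stats_df$pearson_r[s] <- if (stats::sd(fit) > 0) {
      stats::cor(yz, fit)
    } else NA_real_
    raw[s, ] <- ifelse(sx > 0, co * sy / sx, 0)
  }

  sums <- rowSums(raw)
  norm <- raw
  pos <- sums > 0
  norm[pos, ] <- raw[pos, , drop = FALSE] / sums[pos]
  structure(
    list(
      sample_ids = colnames(b),
      exemplar_ids = colnames(x),
      raw_scores = raw,
      normalized_scores = norm,
      detected = NULL,
      fit_stats = stats_df,
      method = method
    ),
    class = "deconvolution_result"
  )
}

# nu-SVR with linear kernel over nu grid; returns coefficient vector of the
# best (lowest reconstruction RMSE) fit.
.fit_nu_svr <- function(xz, yz, nus = c(0.25, 0.5, 0.75)) {
  best <- NULL
  best_rmse <- Inf
  for (nu in nus) {
    fit <- tryCatch(
      e1071::svm(x = xz, y = yz, type = "nu-regression", kernel = "linear",
                 nu = nu, scale = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    w[w < 0] <- 0
    rmse <- sqrt(mean((yz - as.numeric(xz %*% w))^2))
    if (rmse < best_rmse) {
      best_rmse <- rmse
      best <- w
    }
  }
  if (is.null(best)) stop("nu-SVR failed for all nu values")
  best
}

#' Detection calls
#'
#' A signature is detected in a sample when its 0-1 normalized score is at
#' least `threshold` (default 1%).
#'
#' @param result A `deconvolution_result`.
#' @param threshold Detection threshold on the normalized scale. Default 0.01.
#' @return The result with its `detected` boolean matrix filled in.
#' @export
detect <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "deconvolution_result"))
  result$detected <- result$normalized_scores >= threshold
  result$detection_threshold <- threshold
  result
}

#' Per-exemplar detection summary
#'
#' Fraction of samples in which each exemplar is detected, with the
#' reporting bins used for signature catalogs: never detected, detected in
#' under half the samples, in at least half, in at least 90%.
#'
#' @param result A `deconvolution_result` after [detect()].
#' @return Data frame with `exemplar_id`, `fraction` and `bin`.
#' @export
detection_summary <- function(result) {
  stopifnot(inherits(result, "deconvolution_result"))
  if (is.null(result$detected)) stop("run detect() first")
  frac <- colMeans(result$detected)
  bin <- ifelse(frac == 0, "never",
         ifelse(frac >= 0.9, ">=90%",
         ifelse(frac >= 0.5, ">=50%", "<50%")))
  data.frame(
    exemplar_id = result$exemplar_ids,
    fraction = as.numeric(frac),
    bin = bin,
    stringsAsFactors = FALSE
  )
}
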
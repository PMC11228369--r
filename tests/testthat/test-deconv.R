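sig_fixture <- function(G = 300, k = 4, seed = 1) {
  set.seed(seed)
  matrix(rlnorm(G * k, 2, 1), G, k,
         dimnames = list(sprintf("g%03d", seq_len(G)), paste0("X", seq_len(k))))
}

test_that("noiseless convex combinations are recovered exactly", {
  sig <- sig_fixture()
  y <- 0.6 * sig[, 1] + 0.4 * sig[, 2]
  bulk <- expression_matrix(cbind(mixed = y, pure = sig[, 3]), unit = "TPM")
  dr <- deconvolve(bulk, sig)
  expect_equal(unname(dr$normalized_scores["mixed", ]), c(0.6, 0.4, 0, 0),
               tolerance = 1e-6)
  expect_equal(unname(dr$normalized_scores["pure", ]), c(0, 0, 1, 0),
               tolerance = 1e-6)
  expect_true(all(dr$raw_scores >= 0))
  expect_equal(unname(rowSums(dr$normalized_scores)), c(1, 1))
})

test_that("normalized scores are invariant to bulk scaling", {
  sig <- sig_fixture()
  y <- 0.3 * sig[, 1] + 0.5 * sig[, 2] + 0.2 * sig[, 4]
  b1 <- expression_matrix(cbind(s = y), unit = "TPM")
  b2 <- expression_matrix(cbind(s = 1234 * y), unit = "TPM")
  expect_equal(deconvolve(b1, sig)$normalized_scores,
               deconvolve(b2, sig)$normalized_scores, tolerance = 1e-10)
})

test_that("nnls and nu-SVR agree on noiseless mixtures", {
  sig <- sig_fixture()
  y <- 0.5 * sig[, 1] + 0.3 * sig[, 2] + 0.2 * sig[, 3]
  bulk <- expression_matrix(cbind(s = y), unit = "TPM")
  a <- deconvolve(bulk, sig, method = "nnls")$normalized_scores
  b <- deconvolve(bulk, sig, method = "nu_svr")$normalized_scores
  expect_lt(sqrt(mean((a - b)^2)), 0.05)
})

test_that("an absent signature perturbs recovered proportions only slightly", {
  sig <- sig_fixture(k = 5)
  y <- 0.7 * sig[, 1] + 0.3 * sig[, 2]
  bulk <- expression_matrix(cbind(s = y), unit = "TPM")
  with_all <- deconvolve(bulk, sig)$normalized_scores
  without <- deconvolve(bulk, sig[, 1:2])$normalized_scores
  expect_lt(mean(abs(with_all[, 1:2] - without)), 0.05)
})

test_that("input contracts are enforced", {
  sig <- sig_fixture(G = 60)
  bulk_few <- expression_matrix(
    matrix(1:40, 40, 1, dimnames = list(rownames(sig)[1:40], "s")),
    unit = "TPM")
  expect_error(deconvolve(bulk_few, sig), "< 50")
  bulk0 <- expression_matrix(
    matrix(0, 60, 1, dimnames = list(rownames(sig), "z")), unit = "TPM")
  expect_warning(dr <- deconvolve(bulk0, sig), "constant")
  expect_true(all(dr$raw_scores == 0))
  dr <- detect(dr)
  expect_false(any(dr$detected))
})

test_that("detection applies the 1% threshold inclusively", {
  dr <- structure(
    list(sample_ids = c("s1", "s2"), exemplar_ids = c("X1", "X2"),
         raw_scores = matrix(0, 2, 2),
         normalized_scores = matrix(c(0.01, 0.99, 0.0099, 0.9901), 2, 2,
                                    byrow = TRUE,
                                    dimnames = list(c("s1", "s2"),
                                                    c("X1", "X2"))),
         detected = NULL, fit_stats = NULL, method = "nnls"),
    class = "deconvolution_result")
  dr <- detect(dr, threshold = 0.01)
  expect_true(dr$detected["s1", "X1"])     # exactly 0.01 counts
  expect_false(dr$detected["s2", "X1"])    # 0.0099 does not
})

test_that("detection summary bins match brute-force column means", {
  det <- matrix(c(rep(TRUE, 10),
                  rep(c(TRUE, FALSE), 5),
                  rep(FALSE, 10),
                  c(rep(TRUE, 9), FALSE)), 10, 4,
                dimnames = list(paste0("s", 1:10), paste0("X", 1:4)))
  dr <- structure(
    list(sample_ids = paste0("s", 1:10), exemplar_ids = paste0("X", 1:4),
         raw_scores = NULL, normalized_scores = NULL, detected = det,
         fit_stats = NULL, method = "nnls"),
    class = "deconvolution_result")
  ds <- detection_summary(dr)
  expect_equal(ds$fraction, unname(colMeans(det)))
  expect_equal(ds$bin, c(">=90%", ">=50%", "never", ">=90%"))
})

test_that("noisy planted mixtures are recovered accurately", {
  comp <- simulate_compendium(seed = 5)
  cc <- compendium_centroids(comp, seed = 5)
  res <- derive_exemplars(cc$centroids,
                          run_config(edge_quantile = cc$edge_quantile),
                          seed = 5)
  sig <- signature_matrix_from_exemplars(res$exemplars)
  comps <- exemplar_matrix(res$exemplars)
  mx <- simulate_mixtures(comps, n = 60, noise_cv = 0.1, seed = 5)
  dr <- deconvolve(mx$bulk, sig)
  tru <- mx$truth$proportions[, colnames(dr$normalized_scores)] / 100
  est <- dr$normalized_scores
  for (cn in colnames(tru)) {
    expect_gt(cor(tru[, cn], est[, cn]), 0.9)
  }
  expect_lt(sqrt(mean((tru - est)^2)), 0.05)
})

test_that("rank-based signatures do not trail count-based ones on mixtures", {
  comp <- simulate_compendium(seed = 31)
  cc <- compendium_centroids(comp, seed = 31)
  res <- derive_exemplars(cc$centroids,
                          run_config(edge_quantile = cc$edge_quantile),
                          seed = 31)
  # mixtures built from the true (undistorted) type profiles
  profs <- comp$truth$profiles
  mx <- simulate_mixtures(profs, n = 40, noise_cv = 0.1, seed = 31)

  # rank route: pipeline exemplar signature, exemplars matched to types
  sig_rank <- signature_matrix_from_exemplars(res$exemplars)
  type_of <- vapply(res$exemplars, function(ex) {
    names(which.max(table(cc$truth[ex$member_cluster_uids])))
  }, character(1))
  dr_rank <- deconvolve(mx$bulk, sig_rank)
  est_rank <- dr_rank$normalized_scores
  colnames(est_rank) <- unname(type_of[colnames(est_rank)])

  # count route: mean TPM centroids from a single (distorted) dataset
  em1 <- comp$datasets[[1]]
  tt1 <- comp$truth$cell_types[[1]]
  tpm <- sweep(em1$values, 2, colSums(em1$values), "/") * 1e6
  sig_count <- vapply(sort(unique(tt1)), function(ty) {
    rowMeans(tpm[, names(tt1)[tt1 == ty], drop = FALSE])
  }, numeric(nrow(tpm)))
  dr_count <- deconvolve(mx$bulk, sig_count)
  est_count <- dr_count$normalized_scores

  tru <- mx$truth$proportions[, colnames(profs)] / 100
  rmse_rank <- sqrt(mean((est_rank[, colnames(tru)] - tru)^2))
  rmse_count <- sqrt(mean((est_count[, colnames(tru)] - tru)^2))
  expect_lte(rmse_rank, rmse_count + 1e-8)
})
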
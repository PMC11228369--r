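test_that("layout separates blocks, is seeded, and keeps duplicates close", {
  sc <- two_block_scores()
  ly <- layout_samples(sc, seed = 5)
  xy <- cbind(ly$x, ly$y)
  within <- mean(stats::dist(xy[1:40, ]))
  between <- mean(as.matrix(stats::dist(xy))[1:40, 41:80])
  expect_lt(within, between)

  ly2 <- layout_samples(sc, seed = 5)
  expect_identical(cbind(ly$x, ly$y), cbind(ly2$x, ly2$y))

  sc_dup <- sc
  sc_dup[2, ] <- sc_dup[1, ]
  ly3 <- layout_samples(sc_dup, seed = 5)
  diam <- max(stats::dist(cbind(ly3$x, ly3$y)))
  d12 <- sqrt((ly3$x[1] - ly3$x[2])^2 + (ly3$y[1] - ly3$y[2])^2)
  expect_lt(d12, 0.05 * diam)

  expect_error(layout_samples(matrix(1, 20, 4)), "constant")
  expect_error(layout_samples(sc[1:5, ]), "at least 10")
})

test_that("spatial clustering recovers planted blobs and flags noise", {
  set.seed(6)
  pts <- rbind(cbind(rnorm(50, 0, 0.1), rnorm(50, 0, 0.1)),
               cbind(rnorm(50, 5, 0.1), rnorm(50, 5, 0.1)))
  labs <- hdbscan_points(pts, min_cluster_size = 20)
  expect_equal(length(unique(labs[labs > 0])), 2)
  expect_equal(sum(labs == 0), 0)
  expect_equal(length(unique(labs[1:50])), 1)
  expect_equal(length(unique(labs[51:100])), 1)

  set.seed(7)
  noise <- cbind(runif(30, 0, 10), runif(30, 0, 10))
  labs2 <- hdbscan_points(noise, min_cluster_size = 20)
  expect_gt(mean(labs2 == 0), 0.5)

  expect_true(all(hdbscan_points(pts[1:10, ], min_cluster_size = 20) == 0L))
})

test_that("every reported spatial cluster meets the minimum size", {
  set.seed(8)
  pts <- rbind(cbind(rnorm(60, 0, 0.2), rnorm(60, 0, 0.2)),
               cbind(rnorm(25, 8, 0.2), rnorm(25, 8, 0.2)),
               cbind(runif(15, 3, 5), runif(15, 3, 5)))
  labs <- hdbscan_points(pts, min_cluster_size = 20)
  if (any(labs > 0)) {
    expect_true(all(table(labs[labs > 0]) >= 20))
  }
})

test_that("adjusted Rand index has its documented fixed points", {
  a <- rep(c("x", "y"), each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  b <- rep(c("q", "r"), each = 10)      # renamed labels
  expect_equal(adjusted_rand_index(a, b), 1)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_equal(adjusted_rand_index(rep("one", 8), rep("uno", 8)), 1)

  # unassigned samples are excluded before comparison
  a2 <- c(a, "unassigned")
  b2 <- c(b, "x")
  expect_equal(adjusted_rand_index(a2, b2), 1)

  # random shuffles: chance-corrected agreement centers on zero; at n = 20
  # single shuffles can reach |ARI| ~ 0.3, so the bound is on the typical
  # magnitude, not the extreme of 100 draws
  set.seed(9)
  aris <- replicate(100, adjusted_rand_index(a, sample(a)))
  expect_lt(mean(abs(aris)), 0.2)
  expect_lt(abs(mean(aris)), 0.05)
  expect_lt(stats::median(abs(aris)), 0.2)
})

test_that("planted two-population maps cluster to truth across seeds", {
  for (seed in 1:10) {
    sc <- two_block_scores(seed = seed)
    ly <- layout_samples(sc, seed = seed)
    spc <- spatial_clusters(ly, min_cluster_size = 20)
    truth <- rep(c("a", "b"), each = 40)
    expect_equal(length(setdiff(unique(spc$cluster), "unassigned")), 2,
                 label = paste("seed", seed))
    expect_equal(adjusted_rand_index(spc$cluster, truth), 1,
                 label = paste("seed", seed))
  }
})

test_that("differential exemplars match the t statistic and its ordering", {
  set.seed(12)
  sc <- matrix(rnorm(60 * 5), 60, 5,
               dimnames = list(paste0("s", 1:60), paste0("X", 1:5)))
  a_ids <- paste0("s", 1:30)
  b_ids <- paste0("s", 31:60)
  sc[a_ids, "X3"] <- sc[a_ids, "X3"] + 10   # +10 sd in cluster a
  de <- differential_exemplars(sc, a_ids, b_ids)
  expect_equal(de$highest$exemplar_id[1], "X3")
  # oracle: pooled-variance Student t
  for (i in seq_len(nrow(de$table))) {
    ex <- de$table$exemplar_id[i]
    tt <- stats::t.test(sc[a_ids, ex], sc[b_ids, ex], var.equal = TRUE)
    expect_equal(de$table$t_stat[i], unname(tt$statistic))
  }
  expect_error(differential_exemplars(sc, a_ids[1:2], b_ids), "at least 3")

  # zero-variance exemplar skipped with a message
  sc0 <- sc
  sc0[, "X5"] <- 1
  expect_message(de0 <- differential_exemplars(sc0, a_ids, b_ids), "X5")
  expect_false("X5" %in% de0$table$exemplar_id)
})

test_that("cluster survival comparisons honor the 5-sample rule", {
  set.seed(13)
  n <- 200
  ids <- paste0("p", 1:n)
  cl <- stats::setNames(rep(c("c1", "c2"), each = 100), ids)
  clustering <- structure(
    list(sample_ids = ids, cluster = cl, min_cluster_size = 20),
    class = "spatial_clustering")
  disease <- stats::setNames(
    c(rep("DZ", 196), rep("RARE", 4)), ids)  # RARE: only 4 in c2
  gr <- data.frame(sample_id = ids,
                   group = ifelse(cl == "c2", "up", "down"))
  sv <- simulate_survival(gr, hr = 3, censor_frac = 0.2, seed = 13)
  res <- cluster_survival_comparisons(clustering, disease, sv,
                                      per_subtype = FALSE)
  expect_equal(unique(res$cohort), "DZ")    # RARE never compared
  expect_equal(nrow(res), 1)
  expect_lt(res$p, 0.05)                    # planted difference detected
  expect_gt(res$hazard_ratio, 1)
})

test_that("null cluster comparisons stay null", {
  set.seed(14)
  ids <- paste0("p", 1:200)
  cl <- stats::setNames(rep(c("c1", "c2"), each = 100), ids)
  clustering <- structure(
    list(sample_ids = ids, cluster = cl, min_cluster_size = 20),
    class = "spatial_clustering")
  disease <- stats::setNames(rep("DZ", 200), ids)
  gr <- data.frame(sample_id = ids, group = "down")
  sv <- simulate_survival(gr, hr = 1, censor_frac = 0.2, seed = 14)
  res <- cluster_survival_comparisons(clustering, disease, sv,
                                      per_subtype = FALSE)
  expect_equal(nrow(res), 1)
  expect_lt(abs(log(res$hazard_ratio)), 0.5)
})
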
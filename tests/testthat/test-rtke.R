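test_that("top-k gene selection is deterministic with lexicographic ties", {
  r <- c(g1 = 1, g2 = 5, g3 = 2, g4 = 3, g5 = 4, g6 = 6, g7 = 10,
         g8 = 7, g9 = 8, g0 = 9)
  ct <- make_centroid(r)
  expect_equal(top_k_genes(ct, 0.1), "g7")
  expect_setequal(top_k_genes(ct, 1.0), names(r))
  # boundary tie: two genes share the k-th largest value
  rt <- c(g1 = 10, g2 = 5, g9 = 5, g4 = 1, g5 = 1, g6 = 1, g7 = 1,
          g8 = 1, g3 = 1, g0 = 1)
  expect_equal(sort(top_k_genes(make_centroid(rt), 0.2)), c("g1", "g2"))
  expect_error(top_k_genes(make_centroid(numeric(0))), "empty")
})

test_that("rtke_score matches the closed-form worked example", {
  # G=10, |T_a|=|T_b|=2, overlap 1: P(X>=1) = 1 - C(8,2)/C(10,2) = 17/45
  a <- centroid_with_top(10, c("g001", "g002"), uid = "a")
  b <- centroid_with_top(10, c("g002", "g010"), uid = "b")
  expect_equal(rtke_score(a, b, 0.2), -log10(17 / 45), tolerance = 1e-12)
  # disjoint top sets: P = 1, score 0
  d <- centroid_with_top(10, c("g007", "g008"), uid = "d")
  expect_equal(rtke_score(a, d, 0.2), 0)
  # symmetry
  expect_equal(rtke_score(a, b, 0.2), rtke_score(b, a, 0.2))
})

test_that("rtke_score agrees with exhaustive enumeration for small G", {
  for (G in c(10, 12)) {
    for (ka in c(2, 3)) {
      genes <- sprintf("g%03d", seq_len(G))
      for (m in 0:ka) {
        top_a <- genes[seq_len(ka)]
        top_b <- c(genes[seq_len(m)],
                   if (ka - m > 0) genes[(ka + 1):(2 * ka - m)])
        a <- centroid_with_top(G, top_a, uid = "a")
        b <- centroid_with_top(G, top_b, uid = "b")
        got <- rtke_score(a, b, ka / G)
        want <- -log10(hyper_tail_enum(G, ka, ka, m))
        expect_equal(got, want, tolerance = 1e-9,
                     label = sprintf("G=%d ka=%d m=%d", G, ka, m))
      }
    }
  }
})

test_that("score increases strictly with overlap and peaks at identity", {
  G <- 100
  k <- 10
  genes <- sprintf("g%03d", seq_len(G))
  scores <- vapply(0:k, function(m) {
    a <- centroid_with_top(G, genes[1:k], uid = "a")
    top_b <- c(genes[seq_len(m)], genes[(k + 1):(2 * k - m)])
    if (m == k) top_b <- genes[1:k]
    rtke_score(a, centroid_with_top(G, top_b, uid = "b"), k / G)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  # identity equals the closed-form point-mass tail
  expect_equal(scores[k + 1],
               -stats::phyper(k - 1, k, G - k, k, lower.tail = FALSE,
                              log.p = TRUE) / log(10))
})

test_that("random centroid pairs rarely look enriched", {
  G <- 1000
  k <- 100
  set.seed(5)
  scores <- replicate(200, {
    a <- make_centroid(sample(G), uid = "a")
    b <- make_centroid(sample(G), uid = "b")
    rtke_score(a, b, k / G)
  })
  at_2x <- -stats::phyper(2 * k^2 / G - 1, k, G - k, k, lower.tail = FALSE,
                          log.p = TRUE) / log(10)
  expect_lt(stats::quantile(scores, 0.99), at_2x)
})

test_that("pairwise matrix equals looped scores and permutes consistently", {
  set.seed(6)
  cents <- lapply(1:4, function(i) {
    make_centroid(sample(60), uid = paste0("ds", i, ".0"),
                  dataset_id = paste0("ds", i))
  })
  sm <- pairwise_rtke(cents, fraction = 0.2)
  shared <- restrict_to_shared_genes(cents)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(sm$scores[i, j],
                 rtke_score(shared[[i]], shared[[j]], 0.2))
  }
  perm <- c(3, 1, 4, 2)
  sm2 <- pairwise_rtke(cents[perm], fraction = 0.2)
  expect_equal(sm2$scores, sm$scores[perm, perm])
  expect_true(isSymmetric(sm$scores))
  expect_error(pairwise_rtke(cents[1]), "at least 2")
})

test_that("identical and disjoint centroids bound the similarity matrix", {
  g1 <- centroid_with_top(40, sprintf("g%03d", 1:4), uid = "a.0")
  g2 <- centroid_with_top(40, sprintf("g%03d", 1:4), uid = "b.0")
  g3 <- centroid_with_top(40, sprintf("g%03d", 21:24), uid = "c.0")
  sm <- pairwise_rtke(list(g1, g2, g3), fraction = 0.1)
  expect_equal(sm$scores["a.0", "b.0"], sm$scores["a.0", "a.0"])
  expect_equal(sm$scores["a.0", "c.0"], 0)
  expect_equal(sm$scores["b.0", "c.0"], 0)
})

test_that("empirical threshold is the documented interpolated quantile", {
  # fabricate a similarity matrix whose upper triangle is 0..999
  n <- 46   # C(46,2) = 1035 >= 1000; use first 1000 slots then pad
  s <- matrix(0, n, n)
  vals <- c(0:999, rep(999, 35))
  s[upper.tri(s)] <- vals
  s <- s + t(s)
  sm <- structure(list(cluster_uids = paste0("u", 1:n), scores = s,
                       top_k_fraction = 0.1, gene_universe_size = 100),
                  class = "similarity_matrix")
  got <- empirical_threshold(sm, 0.994)
  want <- unname(stats::quantile(vals, 0.994, type = 7))
  expect_equal(got, want)

  # on exactly 0..999 the type-7 value is the interpolated 993.006
  expect_equal(unname(stats::quantile(0:999, 0.994, type = 7)), 993.006)

  # quantile 1 keeps nothing above the max
  expect_equal(empirical_threshold(sm, 1), max(vals))

  s2 <- matrix(5, 4, 4); diag(s2) <- 50
  sm2 <- structure(list(cluster_uids = paste0("u", 1:4), scores = s2,
                        top_k_fraction = 0.1, gene_universe_size = 100),
                   class = "similarity_matrix")
  expect_warning(thr <- empirical_threshold(sm2, 0.994), "degenerate")
  expect_equal(thr, 5)
})

test_that("the rank-sum variant is symmetric and bounded", {
  set.seed(7)
  a <- make_centroid(sample(50), uid = "a")
  b <- make_centroid(sample(50), uid = "b")
  s <- rtke_score(a, b, 0.2, variant = "rank_sum")
  expect_equal(s, rtke_score(b, a, 0.2, variant = "rank_sum"))
  expect_gte(s, 0)
  expect_lte(s, 1)
  expect_gt(rtke_score(a, a, 0.2, variant = "rank_sum"), s)
})
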
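# Weighted-KS enrichment, over-representation, upstream activation z.

mk_ranked <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(gene = sprintf("G%04d", 1:n),
             score = sort(rnorm(n), decreasing = TRUE),
             stringsAsFactors = FALSE)
}

test_that("ES analytic cases: top block scores exactly 1, full list scores 1", {
  rk <- mk_ranked(100)
  for (p in c(0, 1, 2)) {
    top <- es_running_sum(rk, rk$gene[1:10], weight_p = p)
    expect_identical(top$es, 1)
    expect_identical(top$n_hits, 10L)
  }
  whole <- es_running_sum(rk, rk$gene)
  expect_identical(whole$es, 1)
  expect_error(es_running_sum(rk, c("NOPE1", "NOPE2")), "no gene-set member")
})

test_that("ES matches a direct O(N) running-sum re-implementation", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(20:120, 1)
    rk <- mk_ranked(n, seed = i)
    k <- sample(3:min(15, n - 1), 1)
    gs <- sample(rk$gene, k)
    p <- sample(c(0, 1, 2), 1)
    es <- es_running_sum(rk, gs, weight_p = p)$es
    expect_equal(es, brute_force_es(rk$gene, rk$score, gs, p),
                 tolerance = 1e-12)
  }
  # bottom-block case explicitly
  rk <- mk_ranked(50)
  bottom <- es_running_sum(rk, rk$gene[46:50])
  expect_equal(bottom$es,
               brute_force_es(rk$gene, rk$score, rk$gene[46:50], 1),
               tolerance = 1e-12)
  expect_lt(bottom$es, 0)
})

test_that("internal position-based ES equals the full running-sum ES", {
  set.seed(8)
  for (i in 1:25) {
    rk <- mk_ranked(80, seed = 50 + i)
    k <- sample(3:20, 1)
    pos <- sort(sample(80, k))
    gs <- rk$gene[pos]
    a <- abs(rk$score)
    expect_equal(coexsurv:::.es_from_positions(pos, a, 80L),
                 brute_force_es(rk$gene, rk$score, gs, 1),
                 tolerance = 1e-12)
  }
})

test_that("ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  rk <- mk_ranked(200, seed = 3)
  stats <- setNames(rk$score, rk$gene)
  for (i in 1:5) {
    set.seed(i)
    gs <- sample(rk$gene, 12)
    es_pkg <- es_running_sum(rk, gs)$es
    es_ref <- fgsea::calcGseaStat(stats,
                                  selectedStats = which(rk$gene %in% gs),
                                  gseaParam = 1)
    expect_equal(es_pkg, es_ref, tolerance = 1e-9)
  }
})

test_that("ES is invariant to positive score rescaling; reversal negates the classic ES", {
  rk <- mk_ranked(60, seed = 4)
  gs <- sample(rk$gene, 8)
  es1 <- es_running_sum(rk, gs)$es
  rk2 <- rk; rk2$score <- rk2$score * 7.3
  expect_equal(es_running_sum(rk2, gs)$es, es1, tolerance = 1e-12)
  # reversal with p = 0 (rank-only statistic): a top-concentrated set's
  # positive ES becomes the mirror-image negative ES
  gs_top <- rk$gene[3:10]
  rk_rev <- rk[rev(seq_len(nrow(rk))), ]
  es_fwd <- es_running_sum(rk, gs_top, weight_p = 0)$es
  expect_gt(es_fwd, 0)
  expect_equal(es_running_sum(rk_rev, gs_top, weight_p = 0)$es, -es_fwd,
               tolerance = 1e-12)
})

test_that("preranked_gsea is deterministic under a seed and flags planted sets", {
  rk <- mk_ranked(300, seed = 5)
  coll <- list(TOP = rk$gene[1:15], RAND = sample(rk$gene, 15))
  r1 <- preranked_gsea(rk, coll, n_perm = 200, rng_seed = 99)
  r2 <- preranked_gsea(rk, coll, n_perm = 200, rng_seed = 99)
  expect_identical(r1, r2)
  top <- r1[r1$set == "TOP", ]
  expect_identical(top$es, 1)
  expect_lte(top$p_perm, 2 / 201)
  expect_true(all(r1$fdr >= r1$p_perm))
  # absent and oversized sets are skipped with warnings
  expect_warning(
    preranked_gsea(rk, list(NONE = c("X1", "X2"), OK = rk$gene[1:5]),
                   n_perm = 100, rng_seed = 1), "no member")
  expect_warning(
    preranked_gsea(rk, list(BIG = c(rk$gene, "EXTRA", "MORE"),
                            OK = rk$gene[1:5]),
                   n_perm = 100, rng_seed = 1), "larger than")
})

test_that("hypergeometric ORA matches exhaustive enumeration on a small universe", {
  universe <- sprintf("U%02d", 1:12)
  gset <- universe[1:5]
  query <- universe[c(1:3, 9:10)]          # overlap k = 3, n = 5, K = 5
  res <- overrepresentation(query, list(S = gset), universe)
  # exact tail by enumerating all choose(12, 5) draws of the query size
  draws <- combn(12, 5)
  k_obs <- 3
  tail_p <- mean(apply(draws, 2, function(d) sum(d <= 5) >= k_obs))
  expect_equal(res$p, tail_p, tolerance = 1e-12)
  expect_equal(res$neg_log10_p, -log10(res$p))

  # full overlap in a tiny universe
  res2 <- overrepresentation(universe[1:4], list(S = universe[1:4]),
                             universe[1:8])
  expect_equal(res2$p, 1 / choose(8, 4), tolerance = 1e-12)

  # zero overlap with a large set: no enrichment
  res3 <- overrepresentation(universe[9:12], list(S = universe[1:8]),
                             universe)
  expect_equal(res3$p, 1, tolerance = 1e-12)

  expect_error(suppressMessages(
    overrepresentation(c("Z1", "Z2"), list(S = gset), universe)),
    "no query gene")
})

test_that("BH adjustment in ORA is monotone and order-preserving", {
  universe <- sprintf("U%03d", 1:60)
  coll <- list(A = universe[1:10], B = universe[5:30], C = universe[40:55])
  res <- overrepresentation(universe[1:12], coll, universe)
  expect_true(all(res$p_bh >= res$p))
  expect_identical(order(res$p), order(res$p_bh))
})

test_that("upstream activation z follows the closed form and its thresholds", {
  net <- data.frame(regulator = "TF1", target = sprintf("T%02d", 1:10),
                    sign = 1)
  obs_all <- data.frame(gene = sprintf("T%02d", 1:10), direction = 1)
  r <- upstream_activation_z(net, obs_all)
  expect_equal(r$z_activation, 10 / sqrt(10), tolerance = 1e-12)
  expect_identical(r$state, "activated")

  obs_split <- obs_all; obs_split$direction <- rep(c(1, -1), 5)
  r2 <- upstream_activation_z(net, obs_split)
  expect_equal(r2$z_activation, 0)
  expect_identical(r2$state, "not-significant")

  obs_28 <- obs_all; obs_28$direction <- c(1, 1, rep(-1, 8))
  r3 <- upstream_activation_z(net, obs_28)
  expect_equal(r3$z_activation, -6 / sqrt(10), tolerance = 1e-12)
  expect_identical(r3$state, "not-significant")

  # low-evidence flag below 3 observed targets
  net2 <- data.frame(regulator = "TF2", target = c("A", "B"), sign = c(1, -1))
  r4 <- upstream_activation_z(net2, data.frame(gene = c("A", "B"),
                                               direction = c(1, -1)))
  expect_true(r4$low_evidence)
})

test_that("negating all observed directions negates every activation z", {
  set.seed(12)
  net <- data.frame(regulator = rep(sprintf("TF%d", 1:4), each = 8),
                    target = sprintf("T%02d", sample(40, 32)),
                    sign = sample(c(-1, 1), 32, replace = TRUE))
  obs <- data.frame(gene = unique(net$target),
                    direction = sample(c(-1, 1), length(unique(net$target)),
                                       replace = TRUE))
  r_pos <- upstream_activation_z(net, obs)
  obs_neg <- obs; obs_neg$direction <- -obs_neg$direction
  r_neg <- upstream_activation_z(net, obs_neg)
  m <- match(r_pos$regulator, r_neg$regulator)
  expect_equal(r_pos$z_activation, -r_neg$z_activation[m], tolerance = 1e-12)
})
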
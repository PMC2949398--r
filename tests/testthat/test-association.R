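test_that("randomization_p implements (T+1)/(R+1) for both tails", {
  # T = 0, R = 5000 -> p = 1/5001, the minimum attainable bound
  res <- randomization_p(10, rep(0, 5000), tail = "ge")
  expect_equal(res$T, 0)
  expect_equal(res$p, 1 / 5001)
  # T = R -> p = 1
  expect_equal(randomization_p(0, rep(5, 100), tail = "ge")$p, 1)
  # T = 49, R = 5000 -> p = 50/5001
  nulls <- c(rep(11, 49), rep(1, 4951))
  expect_equal(randomization_p(10, nulls, tail = "ge")$p, 50 / 5001)
  # le tail counts the other side
  expect_equal(randomization_p(10, nulls, tail = "le")$T, 4951)
  expect_error(randomization_p(1, numeric(0)), "empty null")
})

test_that("randomization p is bounded and super-uniform under the null", {
  set.seed(10)
  R <- 99
  ps <- replicate(1000, randomization_p(rnorm(1), rnorm(R), "ge")$p)
  expect_true(all(ps >= 1 / (R + 1) & ps <= 1))
  # super-uniformity at deciles: P(p <= q) <= q within 3 SE
  for (q in seq(0.1, 0.9, 0.1)) {
    expect_lte(mean(ps <= q), q + 3 * sqrt(q * (1 - q) / 1000))
  }
})

test_that("ad_statistic is the symmetric absolute difference", {
  expect_equal(ad_statistic(0.9, 0.075), 0.825)
  expect_equal(ad_statistic(0.3, 0.3), 0)
  x <- runif(10); y <- runif(10)
  expect_equal(ad_statistic(x, y), ad_statistic(y, x))
  expect_error(ad_statistic(-0.1, 0.5))
})

test_that("rank_sum_test: exact small-sample and approximate agree", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(rank_sum_test(c(5, 6, 7), c(5, 6, 7)), 1)
  # degenerate all-tied large samples
  expect_equal(rank_sum_test(rep(1, 10), rep(1, 10)), 1)
  # exact vs normal approximation near the switch point
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6, 1)
    exact <- rank_sum_test(a, b)
    ref <- stats::wilcox.test(a, b)$p.value
    expect_lt(abs(exact - ref), 0.02)
  }
  expect_error(rank_sum_test(numeric(0), 1), "empty")
})

test_that("ad_comparison separates planted co and anti structure", {
  # co pairs share identical frequencies; anti pairs divergent;
  # background nodes spread out
  genes <- c("c1", "c2", "a1", "a2", sprintf("r%d", 1:20))
  net <- cca_network(genes,
                     data.frame(from = c("c1", "a1"), to = c("c2", "a2"),
                                relation = c("co", "anti")))
  set.seed(30)
  freqs <- c(c1 = 0.2, c2 = 0.2, a1 = 0.9, a2 = 0.05,
             stats::setNames(runif(20, 0.05, 0.6), sprintf("r%d", 1:20)))
  res <- ad_comparison(net, freqs, R = 499, seed = 3)
  expect_equal(res$ad_co, 0)
  expect_equal(res$ad_anti, 0.85)
  expect_lt(res$co_vs_random$observed,
            stats::median(res$co_vs_random$null_sample))
  expect_gt(res$anti_vs_random$observed,
            stats::median(res$anti_vs_random$null_sample))
  expect_lt(res$co_vs_random$p, 0.1)
  expect_lt(res$anti_vs_random$p, 0.1)

  # all frequencies equal: degenerate ties, rank-sum p = 1
  f0 <- stats::setNames(rep(0.1, length(genes)), genes)
  res0 <- ad_comparison(net, f0, R = 49, seed = 1)
  expect_equal(res0$co_vs_anti_p, 1)

  # identical co and anti AD samples -> p = 1
  netsym <- cca_network(c("x1", "x2", "y1", "y2"),
                        data.frame(from = c("x1", "y1"),
                                   to = c("x2", "y2"),
                                   relation = c("co", "anti")))
  fsym <- c(x1 = 0.1, x2 = 0.3, y1 = 0.5, y2 = 0.7)
  expect_equal(ad_comparison(netsym, fsym, R = 49,
                             seed = 1)$co_vs_anti_p, 1)

  # missing anti edges skip that branch with a message
  noanti <- cca_network(c("x1", "x2"),
                        data.frame(from = "x1", to = "x2",
                                   relation = "co"))
  expect_message(resna <- ad_comparison(noanti, fsym[1:2], R = 49, seed = 1),
                 "skipped")
  expect_null(resna$anti_vs_random)
})

test_that("expression similarity is absolute Pearson with guards", {
  em <- expression_matrix(rbind(gA = c(1, 2, 3, 4),
                                gB = c(2, 4, 6, 8),
                                gC = c(4, 3, 2, 1),
                                gD = c(1, 2, 1, 2),
                                gE = c(1, 1, 2, 2),
                                gF = c(5, 5, 5, 5)))
  expect_equal(expression_similarity(em, "gA", "gB"), 1)
  expect_equal(expression_similarity(em, "gA", "gC"), 1)  # anti-correlated
  expect_equal(expression_similarity(em, "gD", "gE"), 0)  # zero covariance
  expect_true(is.na(expression_similarity(em, "gA", "gF")))
  expect_error(expression_similarity(em, "gA", "nope"), "not in expression")
})

test_that("spearman matches a rank-then-Pearson oracle", {
  set.seed(5)
  for (i in 1:20) {
    x <- sample(20, 15, replace = TRUE)  # force ties
    y <- rnorm(15)
    got <- spearman_cor(x, y)
    expect_equal(got$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
    ref <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("distance-similarity analysis: monotone, null and decaying cases", {
  p4 <- net_path(4)
  # phase-shifted cosine profiles: |cor| = |cos(phase gap)|, strictly
  # decreasing in path distance -> grouped rho = -1
  tt <- 1:200
  em <- expression_matrix(rbind(a = cos(tt), b = cos(tt + 0.4),
                                c = cos(tt + 0.8), d = cos(tt + 1.2)))
  res <- distance_similarity_analysis(p4, em)
  expect_equal(res$grouped$rho, -1)
  expect_lt(res$pairwise$rho, 0)

  # similarity independent of distance: |rho| < 3/sqrt(n)
  g <- net_random(25, 0.15, seed = 6)
  set.seed(61)
  em2 <- expression_matrix(matrix(rnorm(25 * 30), 25,
                                  dimnames = list(g$nodes$gene, NULL)))
  res2 <- distance_similarity_analysis(g, em2)
  expect_lt(abs(res2$pairwise$rho), 3 / sqrt(res2$pairwise$n_pairs))

  # decay generator plants negative pairwise correlation
  p8 <- net_path(8)
  em3 <- simulate_expression(p8, decay_alpha = 0.6, n_tissues = 79,
                             noise_sd = 0.3, seed = 11)
  res3 <- distance_similarity_analysis(p8, em3)
  expect_lt(res3$pairwise$rho, 0)
})

test_that("attribute correlations hit +-1 on constructed attributes", {
  g <- net_random(20, 0.25, seed = 8)
  g$nodes$degree <- unname(node_degrees(g))
  g$nodes$cc <- vapply(g$nodes$gene, function(n)
    clustering_coefficient(g, n), numeric(1))
  # exon_count == degree -> rho 1; length == -degree -> rho -1
  g$nodes$exon_count <- g$nodes$degree
  g$nodes$length_bp <- -g$nodes$degree
  set.seed(9)
  g$nodes$raw_freq <- runif(20)
  tab <- attribute_correlations(g)
  expect_equal(tab$rho[tab$var_a == "degree" & tab$var_b == "exon_count"], 1)
  expect_equal(tab$rho[tab$var_a == "degree" & tab$var_b == "length_bp"], -1)
  # independent attribute: small rho
  rho_f <- tab$rho[tab$var_a == "degree" & tab$var_b == "raw_freq"]
  expect_lt(abs(rho_f), 3 / sqrt(20))
})

test_that("location gradient orders classes and flags monotone medians", {
  g <- net_random(16, 0.3, seed = 12)
  k <- unname(node_degrees(g))
  g$nodes$degree <- k
  g$nodes$cc <- vapply(g$nodes$gene, function(n)
    clustering_coefficient(g, n), numeric(1))
  # plant the gradient: higher-degree nodes to downstream compartments
  ord <- order(k)
  locs <- rep(c("extracellular", "membrane", "cytoplasm", "nucleus"),
              each = 4)
  g$nodes$location <- NA_character_
  g$nodes$location[ord] <- locs
  out <- location_gradient(g)
  expect_equal(out$location,
               c("extracellular", "membrane", "cytoplasm", "nucleus"))
  expect_true(attr(out, "monotone_degree"))

  # unknown locations excluded
  g$nodes$location[1] <- "unknown"
  expect_equal(sum(location_gradient(g)$n), 15)

  one <- g; one$nodes$location <- "nucleus"
  out1 <- location_gradient(one)
  expect_equal(out1$n, c(0L, 0L, 0L, 16L))
})
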
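test_that("same_pathway_pair_count counts each co edge once", {
  net <- cca_network(c("a", "b", "c", "d"),
                     data.frame(from = c("a", "c"), to = c("b", "d"),
                                relation = c("co", "co")))
  pw <- structure(list(p1 = c("a", "b", "c"), p2 = c("a", "b", "x")),
                  class = "pathway_collection")
  # edge (a,b) shares two pathways but counts once; (c,d) shares none
  expect_equal(same_pathway_pair_count(net, pw), 1L)

  anti <- cca_network(c("a", "b"),
                      data.frame(from = "a", to = "b", relation = "anti"))
  expect_equal(same_pathway_pair_count(anti, pw), 0L)
})

test_that("rewire_random conserves nodes and link count, never loops", {
  g <- net_random(15, 0.2, seed = 1)
  set.seed(99)
  for (i in 1:200) {
    rw <- rewire_random(g)
    expect_identical(rw$nodes$gene, g$nodes$gene)
    expect_equal(n_edges(rw), n_edges(g))
    expect_true(all(rw$edges$from != rw$edges$to))
    key <- paste(rw$edges$from, rw$edges$to)
    expect_equal(anyDuplicated(key), 0)
  }
  # complete graph can only rewire to itself
  comp <- net_random(5, 1.01, seed = 1)
  set.seed(1)
  rw <- rewire_random(comp)
  expect_equal(rw$edges[c("from", "to")], comp$edges[c("from", "to")])
})

test_that("degree-preserving rewiring keeps the degree sequence", {
  g <- net_random(20, 0.2, seed = 3)
  set.seed(4)
  rw <- rewire_degree_preserving(g)
  expect_equal(sort(unname(node_degrees(rw))),
               sort(unname(node_degrees(g))))
})

test_that("pathway co-membership randomization test behaves at extremes", {
  net <- net_random(12, 0.25, seed = 2)
  # pathways covering nothing: observed 0, p = 1
  pw0 <- structure(list(p1 = c("zz1", "zz2")), class = "pathway_collection")
  res0 <- pathway_comembership_test(net, pw0, R = 99, seed = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p, 1)

  # every node in one pathway: every possible rewiring ties observed,
  # p = 1 (null always >= observed)
  pw_all <- structure(list(p = net$nodes$gene), class = "pathway_collection")
  res_all <- pathway_comembership_test(net, pw_all, R = 99, seed = 1)
  expect_equal(res_all$p, 1)

  # planted: edges dense inside a small pathway on a large node set
  genes <- sprintf("n%02d", 1:40)
  inpw <- genes[1:6]
  edges <- t(utils::combn(inpw, 2))
  planted <- cca_network(genes,
                         data.frame(from = edges[, 1], to = edges[, 2],
                                    relation = "co"))
  pw <- structure(list(p1 = inpw), class = "pathway_collection")
  res <- pathway_comembership_test(planted, pw, R = 499, seed = 7)
  expect_equal(res$observed, 15)
  expect_equal(res$p, 1 / 500)  # minimum attainable

  # reproducibility with the same seed
  res2 <- pathway_comembership_test(planted, pw, R = 499, seed = 7)
  expect_identical(res$null_sample, res2$null_sample)
})

test_that("direct interaction enrichment builds the right 2x2 universe", {
  net <- cca_network(c("a", "b", "c", "d"),
                     data.frame(from = c("a", "c"), to = c("b", "d"),
                                relation = "co"))
  # all co pairs linked, nothing else linked -> extreme table
  sn <- signaling_network(data.frame(source = c("a", "c"),
                                     target = c("b", "d"),
                                     type = "activation"))
  res <- direct_interaction_enrichment(net, sn)
  expect_equal(res$table["co_edge", "linked"], 2)
  expect_equal(res$table["not_co_edge", "linked"], 0)
  expect_equal(res$frac_linked_co, 1)
  expect_gt(res$odds_ratio, 1)
  expect_equal(sum(res$table), choose(4, 2))

  # direction ignored: reversed link still counts
  sn_rev <- signaling_network(data.frame(source = "b", target = "a",
                                         type = "repression"))
  res2 <- direct_interaction_enrichment(net, sn_rev)
  expect_equal(res2$table["co_edge", "linked"], 1)

  sn_far <- signaling_network(data.frame(source = "x", target = "y",
                                         type = "physical"))
  expect_error(direct_interaction_enrichment(net, sn_far), "fewer than 2")
})

test_that("signal usage counts typed links once per (pair, type)", {
  net <- cca_network(c("a", "b", "c", "d", "e", "f"),
                     data.frame(from = c("a", "c", "e"),
                                to = c("b", "d", "f"), relation = "co"))
  # e-f has two physical links (one per direction): the pair still
  # contributes that type once
  sn <- signaling_network(data.frame(
    source = c("a", "c", "e", "f", "x"),
    target = c("b", "d", "f", "e", "y"),
    type = c("activation", "activation", "physical", "physical",
             "repression")))
  usage <- signal_type_usage(net, sn)
  expect_equal(unname(usage$counts), c(2L, 0L, 1L))
  expect_equal(unname(usage$fractions), c(2 / 3, 0, 1 / 3))
  expect_equal(usage$n_links, 3)

  # no linked pairs -> empty usage
  lone <- cca_network(c("p", "q"),
                      data.frame(from = "p", to = "q", relation = "co"))
  u0 <- signal_type_usage(lone, sn)
  expect_equal(u0$n_links, 0)
  expect_error(signal_usage_tests(u0, sn), "no typed links")
})

test_that("signal usage tests: chi-square and randomization", {
  # observed exactly at expected proportions -> statistic 0, p = 1
  mkusage <- function(counts, expected) {
    structure(list(counts = counts, fractions = counts / sum(counts),
                   expected_fractions = expected, n_links = sum(counts)),
              class = "signal_usage")
  }
  sn <- signaling_network(data.frame(
    source = "x", target = sprintf("y%d", 1:100),
    type = rep(c("activation", "repression", "physical"), c(50, 25, 25))))
  u_eq <- mkusage(c(activation = 8L, repression = 4L, physical = 4L),
                  c(activation = 0.5, repression = 0.25, physical = 0.25))
  res <- signal_usage_tests(u_eq, sn, R = 49, seed = 1)
  expect_equal(res$chisq_stat, 0)
  expect_equal(res$chisq_p, 1)
  expect_equal(res$chisq_df, 2)

  # hand-computed 2-category case: stat 10, df 1, p ~ 0.00157
  u2 <- mkusage(c(activation = 10L, repression = 0L, physical = 0L),
                c(activation = 0.5, repression = 0.5, physical = 0))
  res2 <- signal_usage_tests(u2, sn, R = 49, seed = 1)
  expect_equal(res2$chisq_stat, 10)
  expect_equal(res2$chisq_df, 1)
  expect_equal(res2$chisq_p, 0.001565402, tolerance = 1e-6)

  # all-activation usage against a balanced network: both tails minimal
  sn_bal <- signaling_network(data.frame(
    source = "x", target = sprintf("y%d", 1:300),
    type = rep(c("activation", "repression", "physical"), each = 100)))
  u_act <- mkusage(c(activation = 30L, repression = 0L, physical = 0L),
                   signaling_type_fractions(sn_bal))
  res3 <- signal_usage_tests(u_act, sn_bal, R = 999, seed = 5)
  expect_equal(res3$p_activation$p, 1 / 1000)
  expect_equal(res3$p_repression$p, 1 / 1000)
  expect_true(all(c("n_activation", "n_repression", "count") %in%
                    names(res3$null_grid)))
  expect_equal(sum(res3$null_grid$count), 999)

  # expected 0 with observed > 0 is an error
  u_bad <- mkusage(c(activation = 1L, repression = 1L, physical = 0L),
                   c(activation = 1, repression = 0, physical = 0))
  expect_error(signal_usage_tests(u_bad, sn), "zero expected")
})
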
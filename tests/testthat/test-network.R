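# Within-school network construction and the structural indicators, checked
# against igraph and against plain-loop brute-force oracles.

test_that("networks keep all registered students as nodes", {
  net <- toy_network(letters[1:5], toy_edges(c("a", "b"), c("b", "a")))
  expect_equal(net$n, 5)
  expect_equal(nrow(net$edges), 2)

  empty <- toy_network(letters[1:4],
                       toy_edges(c("a", "b"))[0, ])
  expect_equal(empty$n, 4)
  expect_equal(nrow(empty$edges), 0)

  expect_error(build_network(toy_roster(letters[1:3]), toy_edges(c("a", "b")),
                             "NOPE"), "not in roster")
})

test_that("cross-school nominations never become edges", {
  roster <- rbind(toy_roster(c("a", "b"), "S1"), toy_roster(c("x", "y"), "S2"))
  noms <- toy_edges(c("a", "b"), c("a", "x"))
  net <- build_network(roster, noms, "S1")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$alter_id, "b")
})

test_that("ego positions: degrees on the full node set and the isolation flag", {
  net <- toy_network(letters[1:5],
                     toy_edges(c("a", "b"), c("a", "c"), c("a", "d")))
  pos <- ego_positions(net)
  expect_equal(pos$out_degree[pos$student_id == "a"], 3)
  expect_equal(pos$in_degree[pos$student_id == "a"], 0)
  expect_equal(pos$out_degree[pos$student_id == "b"], 0)
  expect_equal(pos$in_degree[pos$student_id == "b"], 1)
  expect_false(pos$isolated[pos$student_id == "a"])   # has outgoing ties
  expect_true(pos$isolated[pos$student_id == "e"])    # none either way

  # 50 participants with exactly one isolate -> 2%
  ids <- sprintf("s%02d", 1:50)
  ring <- toy_edges()
  ring <- data.frame(ego_id = ids[1:49], alter_id = ids[c(2:49, 1)],
                     rank = 1L, stringsAsFactors = FALSE)
  net50 <- toy_network(ids, ring)
  expect_equal(pct_isolated(ego_positions(net50), ids), 2)
})

test_that("density matches its definition and closed form", {
  complete4 <- do.call(toy_edges, unlist(lapply(letters[1:4], function(x) {
    lapply(setdiff(letters[1:4], x), function(y) c(x, y))
  }), recursive = FALSE))
  expect_equal(net_density(toy_network(letters[1:4], complete4)), 100)

  e6 <- toy_edges(c("a", "b"), c("a", "c"), c("b", "c"), c("c", "a"),
                  c("d", "e"), c("e", "a"))
  expect_equal(net_density(toy_network(letters[1:5], e6)), 30)  # 6/20

  expect_error(net_density(toy_network("a", e6[0, ])), "fewer than 2")
})

test_that("centralization: verbal anchors and the worked value", {
  star_in <- toy_edges(c("b", "a"), c("c", "a"), c("d", "a"), c("e", "a"))
  expect_equal(net_centralization(toy_network(letters[1:5], star_in)), 100)

  cycle <- data.frame(ego_id = letters[1:5], alter_id = letters[c(2:5, 1)],
                      rank = 1L, stringsAsFactors = FALSE)
  expect_equal(net_centralization(toy_network(letters[1:5], cycle)), 0)

  # in-degrees (2,1,1,0): 100 * 4 / 9
  e <- toy_edges(c("b", "a"), c("c", "a"), c("a", "b"), c("a", "c"))
  e$alter_id <- c("a", "a", "b", "c")
  expect_equal(net_centralization(toy_network(letters[1:4], e)), 400 / 9)

  expect_error(net_centralization(toy_network(c("a", "b"), e[0, ])),
               "fewer than 3")
})

test_that("out- and total-degree centralization variants hit their anchors", {
  ids <- letters[1:5]
  star_out <- toy_edges(c("a", "b"), c("a", "c"), c("a", "d"), c("a", "e"))
  expect_equal(net_centralization(toy_network(ids, star_out), "out"), 100)
  mutual_star <- rbind(star_out,
                       data.frame(ego_id = c("b", "c", "d", "e"),
                                  alter_id = "a", rank = 1L))
  expect_equal(net_centralization(toy_network(ids, mutual_star), "total"), 100)
  cycle <- data.frame(ego_id = ids, alter_id = ids[c(2:5, 1)], rank = 1L)
  expect_equal(net_centralization(toy_network(ids, cycle), "total"), 0)
})

test_that("ego clustering counts directed ties among out-neighbours", {
  e <- toy_edges(c("x", "a"), c("x", "b"), c("a", "b"), c("b", "a"))
  net <- toy_network(c("x", "a", "b", "c"), e)
  expect_equal(ego_clustering(net, "x"), 100)

  e2 <- toy_edges(c("x", "a"), c("x", "b"), c("x", "c"))
  expect_equal(ego_clustering(toy_network(c("x", "a", "b", "c"), e2), "x"), 0)

  expect_true(is.na(ego_clustering(net, "a")))   # single alter
  expect_error(ego_clustering(net, "zz"), "not in network")
})

test_that("average clustering is the mean over eligible egos", {
  e <- toy_edges(c("x", "a"), c("x", "b"), c("a", "b"), c("b", "a"),
                 c("y", "a"), c("y", "c"))
  net <- toy_network(c("x", "y", "a", "b", "c"), e)
  # x: 100 (a<->b); y: 0 (no a-c ties); a, b have 1 alter; c none
  expect_equal(avg_clustering(net), 50)
  edgeless <- toy_network(letters[1:3], e[0, ])
  expect_warning(val <- avg_clustering(edgeless), "no ego")
  expect_true(is.na(val))
})

test_that("metrics equal brute force and igraph on random graphs (n <= 15)", {
  set.seed(1234)
  for (rep in 1:40) {
    n <- sample(4:15, 1)
    ids <- sprintf("v%02d", seq_len(n))
    edges <- random_edges(ids)
    net <- toy_network(ids, edges)
    g <- as_igraph(net)

    expect_equal(net_density(net), bf_density(ids, net$edges))
    expect_equal(net_density(net), 100 * igraph::edge_density(g))
    expect_equal(net_centralization(net),
                 bf_centralization_in(ids, net$edges))
    expect_equal(net_centralization(net),
                 100 * igraph::centr_degree(g, mode = "in",
                                            loops = FALSE)$centralization)
    for (ego in sample(ids, 4)) {
      expect_equal(ego_clustering(net, ego),
                   bf_ego_clustering(ids, net$edges, ego))
    }
    expect_equal(suppressWarnings(avg_clustering(net)),
                 bf_avg_clustering(ids, net$edges))
  }
})

test_that("structural invariants: conservation, density identity, relabelling", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:14, 1)
    ids <- sprintf("v%02d", seq_len(n))
    net <- toy_network(ids, random_edges(ids))
    pos <- ego_positions(net)
    expect_equal(mean(pos$in_degree), mean(pos$out_degree))
    expect_equal(net_density(net), 100 * mean(pos$out_degree) / (n - 1))

    # relabelling the students leaves every school metric unchanged
    perm <- setNames(sprintf("w%02d", sample(n)), ids)
    edges2 <- net$edges
    edges2$ego_id <- unname(perm[edges2$ego_id])
    edges2$alter_id <- unname(perm[edges2$alter_id])
    edges2$rank <- 1L
    net2 <- toy_network(unname(perm), edges2)
    expect_equal(net_density(net2), net_density(net))
    expect_equal(net_centralization(net2), net_centralization(net))
    expect_equal(suppressWarnings(avg_clustering(net2)),
                 suppressWarnings(avg_clustering(net)))
  }
})

test_that("school summaries assemble the per-metric values", {
  cohort <- generate_cohort(tiny_config(seed = 12))
  scores <- score_scales(cohort$items, cohort$roster)
  summ <- summarize_schools(cohort$roster, cohort$nominations, scores)
  expect_equal(nrow(summ), 4)
  s1 <- summ$school_id[1]
  net <- build_network(cohort$roster, cohort$nominations, s1)
  expect_equal(summ$density_pct[1], net_density(net))
  expect_equal(summ$centralization_pct[1], net_centralization(net))
  expect_equal(summ$clustering_pct[1], avg_clustering(net))
  sc <- school_connectedness(scores, cohort$roster)
  expect_equal(summ$mean_connectedness,
               sc$mean_connectedness[match(summ$school_id, sc$school_id)])
  expect_true(all(summ$density_pct >= 0 & summ$density_pct <= 100))
  expect_true(all(summ$pct_isolated >= 0 & summ$pct_isolated <= 100))

  # degenerate school: no edges at all
  roster <- toy_roster(letters[1:6], "S0")
  empty <- data.frame(ego_id = character(), alter_id = character(),
                      rank = integer())
  row <- summarize_school(build_network(roster, empty, "S0"), roster)
  expect_equal(row$density_pct, 0)
  expect_true(is.na(row$clustering_pct))
})
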
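test_that("seed resolution partitions requested identifiers", {
  net <- net_from_weights(c("A", "B"), c("B", "C"), c(1, 1))
  s <- resolve_seeds(net, c("A", "C", "Z"))
  expect_setequal(s$mapped, c("A", "C"))
  expect_equal(s$missing, "Z")
  expect_setequal(union(s$mapped, s$missing), s$requested)
  expect_length(intersect(s$mapped, s$missing), 0)
  expect_error(resolve_seeds(net, c("Z1", "Z2")), "insufficient seeds")
  expect_error(resolve_seeds(net, character(0)), "no seed genes")
})

test_that("inner-node tallies are exact on hand-built fixtures in both modes", {
  chain <- net_from_weights(c("A", "B"), c("B", "C"), c(1, 1))
  for (mode in c("all_paths", "one_path")) {
    tal <- seed_pair_betweenness(chain, c("A", "C"), mode)
    expect_equal(tal[tal > 0], c(B = 1))
  }
  diamond <- net_from_weights(c("A", "B", "A", "C"), c("B", "D", "C", "D"), 1)
  tal_all <- seed_pair_betweenness(diamond, c("A", "D"), "all_paths")
  expect_equal(tal_all[tal_all > 0], c(B = 1, C = 1))
  tal_one <- seed_pair_betweenness(diamond, c("A", "D"), "one_path")
  # exactly one of the two tied routes, chosen deterministically (lexicographic)
  expect_equal(tal_one[tal_one > 0], c(B = 1))
  expect_identical(tal_one,
                   seed_pair_betweenness(diamond, c("A", "D"), "one_path"))
})

test_that("a non-seed hub between k planted seeds scores choose(k, 2)", {
  for (k in c(3, 5, 10)) {
    seeds <- sprintf("S%02d", seq_len(k))
    # star: every seed - hub edge weight 1; long decoy ring seed_i - seed_{i+1}
    a <- c(seeds, seeds)
    b <- c(rep("HUB", k), seeds[c(2:k, 1)])
    w <- c(rep(1, k), rep(800, k))
    net <- net_from_weights(a, b, w)
    for (mode in c("all_paths", "one_path")) {
      tal <- seed_pair_betweenness(net, seeds, mode)
      expect_equal(unname(tal[["HUB"]]), choose(k, 2))
    }
    expect_equal(unname(enumeration_betweenness(net, seeds)[["HUB"]]),
                 choose(k, 2))
  }
})

test_that("sigma-product tallies agree with exhaustive enumeration on random graphs", {
  for (seed in 1:10) {
    net <- random_connected_net(18, extra = 22, wmin = 1, wmax = 12,
                                seed = 100 + seed)
    set.seed(seed)
    seeds <- sample(net$nodes, 4)
    expect_equal(seed_pair_betweenness(net, seeds, "all_paths"),
                 enumeration_betweenness(net, seeds),
                 ignore_attr = TRUE)
  }
})

test_that("seed genes are never tallied, even when interior to another pair's path", {
  # chain A-B-C-D-E with seeds {A, C, E}: C sits inside the A-E path but is a seed
  chain <- net_from_weights(c("A", "B", "C", "D"), c("B", "C", "D", "E"), 1)
  tal <- seed_pair_betweenness(chain, c("A", "C", "E"))
  expect_equal(tal[tal > 0], c(B = 2, D = 2))
  expect_equal(unname(tal[["C"]]), 0)
})

test_that("candidate tables hold exactly the inner nodes, ordered and reproducible", {
  chain <- net_from_weights(c("A", "B", "C"), c("B", "C", "D"), 1)
  tab <- discover_candidates(chain, c("A", "D"))
  expect_s3_class(tab, "candidate_table")
  expect_equal(tab$gene, c("B", "C"))
  expect_equal(tab$betweenness, c(1, 1))
  expect_true(all(diff(tab$betweenness) <= 0))
  # all-seed triangle: every shortest path is a single edge
  tri <- net_from_weights(c("A", "B", "C"), c("B", "C", "A"), 1)
  expect_warning(empty <- discover_candidates(tri, c("A", "B", "C")),
                 "no candidate")
  expect_equal(nrow(empty), 0L)
  # determinism: identical inputs, byte-identical output
  net <- random_connected_net(25, extra = 30, seed = 9)
  seeds <- net$nodes[c(2, 9, 17, 21)]
  for (mode in c("all_paths", "one_path")) {
    t1 <- discover_candidates(net, seeds, mode)
    t2 <- discover_candidates(net, seeds, mode)
    expect_identical(t1, t2)
  }
})

test_that("subdividing a unique shortest-path edge promotes the new node to candidate", {
  net <- net_from_weights(c("A", "B"), c("B", "C"), c(2, 2))
  base <- discover_candidates(net, c("A", "C"))
  expect_equal(base$gene, "B")
  # split edge A-B (weight 2) into A-V-B (1 + 1): same total, V now interior
  sub <- net_from_weights(c("A", "V", "B"), c("V", "B", "C"), c(1, 1, 2))
  tab <- discover_candidates(sub, c("A", "C"))
  expect_true("V" %in% tab$gene)
  expect_true(tab$betweenness[tab$gene == "V"] >= 1)
})

test_that("growing the seed set never lowers an existing tally (all-paths mode)", {
  for (seed in c(5, 6)) {
    net <- random_connected_net(20, extra = 25, seed = seed)
    set.seed(seed)
    seeds <- sample(net$nodes, 5)
    t_small <- seed_pair_betweenness(net, seeds[1:4], "all_paths")
    t_big <- seed_pair_betweenness(net, seeds, "all_paths")
    # the promoted node itself stops being tallied; everywhere else the new
    # pairs can only add
    rest <- setdiff(net$nodes, seeds[5])
    expect_true(all(t_big[rest] >= t_small[rest]))
  }
})
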
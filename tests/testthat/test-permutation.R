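test_that("random seed sets are uniform-without-replacement and seed-determined", {
  net <- random_connected_net(20, extra = 10, seed = 2)
  sets <- sample_random_seed_sets(net, size = 5, n_sets = 30, rng_seed = 11)
  expect_length(sets, 30)
  expect_true(all(vapply(sets, function(s) length(unique(s)) == 5L, logical(1))))
  expect_true(all(unlist(sets) %in% net$nodes))
  # same seed -> identical sequence; different seed -> different sequence
  expect_identical(sets, sample_random_seed_sets(net, 5, 30, rng_seed = 11))
  expect_false(identical(sets, sample_random_seed_sets(net, 5, 30, rng_seed = 12)))
  # size = pool size -> every set is the whole pool
  tiny <- net_from_weights(c("A", "B"), c("B", "C"), 1)
  all3 <- sample_random_seed_sets(tiny, 3, n_sets = 4, rng_seed = 1)
  expect_true(all(vapply(all3, function(s) setequal(s, tiny$nodes), logical(1))))
  expect_error(sample_random_seed_sets(tiny, 4, 5, 1), "exceeds")
  # non-seed pool excludes the true seeds
  ns <- sample_random_seed_sets(net, 5, 20, rng_seed = 3,
                                pool = "non_seed_nodes", seeds = net$nodes[1:4])
  expect_false(any(unlist(ns) %in% net$nodes[1:4]))
})

test_that("sampling does not disturb the caller's RNG stream", {
  net <- random_connected_net(10, extra = 5, seed = 4)
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_random_seed_sets(net, 3, 5, rng_seed = 7))
  expect_identical(runif(1), before)
})

test_that("ties never count as exceedances and FDRs are exact multiples of 1/n_sets", {
  # chain A-B-C, seeds {A, C}: B observed = 1. Any random 3-node draw of size 2
  # gives B null betweenness 1 (a tie) or 0, never > 1, so FDR must be exactly 0.
  chain <- net_from_weights(c("A", "B"), c("B", "C"), 1)
  cand <- discover_candidates(chain, c("A", "C"))
  res <- permutation_fdr(chain, c("A", "C"), cand, n_sets = 50, rng_seed = 5)
  expect_equal(res$fdr, 0)
  expect_equal(res$exceed_count, 0L)
  expect_true(res$significant)

  net <- random_connected_net(30, extra = 40, seed = 21)
  seeds <- net$nodes[c(1, 8, 15, 22)]
  cand <- discover_candidates(net, seeds)
  res <- permutation_fdr(net, seeds, cand, n_sets = 40, rng_seed = 6)
  expect_equal(res$fdr * 40, res$exceed_count)
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  expect_equal(res$gene, cand$gene)          # every candidate exactly once
  expect_equal(res$significant, res$fdr < 0.05)
})

test_that("permutation results are reproducible and mode mismatches are refused", {
  net <- random_connected_net(25, extra = 30, seed = 31)
  seeds <- net$nodes[c(3, 10, 18)]
  cand <- discover_candidates(net, seeds)
  r1 <- permutation_fdr(net, seeds, cand, n_sets = 25, rng_seed = 9)
  r2 <- permutation_fdr(net, seeds, cand, n_sets = 25, rng_seed = 9)
  expect_identical(r1, r2)
  r3 <- permutation_fdr(net, seeds, cand, n_sets = 25, rng_seed = 10)
  expect_false(identical(r1$exceed_count, r3$exceed_count))
  expect_error(permutation_fdr(net, seeds, cand, n_sets = 10, rng_seed = 1,
                               mode = "one_path"), "mode mismatch")
  prov <- attr(r1, "provenance")
  expect_equal(prov$n_sets, 25)
  expect_equal(prov$rng_seed, 9)
  expect_equal(prov$seed_set_size, 3)
})

test_that("raising an observed betweenness can only lower its exceed count", {
  net <- random_connected_net(25, extra = 30, seed = 41)
  seeds <- net$nodes[c(2, 11, 20, 24)]
  cand <- discover_candidates(net, seeds)
  res <- permutation_fdr(net, seeds, cand, n_sets = 30, rng_seed = 2)
  bumped <- cand
  bumped$betweenness <- bumped$betweenness + 5
  res2 <- permutation_fdr(net, seeds, bumped, n_sets = 30, rng_seed = 2)
  expect_true(all(res2$exceed_count <= res$exceed_count))
})

test_that("significance selection is strictly below the threshold", {
  tab <- data.frame(gene = paste0("G", 1:5),
                    fdr = c(0.0, 0.02, 0.048, 0.05, 0.3))
  expect_equal(select_significant(tab, 0.05)$gene, c("G1", "G2", "G3"))
  expect_equal(nrow(select_significant(data.frame(gene = "G", fdr = 1.0))), 0L)
  expect_equal(nrow(select_significant(tab, 1.0)), 5L)
})

test_that("permutation TSV output mirrors the supplementary-table layout", {
  chain <- net_from_weights(c("A", "B", "C"), c("B", "C", "D"), 1)
  cand <- discover_candidates(chain, c("A", "D"))
  res <- permutation_fdr(chain, c("A", "D"), cand, n_sets = 20, rng_seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_permutation_tsv(res, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(back),
               c("gene", "betweenness", "permutation_fdr", "significant"))
  expect_equal(back$gene, res$gene)
  prov <- jsonlite::read_json(paste0(path, ".provenance.json"))
  expect_equal(prov$n_sets, 20)
})
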
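test_that("STRING-dialect parsing maps fields, filters self-pairs and low scores", {
  lines <- c("protein1 protein2 combined_score",
             "ENSP000A ENSP000B 999",
             "ENSP000A ENSP000A 800",
             "ENSP000B ENSP000C 149",
             "ENSP000B ENSP000C 150")
  rec <- parse_interactions(lines)
  expect_equal(rec$protein_a, c("ENSP000A", "ENSP000B"))
  expect_equal(rec$protein_b, c("ENSP000B", "ENSP000C"))
  expect_equal(rec$score, c(999L, 150L))
  rep <- attr(rec, "parse_report")
  expect_true(rep$header_dropped)
  expect_equal(rep$rows_retained, 2L)
  expect_equal(rep$dropped_self_loop, 1L)
  expect_equal(rep$dropped_low_score, 1L)
  expect_equal(rep$rows_read, 5L)
})

test_that("parser handles tabs, comments, explicit header flags and extra fields", {
  rec <- parse_interactions(c("# a comment", "A\tB\t500\textra_field"))
  expect_equal(rec$score, 500L)
  # skip_header = FALSE keeps an all-data file intact
  rec2 <- parse_interactions(c("A B 300", "B C 400"), skip_header = FALSE)
  expect_equal(nrow(rec2), 2L)
  # skip_header = TRUE drops the first row unconditionally
  rec3 <- parse_interactions(c("A B 300", "B C 400"), skip_header = TRUE)
  expect_equal(nrow(rec3), 1L)
})

test_that("malformed and empty inputs fail with the offending line named", {
  expect_error(parse_interactions(c("A B 500", "A C")), "line 2")
  expect_error(parse_interactions(c("A B 500", "A C x9")), "line 2")
  expect_error(parse_interactions(character(0)), "empty")
  expect_error(parse_interactions("protein1 protein2 combined_score"), "header")
})

test_that("weight transform is 1000 - score with duplicate pairs collapsed to max score", {
  net <- net_from_edges("A", "B", 999L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 1L)
  expect_equal(net_from_edges("A", "B", 150L)$edges$weight, 850L)
  # both orientations collapse, keeping the strongest evidence
  dup <- net_from_edges(c("A", "B"), c("B", "A"), c(700L, 900L))
  expect_equal(nrow(dup$edges), 1L)
  expect_equal(dup$edges$score, 900L)
  expect_equal(dup$edges$weight, 100L)
})

test_that("network construction rejects empty input, self-loops and out-of-range scores", {
  expect_error(build_network(data.frame(protein_a = character(0),
                                        protein_b = character(0),
                                        score = integer(0))), "zero")
  expect_error(net_from_edges("A", "A", 500L), "self-loop")
  expect_error(net_from_edges("A", "B", 149L), "\\[150, 999\\]")
  expect_error(net_from_edges("A", "B", 1000L), "\\[150, 999\\]")
})

test_that("summary counts nodes, edges and components", {
  tri <- net_from_edges(c("A", "B", "C"), c("B", "C", "A"), 500L)
  s <- network_summary(tri)
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_edges, 3L)
  expect_equal(s$n_components, 1L)
  two <- net_from_edges(c("A", "C"), c("B", "D"), 500L)
  expect_equal(network_summary(two)$n_components, 2L)
  expect_equal(network_summary(two)$n_nodes, 4L)
})

test_that("background generator edge count matches the attachment closed form", {
  net <- generate_background(synthetic_spec(n_background = 100L, attachment = 3L,
                                            rng_seed = 1L))
  s <- network_summary(net)
  expect_equal(s$n_edges, 3L * (100L - 3L))
  expect_equal(s$n_nodes, 100L)
  expect_equal(s$n_components, 1L)
})

test_that("edge-list TSV round-trips and input orientation is irrelevant", {
  for (seed in 1:5) {
    net <- random_connected_net(12, extra = 10, seed = seed)
    # round trip through the canonical TSV
    path <- withr::local_tempfile(fileext = ".tsv")
    write_network_tsv(net, path)
    back <- build_network(
      setNames(utils::read.table(path, header = TRUE)[, 1:3],
               c("protein_a", "protein_b", "score")))
    expect_identical(back$nodes, net$nodes)
    expect_identical(back$edges, net$edges)
    # permuting the identifier columns yields the identical network
    rec <- net$edges
    flipped <- build_network(data.frame(protein_a = rec$b, protein_b = rec$a,
                                        score = rec$score))
    expect_identical(flipped$edges, net$edges)
    # weight bounds and the weight + score = 1000 identity
    expect_true(all(net$edges$weight >= 1L & net$edges$weight <= 850L))
    expect_true(all(net$edges$weight + net$edges$score == 1000L))
  }
})

test_that("gene lists and id mappings read cleanly", {
  path <- withr::local_tempfile(lines = c("# seeds", "G1", "", "G2 ", "G1"))
  expect_equal(read_gene_list(path), c("G1", "G2"))
  map <- withr::local_tempfile(lines = c("ENSP1\tFZD1", "ENSP2\tBCL2"))
  m <- read_id_mapping(map)
  expect_equal(unname(m["ENSP1"]), "FZD1")
})
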
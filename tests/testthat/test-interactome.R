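edges_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(gene_a = m[, 1], gene_b = m[, 2], tag = m[, 3],
             stringsAsFactors = FALSE)
}

test_that("interactome assembly keeps only seed-incident edges", {
  net <- build_interactome("A", edges_df("A", "B", "known",
                                         "A", "C", "novel",
                                         "B", "C", "known"))
  expect_setequal(net$interactors, c("B", "C"))
  expect_equal(net$n_known, 1L)
  expect_equal(net$n_novel, 1L)
  expect_equal(net$n_dropped, 1L)   # B-C touches no seed

  # empty seed set: empty interactome
  empty <- build_interactome(character(), edges_df("A", "B", "known"))
  expect_equal(length(empty$interactors), 0)
  expect_equal(nrow(empty$edges), 0)

  # A-B and B-A collapse to one undirected edge; self-loops are dropped
  dup <- build_interactome("A", edges_df("A", "B", "known",
                                         "B", "A", "known",
                                         "A", "A", "known"))
  expect_equal(nrow(dup$edges), 1)
})

test_that("hypergeometric overlap matches closed forms", {
  # full overlap of two 5-sets in a 10-universe: single term 1/C(10,5)
  expect_equal(hypergeom_overlap(10, 5, 5, 5)$p_tail, 1 / choose(10, 5),
               tolerance = 1e-12)
  # P(X >= 0) = 1
  expect_equal(hypergeom_overlap(10, 5, 5, 0)$p_tail, 1.0)
})

test_that("overlap tail agrees with a Monte-Carlo oracle at moderate p", {
  withr::local_seed(41)
  N <- 60; K <- 15; n <- 12; k <- 6
  p_impl <- hypergeom_overlap(N, K, n, k)$p_tail
  sims <- replicate(40000, {
    length(intersect(sample.int(N, K), sample.int(N, n))) >= k
  })
  p_mc <- mean(sims)
  se <- sqrt(p_mc * (1 - p_mc) / length(sims))
  expect_lt(abs(p_impl - p_mc), 5 * se + 1e-12)
})

test_that("overlap tail is monotone decreasing in k", {
  lp <- vapply(0:20, function(k)
    hypergeom_overlap(2000, 200, 100, k)$log10_p, 0)
  expect_true(all(diff(lp) < 0))
})

test_that("overlap_test compares full node sets and checks the universe", {
  net_a <- build_interactome(c("A1", "A2"),
                             edges_df("A1", "M", "known", "A2", "X", "novel"))
  net_b <- build_interactome("B1", edges_df("B1", "M", "known"))
  ov <- overlap_test(net_a, net_b, universe_n = 100)
  expect_equal(ov$overlap_k, 1)          # M
  expect_equal(ov$size_a, 4)             # seeds + interactors
  expect_equal(ov$common_genes, "M")
  expect_error(overlap_test(net_a, net_b, universe_n = 3), "universe")
  # interactors-only mode
  ov2 <- overlap_test(net_a, net_b, universe_n = 100, mode = "interactors")
  expect_equal(ov2$size_a, 2)
})

test_that("bridge reports match hand-built graphs", {
  # direct seed-seed edge only
  net_a <- build_interactome("X", edges_df("X", "Y", "known"))
  net_b <- build_interactome("Y", edges_df("X", "Y", "known"))
  br <- find_bridges(net_a, net_b)
  expect_equal(nrow(br$direct_edges), 1)
  expect_equal(length(br$common_interactors), 0)

  # X - M - Y: one two-step path through M
  net_a <- build_interactome("X", edges_df("X", "M", "known"))
  net_b <- build_interactome("Y", edges_df("M", "Y", "novel"))
  br <- find_bridges(net_a, net_b)
  expect_equal(br$common_interactors, "M")
  expect_equal(br$two_step_paths,
               data.frame(seed_a = "X", intermediate = "M", seed_b = "Y",
                          stringsAsFactors = FALSE))

  # disconnected components: empty report
  net_a <- build_interactome("X", edges_df("X", "P", "known"))
  net_b <- build_interactome("Y", edges_df("Y", "Q", "known"))
  br <- find_bridges(net_a, net_b)
  expect_equal(nrow(br$direct_edges), 0)
  expect_equal(nrow(br$two_step_paths), 0)
})

test_that("bridge enumeration matches exhaustive search on random graphs", {
  withr::local_seed(42)
  for (rep in 1:15) {
    n_nodes <- sample(10:50, 1)
    nodes <- sprintf("N%02d", seq_len(n_nodes))
    seeds_a <- sample(nodes, sample(2:4, 1))
    seeds_b <- sample(setdiff(nodes, seeds_a), sample(2:4, 1))
    n_edges <- sample(n_nodes:(3 * n_nodes), 1)
    edges <- data.frame(gene_a = sample(nodes, n_edges, replace = TRUE),
                        gene_b = sample(nodes, n_edges, replace = TRUE),
                        tag = "known", stringsAsFactors = FALSE)
    edges <- edges[edges$gene_a != edges$gene_b, ]
    net_a <- build_interactome(seeds_a, edges)
    net_b <- build_interactome(seeds_b, edges)
    br <- find_bridges(net_a, net_b)
    ora <- oracle_bridges(rbind(net_a$edges, net_b$edges), seeds_a, seeds_b)

    expect_setequal(br$common_interactors, ora$common)
    expect_setequal(paste(br$direct_edges$seed_a, br$direct_edges$seed_b),
                    unique(paste(ora$direct[, 1], ora$direct[, 2])))
    expect_setequal(
      paste(br$two_step_paths$seed_a, br$two_step_paths$intermediate,
            br$two_step_paths$seed_b),
      if (nrow(ora$two_step)) paste(ora$two_step[, 1], ora$two_step[, 2],
                                    ora$two_step[, 3]) else character())

    # every reported path's edges exist in the union edge set
    union_keys <- paste(pmin(net_a$edges$gene_a, net_a$edges$gene_b),
                        pmax(net_a$edges$gene_a, net_a$edges$gene_b))
    union_keys <- union(union_keys,
                        paste(pmin(net_b$edges$gene_a, net_b$edges$gene_b),
                              pmax(net_b$edges$gene_a, net_b$edges$gene_b)))
    with(br$two_step_paths, {
      k1 <- paste(pmin(seed_a, intermediate), pmax(seed_a, intermediate))
      k2 <- paste(pmin(intermediate, seed_b), pmax(intermediate, seed_b))
      expect_true(all(c(k1, k2) %in% union_keys))
    })

    # swapping the nets transposes the report
    sw <- find_bridges(net_b, net_a)
    expect_setequal(sw$common_interactors, br$common_interactors)
    expect_setequal(paste(sw$two_step_paths$seed_b, sw$two_step_paths$seed_a),
                    paste(br$two_step_paths$seed_a, br$two_step_paths$seed_b))
  }
})

test_that("candidate connectivity counts seeds reached via one intermediate", {
  net_a <- build_interactome("R", edges_df("R", "M", "known"))
  net_b <- build_interactome("S", edges_df("S", "W", "known"))
  cand_edges <- edges_df("C", "M", "novel", "D", "Q", "known")
  cc <- candidate_connectivity(c("C", "D", "E"), cand_edges, net_a, net_b)
  tab <- cc$per_candidate
  expect_equal(tab$n_seeds_a_two_step[tab$candidate == "C"], 1)  # C-M-R
  expect_equal(tab$n_seeds_b_two_step[tab$candidate == "C"], 0)
  expect_equal(cc$reached_seeds_a, "R")
  # candidate with no edges is isolated with zero counts
  expect_true(tab$isolated[tab$candidate == "E"])
  expect_equal(tab$n_interactors[tab$candidate == "E"], 0)
  # shared interactors with each net's node set
  expect_equal(cc$shared_interactors_a, "M")
  expect_equal(length(cc$shared_interactors_b), 0)
})

test_that("a small candidate interactome reports interactors shared with
           each disease net", {
  # one candidate with its own edge list queried against both nets
  net_a <- build_interactome(c("R1", "R2"),
                             edges_df("R1", "APC", "known",
                                      "R2", "ATF6B", "known"))
  net_b <- build_interactome("S1", edges_df("S1", "APC", "known"))
  cand_edges <- edges_df("C4A", "APC", "novel",
                         "C4A", "ATF6B", "novel",
                         "C4A", "ZZZ", "novel")
  cc <- candidate_connectivity("C4A", cand_edges, net_a, net_b)
  expect_setequal(cc$shared_interactors_a, c("APC", "ATF6B"))
  expect_setequal(cc$shared_interactors_b, "APC")
})

test_that("edge-list reading rejects malformed rows and SIF export works", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\ttag",
               "A\tB\tknown", "\tB\tknown", "A\tC\tweird"), f)
  e <- read_edge_list(f)
  expect_equal(nrow(e), 1)
  expect_equal(attr(e, "n_rejected"), 2L)

  net <- build_interactome("A", e)
  d <- withr::local_tempdir()
  export_interactome(net, file.path(d, "net"))
  expect_equal(readLines(file.path(d, "net.sif")), "A\tpp\tB")
  expect_true(file.exists(file.path(d, "net_nodes.tsv")))
})
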
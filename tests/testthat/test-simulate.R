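test_that("LD blocks land within the requested r2 range", {
  blocks <- ld_block_spec(1, 3, r2_min = 0.8, r2_max = 1)
  hp <- gen_haplotype_panel(200, blocks, seed = 71)
  ids <- hp$truth$blocks[[1]]$snp_ids
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(compute_r2(hp$panel, ids[i], ids[j])$r2, 0.8)
  }
})

test_that("singleton blocks are near-independent at panel size", {
  hp <- gen_haplotype_panel(200, ld_block_spec(12, 1L), seed = 72)
  ids <- hp$panel$variants$snp_id
  r2 <- utils::combn(ids, 2, function(p)
    compute_r2(hp$panel, p[1], p[2])$r2)
  expect_lt(max(r2), 0.2)
})

test_that("panel generation is a pure function of (spec, seed)", {
  blocks <- ld_block_spec(4, c(3, 1, 2, 1))
  a <- gen_haplotype_panel(100, blocks, seed = 73)
  b <- gen_haplotype_panel(100, blocks, seed = 73)
  expect_identical(a$panel$haplotypes, b$panel$haplotypes)
  expect_identical(a$panel$variants, b$panel$variants)
  c <- gen_haplotype_panel(100, blocks, seed = 74)
  expect_false(identical(a$panel$haplotypes, c$panel$haplotypes))
})

test_that("an unattainable r2 range raises a generation error", {
  blocks <- ld_block_spec(1, 2, r2_min = 0.999, r2_max = 0.9995)
  expect_error(gen_haplotype_panel(20, blocks, seed = 75), "infeasible")
})

test_that("planted opposite-direction effects yield opposite sample ORs at
           genome-wide significance", {
  blocks <- ld_block_spec(2, c(1, 1))
  hp <- gen_haplotype_panel(200, blocks, seed = 76)
  effects <- data.frame(snp_id = hp$panel$variants$snp_id[1],
                        or_a = 0.7, or_b = 1.4)
  hits <- 0L
  for (s in 1:20) {
    gw <- gen_two_trait_gwas(hp$panel, effects,
                             n_cases_a = 20000, n_controls_a = 20000,
                             n_cases_b = 20000, n_controls_b = 20000,
                             seed = 1000 + s)
    a <- gw$stats_a[1, ]; b <- gw$stats_b[1, ]
    if (a$odds_ratio < 1 && b$odds_ratio > 1 && a$p_value < 1e-8 &&
        b$p_value < 1e-8) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # >= 95% of seeds at this effect size
})

test_that("null SNPs have mean log-OR near zero across seeds", {
  hp <- gen_haplotype_panel(200, ld_block_spec(10, 1L), seed = 77)
  lo <- unlist(lapply(1:10, function(s) {
    gw <- gen_two_trait_gwas(hp$panel,
                             data.frame(snp_id = character(),
                                        or_a = numeric(), or_b = numeric()),
                             n_cases_a = 5000, n_controls_a = 5000,
                             n_cases_b = 5000, n_controls_b = 5000,
                             seed = 2000 + s)
    log(gw$stats_a$odds_ratio)
  }))
  expect_lt(abs(mean(lo)), 0.01)
})

test_that("GWAS simulation is deterministic and validates sample sizes", {
  hp <- gen_haplotype_panel(60, ld_block_spec(3, 1L), seed = 78)
  eff <- data.frame(snp_id = hp$panel$variants$snp_id[1], or_a = 2, or_b = 1)
  g1 <- gen_two_trait_gwas(hp$panel, eff, seed = 79)
  g2 <- gen_two_trait_gwas(hp$panel, eff, seed = 79)
  expect_identical(g1$stats_a, g2$stats_a)
  expect_identical(g1$stats_b, g2$stats_b)
  expect_error(gen_two_trait_gwas(hp$panel, eff, n_cases_a = 0, seed = 1))
  expect_error(
    gen_two_trait_gwas(hp$panel, data.frame(snp_id = "absent", or_a = 2,
                                            or_b = 1), seed = 1),
    "absent from panel")
})

test_that("generated gene models place SNPs in their intended classes", {
  hp <- gen_haplotype_panel(60, ld_block_spec(5, 1L, gap_bp = 30000),
                            seed = 80)
  planted <- data.frame(
    snp_id = hp$panel$variants$snp_id[1:4],
    class = c("exon", "intron", "flanking", "intergenic"),
    stringsAsFactors = FALSE)
  gm <- gen_gene_models(hp$panel$variants, planted, seed = 81)
  recs <- hp$panel$variants[1:4, c("snp_id", "chrom", "pos")]
  out <- map_to_genes(recs, gm$genes, flank_bp = 5000)
  expect_equal(out$region_class, planted$class)
  expect_equal(out$gene[1:3], gm$truth$planted_classes$gene[1:3])

  # no gene models at all: everything is intergenic
  none <- map_to_genes(recs, gm$genes[0, ], flank_bp = 5000)
  expect_true(all(none$region_class == "intergenic"))
})

test_that("planted PPI overlap is realized exactly and bridges exist", {
  ppi <- gen_ppi_networks(n_seeds_a = 10, n_seeds_b = 8,
                          n_interactors_a = 60, n_interactors_b = 40,
                          n_common = 15, n_direct_a = 2, n_direct_b = 2,
                          n_known_a = 80, n_novel_a = 20,
                          n_known_b = 50, n_novel_b = 15, seed = 82)
  net_a <- build_interactome(ppi$seeds_a, ppi$edges_a)
  net_b <- build_interactome(ppi$seeds_b, ppi$edges_b)
  expect_equal(length(net_a$interactors), 60)
  expect_equal(length(net_b$interactors), 40)
  expect_equal(net_a$n_known, 80); expect_equal(net_a$n_novel, 20)
  expect_setequal(intersect(net_a$nodes, net_b$nodes),
                  ppi$truth$common_genes)
  expect_equal(length(ppi$truth$common_genes), 15)

  br <- find_bridges(net_a, net_b)
  bt <- ppi$truth$bridge_triples
  expect_true(all(paste(bt$seed_a, bt$intermediate, bt$seed_b) %in%
                  paste(br$two_step_paths$seed_a,
                        br$two_step_paths$intermediate,
                        br$two_step_paths$seed_b)))

  # zero planted overlap: no common interactors at all
  ppi0 <- gen_ppi_networks(n_seeds_a = 5, n_seeds_b = 5,
                           n_interactors_a = 20, n_interactors_b = 15,
                           n_common = 0, n_direct_a = 0, n_direct_b = 0,
                           n_known_a = 25, n_novel_a = 5,
                           n_known_b = 18, n_novel_b = 4, seed = 83)
  br0 <- find_bridges(build_interactome(ppi0$seeds_a, ppi0$edges_a),
                      build_interactome(ppi0$seeds_b, ppi0$edges_b))
  expect_equal(length(br0$common_interactors), 0)
})

test_that("inconsistent interactome sizes are rejected", {
  expect_error(gen_ppi_networks(n_seeds_a = 5, n_seeds_b = 5,
                                n_interactors_a = 10, n_interactors_b = 10,
                                n_common = 50, seed = 1),
               "do not fit")
})

test_that("the simulated world round-trips through disk deterministically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_world(simulate_world(seed = 84), d1)
  write_world(simulate_world(seed = 84), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6), label = f)
  }
  stats <- read_summary_stats(file.path(d1, "stats_a.tsv"), "A")
  expect_gt(nrow(stats), 0)
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$seed, 84)
})
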
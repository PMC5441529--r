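make_stats <- function(snp_id, pos, or, p, ea = "G", oa = "A", chrom = "6") {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa,
             odds_ratio = or, p_value = p, trait = "t",
             stringsAsFactors = FALSE)
}

test_that("cross-trait pairing emits self-pairs and LD pairs above the floor", {
  panel <- toy_panel()
  a <- make_stats("s1", 1000L, 0.8, 1e-12)
  # same SNP present in trait B: self-pair at r2 = 1
  b_self <- make_stats("s1", 1000L, 1.2, 1e-9)
  pairs <- pair_cross_trait(a, b_self, panel)
  expect_equal(nrow(pairs), 1)
  expect_true(pairs$same_snp)
  expect_equal(pairs$r2, 1.0)

  # s2 is in high LD with s1 (r2 ~ 0.82): paired; s3 independent: not
  b_ld <- make_stats(c("s2", "s3"), c(2000L, 3000L), c(1.2, 1.3),
                     c(1e-9, 1e-10))
  pairs <- pair_cross_trait(a, b_ld, panel, scan_config(r2_pair_min = 0.8))
  expect_equal(pairs$b_snp_id, "s2")
  expect_gte(pairs$r2, 0.8)
  expect_false(pairs$same_snp)

  # no trait-B SNP within the window: zero pairs
  far_b <- make_stats("s9", 99999000L, 1.2, 1e-9)
  far_b$chrom <- "7"
  expect_equal(nrow(pair_cross_trait(a, far_b, panel)), 0)

  # self-pair mode (panel = NULL): only same-id pairs form
  expect_equal(nrow(pair_cross_trait(a, b_ld, NULL)), 0)
  expect_equal(nrow(pair_cross_trait(a, b_self, NULL)), 1)
})

test_that("deduplication picks max r2, then min p, then position", {
  base <- pair_cross_trait(make_stats("s1", 1000L, 0.8, 1e-12),
                           make_stats("s1", 1000L, 1.2, 1e-9), toy_panel())
  two <- rbind(base, base)
  two$b_snp_id <- c("z1", "z2")
  two$r2 <- c(0.90, 0.95); two$b_p <- c(1e-9, 1e-8)
  expect_equal(dedupe_pairs(two)$b_snp_id, "z2")   # r2 wins first

  two$r2 <- c(0.9, 0.9); two$b_p <- c(1e-12, 1e-9)
  expect_equal(dedupe_pairs(two)$b_snp_id, "z1")   # then p

  two$b_p <- c(1e-9, 1e-9); two$b_pos <- c(5000L, 2000L)
  expect_equal(dedupe_pairs(two)$b_snp_id, "z2")   # then position

  expect_equal(nrow(dedupe_pairs(base)), 1)        # single candidate unchanged
  # result independent of row order
  expect_equal(dedupe_pairs(two[2:1, ])$b_snp_id, dedupe_pairs(two)$b_snp_id)
})

test_that("opposite-direction filter keeps only straddling odds ratios", {
  mk <- function(or_a, or_b) {
    p <- pair_cross_trait(make_stats("s1", 1000L, or_a, 1e-12),
                          make_stats("s1", 1000L, or_b, 1e-9), NULL)
    p
  }
  expect_equal(nrow(opposite_effect_filter(mk(0.89, 1.07423))), 1)
  expect_equal(nrow(opposite_effect_filter(mk(1.2, 1.3))), 0)
  expect_equal(nrow(opposite_effect_filter(mk(1.0, 0.9))), 0)
  expect_equal(nrow(opposite_effect_filter(mk(0.9, 1.0))), 0)
})

test_that("same-SNP cross-verification excludes distinct-SNP pairs and
           harmonizes lookups", {
  stats_a <- make_stats(c("s1", "s2"), c(1000L, 2000L), c(0.89, 0.9),
                        c(1e-12, 1e-11), ea = "T", oa = "C")
  stats_b <- make_stats(c("s1", "s2"), c(1000L, 2000L), c(1.07, 1.2),
                        c(1e-9, 1e-8), ea = "T", oa = "C")
  pairs <- harmonize_pairs(pair_cross_trait(stats_a, stats_b, NULL))
  ver <- verify_same_snp(opposite_effect_filter(pairs), stats_a, stats_b)
  expect_true(all(ver$cross_verified))

  # a pair of two distinct SNPs in LD with opposite ORs is never pleiotropic
  cross <- pair_cross_trait(make_stats("s1", 1000L, 0.8, 1e-12),
                            make_stats("s2", 2000L, 1.2, 1e-9), toy_panel(),
                            scan_config(r2_pair_min = 0.5))
  cross <- cross[!cross$same_snp, , drop = FALSE]
  ver <- verify_same_snp(opposite_effect_filter(cross), stats_a, stats_b)
  expect_false(any(ver$cross_verified))

  # trait-B lookup reports the flipped allele; after harmonization the
  # directions agree, so verification fails
  stats_b_flip <- make_stats("s1", 1000L, 1.2, 1e-9, ea = "C", oa = "T")
  pairs <- harmonize_pairs(pair_cross_trait(stats_a[1, ], stats_b_flip, NULL))
  ver <- verify_same_snp(pairs, stats_a, stats_b_flip)
  expect_false(any(ver$cross_verified))

  # SNP missing from the other study's table: verification fails, logged
  ver <- verify_same_snp(harmonize_pairs(
    pair_cross_trait(stats_a[1, ], stats_b[1, ], NULL)),
    stats_a, stats_b[0, ])
  expect_false(any(ver$cross_verified))
  expect_equal(attr(ver, "n_lookup_failed"), 1L)
})

test_that("the cascade thresholds trait A only: high trait-B p-values survive", {
  ra <- table1_stats("RA"); sz <- table1_stats("SZ")
  res <- suppressWarnings(run_scan(ra, sz, NULL, table1_gene_models()))
  # several fixture SNPs have SZ p-values well above 1e-8 (up to 3.94e-7);
  # the asymmetric cascade must not drop them
  expect_true(any(res$pairs$b_p > 1e-8))
  expect_equal(res$audit[["n_pleiotropic_snps"]], 18)

  # symmetric mode, by contrast, p-thresholds both sides
  sym <- suppressWarnings(run_scan(ra, sz, NULL, table1_gene_models(),
                                   scan_config(symmetric = TRUE)))
  expect_lt(sym$audit[["n_pleiotropic_snps"]], 18)
  expect_true(all(sym$pairs$b_p < 1e-8))
})

test_that("stage counts are monotone non-increasing from pairing onward", {
  w <- simulate_world(seed = 5)
  res <- suppressWarnings(run_scan(w$stats_a, w$stats_b, w$panel, w$genes))
  stages <- res$audit[c("n_pairs", "n_pairs_deduped", "n_opposite",
                        "n_pleiotropic_snps")]
  expect_true(all(diff(stages) <= 0))
  expect_equal(res$audit[["n_genic"]] + res$audit[["n_intergenic"]],
               res$audit[["n_pleiotropic_snps"]])
})

test_that("the pleiotropic set is symmetric under trait swap when both
           sides are thresholded identically", {
  w <- simulate_world(seed = 9)
  cfg <- scan_config(symmetric = TRUE)
  ab <- suppressWarnings(run_scan(w$stats_a, w$stats_b, w$panel, NULL, cfg))
  ba <- suppressWarnings(run_scan(w$stats_b, w$stats_a, w$panel, NULL, cfg))
  ids_ab <- sort(c(ab$pleiotropic$snp_id, ab$intergenic$snp_id))
  ids_ba <- sort(c(ba$pleiotropic$snp_id, ba$intergenic$snp_id))
  expect_equal(ids_ab, ids_ba)
})

test_that("an effectively zero trait-A threshold empties the cascade", {
  ra <- table1_stats("RA"); sz <- table1_stats("SZ")
  res <- run_scan(ra, sz, NULL, NULL, scan_config(p_threshold_a = 1e-300))
  expect_equal(res$audit[["n_a_pruned"]], 0)
  expect_equal(res$audit[["n_pleiotropic_snps"]], 0)
})

test_that("null SNPs (OR = 1 in both traits) are not called pleiotropic,
           and false calls shrink with sample size", {
  # planted nulls: pleiotropy calls can only arise from sampling noise
  blocks <- ld_block_spec(40, 1L)
  hp <- gen_haplotype_panel(200, blocks, seed = 31)
  effects <- data.frame(snp_id = character(), or_a = numeric(),
                        or_b = numeric())
  n_calls <- vapply(c(2000L, 20000L), function(n) {
    calls <- 0L
    for (s in 1:5) {
      gw <- gen_two_trait_gwas(hp$panel, effects, n_cases_a = n,
                               n_controls_a = n, n_cases_b = n,
                               n_controls_b = n, seed = 100 + s)
      res <- run_scan(gw$stats_a, gw$stats_b, hp$panel, NULL)
      calls <- calls + res$audit[["n_pleiotropic_snps"]]
    }
    calls
  }, 0L)
  expect_lte(n_calls[2], n_calls[1])
  expect_equal(n_calls[2], 0L)
})
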
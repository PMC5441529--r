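#' Specify LD blocks for the haplotype-panel generator
#'
#' Convenience constructor for the block layout consumed by
#' [gen_haplotype_panel()]: `n_blocks` blocks of `snps_per_block` variants
#' each, laid out along one chromosome with `gap_bp` between block starts
#' and `spacing_bp` between variants inside a block. Within-block pairwise
#' r-squared is targeted into `[r2_min, r2_max]`; blocks are mutually
#' independent (cross-block r-squared ~ 0 at panel size).
#'
#' @param n_blocks Number of blocks.
#' @param snps_per_block Variants per block (scalar or vector; 1 = an
#'   unlinked singleton).
#' @param chrom Chromosome label (default "6", where the published signals
#'   sit).
#' @param start_bp Position of the first block (default 30e6).
#' @param gap_bp Distance between consecutive block starts (default 20000).
#' @param spacing_bp Distance between variants inside a block (default 500).
#' @param r2_min,r2_max Target within-block r-squared range (defaults 0.8, 1).
#' @return data.frame with one row per block.
#' @export
ld_block_spec <- function(n_blocks, snps_per_block, chrom = "6",
                          start_bp = 30e6, gap_bp = 20000, spacing_bp = 500,
                          r2_min = 0.8, r2_max = 1) {
  stopifnot(n_blocks >= 1, all(snps_per_block >= 1),
            r2_min >= 0, r2_max <= 1, r2_min <= r2_max)
  data.frame(
    chrom = chrom,
    start_bp = as.integer(start_bp + (seq_len(n_blocks) - 1) * gap_bp),
    n_snps = as.integer(rep_len(snps_per_block, n_blocks)),
    spacing_bp = as.integer(spacing_bp),
    r2_min = r2_min, r2_max = r2_max,
    stringsAsFactors = FALSE)
}

.draw_block <- function(n_hap, n_snps, r2_min, r2_max, max_tries = 200) {
  # founder-copy-with-flips: copy a founder column and flip a controlled
  # fraction of entries; for maf near 0.5 the expected r2 is (1-2*eps)^2
  r2_target <- (r2_min + min(r2_max, 0.98)) / 2
  eps <- (1 - sqrt(r2_target)) / 2
  for (try in seq_len(max_tries)) {
    founder <- stats::rbinom(n_hap, 1L, stats::runif(1, 0.35, 0.65))
    cols <- matrix(0L, nrow = n_hap, ncol = n_snps)
    cols[, 1] <- founder
    if (n_snps > 1) {
      for (j in 2:n_snps) {
        flip <- stats::rbinom(n_hap, 1L, eps)
        cols[, j] <- as.integer(xor(founder, flip))
      }
    }
    freqs <- colMeans(cols)
    if (any(freqs == 0 | freqs == 1)) next
    ok <- TRUE
    if (n_snps > 1) {
      for (j in 1:(n_snps - 1)) {
        r2 <- .r2_one_vs_many(cols[, j], cols[, (j + 1):n_snps, drop = FALSE])
        if (any(is.na(r2) | r2 < r2_min | r2 > r2_max)) { ok <- FALSE; break }
      }
    }
    if (ok) return(cols)
  }
  stop("infeasible r2 request [", r2_min, ", ", r2_max, "] for block of ",
       n_snps, " SNPs with ", n_hap, " haplotypes")
}

#' Generate a block-LD phased haplotype panel with known structure
#'
#' Emulates a reference haplotype panel at desk scale: each block is built
#' by copying a founder column and flipping a controlled fraction of
#' entries, which lands within-block pairwise r-squared inside the
#' requested range (verified against [compute_r2()]'s definition, with
#' bounded redraws; an unattainable range raises a generation error).
#' Blocks are mutually independent.
#'
#' @param n_haplotypes Even number of haplotypes, at least 20 (default 200).
#' @param blocks Block layout from [ld_block_spec()].
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return List: `panel` ([haplotype_panel()]) and `truth` (list with
#'   `blocks`: per-block member snp_ids and target range; `seed`).
#' @export
gen_haplotype_panel <- function(n_haplotypes = 200, blocks, seed) {
  stopifnot(n_haplotypes >= 20, n_haplotypes %% 2 == 0)
  withr::local_seed(seed)
  alleles <- c("A", "C", "G", "T")
  cols <- list(); meta <- list(); members <- list()
  snp_i <- 0L
  for (b in seq_len(nrow(blocks))) {
    nb <- blocks$n_snps[b]
    block_cols <- .draw_block(n_haplotypes, nb, blocks$r2_min[b],
                              blocks$r2_max[b])
    ids <- sprintf("snp%05d", snp_i + seq_len(nb))
    snp_i <- snp_i + nb
    ra <- replicate(nb, sample(alleles, 2))
    meta[[b]] <- data.frame(
      snp_id = ids, chrom = blocks$chrom[b],
      pos = blocks$start_bp[b] + (seq_len(nb) - 1L) * blocks$spacing_bp[b],
      ref = ra[1, ], alt = ra[2, ], stringsAsFactors = FALSE)
    cols[[b]] <- block_cols
    members[[b]] <- list(snp_ids = ids,
                         r2_range = c(blocks$r2_min[b], blocks$r2_max[b]))
  }
  variants <- do.call(rbind, meta)
  haps <- do.call(cbind, cols)
  ord <- order(variants$chrom, variants$pos)
  list(panel = haplotype_panel(variants[ord, , drop = FALSE],
                               haps[, ord, drop = FALSE]),
       truth = list(blocks = members, seed = seed))
}

#' Simulate two-trait case/control GWAS summary statistics from a panel
#'
#' For each panel variant and each trait, control allele frequency is the
#' panel frequency; the case frequency is induced by the planted per-allele
#' odds ratio (1 everywhere else). Case and control allele counts are drawn
#' binomially, and the emitted odds ratio and two-sided p-value come from
#' the resulting 2x2 table via the Wald statistic on the log odds ratio,
#' with the Haldane-Anscombe 0.5 correction when any cell is zero. Default
#' sample sizes are the two source studies': trait A (RA-analog)
#' 29,880/73,758 and trait B (SZ-analog) 36,989/113,075 cases/controls.
#'
#' @param panel [haplotype_panel()].
#' @param effects data.frame `snp_id`, `or_a`, `or_b` of planted effects;
#'   every listed SNP must be in the panel.
#' @param n_cases_a,n_controls_a,n_cases_b,n_controls_b Positive sample
#'   sizes.
#' @param seed Integer seed.
#' @return List: `stats_a`, `stats_b` (tables in the
#'   [read_summary_stats()] schema) and `truth` (planted effects + seed).
#' @export
gen_two_trait_gwas <- function(panel, effects,
                               n_cases_a = 29880, n_controls_a = 73758,
                               n_cases_b = 36989, n_controls_b = 113075,
                               seed = 1) {
  stopifnot(n_cases_a > 0, n_controls_a > 0, n_cases_b > 0, n_controls_b > 0)
  if (!all(effects$snp_id %in% panel$variants$snp_id)) {
    stop("planted SNP(s) absent from panel: ",
         paste(setdiff(effects$snp_id, panel$variants$snp_id), collapse = ", "))
  }
  withr::local_seed(seed)
  v <- panel$variants
  p0 <- colMeans(panel$haplotypes)

  or_for <- function(col) {
    or <- rep(1, nrow(v))
    i <- match(effects$snp_id, v$snp_id)
    or[i] <- effects[[col]]
    or
  }
  one_trait <- function(or, n_cases, n_controls, trait) {
    odds1 <- or * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    ca <- stats::rbinom(nrow(v), 2L * n_cases, p1)
    co <- stats::rbinom(nrow(v), 2L * n_controls, p0)
    a <- ca; b <- 2 * n_cases - ca; cc <- co; d <- 2 * n_controls - co
    zero <- a == 0 | b == 0 | cc == 0 | d == 0
    a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
    cc[zero] <- cc[zero] + 0.5; d[zero] <- d[zero] + 0.5
    log_or <- log(a) + log(d) - log(b) - log(cc)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    p <- pmax(2 * stats::pnorm(-abs(log_or) / se), 1e-320)
    data.frame(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
               effect_allele = v$alt, other_allele = v$ref,
               odds_ratio = exp(log_or), p_value = p, trait = trait,
               stringsAsFactors = FALSE)
  }
  list(stats_a = one_trait(or_for("or_a"), n_cases_a, n_controls_a, "traitA"),
       stats_b = one_trait(or_for("or_b"), n_cases_b, n_controls_b, "traitB"),
       truth = list(planted = effects, seed = seed))
}

#' Generate gene models placing chosen SNPs in prescribed region classes
#'
#' Builds one toy transcript per non-intergenic planted SNP so that the SNP
#' falls in the intended zone (exon, intron, flanking), plus optional
#' background genes far from every SNP. Planted SNPs must be far enough
#' apart (`> 2*flank_bp + 1600` bp) that one SNP's gene plus its flank
#' cannot contaminate another SNP's class.
#'
#' @param variants Panel variant metadata (`snp_id`, `chrom`, `pos`).
#' @param planted data.frame `snp_id`, `class` with class in
#'   exon|intron|flanking|intergenic.
#' @param flank_bp Flank width the downstream mapper will use (default 5000).
#' @param n_background Extra genes placed beyond every SNP (default 2).
#' @param seed Integer seed.
#' @return List: `genes` ([gene_models()]) and `truth` (planted classes +
#'   seed).
#' @export
gen_gene_models <- function(variants, planted, flank_bp = 5000,
                            n_background = 2, seed = 1) {
  stopifnot(all(planted$class %in% c("exon", "intron", "flanking",
                                     "intergenic")))
  miss <- setdiff(planted$snp_id, variants$snp_id)
  if (length(miss)) stop("planted SNP(s) not in variants: ",
                         paste(miss, collapse = ", "))
  withr::local_seed(seed)
  pl <- merge(planted, variants[c("snp_id", "chrom", "pos")], by = "snp_id")
  pl <- pl[order(pl$chrom, pl$pos), , drop = FALSE]
  same <- pl$chrom[-1] == pl$chrom[-nrow(pl)]
  gap <- diff(pl$pos)
  if (nrow(pl) > 1 && any(same & gap <= 2L * flank_bp + 1600L)) {
    stop("planted SNPs closer than 2*flank_bp + 1600 bp; classes would collide")
  }
  rows <- list()
  for (i in seq_len(nrow(pl))) {
    p0 <- pl$pos[i] - 1L  # 0-based position of the SNP base
    cls <- pl$class[i]
    nm <- paste0("GENE_", pl$snp_id[i])
    if (cls == "exon") {
      rows[[length(rows) + 1L]] <- list(
        gene_name = nm, chrom = pl$chrom[i], tx_start = p0 - 200L,
        tx_end = p0 + 300L, exon_starts = list(c(p0 - 50L)),
        exon_ends = list(c(p0 + 50L)))
    } else if (cls == "intron") {
      rows[[length(rows) + 1L]] <- list(
        gene_name = nm, chrom = pl$chrom[i], tx_start = p0 - 500L,
        tx_end = p0 + 500L, exon_starts = list(c(p0 - 500L)),
        exon_ends = list(c(p0 - 400L)))
    } else if (cls == "flanking") {
      up <- p0 + 100L + sample.int(flank_bp - 200L, 1)  # SNP upstream of tx
      rows[[length(rows) + 1L]] <- list(
        gene_name = nm, chrom = pl$chrom[i], tx_start = up,
        tx_end = up + 500L, exon_starts = list(up),
        exon_ends = list(up + 500L))
    }  # intergenic: no gene
  }
  max_pos <- max(variants$pos)
  for (j in seq_len(n_background)) {
    s <- as.integer(max_pos + 10L * flank_bp + j * 50000L)
    rows[[length(rows) + 1L]] <- list(
      gene_name = sprintf("BGGENE%02d", j), chrom = variants$chrom[1],
      tx_start = s, tx_end = s + 2000L,
      exon_starts = list(c(s, s + 1200L)),
      exon_ends = list(c(s + 400L, s + 2000L)))
  }
  genes <- gene_models(
    gene_name = vapply(rows, `[[`, "", "gene_name"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = "+",
    tx_start = vapply(rows, function(r) r$tx_start, 0L),
    tx_end = vapply(rows, function(r) r$tx_end, 0L),
    exon_starts = lapply(rows, function(r) r$exon_starts[[1]]),
    exon_ends = lapply(rows, function(r) r$exon_ends[[1]]))
  truth_tab <- data.frame(
    snp_id = pl$snp_id, class = pl$class,
    gene = ifelse(pl$class == "intergenic", NA_character_,
                  paste0("GENE_", pl$snp_id)),
    stringsAsFactors = FALSE)
  list(genes = genes, truth = list(planted_classes = truth_tab, seed = seed))
}

.pick_pairs <- function(seeds, partners, n_extra, existing_keys) {
  # sample n_extra distinct seed-partner pairs not already present
  out <- character(0); pairs <- list()
  guard <- 0L
  while (length(pairs) < n_extra) {
    guard <- guard + 1L
    if (guard > 50L * n_extra + 100L) stop("cannot place extra PPI edges")
    s <- sample(seeds, 1); p <- sample(partners, 1)
    key <- paste(min(s, p), max(s, p))
    if (s != p && !key %in% existing_keys && !key %in% out) {
      out <- c(out, key)
      pairs[[length(pairs) + 1L]] <- c(s, p)
    }
  }
  do.call(rbind, pairs)
}

#' Generate two disease PPI interactomes with a planted overlap
#'
#' Emits two tagged seed-incident edge lists whose realized node overlap is
#' exactly the planted common gene set: a shared interactor pool attached
#' to at least one seed on each side, plus the seeds involved in direct
#' cross-disease edges (a seed of one disease touched by a direct edge is,
#' by construction, an interactor of the other). Per-tag (known/novel) edge
#' counts are exact. Defaults are the published accounting: 98 + 1960 nodes
#' with 2232 known + 598 novel PPIs on the A side, 77 + 968 with 814 + 365
#' on the B side, 316 common genes including direct PPIs between 7 A-seeds
#' and 6 B-seeds.
#'
#' @param n_seeds_a,n_seeds_b Seed (disease gene) counts.
#' @param n_interactors_a,n_interactors_b Interactor counts per side.
#' @param n_common Total common genes between the two node sets.
#' @param n_direct_a,n_direct_b Seeds of each side involved in direct
#'   cross-disease PPIs (0 to disable direct edges).
#' @param n_known_a,n_novel_a,n_known_b,n_novel_b Per-tag edge counts.
#' @param seed Integer seed.
#' @return List: `seeds_a`, `seeds_b`, `edges_a`, `edges_b` (tagged edge
#'   data.frames) and `truth` (`common_genes`, `direct_seeds_a/b`,
#'   `bridge_triples`, `seed`).
#' @export
gen_ppi_networks <- function(n_seeds_a = 98, n_seeds_b = 77,
                             n_interactors_a = 1960, n_interactors_b = 968,
                             n_common = 316, n_direct_a = 7, n_direct_b = 6,
                             n_known_a = 2232, n_novel_a = 598,
                             n_known_b = 814, n_novel_b = 365,
                             seed = 1) {
  withr::local_seed(seed)
  n_common_int <- n_common - n_direct_a - n_direct_b
  n_excl_a <- n_interactors_a - n_direct_b - n_common_int
  n_excl_b <- n_interactors_b - n_direct_a - n_common_int
  if (n_common_int < 0 || n_excl_a < 0 || n_excl_b < 0) {
    stop("inconsistent sizes: common/interactor counts do not fit")
  }
  seeds_a <- sprintf("SA%04d", seq_len(n_seeds_a))
  seeds_b <- sprintf("SB%04d", seq_len(n_seeds_b))
  common <- if (n_common_int) sprintf("CI%05d", seq_len(n_common_int))
            else character()
  excl_a <- if (n_excl_a) sprintf("XA%05d", seq_len(n_excl_a)) else character()
  excl_b <- if (n_excl_b) sprintf("XB%05d", seq_len(n_excl_b)) else character()

  da <- if (n_direct_a) sample(seeds_a, n_direct_a) else character()
  db <- if (n_direct_b) sample(seeds_b, n_direct_b) else character()
  direct <- NULL
  if (n_direct_a > 0 && n_direct_b > 0) {
    n_dir <- max(n_direct_a, n_direct_b)
    direct <- data.frame(
      gene_a = da[((seq_len(n_dir) - 1) %% n_direct_a) + 1],
      gene_b = db[((seq_len(n_dir) - 1) %% n_direct_b) + 1],
      stringsAsFactors = FALSE)
    direct <- direct[!duplicated(paste(direct$gene_a, direct$gene_b)), ]
  } else if (n_direct_a + n_direct_b > 0) {
    stop("direct edges need at least one seed on each side")
  }

  attach_all <- function(partners, seeds) {
    if (!length(partners)) {
      return(data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE))
    }
    data.frame(gene_a = sample(seeds, length(partners), replace = TRUE),
               gene_b = partners, stringsAsFactors = FALSE)
  }
  build_side <- function(seeds, own_int, n_known, n_novel, direct_df) {
    base <- attach_all(own_int, seeds)
    if (!is.null(direct_df)) base <- rbind(base, direct_df)
    n_total <- n_known + n_novel
    if (n_total < nrow(base)) {
      stop("edge budget (", n_total, ") below the ", nrow(base),
           " edges needed to attach every interactor")
    }
    keys <- paste(pmin(base$gene_a, base$gene_b),
                  pmax(base$gene_a, base$gene_b))
    extra_n <- n_total - nrow(base)
    if (extra_n > 0) {
      extra <- .pick_pairs(seeds, own_int, extra_n, keys)
      base <- rbind(base, data.frame(gene_a = extra[, 1], gene_b = extra[, 2],
                                     stringsAsFactors = FALSE))
    }
    base$tag <- sample(rep(c("known", "novel"), c(n_known, n_novel)))
    base
  }
  # interactor sets as seen from each side (direct-opposite seeds included)
  int_a <- c(common, excl_a, db)
  int_b <- c(common, excl_b, da)
  edges_a <- build_side(seeds_a, c(common, excl_a), n_known_a, n_novel_a,
                        direct)
  edges_b <- build_side(seeds_b, c(common, excl_b), n_known_b, n_novel_b,
                        direct)

  bridge_triples <- NULL
  if (length(common)) {
    first_a <- edges_a$gene_a[match(common, edges_a$gene_b)]
    first_b <- edges_b$gene_a[match(common, edges_b$gene_b)]
    bridge_triples <- data.frame(seed_a = first_a, intermediate = common,
                                 seed_b = first_b, stringsAsFactors = FALSE)
  }
  list(seeds_a = seeds_a, seeds_b = seeds_b,
       edges_a = edges_a, edges_b = edges_b,
       truth = list(common_genes = sort(c(common, da, db)),
                    interactors_a = int_a, interactors_b = int_b,
                    direct_seeds_a = sort(da), direct_seeds_b = sort(db),
                    bridge_triples = bridge_triples, seed = seed))
}

#' Generate reciprocal expression signatures and a perturbagen matrix
#'
#' Two disease signatures share a gene universe; a planted set of
#' `n_up_down` genes is up in disease A and down in disease B, `n_down_up`
#' the reverse, and every other gene gets concordant signs (so the planted
#' sets are recovered exactly). The perturbagen matrix contains one planted
#' "reverser" whose profile is the exact negation of the query (the
#' signature of the planted reciprocal genes in disease-A orientation).
#'
#' @param n_genes Gene universe size (default 1000).
#' @param n_up_down,n_down_up Planted reciprocal gene counts (defaults 58
#'   and 48, the published dataset-level counts).
#' @param n_perturbagens Perturbagen count including the reverser
#'   (default 20).
#' @param seed Integer seed.
#' @return List: `sig_a`, `sig_b` ([expression_signature()]), `query`
#'   (signature over the planted reciprocal genes), `perturbagens` (matrix),
#'   `truth` (`up_a_down_b`, `down_a_up_b`, `reverser_id`, `seed`).
#' @export
gen_expression_fixtures <- function(n_genes = 1000, n_up_down = 58,
                                    n_down_up = 48, n_perturbagens = 20,
                                    seed = 1) {
  stopifnot(n_genes >= n_up_down + n_down_up, n_perturbagens >= 2)
  withr::local_seed(seed)
  genes <- sprintf("EXG%05d", seq_len(n_genes))
  idx_ud <- seq_len(n_up_down)
  idx_du <- n_up_down + seq_len(n_down_up)
  mag <- function(n) stats::runif(n, 0.5, 3)
  score_a <- numeric(n_genes); score_b <- numeric(n_genes)
  score_a[idx_ud] <- mag(n_up_down);  score_b[idx_ud] <- -mag(n_up_down)
  score_a[idx_du] <- -mag(n_down_up); score_b[idx_du] <- mag(n_down_up)
  rest <- setdiff(seq_len(n_genes), c(idx_ud, idx_du))
  sgn <- sample(c(-1, 1), length(rest), replace = TRUE)
  score_a[rest] <- sgn * mag(length(rest))
  score_b[rest] <- sgn * mag(length(rest))
  sig_a <- expression_signature(genes, score_a)
  sig_b <- expression_signature(genes, score_b)

  q_genes <- genes[c(idx_ud, idx_du)]
  query <- expression_signature(q_genes, score_a[c(idx_ud, idx_du)])
  mat <- matrix(stats::rnorm(length(q_genes) * n_perturbagens),
                nrow = length(q_genes),
                dimnames = list(q_genes,
                                sprintf("PERT%03d", seq_len(n_perturbagens))))
  reverser <- sprintf("PERT%03d", n_perturbagens)
  mat[, reverser] <- -query$score
  list(sig_a = sig_a, sig_b = sig_b, query = query, perturbagens = mat,
       truth = list(up_a_down_b = sort(genes[idx_ud]),
                    down_a_up_b = sort(genes[idx_du]),
                    reverser_id = reverser, seed = seed))
}

#' Built-in synthetic pipeline presets
#'
#' `paper-scale-mini` is the desk-scale stated world used throughout the
#' tests: 5 planted opposite-direction SNPs (alternating OR 0.7/1.4 and
#' 1.4/0.7) in 3-SNP LD blocks among null singleton blocks on chromosome 6,
#' source-study sample sizes, and scaled-down interactome/expression
#' components that keep the planted structure (shared interactors, direct
#' edges, reciprocal counts 58/48) intact.
#'
#' @param preset Preset name (currently only `"paper-scale-mini"`).
#' @return Named list of generator parameters.
#' @export
simulate_preset <- function(preset = "paper-scale-mini") {
  if (preset != "paper-scale-mini") stop("unknown preset: ", preset)
  list(
    n_haplotypes = 200,
    n_planted = 5L, n_null = 195L, snps_per_planted_block = 3L,
    or_a = c(0.7, 1.4, 0.7, 1.4, 0.7),
    or_b = c(1.4, 0.7, 1.4, 0.7, 1.4),
    n_cases_a = 29880, n_controls_a = 73758,
    n_cases_b = 36989, n_controls_b = 113075,
    planted_classes = c("exon", "intron", "flanking", "exon", "intergenic"),
    ppi = list(n_seeds_a = 20, n_seeds_b = 15, n_interactors_a = 120,
               n_interactors_b = 80, n_common = 30, n_direct_a = 3,
               n_direct_b = 2, n_known_a = 160, n_novel_a = 40,
               n_known_b = 100, n_novel_b = 30),
    n_pathways = 10L, pathway_size = 25L,
    expr = list(n_genes = 500, n_up_down = 58, n_down_up = 48,
                n_perturbagens = 10)
  )
}

#' Generate every pipeline input in memory with ground truth
#'
#' Runs all generators under one master seed (sub-seeds are derived
#' deterministically) and returns the objects plus a merged truth record.
#'
#' @param preset Preset name for [simulate_preset()], or a parameter list of
#'   the same shape.
#' @param seed Master integer seed.
#' @return List: `stats_a`, `stats_b`, `panel`, `genes`, `ppi` (seeds and
#'   edge lists), `gmt`, `expr` (signatures + matrix), `truth`.
#' @export
simulate_world <- function(preset = "paper-scale-mini", seed = 1) {
  par <- if (is.character(preset)) simulate_preset(preset) else preset
  sub <- function(k) as.integer((as.numeric(seed) * 131 + k) %% 2147483647)

  blocks <- rbind(
    ld_block_spec(par$n_planted, par$snps_per_planted_block,
                  start_bp = 30e6, r2_min = 0.8, r2_max = 1),
    ld_block_spec(par$n_null, 1L, start_bp = 32e6, r2_min = 0, r2_max = 1))
  hp <- gen_haplotype_panel(par$n_haplotypes, blocks, seed = sub(1))

  planted_ids <- vapply(hp$truth$blocks[seq_len(par$n_planted)],
                        function(b) b$snp_ids[1], "")
  effects <- data.frame(snp_id = planted_ids, or_a = par$or_a,
                        or_b = par$or_b, stringsAsFactors = FALSE)
  gw <- gen_two_trait_gwas(hp$panel, effects,
                           n_cases_a = par$n_cases_a,
                           n_controls_a = par$n_controls_a,
                           n_cases_b = par$n_cases_b,
                           n_controls_b = par$n_controls_b, seed = sub(2))

  planted_cls <- data.frame(snp_id = planted_ids,
                            class = rep_len(par$planted_classes,
                                            length(planted_ids)),
                            stringsAsFactors = FALSE)
  gm <- gen_gene_models(hp$panel$variants, planted_cls, seed = sub(3))

  ppi <- do.call(gen_ppi_networks, c(par$ppi, list(seed = sub(4))))

  withr::local_seed(sub(5))
  pool <- unique(c(ppi$seeds_a, ppi$seeds_b, ppi$truth$interactors_a,
                   ppi$truth$interactors_b,
                   sprintf("PW%05d", seq_len(200))))
  gmt <- lapply(seq_len(par$n_pathways), function(i)
    sample(pool, par$pathway_size))
  names(gmt) <- sprintf("pathway_%02d", seq_len(par$n_pathways))

  expr <- do.call(gen_expression_fixtures,
                  c(par$expr, list(seed = sub(6))))

  truth <- list(
    seed = seed,
    planted_pleiotropic_snps = effects,
    planted_block_structure = hp$truth$blocks,
    planted_classes = gm$truth$planted_classes,
    planted_overlap_genes = ppi$truth$common_genes,
    planted_reciprocal = list(up_a_down_b = expr$truth$up_a_down_b,
                              down_a_up_b = expr$truth$down_a_up_b),
    reverser_id = expr$truth$reverser_id)
  list(stats_a = gw$stats_a, stats_b = gw$stats_b, panel = hp$panel,
       genes = gm$genes, ppi = ppi, gmt = gmt, expr = expr, truth = truth)
}

#' Write a simulated world to disk in the pipeline's file formats
#'
#' Emits exactly the formats the pipeline consumes: summary-statistics TSVs,
#' haplotype matrix + variant sidecar TSVs, BED12 gene models, tagged PPI
#' edge TSVs with seed lists, a GMT, signature TSVs, a perturbagen matrix
#' TSV, and `truth.json`.
#'
#' @param world Output of [simulate_world()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_summary_stats(world$stats_a, p("stats_a.tsv"))
  write_summary_stats(world$stats_b, p("stats_b.tsv"))
  write_haplotype_matrix(world$panel, p("panel_matrix.tsv"),
                         p("panel_variants.tsv"))
  write_gene_models(world$genes, p("genes.bed"))
  data.table::fwrite(world$ppi$edges_a, p("ppi_a.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(world$ppi$edges_b, p("ppi_b.tsv"), sep = "\t",
                     quote = FALSE)
  writeLines(world$ppi$seeds_a, p("seeds_a.txt"))
  writeLines(world$ppi$seeds_b, p("seeds_b.txt"))
  write_gmt(world$gmt, p("pathways.gmt"))
  data.table::fwrite(world$expr$sig_a[c("gene", "score")], p("sig_a.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(world$expr$sig_b[c("gene", "score")], p("sig_b.tsv"),
                     sep = "\t", quote = FALSE)
  pm <- data.frame(gene = rownames(world$expr$perturbagens),
                   world$expr$perturbagens, check.names = FALSE)
  data.table::fwrite(pm, p("perturbagens.tsv"), sep = "\t", quote = FALSE)
  truth <- world$truth
  truth$planted_block_structure <- NULL  # bulky; block truth re-derivable
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(dir)
}
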
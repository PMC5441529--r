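#' Configuration for the cross-trait pleiotropy scan
#'
#' Defaults are the thresholds of the published cascade: genome-wide
#' significance `p < 1e-8` for the trait-A (RA-analog) list, pruning at
#' `r2 <= 0.6`, cross-trait pairing at `r2 >= 0.8`, and gene mapping with
#' 5000 bp flanks.
#'
#' @param p_threshold_a Trait-A significance threshold (default `1e-8`).
#' @param r2_prune_max Pruning r-squared ceiling (default 0.6).
#' @param r2_pair_min Cross-trait pairing r-squared floor (default 0.8).
#' @param flank_bp Gene-mapping flank in bp (default 5000).
#' @param window_bp LD window in bp for pruning and pairing (default 1e6).
#' @param drop_ambiguous Drop palindromic (A/T, C/G) same-SNP pairs instead
#'   of retaining them as-read with a warning (default FALSE).
#' @param symmetric Also p-threshold the trait-B table before pairing
#'   (default FALSE: the published cascade thresholds trait A only, so
#'   trait-B members of a pair may carry p-values above `p_threshold_a`).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(p_threshold_a = 1e-8, r2_prune_max = 0.6,
                        r2_pair_min = 0.8, flank_bp = 5000,
                        window_bp = 1e6, drop_ambiguous = FALSE,
                        symmetric = FALSE) {
  stopifnot(p_threshold_a > 0, p_threshold_a <= 1,
            r2_prune_max >= 0, r2_prune_max <= 1,
            r2_pair_min >= 0, r2_pair_min <= 1,
            flank_bp >= 0, window_bp >= 0)
  structure(list(p_threshold_a = p_threshold_a, r2_prune_max = r2_prune_max,
                 r2_pair_min = r2_pair_min, flank_bp = flank_bp,
                 window_bp = window_bp, drop_ambiguous = drop_ambiguous,
                 symmetric = symmetric),
            class = "scan_config")
}

.empty_pairs <- function() {
  data.frame(
    a_snp_id = character(), a_chrom = character(), a_pos = integer(),
    a_effect_allele = character(), a_other_allele = character(),
    a_or = numeric(), a_p = numeric(),
    b_snp_id = character(), b_chrom = character(), b_pos = integer(),
    b_effect_allele = character(), b_other_allele = character(),
    b_or = numeric(), b_p = numeric(),
    r2 = numeric(), same_snp = logical(),
    flip_applied = logical(), ambiguous_strand = logical(),
    stringsAsFactors = FALSE)
}

.as_pair_rows <- function(a, b, r2, same_snp) {
  data.frame(
    a_snp_id = a$snp_id, a_chrom = a$chrom, a_pos = a$pos,
    a_effect_allele = a$effect_allele, a_other_allele = a$other_allele,
    a_or = a$odds_ratio, a_p = a$p_value,
    b_snp_id = b$snp_id, b_chrom = b$chrom, b_pos = b$pos,
    b_effect_allele = b$effect_allele, b_other_allele = b$other_allele,
    b_or = b$odds_ratio, b_p = b$p_value,
    r2 = r2, same_snp = same_snp,
    flip_applied = FALSE, ambiguous_strand = FALSE,
    stringsAsFactors = FALSE)
}

#' Pair pruned trait-A SNPs with trait-B SNPs by LD
#'
#' For every pruned trait-A SNP, emits a pair with every trait-B SNP within
#' `window_bp` on the same chromosome whose panel r-squared is at least
#' `r2_pair_min`. A SNP present in both studies pairs with itself at
#' `r2 = 1` by definition. With `panel = NULL` (self-pair mode, used when no
#' reference panel is at hand) only same-id pairs are formed.
#'
#' @param pruned_a Trait-A table, already thresholded/pruned.
#' @param all_b Full trait-B table.
#' @param panel [haplotype_panel()] or NULL for self-pair mode.
#' @param cfg [scan_config()].
#' @return Pair table (one row per retained (r, z) pair) with attribute
#'   `n_not_in_panel` counting B SNPs that could not be looked up.
#' @export
pair_cross_trait <- function(pruned_a, all_b, panel, cfg = scan_config()) {
  out <- list()
  n_missing <- 0L
  if (nrow(pruned_a) == 0) return(.empty_pairs())
  for (i in seq_len(nrow(pruned_a))) {
    a <- pruned_a[i, , drop = FALSE]
    self <- all_b[all_b$snp_id == a$snp_id, , drop = FALSE]
    if (nrow(self)) {
      out[[length(out) + 1L]] <- .as_pair_rows(a, self[1, ], 1.0, TRUE)
    }
    if (is.null(panel)) next
    cand <- all_b[all_b$chrom == a$chrom &
                  abs(all_b$pos - a$pos) <= cfg$window_bp &
                  all_b$snp_id != a$snp_id, , drop = FALSE]
    if (nrow(cand) == 0) next
    ia <- match(a$snp_id, panel$variants$snp_id)
    ib <- match(cand$snp_id, panel$variants$snp_id)
    if (is.na(ia)) { n_missing <- n_missing + nrow(cand); next }
    n_missing <- n_missing + sum(is.na(ib))
    cand <- cand[!is.na(ib), , drop = FALSE]
    ib <- ib[!is.na(ib)]
    if (nrow(cand) == 0) next
    r2 <- .r2_one_vs_many(panel$haplotypes[, ia],
                          panel$haplotypes[, ib, drop = FALSE])
    keep <- !is.na(r2) & r2 >= cfg$r2_pair_min
    if (any(keep)) {
      out[[length(out) + 1L]] <-
        .as_pair_rows(a[rep(1, sum(keep)), ], cand[keep, , drop = FALSE],
                      r2[keep], FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_pairs()
  rownames(res) <- NULL
  attr(res, "n_not_in_panel") <- n_missing
  res
}

#' Deduplicate pairs to one trait-B partner per trait-A SNP
#'
#' When several trait-B SNPs match one trait-A SNP, the winner is chosen
#' lexicographically: highest r-squared, then lowest trait-B p-value, then
#' smallest trait-B position, then trait-B snp_id (the last two are
#' deterministic tie-breaks so output never depends on input order).
#'
#' @param pairs Pair table from [pair_cross_trait()].
#' @return Pair table with at most one row per `a_snp_id`.
#' @export
dedupe_pairs <- function(pairs) {
  if (nrow(pairs) <= 1) return(pairs)
  ord <- order(pairs$a_snp_id, -pairs$r2, pairs$b_p, pairs$b_pos,
               pairs$b_snp_id)
  pairs <- pairs[ord, , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$a_snp_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Harmonize same-SNP pairs onto a shared effect allele
#'
#' Applies [harmonize_alleles()] to every pair whose two members are the same
#' physical SNP, rewriting `b_or` onto trait A's effect allele and setting
#' `flip_applied` / `ambiguous_strand`. Pairs of two distinct SNPs are left
#' as read (their alleles are independent). Palindromic same-SNP pairs are
#' retained as-read with a warning, or dropped when `drop_ambiguous`.
#'
#' @param pairs Pair table.
#' @param drop_ambiguous Drop palindromic same-SNP pairs (default FALSE).
#' @return Pair table with harmonized `b_or`.
#' @export
harmonize_pairs <- function(pairs, drop_ambiguous = FALSE) {
  if (nrow(pairs) == 0) return(pairs)
  for (i in which(pairs$same_snp)) {
    h <- harmonize_alleles(
      list(snp_id = pairs$a_snp_id[i], effect_allele = pairs$a_effect_allele[i],
           other_allele = pairs$a_other_allele[i], odds_ratio = pairs$a_or[i],
           p_value = pairs$a_p[i]),
      list(snp_id = pairs$b_snp_id[i], effect_allele = pairs$b_effect_allele[i],
           other_allele = pairs$b_other_allele[i], odds_ratio = pairs$b_or[i],
           p_value = pairs$b_p[i]))
    pairs$b_or[i] <- h$or_trait_b
    pairs$b_effect_allele[i] <- h$effect_allele
    pairs$b_other_allele[i] <- h$other_allele
    pairs$flip_applied[i] <- h$flip_applied
    pairs$ambiguous_strand[i] <- h$ambiguous_strand
  }
  n_amb <- sum(pairs$ambiguous_strand)
  if (n_amb > 0 && !drop_ambiguous) {
    warning(n_amb, " palindromic same-SNP pair(s) retained as-read ",
            "(strand unresolvable from alleles)")
  }
  if (drop_ambiguous) {
    pairs <- pairs[!pairs$ambiguous_strand, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Keep pairs whose odds ratios point in opposite directions
#'
#' A pair survives iff one member has OR < 1 and the other OR > 1, i.e.
#' `sign(or_a - 1) * sign(or_b - 1) < 0`. An OR exactly 1 is directionless
#' and never passes. Assumes same-SNP pairs were harmonized first
#' ([harmonize_pairs()]).
#'
#' @param pairs Pair table.
#' @return Pair table restricted to opposite-direction pairs, with column
#'   `opposite_effects = TRUE`.
#' @export
opposite_effect_filter <- function(pairs) {
  keep <- sign(pairs$a_or - 1) * sign(pairs$b_or - 1) < 0
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out)) out$opposite_effects <- TRUE
  rownames(out) <- NULL
  out
}

#' Cross-verify putative pleiotropy for same-SNP pairs
#'
#' The opposite-direction call so far uses SNP r's trait-A effect and SNP
#' z's trait-B effect. For a pair to evidence *pleiotropy of one SNP*, the
#' same SNP must show opposite directions when looked up in both studies'
#' full tables. That check is applicable only where r and z are the same
#' SNP; pairs of two distinct SNPs get `cross_verified = FALSE` and are
#' excluded from the pleiotropic set. Lookups are allele-harmonized before
#' comparing directions; a SNP missing from either table fails verification
#' (with attribute `n_lookup_failed` counting such cases).
#'
#' @param pairs Opposite-direction pair table.
#' @param stats_a,stats_b The two studies' full association tables.
#' @return Pair table with logical column `cross_verified`.
#' @export
verify_same_snp <- function(pairs, stats_a, stats_b) {
  if (nrow(pairs) == 0) {
    pairs$cross_verified <- logical(0)
    return(pairs)
  }
  pairs$cross_verified <- FALSE
  n_fail <- 0L
  for (i in which(pairs$same_snp)) {
    snp <- pairs$a_snp_id[i]
    ra <- stats_a[stats_a$snp_id == snp, , drop = FALSE]
    rb <- stats_b[stats_b$snp_id == snp, , drop = FALSE]
    if (nrow(ra) == 0 || nrow(rb) == 0) { n_fail <- n_fail + 1L; next }
    h <- tryCatch(harmonize_alleles(ra[1, ], rb[1, ]), error = function(e) NULL)
    if (is.null(h)) { n_fail <- n_fail + 1L; next }
    pairs$cross_verified[i] <-
      sign(h$or_trait_a - 1) * sign(h$or_trait_b - 1) < 0
  }
  attr(pairs, "n_lookup_failed") <- n_fail
  pairs
}

.pairs_to_records <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(data.frame(
      snp_id = character(), chrom = character(), pos = integer(),
      allele_pair = character(), or_a = numeric(), p_a = numeric(),
      or_b = numeric(), p_b = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(
    snp_id = pairs$a_snp_id, chrom = pairs$a_chrom, pos = pairs$a_pos,
    allele_pair = paste0(pairs$a_effect_allele, "/", pairs$a_other_allele),
    or_a = pairs$a_or, p_a = pairs$a_p,
    or_b = pairs$b_or, p_b = pairs$b_p,
    stringsAsFactors = FALSE)
}

#' Run the full cascaded pleiotropy scan
#'
#' Executes the cascade: trait-A p-thresholding and LD pruning, cross-trait
#' LD pairing, per-A-SNP deduplication, allele harmonization,
#' opposite-direction filtering, same-SNP cross-verification, and gene-region
#' mapping. Stage sizes are recorded in `audit` so a run can be compared
#' against the published narrative (all pairs, deduplicated pairs,
#' opposite-direction pairs, same-SNP pleiotropic SNPs, genic/intergenic
#' split).
#'
#' @param stats_a Trait-A (RA-analog) association table; only this side is
#'   thresholded and pruned unless `cfg$symmetric`.
#' @param stats_b Trait-B (SZ-analog) association table.
#' @param panel [haplotype_panel()] or NULL for self-pair mode (no pruning
#'   beyond the p-threshold; pairs are same-id only).
#' @param genes [gene_models()] or NULL to skip gene mapping (all records
#'   then reported as intergenic).
#' @param cfg [scan_config()].
#' @return List of class `pleio_scan`: `pleiotropic` (gene-region records),
#'   `intergenic` (records outside genes and flanks), `pairs` (the final
#'   verified pair table), `audit` (named stage counts), `cfg`.
#' @export
run_scan <- function(stats_a, stats_b, panel = NULL, genes = NULL,
                     cfg = scan_config()) {
  audit <- c(n_a_total = nrow(stats_a), n_b_total = nrow(stats_b))
  if (cfg$symmetric) {
    stats_b_paired <- stats_b[stats_b$p_value < cfg$p_threshold_a, ,
                              drop = FALSE]
  } else {
    stats_b_paired <- stats_b
  }
  if (is.null(panel)) {
    pruned <- stats_a[stats_a$p_value < cfg$p_threshold_a, , drop = FALSE]
  } else {
    pruned <- ld_prune(stats_a, panel, p_threshold = cfg$p_threshold_a,
                       r2_max = cfg$r2_prune_max, window_bp = cfg$window_bp)
  }
  audit["n_a_pruned"] <- nrow(pruned)

  pairs <- pair_cross_trait(pruned, stats_b_paired, panel, cfg)
  audit["n_pairs"] <- nrow(pairs)

  pairs <- dedupe_pairs(pairs)
  audit["n_pairs_deduped"] <- nrow(pairs)

  pairs <- harmonize_pairs(pairs, drop_ambiguous = cfg$drop_ambiguous)
  pairs <- opposite_effect_filter(pairs)
  audit["n_opposite"] <- nrow(pairs)

  pairs <- verify_same_snp(pairs, stats_a, stats_b)
  pleio <- pairs[pairs$same_snp & pairs$cross_verified, , drop = FALSE]
  audit["n_pleiotropic_snps"] <- nrow(pleio)

  records <- map_to_genes(.pairs_to_records(pleio), genes,
                          flank_bp = cfg$flank_bp)
  genic <- records[records$region_class != "intergenic", , drop = FALSE]
  inter <- records[records$region_class == "intergenic", , drop = FALSE]
  rownames(genic) <- rownames(inter) <- NULL
  audit["n_genic"] <- nrow(genic)
  audit["n_intergenic"] <- nrow(inter)

  structure(list(pleiotropic = genic, intergenic = inter, pairs = pairs,
                 audit = audit, cfg = cfg),
            class = "pleio_scan")
}

#' @export
print.pleio_scan <- function(x, ...) {
  cat("<pleio_scan>\n")
  for (nm in names(x$audit)) cat(sprintf("  %-20s %d\n", nm, x$audit[[nm]]))
  if (nrow(x$pleiotropic)) {
    cat("  genes:", paste(sort(unique(x$pleiotropic$gene)), collapse = ", "),
        "\n")
  }
  invisible(x)
}
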
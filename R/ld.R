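#' Construct a phased haplotype panel
#'
#' A panel is the substrate for r-squared: an H x V matrix of 0/1 allele
#' indicators (H haplotypes, V variants) plus per-variant metadata. Variants
#' must be strictly ordered by (chrom, pos), mirroring a sorted reference
#' panel.
#'
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, in strictly increasing (chrom, pos) order.
#' @param haplotypes Integer/numeric matrix of 0/1 with `ncol == nrow(variants)`
#'   and at least 2 rows; columns are variants in the same order.
#' @return Object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, haplotypes) {
  stopifnot(is.data.frame(variants),
            all(c("snp_id", "chrom", "pos") %in% names(variants)))
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) < 2) stop("panel needs at least 2 haplotypes")
  if (ncol(haplotypes) != nrow(variants)) {
    stop("haplotype matrix has ", ncol(haplotypes),
         " columns but metadata describes ", nrow(variants), " variants")
  }
  if (!all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype matrix entries must all be 0 or 1")
  }
  ord <- order(variants$chrom, variants$pos)
  if (any(ord != seq_len(nrow(variants)))) {
    stop("variants must be strictly sorted by (chrom, pos)")
  }
  if (any(duplicated(variants[c("chrom", "pos")]))) {
    stop("duplicate (chrom, pos) in variant metadata")
  }
  if (anyDuplicated(variants$snp_id)) stop("duplicate snp_id in panel")
  colnames(haplotypes) <- variants$snp_id
  structure(list(variants = as.data.frame(variants), haplotypes = haplotypes),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d variants (%s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              paste(unique(x$variants$chrom), collapse = ",")))
  invisible(x)
}

.panel_index <- function(panel, snp) {
  i <- match(snp, panel$variants$snp_id)
  if (is.na(i)) stop("SNP not in panel: ", snp)
  i
}

# r^2 between a single 0/1 column and a set of 0/1 columns, via the
# haplotype-frequency definition D = pAB - pA pB. NA where a column is
# monomorphic.
.r2_one_vs_many <- function(x, mat) {
  h <- length(x)
  pa <- mean(x)
  pb <- colMeans(mat)
  pab <- as.vector(crossprod(x, mat)) / h
  d <- pab - pa * pb
  denom <- pa * (1 - pa) * pb * (1 - pb)
  out <- d^2 / denom
  out[denom == 0] <- NA_real_
  out
}

#' Pairwise linkage disequilibrium (r-squared) from phased haplotypes
#'
#' Computes the standard haplotype-frequency r-squared
#' `r2 = D^2 / (pA(1-pA) pB(1-pB))` with `D = pAB - pA pB`, where all
#' frequencies are counted directly over the panel's phased haplotypes.
#'
#' @param panel [haplotype_panel()].
#' @param snp_a,snp_b Variant identifiers present in the panel. Both must be
#'   polymorphic in the panel; LD with a monomorphic variant is undefined and
#'   raises an error.
#' @return A list of class `ld_statistic` with `snp_a`, `snp_b`, `r2`.
#' @export
compute_r2 <- function(panel, snp_a, snp_b) {
  ia <- .panel_index(panel, snp_a)
  ib <- .panel_index(panel, snp_b)
  x <- panel$haplotypes[, ia]
  y <- panel$haplotypes[, ib]
  pa <- mean(x); pb <- mean(y)
  if (pa %in% c(0, 1)) stop("LD undefined: monomorphic SNP ", snp_a)
  if (pb %in% c(0, 1)) stop("LD undefined: monomorphic SNP ", snp_b)
  d <- mean(x == 1L & y == 1L) - pa * pb
  structure(list(snp_a = snp_a, snp_b = snp_b,
                 r2 = d^2 / (pa * (1 - pa) * pb * (1 - pb))),
            class = "ld_statistic")
}

#' @export
print.ld_statistic <- function(x, ...) {
  cat(sprintf("<ld_statistic> r2(%s, %s) = %.6f\n", x$snp_a, x$snp_b, x$r2))
  invisible(x)
}

#' Greedy p-value-ordered LD pruning
#'
#' Restricts an association table to genome-wide-significant SNPs
#' (`p < p_threshold`) and thins them so that no retained pair within
#' `window_bp` on one chromosome exceeds `r2_max`. Standard clumping
#' semantics: candidates are visited in ascending p (ties broken by chrom,
#' pos, then snp_id, so the result is independent of input row order) and a
#' candidate is accepted iff its r-squared with every already-accepted SNP in
#' the window is at most `r2_max`. Cross-chromosome r-squared is defined as 0.
#'
#' @param assocs Association table (see [read_summary_stats()]).
#' @param panel [haplotype_panel()] used for r-squared. SNPs absent from the
#'   panel (matched by `snp_id`, falling back to `(chrom, pos)`) are excluded
#'   and counted in attribute `n_not_in_panel`.
#' @param p_threshold Genome-wide significance cutoff (default `1e-8`).
#' @param r2_max Maximum tolerated r-squared between retained SNPs
#'   (default 0.6).
#' @param window_bp Window within which LD is checked (default 1e6 bp).
#' @return The retained rows, sorted by (p, chrom, pos), with attribute
#'   `n_not_in_panel`.
#' @export
ld_prune <- function(assocs, panel, p_threshold = 1e-8, r2_max = 0.6,
                     window_bp = 1e6) {
  stopifnot(p_threshold > 0, p_threshold <= 1, r2_max >= 0, r2_max <= 1)
  sig <- assocs[assocs$p_value < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    attr(sig, "n_not_in_panel") <- 0L
    return(sig)
  }
  idx <- match(sig$snp_id, panel$variants$snp_id)
  pos_key <- paste(panel$variants$chrom, panel$variants$pos)
  idx[is.na(idx)] <- match(paste(sig$chrom, sig$pos)[is.na(idx)], pos_key)
  n_missing <- sum(is.na(idx))
  sig <- sig[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]

  ord <- order(sig$p_value, sig$chrom, sig$pos, sig$snp_id)
  sig <- sig[ord, , drop = FALSE]
  idx <- idx[ord]

  accepted <- logical(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    prior <- which(accepted &
                   sig$chrom == sig$chrom[i] &
                   abs(sig$pos - sig$pos[i]) <= window_bp)
    ok <- TRUE
    if (length(prior)) {
      r2 <- .r2_one_vs_many(panel$haplotypes[, idx[i]],
                            panel$haplotypes[, idx[prior], drop = FALSE])
      ok <- all(is.na(r2) | r2 <= r2_max)
    }
    accepted[i] <- ok
  }
  out <- sig[accepted, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_not_in_panel") <- n_missing
  out
}

#' Read a haplotype panel from a 0/1 matrix TSV plus a variant sidecar
#'
#' The matrix file is H rows x V columns of 0/1 with variant ids as header;
#' the sidecar is a TSV with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`
#' in matrix column order.
#'
#' @param matrix_path Path to the haplotype matrix TSV.
#' @param variants_path Path to the variant metadata TSV.
#' @return [haplotype_panel()].
#' @export
read_haplotype_matrix <- function(matrix_path, variants_path) {
  variants <- data.table::fread(variants_path, data.table = FALSE,
                                colClasses = list(character = "chrom"))
  haps <- as.matrix(data.table::fread(matrix_path, data.table = FALSE))
  haplotype_panel(variants, haps)
}

#' Write a haplotype panel as matrix TSV + variant sidecar
#'
#' @param panel [haplotype_panel()].
#' @param matrix_path,variants_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_haplotype_matrix <- function(panel, matrix_path, variants_path) {
  data.table::fwrite(as.data.frame(panel$haplotypes), matrix_path,
                     sep = "\t", quote = FALSE)
  data.table::fwrite(panel$variants, variants_path, sep = "\t", quote = FALSE)
  invisible(matrix_path)
}

#' Read a haplotype panel from a phased VCF
#'
#' Requires the `VariantAnnotation` package. Every genotype must be phased
#' (`|` separator); each sample contributes two haplotypes.
#'
#' @param path Path to a VCF with phased GT fields.
#' @return [haplotype_panel()].
#' @export
read_haplotype_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VariantAnnotation is required to ingest VCF panels")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (any(!grepl("|", gt, fixed = TRUE))) {
    stop("panel VCF must be fully phased (GT with '|')")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  split_gt <- function(g, which) as.integer(vapply(
    strsplit(g, "|", fixed = TRUE), `[[`, "", which))
  # haplotypes: for each sample, two rows
  haps <- do.call(rbind, lapply(seq_len(ncol(gt)), function(j) {
    rbind(split_gt(gt[, j], 1L), split_gt(gt[, j], 2L))
  }))
  variants <- data.frame(
    snp_id = rownames(gt),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], ""),
    stringsAsFactors = FALSE
  )
  ord <- order(variants$chrom, variants$pos)
  haplotype_panel(variants[ord, , drop = FALSE], haps[, ord, drop = FALSE])
}

#' Export pairwise LD statistics as a 3-column TSV
#'
#' @param panel [haplotype_panel()].
#' @param snp_ids Variants to query (all pairs among them).
#' @param path Output TSV (`snp_a`, `snp_b`, `r2`).
#' @return The LD table, invisibly.
#' @export
export_ld_table <- function(panel, snp_ids, path) {
  pairs <- utils::combn(snp_ids, 2)
  out <- data.frame(
    snp_a = pairs[1, ], snp_b = pairs[2, ],
    r2 = vapply(seq_len(ncol(pairs)), function(i) {
      compute_r2(panel, pairs[1, i], pairs[2, i])$r2
    }, 0), stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(out)
}
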
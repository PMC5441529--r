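#' Path to the packaged 18-SNP cross-disorder fixture table
#'
#' The packaged TSV transcribes the 18 putatively pleiotropic SNPs in the
#' extended HLA region reported for rheumatoid arthritis vs schizophrenia:
#' per SNP, the hg19 position, harboring gene and region class, shared
#' allele pair, and the odds ratio and p-value in each disorder's GWAS.
#'
#' @return Path to `table1.tsv`.
#' @export
table1_path <- function() {
  system.file("extdata", "table1.tsv", package = "pleioscan", mustWork = TRUE)
}

#' Read the 18-SNP fixture as one or both traits' association tables
#'
#' The fixture lists both disorders' effects per SNP on one shared allele
#' pair, so each side can be lifted into the standard summary-statistics
#' schema. `trait = "RA"` takes the RA odds ratio / p-value columns,
#' `trait = "SZ"` the SZ ones.
#'
#' @param trait `"RA"` or `"SZ"`.
#' @return data.frame in the [read_summary_stats()] schema.
#' @export
table1_stats <- function(trait = c("RA", "SZ")) {
  trait <- match.arg(trait)
  tab <- data.table::fread(table1_path(), data.table = FALSE,
                           colClasses = list(character = "chrom"))
  data.frame(
    snp_id = tab$snp_name, chrom = tab$chrom, pos = tab$pos,
    effect_allele = tab$effect_allele, other_allele = tab$other_allele,
    odds_ratio = if (trait == "RA") tab$ra_or else tab$sz_or,
    p_value = if (trait == "RA") tab$ra_p else tab$sz_p,
    trait = trait, stringsAsFactors = FALSE)
}

#' Read the fixture's printed gene and region-class annotations
#'
#' @return data.frame `snp_id`, `gene`, `region`.
#' @export
table1_annotations <- function() {
  tab <- data.table::fread(table1_path(), data.table = FALSE)
  data.frame(snp_id = tab$snp_name, gene = tab$gene, region = tab$region,
             stringsAsFactors = FALSE)
}

#' Toy gene models consistent with the fixture's printed region classes
#'
#' Synthetic transcript models (coordinates invented, not the real
#' knownCanonical hg19 structures) built so that every fixture SNP falls in
#' its printed gene with its printed class under [map_to_genes()] with
#' 5000 bp flanks: exonic SNPs inside an exon interval, intronic SNPs
#' inside the transcript but outside exons, flanking SNPs within 5 kb
#' outside the transcript.
#'
#' @return [gene_models()] with the fixture's 8 genes.
#' @export
table1_gene_models <- function() {
  gene_models(
    gene_name = c("PSORS1C1", "HLA-C", "HLA-B", "HCP5", "MICB", "TNXB",
                  "NOTCH4", "C6orf10"),
    chrom = "6",
    strand = "+",
    tx_start = c(31100000L, 31239000L, 31241000L, 31396000L, 31471000L,
                 32064000L, 32190000L, 32339000L),
    tx_end = c(31103000L, 31240200L, 31325000L, 31399000L, 31474000L,
               32068000L, 32191000L, 32340000L),
    exon_starts = list(
      31100000L,                  # PSORS1C1: short 5' exon, SNP intronic
      31239400L,                  # HLA-C: exon covering rs1050420
      c(31241000L, 31324100L),    # HLA-B: 3' exon covers the three exonic SNPs
      31396000L,                  # HCP5
      31471000L,                  # MICB
      32064000L,                  # TNXB
      32190000L,                  # NOTCH4: single-exon, rs915894 exonic
      32339000L),                 # C6orf10: single-exon, rs2073045 exonic
    exon_ends = list(
      31100100L,
      31239700L,
      c(31241100L, 31325000L),
      31396200L,
      31471200L,
      32064200L,
      32191000L,
      32340000L)
  )
}

#' Synthetic reconstruction of the 46 opposite-direction SNP pairs
#'
#' The published cascade reported 46 LD pairs with opposite-direction odds
#' ratios, of which 29 were pairs of one and the same SNP; the underlying
#' pair list lives in a supplementary file that is not redistributable
#' here. This builds a synthetic stand-in with that reported composition:
#' the 18 genic same-SNP pairs are the real fixture rows, the 11 intergenic
#' same-SNP pairs and the 17 distinct-SNP LD pairs are invented (ids
#' prefixed `syn`), every pair opposite-direction by construction. It
#' exercises the same-SNP counting logic, not the real supplement.
#'
#' @return Pair table in the [pair_cross_trait()] schema (46 rows).
#' @export
synthetic_opposite_pairs <- function() {
  ra <- table1_stats("RA")
  sz <- table1_stats("SZ")
  genic <- .as_pair_rows(ra, sz, rep(1, nrow(ra)), TRUE)

  syn_same <- lapply(seq_len(11), function(i) {
    or_a <- if (i %% 2) 0.8 else 1.25
    a <- list(snp_id = sprintf("syn_same%02d", i), chrom = "6",
              pos = 33000000L + i * 20000L, effect_allele = "A",
              other_allele = "G", odds_ratio = or_a, p_value = 1e-10)
    b <- a; b$odds_ratio <- 1 / or_a; b$p_value <- 1e-8
    .as_pair_rows(as.data.frame(a), as.data.frame(b), 1, TRUE)
  })
  syn_cross <- lapply(seq_len(17), function(i) {
    or_a <- if (i %% 2) 0.85 else 1.2
    a <- list(snp_id = sprintf("syn_r%02d", i), chrom = "6",
              pos = 34000000L + i * 20000L, effect_allele = "T",
              other_allele = "C", odds_ratio = or_a, p_value = 1e-11)
    b <- list(snp_id = sprintf("syn_z%02d", i), chrom = "6",
              pos = 34000500L + i * 20000L, effect_allele = "A",
              other_allele = "G", odds_ratio = 1 / or_a, p_value = 1e-7)
    .as_pair_rows(as.data.frame(a), as.data.frame(b), 0.9, FALSE)
  })
  out <- rbind(genic, do.call(rbind, syn_same), do.call(rbind, syn_cross))
  rownames(out) <- NULL
  out
}

#' Printed NFAT-pathway gene partition fixture
#'
#' One row of the published merged pathway table ("Role of NFAT in
#' Regulation of the Immune Response"): the genes hit by the RA and SZ
#' interactomes partitioned into exclusive-RA / common / exclusive-SZ, with
#' the published BH-corrected p-values. Used only for structural tests of
#' the partition logic; the p-values come from a proprietary pathway suite
#' with its own universe and are not recomputed here. Composite labels
#' ("FCGR3A/FCGR3B", "CALM1 (includes others)") are opaque single symbols.
#' Note: the source text refers to 43 common genes for this pathway in
#' prose while its table lists these 19; the discrepancy is unresolved at
#' the source and is left as printed.
#'
#' @return List: `pathway`, `p_a`, `p_b`, `exclusive_a`, `common`,
#'   `exclusive_b`.
#' @export
table2_nfat <- function() {
  list(
    pathway = "Role of NFAT in Regulation of the Immune Response",
    p_a = 6.3e-28, p_b = 3.0e-07,
    exclusive_a = c(
      "NFATC2", "NFKBIB", "GNAO1", "HRAS", "ATM", "NFKBIE", "CD4", "MAP2K1",
      "CD247", "IKBKAP", "IKBKG", "IKBKE", "CD86", "RAF1", "CD79A", "XPO1",
      "FCER1G", "FCER1A", "PIK3CA", "PIK3CD", "PIK3CG", "CSNK1D", "MAPK1",
      "PIK3R3", "PIK3R2", "NFKB2", "CD80", "MS4A2", "CD28", "PLCB4",
      "FCGR2B", "FCGR2A", "GNG5", "PRKCQ", "GATA4", "LYN", "NFKBIA",
      "IKBKB", "ITK", "SOS1", "LCK", "CSNK1E", "GRB2", "GNA12", "HLA-DOA",
      "CD79B", "MEF2D", "LAT", "FCGR3A/FCGR3B", "PPP3CB", "CD3E", "ATF2"),
    common = c(
      "GSK3A", "NFATC3", "MAPK3", "SYK", "JUN", "FOS", "FYN", "CHUK",
      "CALM1 (includes others)", "GNB2L1", "PLCG2", "PLCG1", "AKT1",
      "ZAP70", "PIK3R1", "LCP2", "NFKB1", "RELA", "BTK"),
    exclusive_b = c(
      "CSNK1A1", "GNAS", "GNB5", "GNG10", "GNB1", "GSK3B", "AKT3",
      "HLA-DMB"))
}
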
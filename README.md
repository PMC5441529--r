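# pleioscan

Cross-disorder GWAS pleiotropy scan and dual-disease interactome analysis
in R.

## The problem

Schizophrenia (SZ) and rheumatoid arthritis (RA) are inversely related in
epidemiological data — each disorder, and family history of it, lowers
the apparent risk of the other — and genome-wide studies report small
negative genetic correlations between them. One mechanistic candidate is
*opposite-direction pleiotropy*: a single SNP whose one allele raises risk
for SZ while the other raises risk for RA. `pleioscan` is for
statistical-genetics and systems-biology analysts who want to run that
search, and the companion network analyses, as tested, reproducible code
on their own summary statistics, reference panels, PPI edge lists, GMT
pathway files, and expression signatures.

## What it computes

**The pleiotropy cascade** (`run_scan()`): from two summary-statistics
tables and a phased haplotype panel, with thresholds `p < 10⁻⁸` (trait A),
pruning `r² ≤ 0.6`, pairing `r² ≥ 0.8`, and 5 kb gene flanks:

1. p-threshold and greedily LD-prune trait A (r² is the haplotype
   frequency statistic `D²/(p_A q_A p_B q_B)` from the panel);
2. pair each retained trait-A SNP *r* with every trait-B SNP *z* at
   `r²(r, z) ≥ 0.8`;
3. keep one *z* per *r* (max r², then min p, deterministic tie-breaks);
4. harmonize alleles and keep pairs with ORs on opposite sides of 1;
5. call a SNP pleiotropic only if *r* and *z* are the *same* SNP with
   opposite directions confirmed in both studies' tables;
6. classify each SNP as exon / intron / flanking / intergenic against
   transcript models with 5 kb flanks.

**Interactome analysis**: seed-incident PPI graphs from tagged
(known/novel) edge lists; overlap of two interactomes scored by the
upper-tail hypergeometric probability in log space; exhaustive bridge
enumeration (direct seed–seed edges, common interactors, two-step paths);
connectivity of a candidate gene set to both disease networks.

**Pathway enrichment**: hypergeometric over-representation against GMT
gene sets with Benjamini–Hochberg correction, and a two-interactome merge
that partitions each pathway's hits into exclusive-A / common /
exclusive-B.

**Reciprocal expression**: genes up in one disease and down in the other,
and Spearman connectivity scoring of a query signature against perturbagen
profiles (strong negative scores flag signature-reversing compounds).

**Synthetic data**: seeded generators (`simulate_world()`, `gen_*`) for
every input — block-LD haplotype panels, two-trait case/control GWAS with
planted opposite-direction effects at the source studies' sample sizes,
gene models, paired interactomes with an exactly-planted overlap, and
reciprocal signatures — with ground truth serialized alongside.

## Worked example

The package ships an 18-SNP fixture transcribing the published table of
putatively pleiotropic SNPs in the extended HLA region, with each SNP's
RA and SZ odds ratios on a shared allele. Feeding the two sides as the
two studies (self-pair mode; toy gene models matching the printed
classes):

```r
library(pleioscan)
ra  <- table1_stats("RA")
sz  <- table1_stats("SZ")
res <- run_scan(ra, sz, panel = NULL, genes = table1_gene_models())
res
#> <pleio_scan>
#>   n_a_total            18
#>   n_b_total            18
#>   n_a_pruned           18
#>   n_pairs              18
#>   n_pairs_deduped      18
#>   n_opposite           18
#>   n_pleiotropic_snps   18
#>   n_genic              18
#>   n_intergenic         0
#>   genes: C6orf10, HCP5, HLA-B, HLA-C, MICB, NOTCH4, PSORS1C1, TNXB
head(res$pleiotropic[c("snp_id", "or_a", "or_b", "gene", "region_class")], 4)
#>       snp_id or_a    or_b  gene region_class
#> 1  rs1050420 0.90 1.07090 HLA-C         exon
#> 2  rs1131163 0.86 1.07058 HLA-B         exon
#> 3  rs1265888 1.19 0.90041  TNXB       intron
#> 4 rs12721827 0.88 1.07466 HLA-B         exon
```

All 18 SNPs survive every stage (each has one OR below 1 and one above),
map to 8 distinct genes, and 4 genes (NOTCH4, C6orf10, HLA-C, HLA-B)
carry exonic hits. The interactome overlap at the published sizes —
98+1960 vs 77+968 genes with 316 in common, universe 20,000:

```r
hypergeom_overlap(20000, 98 + 1960, 77 + 968, 316)
#> <overlap_test> N=20000 K=2058 n=1045 k=316  P(X>=k) = 4.96e-76 (log10 = -75.3045)
```

i.e. far below the published `p < 10⁻⁷²` significance bound.

An end-to-end synthetic run (generate inputs, scan, interactomes,
enrichment, expression, joint candidate report) is one call:

```r
cmd_all("run_dir", seed = 1)
```

A thin CLI wrapper with the same subcommands is installed at
`system.file("scripts", "pleioscan.R", package = "pleioscan")`.

See `vignettes/cross-disorder-pleiotropy.Rmd` for the model, the design
decisions taken where the source procedure was underspecified, and what
the synthetic world does and does not emulate.

## Acceptance script

`scripts/acceptance.R` re-runs the package's headline computations from
scratch against the installed package: the 18-SNP fixture cascade, the
hypergeometric overlap at the published sizes, and a seeded synthetic
end-to-end pipeline run, then writes its JSON report.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
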
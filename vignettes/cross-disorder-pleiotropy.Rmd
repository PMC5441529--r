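---
title: "Methods: the cross-disorder pleiotropy scan and interactome analysis"
author: "pleioscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cross-disorder pleiotropy scan and interactome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## The scientific problem

Schizophrenia (SZ) and rheumatoid arthritis (RA) show an inverse
epidemiological relationship: people with one disorder, and their
relatives, are less likely to develop the other, and genome-wide analyses
report small negative genetic correlations between them. One candidate
explanation is *pleiotropy with opposite directions of effect*: a single
polymorphism whose one allele raises risk for SZ while the other raises
risk for RA. `pleioscan` implements, as reusable and tested code, the
published desk procedure for finding such variants from GWAS summary
statistics, together with the companion network analyses: construction and
comparison of the two disorders' protein interactomes, pathway enrichment,
and reciprocal gene-expression signature analysis.

## The cascade

The scan consumes two per-SNP association tables (SNP id, chromosome,
1-based position, effect/other allele, odds ratio OR, p-value) and a
phased haplotype reference panel, and proceeds through fixed stages
(`run_scan()`):

1. **Threshold and prune trait A** (the RA-analog). Keep SNPs with
   `p < 1e-8`; thin them greedily in ascending-p order so that no retained
   pair within the LD window has `r² > 0.6`. The r² is the standard
   haplotype-frequency statistic `D²/(pA qA pB qB)` counted over the
   panel's phased haplotypes (`compute_r2()`).
2. **Pair across traits.** Each retained trait-A SNP *r* is paired with
   every trait-B SNP *z* whose panel r² with *r* is at least 0.8. A SNP
   present in both studies pairs with itself at r² = 1.
3. **Deduplicate.** When several *z* match one *r*, keep the pair with the
   highest r², then the lowest trait-B p-value (with position and id as
   final deterministic tie-breaks, so results never depend on input
   order).
4. **Opposite directions.** After allele harmonization, keep pairs with
   one OR below 1 and the other above 1. An OR of exactly 1 is
   directionless and never passes.
5. **Same-SNP verification.** Opposite directions across a *pair of SNPs
   in LD* may reflect haplotype structure rather than pleiotropy of one
   variant, so a pair evidences pleiotropy only when *r* and *z* are the
   same SNP and that SNP shows opposite directions when looked up in both
   studies' full tables.
6. **Gene mapping.** Verified SNPs are classified against transcript
   models with 5000 bp flanks as exonic, intronic, flanking, or
   intergenic. Intergenic records are written to their own output, not
   discarded — they remain of scientific interest.

Audit counts after every stage are part of the result (`$audit`),
mirroring the published narrative of 1376 pairs → 290 deduplicated → 46
opposite-direction → 29 same-SNP → 18 genic + 11 intergenic.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p_threshold_a` | 1e-8 | genome-wide significance for the trait-A list |
| `r2_prune_max` | 0.6 | ceiling for within-list LD after pruning |
| `r2_pair_min` | 0.8 | floor for cross-trait LD pairing |
| `flank_bp` | 5000 | flank width for gene mapping (bp) |
| `window_bp` | 1e6 | LD window for pruning and pairing (bp) |

The first four are the published thresholds. The window is our own bound:
the published signals all lie in one ~4 Mb region, so a 1 Mb window only
bounds cost; it is configurable for genome-wide pairing.

### Design choices the source left open

* **Asymmetry.** Only trait A is thresholded and pruned, exactly as
  published; consequently trait-B members of retained pairs may carry
  p-values well above 1e-8 (the packaged 18-SNP fixture contains SZ
  p-values up to 3.9e-7), and the test suite asserts they are not dropped.
  A `symmetric = TRUE` mode thresholds both sides, and the suite checks
  that the pleiotropic set is then invariant under swapping the traits.
* **Allele harmonization.** The source procedure examines ORs "as given"
  and never states how (or whether) alleles were reoriented between
  studies. We harmonize before any direction comparison: align on the
  effect allele, invert the OR on an effect/other swap, complement on an
  apparent strand flip. Palindromic (A/T, C/G) SNPs cannot be
  strand-resolved from allele labels; they are flagged and kept as-read
  with a warning by default (`drop_ambiguous` excludes them), because the
  fixture itself contains A/T SNPs and silent exclusion would change the
  printed counts.
* **Pruning algorithm.** The published run used an external clumping tool
  without stating parameters; we adopt standard deterministic clumping
  semantics (ascending-p greedy acceptance). Cross-chromosome r² is
  defined as 0.
* **Multiple gene hits.** The source prints exactly one gene per SNP; when
  several transcripts hit, we choose by class priority exon > intron >
  flanking, breaking ties by distance to the transcript midpoint, and
  retain all hits in a secondary column.
* **Threshold of zero.** The configuration contract requires
  `0 < p_threshold_a ≤ 1` (a literal 0 would make the strict comparison
  `p < 0` vacuous anyway); an effectively-zero threshold such as 1e-300
  empties the cascade at stage 1 and is tested.

## Interactome analysis

A disease interactome is the graph of its GWAS-associated (seed) genes
plus every protein connected to a seed by a protein–protein interaction.
Edges arrive as labelled input (`known` from curated databases, `novel`
from upstream computational prediction — prediction itself is out of
scope here); only seed-incident edges are retained, undirected and
deduplicated. Overlap between two interactomes is scored with the
upper-tail hypergeometric probability of drawing `k` shared genes between
node sets of sizes `K` and `n` from a universe of `N` genes
(`overlap_test()`), computed in log space via `phyper(log.p = TRUE)` so
probabilities far below double underflow are carried as log10 values; the
test suite cross-checks against an independent log-gamma term summation.
At the published sizes (98+1960 vs 77+968 nodes, 316 shared, N = 20000)
the tail is ~1e-75, below the published 1e-72 bound.

Open choices: the universe `N` is not stated at the source; we default to
20,000 (approximate human protein-coding gene count) and report the value
used — the published bound is insensitive to any N in 18k–25k. Whether the
316-gene overlap counted seeds+interactors or interactors only is also
unstated; the printed set sizes imply seeds+interactors, which is our
default, with an interactors-only mode available. Gene identity is by
case-preserved symbol string; composite labels ("FCGR3A/FCGR3B") are
opaque single symbols.

`find_bridges()` enumerates connections between two interactomes — direct
seed–seed edges, common interactors adjacent to seeds of both sides, and
every seedA–intermediate–seedB two-step path — exhaustively, and
`candidate_connectivity()` asks the same questions of a candidate gene set
(e.g. the genes harboring the pleiotropic SNPs) against both disease
networks.

## Pathway enrichment

`enrich()` is a hypergeometric over-representation test against
user-supplied GMT gene sets with Benjamini–Hochberg correction across the
tested pathways; all hit pathways are returned regardless of
significance. The published pathway analysis used a proprietary suite
whose private universe and pathway definitions make its printed p-values
(e.g. 6.3e-28) irreproducible in principle; those numbers are therefore
*not* an acceptance surface here. The printed gene partition for the NFAT
immune-response pathway is packaged (`table2_nfat()`) purely as a
structural fixture for the merge logic, which splits each pathway's hits
into exclusive-A / common / exclusive-B sets (pairwise disjoint, union
equal to the combined hits). Note the source's own inconsistency: its
prose speaks of 43 common genes for that pathway while its table lists
19; we do not reconcile this and carry the table as printed. The default
enrichment universe is the unique genes of the GMT unioned with the query
set (so the documented precondition `universe_n ≥ |gene_set ∪ pathway|`
always holds for the default), overridable and recorded in the output.

## Reciprocal expression and connectivity scoring

`reciprocal_genes()` intersects two disease signatures on their shared
gene universe and returns the genes up in one and down in the other, in
both orientations. Direction calls come from the sign of the score with a
configurable dead-zone (`epsilon`, default 0) mirroring threshold-based
differential-expression calls. `connectivity_score()` ranks perturbagen
profiles by Spearman rank correlation with a query signature over shared
genes; rank correlation was chosen over weighted Kolmogorov–Smirnov
scoring for determinism and testability (the hook is a single function if
an alternative metric is wanted). Strong negative scores flag
signature-reversing, potentially therapeutic, perturbagens. The published
compound hits and the 369/101/150 gene counts came from hosted services
on real data and are not reproduced; the operations themselves are.

## The synthetic world

The generators (`simulate_world()` and the `gen_*` functions) are the
package's stand-in for the external inputs: genotype-level reference
panels, two large case/control GWAS, gene models, curated plus predicted
PPI networks, and expression signatures. Defaults are the stated
conditions of the motivating study where it states them, and a fixed
realistic choice where it does not:

* **Haplotype panel.** Block LD is generated by copying a founder column
  and flipping a controlled fraction of entries — enough to exercise r²
  thresholds (the generator verifies realized within-block r² against
  `compute_r2()` and errors on infeasible requests), deliberately not a
  coalescent simulation. 200 haplotypes by default, founder frequencies
  0.35–0.65. It does not emulate human allele-frequency spectra, real LD
  maps, or MHC-specific haplotype structure, so green tests establish
  correctness of the *filtering logic*, not realism of LD.
* **GWAS tables.** Trait A uses 29,880 cases / 73,758 controls and trait
  B 36,989 / 113,075 — the two source studies' sizes. Per SNP, control
  allele frequency is the panel frequency, the case frequency is induced
  by the planted per-allele OR (1 everywhere else), allele counts are
  binomial, and OR/p come from the 2×2 table Wald statistic with the
  Haldane–Anscombe 0.5 correction on zero cells. The planted
  opposite-direction effects default to OR 0.7 vs 1.4 — comfortably
  genome-wide-significant at these sample sizes, as a planted truth
  should be.
* **Interactomes.** Node and per-tag edge counts default to the published
  accounting (98+1960 / 77+968 nodes, 2232+598 / 814+365 edges, 316
  common genes, direct PPIs between 7 and 6 seeds); the realized node
  overlap equals the planted common set exactly, by construction.
* **Expression.** 58 up/down and 48 down/up reciprocal genes (the
  published dataset-level counts) planted among concordant background
  genes, plus one perturbagen whose profile exactly negates the query.

Every generator is a pure function of (parameters, seed): identical
inputs give byte-identical outputs, which the suite verifies end-to-end
through disk.

## Numerical choices and degenerate inputs

* p-values parse into ordinary doubles (the smallest printed fixture
  value, 3.7e-151, is representable); comparisons always use the parsed
  value. Simulated p-values are floored at 1e-320 to stay within (0, 1].
* Summary statistics are serialized with 17 significant digits so
  write-then-read round-trips bit-exactly.
* Coordinates: GWAS positions are 1-based; gene models are stored
  half-open 0-based (BED convention) and converted at the point of
  comparison.
* Empty inputs are empty outputs, not errors (empty statistics file,
  empty GMT, empty seed set); truly malformed inputs (irreconcilable
  alleles, monomorphic SNPs in an LD query, a universe smaller than the
  union it must contain) raise informative errors.
* The pipeline configuration file is JSON rather than YAML, as no YAML
  parser is available in the supported dependency set; the substance —
  one file holding every threshold, echoed into each run's manifest — is
  unchanged.

## Worked example

```{r example}
ra <- table1_stats("RA")
sz <- table1_stats("SZ")
res <- suppressWarnings(run_scan(ra, sz, panel = NULL,
                                 genes = table1_gene_models()))
res
head(res$pleiotropic[c("snp_id", "or_a", "or_b", "gene", "region_class")])
```

Here the two sides of the packaged 18-SNP fixture are fed as the two
studies (self-pair mode: no panel, pairs form only between identical
ids). All 18 survive opposite-direction filtering and same-SNP
verification and map to 8 genes; 4 of those genes carry exonic SNPs.
The warning being suppressed is the palindromic-SNP notice — the fixture
contains A/T SNPs, which is precisely why they are retained rather than
dropped.

## Known limitations

* No colocalization, conditional analysis, fine-mapping, or polygenic
  correlation; the scan detects opposite marginal directions, which is
  why it deliberately labels its output *putative* pleiotropy.
* LD requires phased input (a haplotype matrix or phased VCF); there is
  no EM estimator for unphased genotypes, no D′, no LD-score machinery.
* PPI prediction is out of scope; novel edges are trusted labelled input.
* Enrichment p-values depend on the supplied GMT and universe and are not
  comparable to proprietary-suite outputs.
* The supplementary pair list behind the published count of 46
  opposite-direction pairs is not redistributable; the packaged
  46-pair object (`synthetic_opposite_pairs()`) reconstructs its reported
  composition (29 same-SNP of which 18 genic) with the 18 genic rows real
  and the rest synthetic, and tests the counting operation, not the
  original data.
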
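# Independent brute-force oracles used to cross-check the implementation.
# Each deliberately takes a different computational route than the package.

# r^2 by explicit enumeration of the 2x2 haplotype contingency table
oracle_r2 <- function(x, y) {
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  h <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / h
  pB <- (n11 + n01) / h
  D <- n11 / h - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# upper-tail hypergeometric by direct log-gamma term summation (log-sum-exp)
oracle_log10_hyper <- function(N, K, n, k) {
  i <- k:min(K, n)
  lt <- (lgamma(K + 1) - lgamma(i + 1) - lgamma(K - i + 1)) +
        (lgamma(N - K + 1) - lgamma(n - i + 1) - lgamma(N - K - n + i + 1)) -
        (lgamma(N + 1) - lgamma(n + 1) - lgamma(N - n + 1))
  m <- max(lt)
  (m + log(sum(exp(lt - m)))) / log(10)
}

# Benjamini-Hochberg step-up by the textbook sort / scale / cummin route
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# exhaustive bridge search: triple loop over seedsA x nodes x seedsB
oracle_bridges <- function(edges, seeds_a, seeds_b) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- unique(key(edges$gene_a, edges$gene_b))
  has_edge <- function(a, b) key(a, b) %in% ek
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  direct <- list(); two_step <- list(); common <- character()
  for (sa in intersect(seeds_a, nodes)) {
    for (sb in intersect(seeds_b, nodes)) {
      if (sa != sb && has_edge(sa, sb)) {
        direct[[length(direct) + 1L]] <- c(sa, sb)
      }
    }
  }
  for (m in setdiff(nodes, union(seeds_a, seeds_b))) {
    touches_a <- FALSE; touches_b <- FALSE
    for (sa in seeds_a) if (has_edge(m, sa)) touches_a <- TRUE
    for (sb in seeds_b) if (has_edge(m, sb)) touches_b <- TRUE
    if (touches_a && touches_b) {
      common <- c(common, m)
      for (sa in seeds_a) {
        for (sb in seeds_b) {
          if (has_edge(sa, m) && has_edge(m, sb)) {
            two_step[[length(two_step) + 1L]] <- c(sa, m, sb)
          }
        }
      }
    }
  }
  list(
    direct = if (length(direct)) do.call(rbind, direct) else
      matrix(character(), ncol = 2),
    common = sort(common),
    two_step = if (length(two_step)) do.call(rbind, two_step) else
      matrix(character(), ncol = 3))
}

# naive interval scan for gene-region classification
oracle_region_class <- function(pos, genes, flank_bp = 5000) {
  # pos is 1-based; gene coordinates half-open 0-based
  p0 <- pos - 1
  best <- list(class = "intergenic", gene = NA_character_, dist = Inf)
  rank <- c(exon = 1, intron = 2, flanking = 3, intergenic = 4)
  for (i in seq_len(nrow(genes))) {
    cls <- NULL
    if (p0 >= genes$tx_start[i] && p0 < genes$tx_end[i]) {
      cls <- "intron"
      es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
      for (j in seq_along(es)) {
        if (p0 >= es[j] && p0 < ee[j]) cls <- "exon"
      }
    } else if (p0 >= genes$tx_start[i] - flank_bp &&
               p0 < genes$tx_end[i] + flank_bp) {
      cls <- "flanking"
    }
    if (!is.null(cls)) {
      d <- abs(p0 + 0.5 - (genes$tx_start[i] + genes$tx_end[i]) / 2)
      better <- rank[cls] < rank[best$class] ||
        (rank[cls] == rank[best$class] &&
         (d < best$dist ||
          (d == best$dist && genes$gene_name[i] < best$gene)))
      if (better) best <- list(class = cls, gene = genes$gene_name[i],
                               dist = d)
    }
  }
  best
}

# small deterministic panel used across LD tests: known column structure
toy_panel <- function() {
  cols <- cbind(
    s1 = c(rep(0L, 10), rep(1L, 10)),
    s2 = c(rep(0L, 9), 1L, rep(1L, 10)),      # s1 with one flip: high r2
    s3 = rep(c(0L, 1L), 10),                  # independent of s1/s2
    s4 = c(rep(0L, 10), rep(1L, 10)))         # identical to s1
  variants <- data.frame(
    snp_id = colnames(cols), chrom = "6",
    pos = c(1000L, 2000L, 3000L, 4000L),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  haplotype_panel(variants, cols)
}

random_small_panel <- function(n_snps = 5, n_hap = 24) {
  repeat {
    m <- matrix(rbinom(n_hap * n_snps, 1L, runif(1, 0.2, 0.8)),
                nrow = n_hap)
    if (all(colMeans(m) > 0 & colMeans(m) < 1)) break
  }
  variants <- data.frame(
    snp_id = sprintf("v%02d", seq_len(n_snps)), chrom = "1",
    pos = seq_len(n_snps) * 100L, ref = "A", alt = "C",
    stringsAsFactors = FALSE)
  haplotype_panel(variants, m)
}

# minimal association-record constructor for harmonization tests
assoc <- function(snp_id, ea, oa, or, p = 1e-9, chrom = "6", pos = 1L) {
  list(snp_id = snp_id, chrom = chrom, pos = pos,
       effect_allele = ea, other_allele = oa,
       odds_ratio = or, p_value = p)
}
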
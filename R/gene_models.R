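#' Construct a gene-model table
#'
#' Transcript models with exon structure, stored half-open 0-based (BED
#' convention) internally; GWAS positions are 1-based and converted at the
#' point of comparison.
#'
#' @param gene_name,chrom,strand Character vectors.
#' @param tx_start,tx_end Integer vectors, half-open 0-based transcript
#'   bounds (`tx_start < tx_end`).
#' @param exon_starts,exon_ends Lists of integer vectors (half-open 0-based),
#'   one per gene; exons must lie within the transcript, be sorted and
#'   non-overlapping.
#' @return data.frame of class `gene_models` with list-columns `exon_starts`,
#'   `exon_ends`.
#' @export
gene_models <- function(gene_name, chrom, strand, tx_start, tx_end,
                        exon_starts, exon_ends) {
  n <- length(gene_name)
  stopifnot(length(tx_start) == n, length(tx_end) == n,
            length(exon_starts) == n, length(exon_ends) == n)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(strand) == 1) strand <- rep(strand, n)
  stopifnot(length(chrom) == n)
  for (i in seq_len(n)) {
    s <- as.integer(exon_starts[[i]]); e <- as.integer(exon_ends[[i]])
    if (length(s) != length(e) || any(s >= e)) {
      stop("malformed exons for ", gene_name[i])
    }
    if (any(s < tx_start[i]) || any(e > tx_end[i])) {
      stop("exons outside transcript for ", gene_name[i])
    }
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] < e[-length(e)])) {
      stop("exons must be sorted and non-overlapping for ", gene_name[i])
    }
    exon_starts[[i]] <- s; exon_ends[[i]] <- e
  }
  if (any(tx_start >= tx_end)) stop("tx_start must be < tx_end")
  out <- data.frame(gene_name = gene_name, chrom = as.character(chrom),
                    strand = strand,
                    tx_start = as.integer(tx_start),
                    tx_end = as.integer(tx_end),
                    stringsAsFactors = FALSE)
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Read gene models from a BED12 file
#'
#' Uses `rtracklayer::import`; block fields carry the exon structure. BED
#' files without blocks are treated as single-exon transcripts.
#'
#' @param path Path to a BED file.
#' @return [gene_models()].
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read BED gene models")
  }
  gr <- rtracklayer::import(path)
  tx_start <- GenomicRanges::start(gr) - 1L  # back to 0-based half-open
  tx_end <- GenomicRanges::end(gr)
  mc <- S4Vectors::mcols(gr)
  if ("blocks" %in% names(mc)) {
    # blocks are 1-based ranges relative to the feature start
    exon_starts <- lapply(seq_along(gr), function(i) {
      tx_start[i] + IRanges::start(mc$blocks[[i]]) - 1L
    })
    exon_ends <- lapply(seq_along(gr), function(i) {
      tx_start[i] + IRanges::end(mc$blocks[[i]])
    })
  } else {
    exon_starts <- as.list(tx_start)
    exon_ends <- as.list(tx_end)
  }
  gene_models(
    gene_name = mc$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    tx_start = tx_start, tx_end = tx_end,
    exon_starts = exon_starts, exon_ends = exon_ends
  )
}

#' Write gene models as BED12
#'
#' @param models [gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    strand <- models$strand[i]
    if (!strand %in% c("+", "-")) strand <- "+"
    paste(models$chrom[i], models$tx_start[i], models$tx_end[i],
          models$gene_name[i], 0, strand,
          models$tx_start[i], models$tx_end[i], "0",
          length(s),
          paste0(paste(e - s, collapse = ","), ","),
          paste0(paste(s - models$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.models_granges <- function(models) {
  n_ex <- lengths(models$exon_starts)
  list(
    tx = GenomicRanges::GRanges(
      models$chrom,
      IRanges::IRanges(start = models$tx_start + 1L, end = models$tx_end),
      gene = models$gene_name
    ),
    exons = GenomicRanges::GRanges(
      rep(models$chrom, n_ex),
      IRanges::IRanges(start = unlist(models$exon_starts) + 1L,
                       end = unlist(models$exon_ends)),
      gene = rep(models$gene_name, n_ex)
    )
  )
}

#' Map SNPs to gene regions with flanking zones
#'
#' Classifies each SNP position against a set of transcript models:
#' `exon` if it falls in an exon interval, `intron` if inside the transcript
#' but not exonic, `flanking` if within `flank_bp` outside the transcript
#' (both sides), `intergenic` otherwise. When several genes hit one SNP, the
#' primary gene is chosen by class priority exon > intron > flanking, ties
#' broken by distance to the transcript midpoint (then gene name); all hits
#' are kept in `all_hits` as `gene:class` entries.
#'
#' @param records data.frame with at least `snp_id`, `chrom`, `pos`
#'   (1-based).
#' @param genes [gene_models()]. May be empty.
#' @param flank_bp Flank width in bp (default 5000).
#' @return `records` with added columns `gene` (NA when intergenic),
#'   `region_class`, `all_hits`.
#' @export
map_to_genes <- function(records, genes, flank_bp = 5000) {
  stopifnot(flank_bp >= 0)
  records <- as.data.frame(records)
  records$gene <- rep(NA_character_, nrow(records))
  records$region_class <- rep("intergenic", nrow(records))
  records$all_hits <- rep("", nrow(records))
  if (nrow(records) == 0 || is.null(genes) || nrow(genes) == 0) {
    return(records)
  }
  unknown <- setdiff(unique(records$chrom), unique(genes$chrom))
  if (length(unknown)) {
    warning("chromosome(s) absent from gene models, classified intergenic: ",
            paste(unknown, collapse = ", "))
  }

  grs <- .models_granges(genes)
  snps <- GenomicRanges::GRanges(records$chrom,
                                 IRanges::IRanges(records$pos, records$pos))
  flank <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$tx_start + 1L - flank_bp, 1L),
                     end = genes$tx_end + flank_bp),
    gene = genes$gene_name
  )

  hit_tab <- function(subject, class) {
    # seqlevel mismatches are already reported above; silence the GRanges
    # "no sequence levels in common" chatter
    ov <- suppressWarnings(GenomicRanges::findOverlaps(snps, subject))
    qh <- S4Vectors::queryHits(ov)
    data.frame(rec = qh, gene = subject$gene[S4Vectors::subjectHits(ov)],
               class = rep_len(class, length(qh)), stringsAsFactors = FALSE)
  }
  hits <- rbind(hit_tab(grs$exons, "exon"),
                hit_tab(grs$tx, "intron"),
                hit_tab(flank, "flanking"))
  if (nrow(hits) == 0) return(records)

  # one row per (record, gene), best class for that gene
  prio <- c(exon = 1L, intron = 2L, flanking = 3L)
  hits$rank <- prio[hits$class]
  hits <- hits[order(hits$rec, hits$gene, hits$rank), , drop = FALSE]
  hits <- hits[!duplicated(hits[c("rec", "gene")]), , drop = FALSE]

  mid <- (genes$tx_start + genes$tx_end) / 2
  names(mid) <- genes$gene_name
  hits$dist_mid <- abs(records$pos[hits$rec] - 0.5 - mid[hits$gene])

  hits <- hits[order(hits$rec, hits$rank, hits$dist_mid, hits$gene), ,
               drop = FALSE]
  for (r in unique(hits$rec)) {
    h <- hits[hits$rec == r, , drop = FALSE]
    records$gene[r] <- h$gene[1]
    records$region_class[r] <- h$class[1]
    records$all_hits[r] <- paste(paste0(h$gene, ":", h$class), collapse = ";")
  }
  records
}
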
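#' Default column mapping for summary-statistics files
#'
#' Maps the internal field names of a SNP association record to the column
#' headers found in a delimited summary-statistics file. Two GWAS releases
#' rarely share headers, so [read_summary_stats()] takes one of these per
#' file.
#'
#' @param ... named overrides, e.g. `odds_ratio = "OR"`, `p_value = "P"`.
#' @return Named character vector mapping internal field -> file column.
#' @export
#' @examples
#' stats_col_map(snp_id = "SNP", odds_ratio = "OR", p_value = "P")
stats_col_map <- function(...) {
  map <- c(
    snp_id        = "snp_id",
    chrom         = "chrom",
    pos           = "pos",
    effect_allele = "effect_allele",
    other_allele  = "other_allele",
    odds_ratio    = "odds_ratio",
    p_value       = "p_value"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(map))
    if (length(bad)) {
      stop("unknown summary-statistics fields in column map: ",
           paste(bad, collapse = ", "))
    }
    map[names(over)] <- over
  }
  map
}

#' Read GWAS summary statistics for one trait
#'
#' Reads a delimited (TSV/CSV) table of per-SNP association results and
#' validates each row against the SNP-association contract: odds ratio a
#' positive real, p-value in (0, 1], a 1-based position, and two distinct
#' single-nucleotide alleles. Rows violating any of these are dropped and
#' returned in a rejects report rather than silently discarded, because the
#' downstream opposite-direction counts depend on how many records survive
#' ingest.
#'
#' @param path Path to the delimited file. An empty file yields an empty
#'   table (not an error).
#' @param trait Trait label stored on every record (e.g. `"RA"`, `"SZ"`).
#' @param col_map Column mapping from [stats_col_map()].
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `odds_ratio`, `p_value`, `trait`.
#'   Attributes: `rejects` (a data.frame of dropped raw rows with a `reason`
#'   column) and `n_rejected`.
#' @seealso [write_summary_stats()], [harmonize_alleles()]
#' @export
read_summary_stats <- function(path, trait, col_map = stats_col_map()) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  empty <- data.frame(
    snp_id = character(), chrom = character(), pos = integer(),
    effect_allele = character(), other_allele = character(),
    odds_ratio = numeric(), p_value = numeric(), trait = character(),
    stringsAsFactors = FALSE
  )
  if (file.size(path) == 0) {
    attr(empty, "rejects") <- empty[, 0]
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  raw <- data.table::fread(path, colClasses = "character", data.table = FALSE)
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing)) {
    stop("summary-statistics file ", path,
         " lacks mapped column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    attr(empty, "rejects") <- raw[0, , drop = FALSE]
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }

  out <- data.frame(
    snp_id        = raw[[col_map[["snp_id"]]]],
    chrom         = raw[[col_map[["chrom"]]]],
    pos           = suppressWarnings(as.integer(raw[[col_map[["pos"]]]])),
    effect_allele = toupper(raw[[col_map[["effect_allele"]]]]),
    other_allele  = toupper(raw[[col_map[["other_allele"]]]]),
    odds_ratio    = suppressWarnings(as.numeric(raw[[col_map[["odds_ratio"]]]])),
    p_value       = suppressWarnings(as.numeric(raw[[col_map[["p_value"]]]])),
    trait         = trait,
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, nrow(out))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(out$odds_ratio) | out$odds_ratio <= 0, "bad_odds_ratio")
  reason <- bad(is.na(out$p_value) | out$p_value <= 0 | out$p_value > 1, "bad_p_value")
  reason <- bad(is.na(out$pos) | out$pos < 1, "bad_position")
  reason <- bad(!out$effect_allele %in% c("A", "C", "G", "T") |
                !out$other_allele %in% c("A", "C", "G", "T"), "bad_allele")
  reason <- bad(out$effect_allele == out$other_allele, "identical_alleles")
  reason <- bad(is.na(out$snp_id) | out$snp_id == "", "missing_snp_id")

  keep <- is.na(reason)
  rejects <- raw[!keep, , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- reason[!keep]
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rejects") <- rejects
  attr(res, "n_rejected") <- sum(!keep)
  res
}

#' Write summary statistics to TSV
#'
#' Numeric columns are serialized with 17 significant digits so a
#' read-after-write round-trip reproduces the in-memory doubles bit-exactly.
#'
#' @param stats Table from [read_summary_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- stats
  for (col in c("odds_ratio", "p_value")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a rejects report
#'
#' @param stats Table from [read_summary_stats()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rejects_report <- function(stats, path) {
  rej <- attr(stats, "rejects")
  if (is.null(rej)) rej <- data.frame()
  data.table::fwrite(rej, path, sep = "\t", quote = FALSE)
  invisible(path)
}

.complement <- function(x) chartr("ACGT", "TGCA", x)

.is_palindromic <- function(ea, oa) ea == .complement(oa)

#' Align two association records of one variant onto a shared effect allele
#'
#' Two studies may report the same physical SNP on different strands or with
#' effect/other alleles swapped. Opposite-direction calls are only meaningful
#' after both odds ratios are expressed per the same allele, so this puts
#' record `b` into `a`'s orientation:
#'
#' * alleles identical: kept as read;
#' * alleles swapped (b's effect allele is a's other allele): b's OR is
#'   inverted (`1/OR`) and `flip_applied = TRUE`;
#' * alleles match only after complementing: treated as a strand flip and
#'   aligned the same way;
#' * anything else (e.g. A/G vs A/C): an irreconcilable mismatch, an error.
#'
#' Palindromic (A/T, C/G) SNPs cannot be strand-resolved from alleles alone;
#' they are flagged `ambiguous_strand = TRUE` and aligned as read. Callers
#' may drop them via the `drop_ambiguous` option of [run_scan()].
#'
#' @param a,b Single SNP-association records (one-row data.frames or lists
#'   with fields `snp_id`, `effect_allele`, `other_allele`, `odds_ratio`,
#'   `p_value`). Both must describe the same physical variant.
#' @return A list of class `harmonized_pair`: `snp_id`, `effect_allele`,
#'   `other_allele`, `or_trait_a`, `p_trait_a`, `or_trait_b`, `p_trait_b`,
#'   `flip_applied`, `ambiguous_strand`.
#' @export
#' @examples
#' a <- list(snp_id = "rs1", effect_allele = "T", other_allele = "C",
#'           odds_ratio = 0.90, p_value = 1e-10)
#' b <- list(snp_id = "rs1", effect_allele = "C", other_allele = "T",
#'           odds_ratio = 1.10, p_value = 1e-8)
#' harmonize_alleles(a, b)$or_trait_b  # 1/1.10
harmonize_alleles <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  ea <- toupper(a$effect_allele); oa <- toupper(a$other_allele)
  eb <- toupper(b$effect_allele); ob <- toupper(b$other_allele)

  or_b <- b$odds_ratio
  flip <- FALSE
  if (eb == ea && ob == oa) {
    # as read
  } else if (eb == oa && ob == ea) {
    or_b <- 1 / or_b
    flip <- TRUE
  } else if (.complement(eb) == ea && .complement(ob) == oa) {
    # pure strand flip: alleles relabelled, OR orientation unchanged
  } else if (.complement(eb) == oa && .complement(ob) == ea) {
    or_b <- 1 / or_b
    flip <- TRUE
  } else {
    stop("irreconcilable alleles for ", a$snp_id, ": ",
         ea, "/", oa, " vs ", eb, "/", ob)
  }

  structure(list(
    snp_id = a$snp_id,
    effect_allele = ea,
    other_allele = oa,
    or_trait_a = a$odds_ratio,
    p_trait_a = a$p_value,
    or_trait_b = or_b,
    p_trait_b = b$p_value,
    flip_applied = flip,
    ambiguous_strand = .is_palindromic(ea, oa)
  ), class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("<harmonized_pair> %s [%s/%s] OR_a=%.4g OR_b=%.4g%s%s\n",
              x$snp_id, x$effect_allele, x$other_allele,
              x$or_trait_a, x$or_trait_b,
              if (x$flip_applied) " (flipped)" else "",
              if (x$ambiguous_strand) " [palindromic]" else ""))
  invisible(x)
}
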
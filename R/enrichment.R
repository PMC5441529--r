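#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated `name`, `description`,
#' then member genes. (Parsed directly; no GMT reader ships with the
#' installed stack.)
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  out
}

#' Write pathway gene sets to a GMT file
#'
#' @param gmt Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gmt, path) {
  writeLines(vapply(names(gmt), function(nm) {
    paste(c(nm, "na", gmt[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Hypergeometric pathway enrichment with Benjamini-Hochberg correction
#'
#' For each pathway with at least one hit, computes the upper-tail
#' hypergeometric probability of drawing that many pathway members in a
#' sample of `length(gene_set)` genes from a universe of `universe_n`, then
#' adjusts across all returned pathways with the BH step-up procedure. All
#' hit pathways are returned regardless of significance, so callers can
#' apply their own cutoff.
#'
#' @param gene_set Character vector of query genes (e.g. an interactome's
#'   nodes).
#' @param gmt Named list of pathways from [read_gmt()].
#' @param universe_n Universe size. Default: the number of unique genes in
#'   the GMT unioned with the query set (so the universe always covers both;
#'   override to a fixed genome-wide count for comparability across runs).
#' @return data.frame of class `pathway_results`: `pathway_id`, `n_genes`,
#'   `n_hits`, `p_raw`, `p_bh`, `genes_hit` (list-column), sorted by
#'   `p_raw`; attribute `universe_n`.
#' @export
enrich <- function(gene_set, gmt, universe_n = NULL) {
  gene_set <- unique(as.character(gene_set))
  if (length(gmt) == 0) {
    out <- data.frame(pathway_id = character(), n_genes = integer(),
                      n_hits = integer(), p_raw = numeric(),
                      p_bh = numeric(), stringsAsFactors = FALSE)
    out$genes_hit <- list()
    class(out) <- c("pathway_results", "data.frame")
    return(out)
  }
  if (is.null(universe_n)) {
    universe_n <- length(unique(c(unlist(gmt), gene_set)))
  }
  biggest <- max(vapply(gmt, function(g)
    length(union(g, gene_set)), 0L))
  if (universe_n < biggest) {
    stop("universe_n (", universe_n,
         ") smaller than |gene_set union pathway| (", biggest, ")")
  }
  hits <- lapply(gmt, intersect, gene_set)
  k <- lengths(hits)
  keep <- k > 0
  K <- lengths(gmt)[keep]
  k <- k[keep]
  n <- length(gene_set)
  p_raw <- stats::phyper(k - 1, K, universe_n - K, n, lower.tail = FALSE)
  out <- data.frame(pathway_id = names(gmt)[keep],
                    n_genes = unname(K), n_hits = unname(k),
                    p_raw = unname(p_raw),
                    p_bh = unname(stats::p.adjust(p_raw, method = "BH")),
                    stringsAsFactors = FALSE)
  out$genes_hit <- unname(hits[keep])
  out <- out[order(out$p_raw, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universe_n") <- universe_n
  class(out) <- c("pathway_results", "data.frame")
  out
}

#' Merge two interactomes' pathway tables
#'
#' Produces one row per pathway hit in either result, partitioning the hit
#' genes into exclusive-to-A, common, and exclusive-to-B (pairwise disjoint;
#' union = hits in A plus hits in B). A pathway absent from one side gets
#' that side's p = 1 and an empty hit set. Rows are sorted by
#' `min(p_a, p_b)`.
#'
#' @param res_a,res_b [enrich()] results computed against the same GMT.
#' @return data.frame: `pathway_id`, `p_a`, `p_b`, counts
#'   `n_exclusive_a`/`n_common`/`n_exclusive_b` (bar-plot-ready), and
#'   list-columns `genes_exclusive_a`, `genes_common`, `genes_exclusive_b`.
#' @export
merge_pathway_tables <- function(res_a, res_b) {
  ids <- union(res_a$pathway_id, res_b$pathway_id)
  rows <- lapply(ids, function(id) {
    ia <- match(id, res_a$pathway_id)
    ib <- match(id, res_b$pathway_id)
    hits_a <- if (is.na(ia)) character() else res_a$genes_hit[[ia]]
    hits_b <- if (is.na(ib)) character() else res_b$genes_hit[[ib]]
    list(pathway_id = id,
         p_a = if (is.na(ia)) 1 else res_a$p_bh[ia],
         p_b = if (is.na(ib)) 1 else res_b$p_bh[ib],
         excl_a = sort(setdiff(hits_a, hits_b)),
         common = sort(intersect(hits_a, hits_b)),
         excl_b = sort(setdiff(hits_b, hits_a)))
  })
  out <- data.frame(
    pathway_id = vapply(rows, `[[`, "", "pathway_id"),
    p_a = vapply(rows, `[[`, 0, "p_a"),
    p_b = vapply(rows, `[[`, 0, "p_b"),
    n_exclusive_a = vapply(rows, function(r) length(r$excl_a), 0L),
    n_common = vapply(rows, function(r) length(r$common), 0L),
    n_exclusive_b = vapply(rows, function(r) length(r$excl_b), 0L),
    stringsAsFactors = FALSE)
  out$genes_exclusive_a <- lapply(rows, `[[`, "excl_a")
  out$genes_common <- lapply(rows, `[[`, "common")
  out$genes_exclusive_b <- lapply(rows, `[[`, "excl_b")
  out <- out[order(pmin(out$p_a, out$p_b), out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a pathway-results or merged table as TSV
#'
#' List-columns of gene sets are collapsed with commas.
#'
#' @param tab Table from [enrich()] or [merge_pathway_tables()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_table <- function(tab, path) {
  out <- as.data.frame(tab)
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      out[[col]] <- vapply(out[[col]], paste, "", collapse = ",")
    }
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
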
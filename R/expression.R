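#' Read a differential-expression signature
#'
#' Accepts two-column (`gene`, signed `score`) or three-column (`gene`,
#' `direction`, `score`) TSVs. Directions are derived from the sign of the
#' score with an optional dead-zone: `|score| <= epsilon` is called neither
#' up nor down (mirroring threshold-based DE calls).
#'
#' @param path Path to the signature TSV.
#' @param epsilon Dead-zone half-width on the score (default 0: any nonzero
#'   score gets a direction).
#' @return data.frame of class `expression_signature`: `gene`, `score`,
#'   `direction` (`up`/`down`/`flat`), one row per gene.
#' @export
read_signature <- function(path, epsilon = 0) {
  raw <- data.table::fread(path, data.table = FALSE)
  if (ncol(raw) >= 3 && !is.numeric(raw[[2]])) {
    df <- data.frame(gene = as.character(raw[[1]]),
                     score = as.numeric(raw[[3]]), stringsAsFactors = FALSE)
  } else {
    df <- data.frame(gene = as.character(raw[[1]]),
                     score = as.numeric(raw[[2]]), stringsAsFactors = FALSE)
  }
  expression_signature(df$gene, df$score, epsilon = epsilon)
}

#' Construct an expression signature from genes and signed scores
#'
#' @param gene Character vector (must be unique).
#' @param score Signed numeric scores.
#' @param epsilon Dead-zone half-width for direction calls (default 0).
#' @return data.frame of class `expression_signature`.
#' @export
expression_signature <- function(gene, score, epsilon = 0) {
  stopifnot(length(gene) == length(score), epsilon >= 0)
  if (anyDuplicated(gene)) stop("duplicate genes in signature")
  direction <- ifelse(abs(score) <= epsilon, "flat",
                      ifelse(score > 0, "up", "down"))
  out <- data.frame(gene = as.character(gene), score = as.numeric(score),
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("expression_signature", "data.frame")
  out
}

#' Genes with reciprocal (opposite-direction) expression in two diseases
#'
#' Intersects the two signatures' gene universes and returns the genes
#' up-regulated in A and down-regulated in B, and vice versa. Genes absent
#' from either signature, or flat in either, are ignored.
#'
#' @param sig_a,sig_b [expression_signature()] objects.
#' @return List with `up_a_down_b` and `down_a_up_b` (sorted character
#'   vectors).
#' @export
reciprocal_genes <- function(sig_a, sig_b) {
  shared <- intersect(sig_a$gene, sig_b$gene)
  da <- sig_a$direction[match(shared, sig_a$gene)]
  db <- sig_b$direction[match(shared, sig_b$gene)]
  list(
    up_a_down_b = sort(shared[da == "up" & db == "down"]),
    down_a_up_b = sort(shared[da == "down" & db == "up"])
  )
}

#' Score a query signature against perturbagen signatures
#'
#' Connectivity-style scoring: for each perturbagen column, the Spearman
#' rank correlation between the query's signed scores and the perturbagen's
#' scores over their shared genes. Perturbagens sharing fewer than
#' `min_genes` genes with the query are skipped with a warning. Strong
#' negative scores flag signature-reversing (potentially therapeutic)
#' perturbagens.
#'
#' @param query [expression_signature()].
#' @param perturbagen_matrix Numeric matrix, gene rows (rownames) x
#'   perturbagen columns (colnames).
#' @param min_genes Minimum shared genes per perturbagen (default 3).
#' @return data.frame sorted by descending score: `perturbagen_id`, `score`
#'   in \[-1, 1\], `n_genes_used`.
#' @export
connectivity_score <- function(query, perturbagen_matrix, min_genes = 3) {
  stopifnot(min_genes >= 2)
  mat <- as.matrix(perturbagen_matrix)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("perturbagen matrix needs gene rownames and perturbagen colnames")
  }
  shared <- intersect(query$gene, rownames(mat))
  if (length(shared) < min_genes) {
    stop("fewer than ", min_genes, " genes shared between query and matrix")
  }
  q <- query$score[match(shared, query$gene)]
  res <- lapply(colnames(mat), function(pid) {
    col <- mat[shared, pid]
    ok <- !is.na(col)
    if (sum(ok) < min_genes) {
      warning("perturbagen ", pid, " skipped: fewer than ", min_genes,
              " shared genes")
      return(NULL)
    }
    data.frame(perturbagen_id = pid,
               score = stats::cor(q[ok], col[ok], method = "spearman"),
               n_genes_used = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(perturbagen_id = character(), score = numeric(),
                      n_genes_used = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(-out$score, out$perturbagen_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a perturbagen score matrix (genes x perturbagens) from TSV
#'
#' First column is the gene symbol; remaining columns are perturbagens.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene rownames.
#' @export
read_perturbagen_matrix <- function(path) {
  raw <- data.table::fread(path, data.table = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  m
}
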
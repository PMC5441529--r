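#' Read a tagged PPI edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `tag` (tag in known|novel). Rows
#' with an empty gene symbol or an unknown tag are rejected and counted.
#'
#' @param path Path to the edge TSV.
#' @return data.frame `gene_a`, `gene_b`, `tag` with attribute `n_rejected`.
#' @export
read_edge_list <- function(path) {
  raw <- data.table::fread(path, data.table = FALSE, colClasses = "character")
  names(raw)[1:3] <- c("gene_a", "gene_b", "tag")
  ok <- !is.na(raw$gene_a) & raw$gene_a != "" &
        !is.na(raw$gene_b) & raw$gene_b != "" &
        raw$tag %in% c("known", "novel")
  out <- raw[ok, c("gene_a", "gene_b", "tag"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!ok)
  out
}

.canon_edges <- function(edges) {
  # undirected canonical form + symmetric dedup; self-loops dropped
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  keep <- a != b
  e <- data.frame(gene_a = a[keep], gene_b = b[keep], tag = edges$tag[keep],
                  stringsAsFactors = FALSE)
  e <- e[!duplicated(paste(e$gene_a, e$gene_b)), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Build a disease interactome from seed genes and tagged PPI edges
#'
#' An interactome is the graph of a disease's associated (seed) genes plus
#' every protein linked to a seed by a known or novel (computationally
#' predicted, supplied as labelled input) interaction. Only edges incident
#' to at least one seed are retained; edges between two non-seeds are
#' dropped and counted. Edges are undirected, deduplicated under symmetry,
#' and self-loops are removed.
#'
#' @param seeds Character vector of disease-associated gene symbols.
#' @param edges data.frame `gene_a`, `gene_b`, `tag` (known|novel), e.g.
#'   from [read_edge_list()].
#' @param name Label for printing.
#' @return Object of class `interactome`: `seeds`, `edges`, `interactors`
#'   (non-seed nodes), `nodes`, and per-tag edge counts.
#' @export
build_interactome <- function(seeds, edges, name = "interactome") {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0 || nrow(edges) == 0) {
    e <- .canon_edges(edges[0, , drop = FALSE])
    return(structure(list(name = name, seeds = seeds, edges = e,
                          interactors = character(), nodes = seeds,
                          n_known = 0L, n_novel = 0L, n_dropped = 0L),
                     class = "interactome"))
  }
  e <- .canon_edges(edges)
  touches <- e$gene_a %in% seeds | e$gene_b %in% seeds
  dropped <- sum(!touches)
  e <- e[touches, , drop = FALSE]
  nodes <- unique(c(seeds, e$gene_a, e$gene_b))
  structure(list(
    name = name, seeds = seeds, edges = e,
    interactors = setdiff(nodes, seeds), nodes = nodes,
    n_known = sum(e$tag == "known"), n_novel = sum(e$tag == "novel"),
    n_dropped = dropped
  ), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome '%s'> %d seeds, %d interactors, %d known + %d novel PPIs\n",
              x$name, length(x$seeds), length(x$interactors),
              x$n_known, x$n_novel))
  invisible(x)
}

#' Upper-tail hypergeometric overlap probability, log-space
#'
#' `P(X >= k)` for the overlap of a size-`K` and a size-`n` set drawn from a
#' universe of `N`. Computed with `phyper(log.p = TRUE)` so probabilities far
#' below double underflow (the interactome overlaps here sit near 1e-75) are
#' carried as log10 values.
#'
#' @param universe_n,size_a,size_b,overlap_k The (N, K, n, k) record.
#' @return Object of class `overlap_test`: the four sizes, `p_tail` (linear;
#'   0 when below ~1e-308) and `log10_p`.
#' @export
hypergeom_overlap <- function(universe_n, size_a, size_b, overlap_k) {
  stopifnot(overlap_k >= 0, overlap_k <= min(size_a, size_b),
            size_a <= universe_n, size_b <= universe_n)
  lp <- stats::phyper(overlap_k - 1, size_a, universe_n - size_a, size_b,
                      lower.tail = FALSE, log.p = TRUE)
  structure(list(universe_n = universe_n, size_a = size_a, size_b = size_b,
                 overlap_k = overlap_k,
                 p_tail = exp(lp), log10_p = lp / log(10)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("<overlap_test> N=%d K=%d n=%d k=%d  P(X>=k) = %.4g (log10 = %.4f)\n",
              x$universe_n, x$size_a, x$size_b, x$overlap_k,
              x$p_tail, x$log10_p))
  invisible(x)
}

#' Hypergeometric overlap between two interactomes
#'
#' Compares the two node sets (seeds plus interactors by default, the
#' convention matching the published 98+1960 / 77+968 / 316 accounting;
#' `mode = "interactors"` restricts to non-seed interactors).
#'
#' @param net_a,net_b [build_interactome()] objects.
#' @param universe_n Size of the gene universe (default 20000, roughly the
#'   human protein-coding gene count; must be at least the size of the two
#'   node sets' union).
#' @param mode `"all"` (seeds + interactors) or `"interactors"`.
#' @return [hypergeom_overlap()] result with an added `common_genes` field.
#' @export
overlap_test <- function(net_a, net_b, universe_n = 20000,
                         mode = c("all", "interactors")) {
  mode <- match.arg(mode)
  set_a <- if (mode == "all") net_a$nodes else net_a$interactors
  set_b <- if (mode == "all") net_b$nodes else net_b$interactors
  if (universe_n < length(union(set_a, set_b))) {
    stop("universe_n (", universe_n, ") smaller than the union of the two ",
         "node sets (", length(union(set_a, set_b)), ")")
  }
  common <- intersect(set_a, set_b)
  res <- hypergeom_overlap(universe_n, length(set_a), length(set_b),
                           length(common))
  res$common_genes <- sort(common)
  res
}

.union_graph <- function(net_a, net_b) {
  e <- rbind(net_a$edges, net_b$edges)
  .canon_edges(e)
}

.neighbors <- function(edges, node) {
  unique(c(edges$gene_b[edges$gene_a %in% node],
           edges$gene_a[edges$gene_b %in% node]))
}

#' Enumerate bridges between two interactomes
#'
#' On the union graph of both edge sets, reports (i) direct edges joining a
#' seed of A to a seed of B, (ii) common interactors: non-seed nodes
#' adjacent to at least one seed of each side, and (iii) every two-step path
#' `seedA - intermediate - seedB` through such intermediates, enumerated
#' exhaustively.
#'
#' @param net_a,net_b [build_interactome()] objects.
#' @return List of class `bridge_report`: `direct_edges` (data.frame
#'   `seed_a`, `seed_b`), `common_interactors` (character),
#'   `two_step_paths` (data.frame `seed_a`, `intermediate`, `seed_b`).
#' @export
find_bridges <- function(net_a, net_b) {
  edges <- .union_graph(net_a, net_b)
  sa <- net_a$seeds; sb <- net_b$seeds
  all_seeds <- union(sa, sb)

  in_a <- edges$gene_a %in% sa | edges$gene_b %in% sa
  in_b <- edges$gene_a %in% sb | edges$gene_b %in% sb
  direct <- edges[in_a & in_b, , drop = FALSE]
  direct_edges <- data.frame(
    seed_a = ifelse(direct$gene_a %in% sa, direct$gene_a, direct$gene_b),
    seed_b = ifelse(direct$gene_a %in% sb, direct$gene_a, direct$gene_b),
    stringsAsFactors = FALSE)
  direct_edges <- direct_edges[order(direct_edges$seed_a, direct_edges$seed_b), ,
                               drop = FALSE]
  rownames(direct_edges) <- NULL

  g <- igraph::graph_from_data_frame(edges[c("gene_a", "gene_b")],
                                     directed = FALSE)
  nodes <- igraph::V(g)$name
  candidates <- setdiff(nodes, all_seeds)
  paths <- list()
  common <- character()
  for (m in candidates) {
    nb <- igraph::V(g)$name[igraph::neighbors(g, m)]
    na_ <- intersect(nb, sa)
    nb_ <- intersect(nb, sb)
    if (length(na_) && length(nb_)) {
      common <- c(common, m)
      paths[[length(paths) + 1L]] <- data.frame(
        seed_a = rep(na_, times = length(nb_)),
        intermediate = m,
        seed_b = rep(nb_, each = length(na_)),
        stringsAsFactors = FALSE)
    }
  }
  two_step <- if (length(paths)) do.call(rbind, paths) else
    data.frame(seed_a = character(), intermediate = character(),
               seed_b = character(), stringsAsFactors = FALSE)
  two_step <- two_step[order(two_step$seed_a, two_step$intermediate,
                             two_step$seed_b), , drop = FALSE]
  rownames(two_step) <- NULL

  structure(list(direct_edges = direct_edges,
                 common_interactors = sort(common),
                 two_step_paths = two_step),
            class = "bridge_report")
}

#' @export
print.bridge_report <- function(x, ...) {
  cat(sprintf("<bridge_report> %d direct edges, %d common interactors, %d two-step paths\n",
              nrow(x$direct_edges), length(x$common_interactors),
              nrow(x$two_step_paths)))
  invisible(x)
}

#' Connectivity of a candidate gene set to two disease interactomes
#'
#' For each candidate (e.g. a gene harboring a putatively pleiotropic SNP),
#' counts its interactors in its own edge list, the disease-A and disease-B
#' seeds it reaches through exactly one intermediate interactor, and the
#' interactors it shares with each interactome's node set. Candidates with
#' no edges are reported as isolated with zero counts.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param cand_edges Tagged edge data.frame for the candidates (`gene_a`,
#'   `gene_b`, `tag`).
#' @param net_a,net_b [build_interactome()] objects.
#' @return List of class `candidate_connectivity`: `per_candidate`
#'   (data.frame with counts and isolation flags), `reached_seeds_a`,
#'   `reached_seeds_b`, `shared_interactors_a`, `shared_interactors_b`
#'   (character vectors over all candidates), `bridging_interactors`
#'   (candidate interactors adjacent to a seed of either net).
#' @export
candidate_connectivity <- function(candidates, cand_edges, net_a, net_b) {
  candidates <- unique(as.character(candidates))
  ce <- .canon_edges(cand_edges)
  per <- lapply(candidates, function(cand) {
    nb <- .neighbors(ce, cand)
    # seeds reachable via exactly one intermediate: cand - m - seed, where
    # cand-m is a candidate edge and m-seed an edge of the disease net
    mids <- setdiff(nb, c(net_a$seeds, net_b$seeds))
    seeds_a <- unique(unlist(lapply(mids, function(m)
      intersect(.neighbors(net_a$edges, m), net_a$seeds))))
    seeds_b <- unique(unlist(lapply(mids, function(m)
      intersect(.neighbors(net_b$edges, m), net_b$seeds))))
    list(candidate = cand, n_interactors = length(nb),
         isolated = length(nb) == 0,
         shared_a = intersect(nb, net_a$nodes),
         shared_b = intersect(nb, net_b$nodes),
         seeds_a = as.character(seeds_a), seeds_b = as.character(seeds_b))
  })
  tab <- data.frame(
    candidate = vapply(per, `[[`, "", "candidate"),
    n_interactors = vapply(per, `[[`, 0L, "n_interactors"),
    isolated = vapply(per, `[[`, TRUE, "isolated"),
    n_seeds_a_two_step = vapply(per, function(p) length(p$seeds_a), 0L),
    n_seeds_b_two_step = vapply(per, function(p) length(p$seeds_b), 0L),
    n_shared_interactors_a = vapply(per, function(p) length(p$shared_a), 0L),
    n_shared_interactors_b = vapply(per, function(p) length(p$shared_b), 0L),
    stringsAsFactors = FALSE)
  structure(list(
    per_candidate = tab,
    reached_seeds_a = sort(unique(unlist(lapply(per, `[[`, "seeds_a")))),
    reached_seeds_b = sort(unique(unlist(lapply(per, `[[`, "seeds_b")))),
    shared_interactors_a = sort(unique(unlist(lapply(per, `[[`, "shared_a")))),
    shared_interactors_b = sort(unique(unlist(lapply(per, `[[`, "shared_b"))))
  ), class = "candidate_connectivity")
}

#' @export
print.candidate_connectivity <- function(x, ...) {
  cat(sprintf("<candidate_connectivity> %d candidates reach %d A-seeds and %d B-seeds via one intermediate\n",
              nrow(x$per_candidate), length(x$reached_seeds_a),
              length(x$reached_seeds_b)))
  invisible(x)
}

#' Export an interactome as SIF plus node/edge attribute tables
#'
#' @param net [build_interactome()] object.
#' @param prefix Output path prefix; writes `<prefix>.sif`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`.
#' @return `prefix`, invisibly.
#' @export
export_interactome <- function(net, prefix) {
  writeLines(paste(net$edges$gene_a, "pp", net$edges$gene_b, sep = "\t"),
             paste0(prefix, ".sif"))
  data.table::fwrite(
    data.frame(gene = net$nodes, is_seed = net$nodes %in% net$seeds),
    paste0(prefix, "_nodes.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(net$edges, paste0(prefix, "_edges.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(prefix)
}
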
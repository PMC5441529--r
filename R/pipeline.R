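#' Read a pipeline configuration file
#'
#' JSON with any of the [scan_config()] fields plus optional
#' `universe_n` (interactome overlap), `enrich_universe_n`, `preset`,
#' `seed`. Unknown keys raise a usage error naming the offending key.
#'
#' @param path Path to a JSON config file, or NULL for all defaults.
#' @return List with `scan` ([scan_config()]) and the extra fields.
#' @export
read_pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else jsonlite::read_json(path)
  known <- c("p_threshold_a", "r2_prune_max", "r2_pair_min", "flank_bp",
             "window_bp", "drop_ambiguous", "symmetric",
             "universe_n", "enrich_universe_n", "preset", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "))
  scan_args <- raw[intersect(names(raw), names(formals(scan_config)))]
  list(scan = do.call(scan_config, scan_args),
       universe_n = raw$universe_n %||% 20000,
       enrich_universe_n = raw$enrich_universe_n,
       preset = raw$preset %||% "paper-scale-mini",
       seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.require_inputs <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

.write_manifest <- function(out_dir, config, inputs, stage_counts, seed) {
  manifest <- list(
    tool = "pleioscan",
    version = as.character(utils::packageVersion("pleioscan")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = config,
    input_digests = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    stage_counts = as.list(stage_counts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate all pipeline inputs to a directory
#'
#' @param out_dir Output directory.
#' @param preset Preset for [simulate_preset()].
#' @param seed Master seed.
#' @return Invisibly, the in-memory world from [simulate_world()].
#' @export
cmd_simulate <- function(out_dir, preset = "paper-scale-mini", seed = 1) {
  world <- simulate_world(preset, seed = seed)
  write_world(world, out_dir)
  .write_manifest(out_dir, list(preset = preset), character(0),
                  c(n_variants = nrow(world$panel$variants),
                    n_planted = nrow(world$truth$planted_pleiotropic_snps)),
                  seed)
  invisible(world)
}

#' Run the pleiotropy scan branch on files
#'
#' Reads both studies' statistics, the haplotype panel, and the gene
#' models; runs [run_scan()]; writes `pleiotropic.tsv`, `intergenic.tsv`,
#' `pairs_audit.tsv` and a manifest with stage counts.
#'
#' @param stats_a_path,stats_b_path Summary-statistics TSVs (standard
#'   column names; use [read_summary_stats()] directly for exotic headers).
#' @param panel_matrix_path,panel_variants_path Haplotype panel files, or
#'   NULL for self-pair mode.
#' @param genes_path BED gene models, or NULL to skip gene mapping.
#' @param out_dir Output directory.
#' @param cfg [scan_config()].
#' @param seed Recorded in the manifest (the scan itself is deterministic).
#' @return The [run_scan()] result, invisibly.
#' @export
cmd_scan <- function(stats_a_path, stats_b_path,
                     panel_matrix_path = NULL, panel_variants_path = NULL,
                     genes_path = NULL, out_dir = ".",
                     cfg = scan_config(), seed = 1) {
  .require_inputs(stats_a_path, stats_b_path,
                  panel_matrix_path, panel_variants_path, genes_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stats_a <- read_summary_stats(stats_a_path, "traitA")
  stats_b <- read_summary_stats(stats_b_path, "traitB")
  panel <- if (!is.null(panel_matrix_path)) {
    read_haplotype_matrix(panel_matrix_path, panel_variants_path)
  }
  genes <- if (!is.null(genes_path)) read_gene_models(genes_path)
  res <- run_scan(stats_a, stats_b, panel, genes, cfg)
  data.table::fwrite(res$pleiotropic, file.path(out_dir, "pleiotropic.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(res$intergenic, file.path(out_dir, "intergenic.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(res$pairs, file.path(out_dir, "pairs_audit.tsv"),
                     sep = "\t", quote = FALSE)
  .write_manifest(out_dir, unclass(cfg),
                  c(stats_a_path, stats_b_path, panel_matrix_path,
                    panel_variants_path, genes_path),
                  res$audit, seed)
  invisible(res)
}

#' Run the interactome branch on files
#'
#' Builds both interactomes, tests their node overlap, enumerates bridges,
#' and writes summary TSV/JSON outputs.
#'
#' @param seeds_a_path,seeds_b_path One-symbol-per-line seed gene files.
#' @param edges_a_path,edges_b_path Tagged edge TSVs.
#' @param out_dir Output directory.
#' @param universe_n Gene universe for the overlap test (default 20000).
#' @param seed Recorded in the manifest.
#' @return List with `net_a`, `net_b`, `overlap`, `bridges`, invisibly.
#' @export
cmd_interactome <- function(seeds_a_path, edges_a_path,
                            seeds_b_path, edges_b_path,
                            out_dir = ".", universe_n = 20000, seed = 1) {
  .require_inputs(seeds_a_path, edges_a_path, seeds_b_path, edges_b_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net_a <- build_interactome(readLines(seeds_a_path),
                             read_edge_list(edges_a_path), name = "diseaseA")
  net_b <- build_interactome(readLines(seeds_b_path),
                             read_edge_list(edges_b_path), name = "diseaseB")
  ov <- overlap_test(net_a, net_b, universe_n = universe_n)
  br <- find_bridges(net_a, net_b)
  export_interactome(net_a, file.path(out_dir, "net_a"))
  export_interactome(net_b, file.path(out_dir, "net_b"))
  jsonlite::write_json(
    list(universe_n = ov$universe_n, size_a = ov$size_a, size_b = ov$size_b,
         overlap_k = ov$overlap_k, p_tail = ov$p_tail, log10_p = ov$log10_p,
         common_genes = ov$common_genes),
    file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(br$direct_edges, file.path(out_dir, "bridges_direct.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(br$two_step_paths,
                     file.path(out_dir, "bridges_two_step.tsv"),
                     sep = "\t", quote = FALSE)
  writeLines(br$common_interactors,
             file.path(out_dir, "common_interactors.txt"))
  .write_manifest(out_dir, list(universe_n = universe_n),
                  c(seeds_a_path, edges_a_path, seeds_b_path, edges_b_path),
                  c(nodes_a = length(net_a$nodes),
                    nodes_b = length(net_b$nodes),
                    overlap_k = ov$overlap_k,
                    n_direct = nrow(br$direct_edges),
                    n_common_interactors = length(br$common_interactors)),
                  seed)
  invisible(list(net_a = net_a, net_b = net_b, overlap = ov, bridges = br))
}

#' Run pathway enrichment for two gene sets and merge the tables
#'
#' @param genes_a,genes_b Character vectors (e.g. interactome node sets).
#' @param gmt_path GMT pathway file.
#' @param out_dir Output directory.
#' @param universe_n Optional enrichment universe override.
#' @param seed Recorded in the manifest.
#' @return List with `res_a`, `res_b`, `merged`, invisibly.
#' @export
cmd_enrich <- function(genes_a, genes_b, gmt_path, out_dir = ".",
                       universe_n = NULL, seed = 1) {
  .require_inputs(gmt_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gmt <- read_gmt(gmt_path)
  res_a <- enrich(genes_a, gmt, universe_n = universe_n)
  res_b <- enrich(genes_b, gmt, universe_n = universe_n)
  merged <- merge_pathway_tables(res_a, res_b)
  write_pathway_table(res_a, file.path(out_dir, "enrichment_a.tsv"))
  write_pathway_table(res_b, file.path(out_dir, "enrichment_b.tsv"))
  write_pathway_table(merged, file.path(out_dir, "pathways_merged.tsv"))
  .write_manifest(out_dir, list(universe_n = universe_n), gmt_path,
                  c(n_pathways_a = nrow(res_a), n_pathways_b = nrow(res_b),
                    n_merged = nrow(merged)), seed)
  invisible(list(res_a = res_a, res_b = res_b, merged = merged))
}

#' Run the reciprocal-expression branch on files
#'
#' @param sig_a_path,sig_b_path Signature TSVs.
#' @param perturbagen_path Perturbagen matrix TSV (or NULL to skip
#'   connectivity scoring).
#' @param out_dir Output directory.
#' @param seed Recorded in the manifest.
#' @return List with `reciprocal` and `connectivity`, invisibly.
#' @export
cmd_expression <- function(sig_a_path, sig_b_path, perturbagen_path = NULL,
                           out_dir = ".", seed = 1) {
  .require_inputs(sig_a_path, sig_b_path, perturbagen_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sig_a <- read_signature(sig_a_path)
  sig_b <- read_signature(sig_b_path)
  rec <- reciprocal_genes(sig_a, sig_b)
  writeLines(rec$up_a_down_b, file.path(out_dir, "up_a_down_b.txt"))
  writeLines(rec$down_a_up_b, file.path(out_dir, "down_a_up_b.txt"))
  conn <- NULL
  if (!is.null(perturbagen_path)) {
    mat <- read_perturbagen_matrix(perturbagen_path)
    q_genes <- c(rec$up_a_down_b, rec$down_a_up_b)
    query <- expression_signature(
      q_genes, ifelse(q_genes %in% rec$up_a_down_b, 1, -1) *
        abs(sig_a$score[match(q_genes, sig_a$gene)]))
    conn <- connectivity_score(query, mat)
    data.table::fwrite(conn, file.path(out_dir, "connectivity.tsv"),
                       sep = "\t", quote = FALSE)
  }
  .write_manifest(out_dir, list(), c(sig_a_path, sig_b_path, perturbagen_path),
                  c(n_up_a_down_b = length(rec$up_a_down_b),
                    n_down_a_up_b = length(rec$down_a_up_b),
                    n_perturbagens = if (is.null(conn)) 0L else nrow(conn)),
                  seed)
  invisible(list(reciprocal = rec, connectivity = conn))
}

#' Run the whole pipeline end-to-end on a simulated or existing input set
#'
#' Mirrors the two parallel and independent published analyses: the
#' pleiotropy-scan branch and the interactome branch run independently,
#' then a joint report connects the scan's candidate genes to both disease
#' interactomes ([candidate_connectivity()]), followed by enrichment and
#' reciprocal-expression analyses. With `simulate = TRUE` (default) the
#' inputs are first generated under `seed` into `in_dir`.
#'
#' @param out_dir Output directory (subdirectories per branch).
#' @param in_dir Input directory (written by [cmd_simulate()] /
#'   [write_world()] naming conventions).
#' @param preset Simulation preset.
#' @param seed Master seed.
#' @param cfg [scan_config()].
#' @param universe_n Interactome-overlap universe.
#' @param simulate Generate inputs first (default TRUE).
#' @return List with each branch's results, invisibly.
#' @export
cmd_all <- function(out_dir, in_dir = file.path(out_dir, "inputs"),
                    preset = "paper-scale-mini", seed = 1,
                    cfg = scan_config(), universe_n = 20000,
                    simulate = TRUE) {
  if (simulate) cmd_simulate(in_dir, preset, seed)
  p <- function(f) file.path(in_dir, f)
  scan <- cmd_scan(p("stats_a.tsv"), p("stats_b.tsv"),
                   p("panel_matrix.tsv"), p("panel_variants.tsv"),
                   p("genes.bed"), out_dir = file.path(out_dir, "scan"),
                   cfg = cfg, seed = seed)
  inter <- cmd_interactome(p("seeds_a.txt"), p("ppi_a.tsv"),
                           p("seeds_b.txt"), p("ppi_b.tsv"),
                           out_dir = file.path(out_dir, "interactome"),
                           universe_n = universe_n, seed = seed)
  enr <- cmd_enrich(inter$net_a$nodes, inter$net_b$nodes, p("pathways.gmt"),
                    out_dir = file.path(out_dir, "enrichment"), seed = seed)
  expr <- cmd_expression(p("sig_a.tsv"), p("sig_b.tsv"), p("perturbagens.tsv"),
                         out_dir = file.path(out_dir, "expression"),
                         seed = seed)

  # joint report: genes carrying pleiotropic SNPs as candidates against
  # both disease interactomes (their "own" PPIs stand in via the union)
  candidates <- unique(scan$pleiotropic$gene)
  cand_edges <- rbind(inter$net_a$edges, inter$net_b$edges)
  joint <- candidate_connectivity(candidates, cand_edges,
                                  inter$net_a, inter$net_b)
  dir.create(file.path(out_dir, "joint"), showWarnings = FALSE,
             recursive = TRUE)
  data.table::fwrite(joint$per_candidate,
                     file.path(out_dir, "joint", "candidate_connectivity.tsv"),
                     sep = "\t", quote = FALSE)
  .write_manifest(out_dir, c(unclass(cfg), list(universe_n = universe_n,
                                                preset = preset)),
                  character(0),
                  c(scan$audit,
                    overlap_k = inter$overlap$overlap_k,
                    n_candidates = length(candidates)),
                  seed)
  invisible(list(scan = scan, interactome = inter, enrichment = enr,
                 expression = expr, joint = joint))
}
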
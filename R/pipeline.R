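#' Pipeline configuration
#'
#' Validated bundle of input paths and parameters for [run_pipeline()].
#' Any of the expression / annotation / Ct inputs may be omitted, in which
#' case the corresponding stages are skipped (network-only runs are
#' supported).
#'
#' @param network path to the network file (edge list or SIF), or a
#'   [ppi_network] object.
#' @param expression,phenotype paths to the expression matrix and
#'   phenotype table, or an [expression_dataset] passed as `expression`.
#' @param annotations path to a GMT file, or an [annotation_collection].
#' @param ct path to a Ct table, or a [ct_table] (requires
#'   `ct_reference` when a path).
#' @param ct_reference housekeeping gene for the Ct table.
#' @param top_k bottlenecks reported (default 10).
#' @param alpha enrichment significance level on corrected p (default
#'   0.01).
#' @param min_module_size flagging threshold for small modules (default 3).
#' @param ridge_lambda ridge penalty for classifiers (default 1e-8).
#' @param gene_p panel-assembly threshold on nominal gene p (default 0.02).
#' @param module_p panel-assembly threshold on corrected module p
#'   (default 0.05).
#' @param n_perm permutations for the degree-traffic correlation test
#'   (default 10000).
#' @param seed integer seed for all stochastic steps.
#' @param out_dir optional output directory for report tables.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(network, expression = NULL, phenotype = NULL,
                            annotations = NULL, ct = NULL,
                            ct_reference = NULL, top_k = 10L, alpha = 0.01,
                            min_module_size = 3L, ridge_lambda = 1e-8,
                            gene_p = 0.02, module_p = 0.05,
                            n_perm = 10000L, seed = 1L, out_dir = NULL) {
  chk_path <- function(x, what) {
    if (is.character(x) && !file.exists(x))
      stop(what, " file not found: ", x)
    x
  }
  if (is.character(network)) chk_path(network, "network")
  if (is.character(expression)) {
    chk_path(expression, "expression")
    if (is.null(phenotype)) stop("expression path requires `phenotype`")
    chk_path(phenotype, "phenotype")
  }
  if (is.character(annotations)) chk_path(annotations, "annotations")
  if (is.character(ct)) {
    chk_path(ct, "Ct")
    if (is.null(ct_reference)) stop("Ct path requires `ct_reference`")
  }
  stopifnot(top_k >= 1L, alpha > 0, alpha < 1, min_module_size >= 1L,
            ridge_lambda >= 0, n_perm >= 1L)
  structure(
    list(network = network, expression = expression, phenotype = phenotype,
         annotations = annotations, ct = ct, ct_reference = ct_reference,
         top_k = as.integer(top_k), alpha = alpha,
         min_module_size = as.integer(min_module_size),
         ridge_lambda = ridge_lambda, gene_p = gene_p, module_p = module_p,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Assemble candidate biomarker panels
#'
#' Builds the three panel families the discovery workflow evaluates:
#' \enumerate{
#'   \item mean-expression profiles of the differentially expressed
#'     modules (corrected p <= `module_p`);
#'   \item the individual genes of those modules (those with expression
#'     data);
#'   \item the union of differentially expressed top-traffic genes
#'     (nominal p <= `gene_p` among the top-`top_k` bottlenecks) and the
#'     differentially expressed genes of the selected modules.
#' }
#'
#' @param topology topology table from [node_topology()].
#' @param module_de module-level DE table from [module_de()].
#' @param gene_de gene-level DE table from [gene_de_scan()].
#' @param partition the `module_partition` the module table refers to.
#' @param ds the [expression_dataset] (features must have data).
#' @param top_k,gene_p,module_p selection rules (see [pipeline_config()]).
#' @return List of [feature_panel]s (possibly empty, with a warning).
#' @export
assemble_panels <- function(topology, module_de, gene_de, partition, ds,
                            top_k = 10L, gene_p = 0.02, module_p = 0.05) {
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  sig_modules <- module_de$unit[module_de$p_adj <= module_p]
  bottle <- rank_bottlenecks(topology, k = top_k)$protein
  sig_genes <- gene_de$unit[gene_de$p_nominal <= gene_p]
  sig_bottle <- intersect(bottle, sig_genes)
  module_gene_pool <- unlist(lapply(sig_modules, function(mid)
    intersect(names(assignment)[as.character(assignment) == mid], ds$genes)),
    use.names = FALSE)
  panels <- list()
  if (length(sig_modules)) {
    panels <- c(panels, list(
      feature_panel("module_means", modules = sig_modules)))
    if (length(module_gene_pool))
      panels <- c(panels, list(
        feature_panel("module_genes", genes = module_gene_pool)))
  }
  combo <- union(sig_bottle, intersect(module_gene_pool, sig_genes))
  if (length(combo))
    panels <- c(panels, list(feature_panel("bottleneck_module_union",
                                           genes = combo)))
  if (!length(panels))
    warning("no qualifying modules or genes; no panels assembled")
  panels
}

load_stage_input <- function(x, loader, ...) {
  if (is.character(x)) loader(x, ...) else x
}

#' Run the full discovery pipeline
#'
#' Stages, in order: load network -> giant component -> topology (degree,
#' traffic, bottleneck ranking, degree-traffic correlation) -> greedy
#' modules -> module stats -> annotation enrichment (if annotations given)
#' -> gene and module differential expression (if expression given) ->
#' candidate panel assembly -> LOOCV panel evaluation -> Ct normalization
#' (if a Ct table is given). A failing stage aborts with the stage named;
#' when `out_dir` is set, tables produced so far are retained next to a
#' `FAILED` marker file.
#'
#' @param cfg a [pipeline_config].
#' @return An object of class `run_report`: list with `network_summary`,
#'   `bottlenecks`, `spearman`, `partition`, `module_stats`, `enrichment`,
#'   `gene_de`, `module_de`, `panels`, `evaluations`, `pcr`, and
#'   `provenance` (config hash, seed, timestamp, package version). When
#'   `cfg$out_dir` is set, tab-delimited tables plus a `summary.json` are
#'   written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  report <- list()
  stage <- "init"
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_msg <- function(...) message("[netmarker] ", ...)
  on_fail <- function(e) {
    if (!is.null(out_dir))
      writeLines(paste("failed at stage:", stage, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "load_network"
    net <- load_stage_input(cfg$network, read_network)
    log_msg("network: ", length(net$nodes), " nodes, ", nrow(net$edges),
            " edges")
    stage <- "giant_component"
    giant <- largest_component(net)
    report$network_summary <- cbind(summarize_network(net),
                                    giant_edges = n_edges(giant))
    stage <- "topology"
    topo <- node_topology(giant)
    report$topology <- topo
    report$bottlenecks <- rank_bottlenecks(topo, k = cfg$top_k)
    report$spearman <- degree_traffic_spearman(topo, n_perm = cfg$n_perm,
                                               seed = cfg$seed)
    log_msg("degree-traffic Spearman rho = ",
            format(report$spearman$rho, digits = 3))
    stage <- "greedy_modules"
    part <- greedy_modules(giant, min_size = cfg$min_module_size)
    report$partition <- part
    log_msg(part$n_modules, " modules, Q = ", format(part$Q, digits = 4))
    stage <- "module_stats"
    report$module_stats <- module_stats(giant, part)
    if (!is.null(cfg$annotations)) {
      stage <- "enrichment"
      ann <- load_stage_input(cfg$annotations, read_gmt)
      report$enrichment <- enrich_modules(part, ann, alpha = cfg$alpha)
      log_msg(sum(report$enrichment$significant), " significant (module, term) pairs")
    }
    ds <- NULL
    if (!is.null(cfg$expression)) {
      stage <- "expression"
      ds <- if (is.character(cfg$expression))
        read_expression(cfg$expression, cfg$phenotype) else cfg$expression
      stage <- "gene_de"
      report$gene_de <- gene_de_scan(ds)
      stage <- "module_de"
      report$module_de <- module_de(ds, part)
      stage <- "assemble_panels"
      report$panels <- withCallingHandlers(
        assemble_panels(topo, report$module_de, report$gene_de, part, ds,
                        top_k = cfg$top_k, gene_p = cfg$gene_p,
                        module_p = cfg$module_p),
        warning = function(w) { log_msg(conditionMessage(w))
                                invokeRestart("muffleWarning") })
      stage <- "loocv"
      ccfg <- classifier_config(ridge_lambda = cfg$ridge_lambda)
      report$evaluations <- lapply(report$panels, function(p)
        loocv_evaluate(ds, p, ccfg, partition = part))
      for (ev in report$evaluations)
        log_msg("panel '", ev$panel$name, "': AUC = ",
                format(ev$auc, digits = 3))
    }
    if (!is.null(cfg$ct)) {
      stage <- "pcr"
      ct <- if (is.character(cfg$ct)) read_ct(cfg$ct, cfg$ct_reference)
            else cfg$ct
      report$pcr <- pcr_normalize(ct)
    }
    stage <- "report"
    report$provenance <- pipeline_provenance(cfg)
    report <- structure(report, class = "run_report")
    if (!is.null(out_dir)) write_report(report, out_dir)
    report
  }, error = on_fail)
}

pipeline_provenance <- function(cfg) {
  ser <- cfg
  ser$out_dir <- NULL    # output location is not part of the analysis identity
  ser$network <- if (is.character(ser$network)) ser$network else "<object>"
  for (f in c("expression", "phenotype", "annotations", "ct"))
    if (!is.null(ser[[f]]) && !is.character(ser[[f]])) ser[[f]] <- "<object>"
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(ser), tmp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  list(config_hash = unname(tools::md5sum(tmp)),
       seed = cfg$seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       package_version = as.character(utils::packageVersion("netmarker")))
}

write_report <- function(report, out_dir) {
  wt <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(report$network_summary, "network_summary.tsv")
  wt(report$bottlenecks, "bottlenecks.tsv")
  wt(data.frame(protein = names(report$partition$assignment),
                module_id = unname(report$partition$assignment)),
     "module_membership.tsv")
  wt(report$module_stats, "module_stats.tsv")
  if (!is.null(report$enrichment)) wt(report$enrichment, "enrichment.tsv")
  if (!is.null(report$gene_de)) wt(report$gene_de, "gene_de.tsv")
  if (!is.null(report$module_de)) wt(report$module_de, "module_de.tsv")
  if (!is.null(report$evaluations)) {
    oof <- do.call(rbind, lapply(report$evaluations, function(ev)
      data.frame(panel = ev$panel$name, sample = names(ev$oof_scores),
                 score = unname(ev$oof_scores),
                 label = as.character(ev$labels))))
    wt(oof, "oof_scores.tsv")
  }
  summary <- list(
    network = as.list(report$network_summary),
    spearman = report$spearman,
    modularity_q = report$partition$Q,
    n_modules = report$partition$n_modules,
    panels = if (!is.null(report$evaluations))
      lapply(report$evaluations, function(ev)
        list(panel = ev$panel$name, n = length(ev$oof_scores), auc = ev$auc))
    else list(),
    # timestamp stays out of the JSON so identical (config, seed) runs
    # produce byte-identical summaries
    provenance = report$provenance[c("config_hash", "seed", "package_version")]
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("netmarker run report\n")
  print(x$network_summary)
  cat("modules:", x$partition$n_modules, " Q =",
      format(x$partition$Q, digits = 4), "\n")
  if (!is.null(x$evaluations))
    for (ev in x$evaluations)
      cat("  panel", ev$panel$name, "AUC =", format(ev$auc, digits = 3), "\n")
  invisible(x)
}
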
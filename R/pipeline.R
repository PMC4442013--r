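#' Run the full key-gene prediction study from one configuration
#'
#' Orchestrates every stage — per-dataset preprocessing, module
#' detection, metabolic-network construction, gene scoring, cross-
#' dataset combination, term enrichment, and the shortest-path
#' association test — and writes all tables plus a machine-readable
#' `manifest.json` into `out_dir`. Reruns with the same configuration
#' and seeds produce byte-identical outputs.
#'
#' The configuration is a YAML file or an equivalent nested list:
#'
#' ```yaml
#' datasets:
#'   - id: gds_a
#'     expression: a.tsv     # matrix TSV (or SOFT file)
#'     labels: a_labels.tsv  # omitted for SOFT input
#'     format: tsv
#' reactions: {path: reactions.tsv, format: reaction_tsv}
#' terms: {path: terms.gmt, format: gmt}
#' association_network: funcoup.tsv
#' disease_genes: disease_genes.txt   # one gene id per line
#' parameters:                        # all mandatory, no silent defaults
#'   max_null_fraction: 0.8
#'   normalize: per_gene_zscore
#'   edge_threshold: 0.7
#'   min_module_size: 11
#'   max_metabolite_reactions: 18
#'   excluded_pathways: [Xenobiotics Biodegradation and Metabolism]
#'   combiner: product_neglog
#'   median_rule: strict
#'   min_datasets: 2
#'   n_perm: 1000
#'   pool: network
#'   distance_mode: hops
#'   seed: 1
#' ```
#'
#' Every ambiguous analysis parameter must be stated explicitly in
#' pipeline mode; a missing parameter is an error. The `terms`,
#' `association_network` and `disease_genes` entries are optional —
#' their stages are skipped when absent. Any stage failure aborts with
#' the stage name and cause and leaves a `FAILED` marker file in
#' `out_dir`.
#'
#' @param config path to a YAML file, or a nested list as above.
#' @param out_dir run directory, created if needed.
#' @param quiet suppress per-stage log lines.
#' @return the manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- "configure"
  manifest <- list(package_version = as.character(utils::packageVersion("metexpress")),
                   parameters = cfg$parameters, datasets = list())
  on_fail <- function(e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    p <- cfg$parameters

    stage <- "metabolic_network"
    rx <- parse_reactions(cfg$reactions$path, format = cfg$reactions$format)
    retained <- filter_metabolites(
      rx, max_reaction_count = p$max_metabolite_reactions,
      excluded_pathways = unlist(p$excluded_pathways))
    net <- build_enzyme_graph(rx, retained)
    background <- outward_genes(net)
    write_metnet_tsv(net, file.path(out_dir, "metabolic_edges.tsv"),
                     file.path(out_dir, "background_genes.txt"))
    manifest$metabolic_network <- list(
      directed_reactions = nrow(rx),
      retained_metabolites = length(retained),
      enzyme_genes = length(net$nodes),
      edges = nrow(net$edges),
      background_genes = length(background))
    log_line(stage, "%d directed reactions -> %d edges, %d background genes",
             nrow(rx), nrow(net$edges), length(background))

    selections <- list()
    for (i in seq_along(cfg$datasets)) {
      dcfg <- cfg$datasets[[i]]
      stage <- paste0("preprocess:", dcfg$id)
      ds <- load_expression(dcfg$expression, format = dcfg$format,
                            labels = dcfg$labels, dataset_id = dcfg$id)
      genes_in <- nrow(ds$values)
      ds <- filter_missing(ds, p$max_null_fraction)
      ds <- normalize_expression(ds, p$normalize)
      log_line(stage, "%d genes in, %d after missingness filter",
               genes_in, nrow(ds$values))

      stage <- paste0("modules:", dcfg$id)
      mods <- detect_modules(ds, threshold = p$edge_threshold,
                             min_size = p$min_module_size,
                             seed = derive_seed(p$seed, i))
      write_modules_tsv(mods, file.path(out_dir,
                                        sprintf("modules_%s.tsv", dcfg$id)))
      log_line(stage, "%d modules retained (Q = %.3f)",
               length(mods$modules), mods$Q)

      stage <- paste0("score:", dcfg$id)
      scores <- score_genes(ds, mods, net, background,
                            combiner = p$combiner,
                            median_rule = p$median_rule)
      write_scores_tsv(scores, file.path(out_dir,
                                         sprintf("scores_%s.tsv", dcfg$id)))
      selections[[dcfg$id]] <- scores$gene_id[scores$selected]
      manifest$datasets[[dcfg$id]] <- list(
        genes_in = genes_in,
        genes_after_filter = nrow(ds$values),
        modules_retained = length(mods$modules),
        modularity_Q = mods$Q,
        scored_genes = nrow(scores),
        candidates = length(selections[[dcfg$id]]))
      log_line(stage, "%d of %d scored genes selected",
               length(selections[[dcfg$id]]), nrow(scores))
    }

    stage <- "combine"
    combined <- combine_datasets(selections, min_datasets = p$min_datasets)
    write.table(as.data.frame(combined),
                file.path(out_dir, "keygenes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$combined <- list(
      key_genes = nrow(combined),
      all_datasets_core = length(attr(combined, "core")))
    log_line(stage, "%d key genes (>= %d datasets), %d in all datasets",
             nrow(combined), p$min_datasets, length(attr(combined, "core")))

    if (!is.null(cfg$terms)) {
      stage <- "enrichment"
      term_map <- read_term_map(cfg$terms$path, format = cfg$terms$format)
      enr <- fisher_enrichment(combined$gene_id, term_map, background)
      write.table(enr, file.path(out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$enrichment <- list(
        terms_tested = nrow(enr),
        terms_q_le_0.05 = sum(enr$q <= 0.05))
      log_line(stage, "%d / %d terms at q <= 0.05",
               sum(enr$q <= 0.05), nrow(enr))
    }

    if (!is.null(cfg$association_network) && !is.null(cfg$disease_genes)) {
      stage <- "association"
      net_fc <- read_association_network(cfg$association_network)
      disease <- readLines(cfg$disease_genes, warn = FALSE)
      disease <- disease[nzchar(disease)]
      assoc <- permutation_test(
        combined$gene_id, disease, net_fc, n_perm = p$n_perm,
        pool = if (identical(p$pool, "enzyme_background")) background
               else "network",
        seed = derive_seed(p$seed, 999L), mode = p$distance_mode)
      jsonlite::write_json(
        list(observed_mean = assoc$observed_mean,
             p_empirical = assoc$p_empirical,
             p_smoothed = assoc$p_smoothed,
             null_summary = as.list(assoc$null_summary),
             n_perm = assoc$n_perm,
             excluded = assoc$excluded),
        file.path(out_dir, "association.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write.table(rank_closest(assoc$per_gene_mean_distance),
                  file.path(out_dir, "association_ranking.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$association <- list(
        observed_mean = assoc$observed_mean,
        p_empirical = assoc$p_empirical,
        null_mean = unname(assoc$null_summary["mean"]))
      log_line(stage, "observed mean %.3f, empirical p %.4g",
               assoc$observed_mean, assoc$p_empirical)
    }

    stage <- "manifest"
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = on_fail)
}

.required_params <- c("max_null_fraction", "normalize", "edge_threshold",
                      "min_module_size", "max_metabolite_reactions",
                      "excluded_pathways", "combiner", "median_rule",
                      "min_datasets", "n_perm", "pool", "distance_mode",
                      "seed")

.validate_config <- function(config) {
  if (is.null(config$datasets) || !length(config$datasets))
    stop("config needs at least one dataset")
  if (is.null(config$reactions$path))
    stop("config needs a reactions source")
  missing <- setdiff(.required_params, names(config$parameters))
  if (length(missing))
    stop("missing mandatory parameter(s): ", paste(missing, collapse = ", "))
  config$reactions$format <- config$reactions$format %||% "reaction_tsv"
  if (!is.null(config$terms))
    config$terms$format <- config$terms$format %||% "gmt"
  config$datasets <- lapply(seq_along(config$datasets), function(i) {
    d <- config$datasets[[i]]
    d$id <- d$id %||% sprintf("dataset%d", i)
    d$format <- d$format %||% "tsv"
    if (is.null(d$expression)) stop("dataset '", d$id, "' has no expression path")
    paths <- c(d$expression, d$labels)
    bad <- paths[!file.exists(paths)]
    if (length(bad)) stop("missing input file(s): ", paste(bad, collapse = ", "))
    d
  })
  for (path in c(config$reactions$path, config$terms$path,
                 config$association_network, config$disease_genes))
    if (!is.null(path) && !file.exists(path))
      stop("missing input file: ", path)
  config
}
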
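#' Generate an expression dataset with planted coexpression modules
#'
#' Latent-factor Gaussian model: genes of module `m` in sample `s` are
#' `sqrt(rho) * f[m, s] + sqrt(1 - rho) * noise`, giving within-module
#' correlation approximately `rho = within_module_corr`. Module 1 is the
#' planted disease-specific module: its latent factor is shifted by
#' `effect_size` (in factor standard deviations) in disease samples.
#' Genes outside any module are independent noise. Missing entries are
#' sprinkled independently at `missing_rate`. Everything is a pure
#' function of the parameters and `seed`.
#'
#' @param n_genes total genes (ids `G001`, ...).
#' @param n_samples_per_class disease and normal sample count.
#' @param n_modules number of planted modules (>= 1).
#' @param module_size genes per module; `n_modules * module_size` must
#'   not exceed `n_genes`.
#' @param effect_size disease shift of module 1's factor, in sd units.
#' @param noise_sd overall scale (irrelevant after z-scoring).
#' @param within_module_corr target within-module correlation in \[0,1).
#' @param missing_rate probability an entry is missing.
#' @param seed integer seed.
#' @param dataset_id dataset identifier.
#' @return list `dataset` (a [expression_dataset()]) and `truth` (list:
#'   `planted_module_genes`, `module_assignments`, `effect_size`,
#'   `seed`).
#' @export
gen_expression <- function(n_genes = 200L, n_samples_per_class = 20L,
                           n_modules = 5L, module_size = 20L,
                           effect_size = 2, noise_sd = 1,
                           within_module_corr = 0.8, missing_rate = 0.02,
                           seed = 1L, dataset_id = "synthetic") {
  if (n_modules * module_size > n_genes)
    stop("infeasible parameters: modules larger than the gene universe")
  if (within_module_corr < 0 || within_module_corr >= 1)
    stop("within_module_corr must be in [0, 1)")
  set.seed(seed)
  wid <- nchar(as.character(n_genes))
  gene_ids <- sprintf("G%0*d", wid, seq_len(n_genes))
  ns <- 2L * n_samples_per_class
  sample_ids <- sprintf("S%02d", seq_len(ns))
  labels <- rep(c(1L, 0L), each = n_samples_per_class)

  assignment <- rep(NA_integer_, n_genes)
  assignment[seq_len(n_modules * module_size)] <-
    rep(seq_len(n_modules), each = module_size)

  f <- matrix(rnorm(n_modules * ns), n_modules, ns)
  f[1L, ] <- f[1L, ] + effect_size * labels
  rho <- within_module_corr
  X <- matrix(rnorm(n_genes * ns), n_genes, ns)
  in_mod <- !is.na(assignment)
  X[in_mod, ] <- sqrt(rho) * f[assignment[in_mod], , drop = FALSE] +
    sqrt(1 - rho) * X[in_mod, , drop = FALSE]
  X <- X * noise_sd
  dimnames(X) <- list(gene_ids, sample_ids)
  if (missing_rate > 0) {
    X[matrix(runif(length(X)) < missing_rate, nrow(X))] <- NA_real_
  }
  truth <- list(
    planted_module_genes = gene_ids[which(assignment == 1L)],
    module_assignments = setNames(assignment, gene_ids),
    effect_size = effect_size, seed = seed)
  list(dataset = expression_dataset(X, labels, dataset_id), truth = truth)
}

#' Generate a toy reaction set with planted key enzymes
#'
#' Every enzyme gets one production reaction (a private substrate to a
#' private metabolite), so each enzyme produces exactly one metabolite.
#' Out-links are realized as consumption reactions (the consumer enzyme
#' turns the producer's metabolite into a private sink). Planted key
#' genes link to `key_out_degree` distinct genes drawn from
#' `key_target_pool` (their planted coexpression module); other enzymes
#' link to `1 + Poisson(mean_out_degree - 1)` random genes, so every
#' enzyme has outward edges. `currency_metabolite_count` designated
#' currency metabolites are appended to 18 reactions each (the first
#' count excluded by the default filter), so the currency filter
#' provably removes them. A `reversible_fraction` of consumption
#' reactions is marked reversible.
#'
#' @param enzyme_ids enzyme gene ids (typically the expression genes).
#' @param key_gene_ids planted key genes, a subset of `enzyme_ids`.
#' @param key_target_pool genes the key genes' consumers are drawn from
#'   (their module-mates). Required when `key_gene_ids` is non-empty.
#' @param key_out_degree out-links per planted key gene.
#' @param mean_out_degree mean out-links of non-key enzymes (>= 1).
#' @param reversible_fraction fraction of consumption reactions marked
#'   reversible.
#' @param currency_metabolite_count planted currency metabolites.
#' @param n_pathways synthetic pathway labels to distribute reactions
#'   over.
#' @param seed integer seed.
#' @return list `reactions` (source reaction data frame for
#'   [split_reactions()] / [write_reactions_tsv()]) and `truth` (list:
#'   `planted_key_genes`, `key_targets`, `currency_metabolites`,
#'   `seed`).
#' @export
gen_reactions <- function(enzyme_ids, key_gene_ids = character(0),
                          key_target_pool = NULL, key_out_degree = 8L,
                          mean_out_degree = 1.5, reversible_fraction = 0.2,
                          currency_metabolite_count = 2L, n_pathways = 5L,
                          seed = 1L) {
  stopifnot(all(key_gene_ids %in% enzyme_ids), mean_out_degree >= 1)
  if (length(key_gene_ids)) {
    if (is.null(key_target_pool)) stop("key_target_pool required for planted key genes")
    if (length(setdiff(key_target_pool, key_gene_ids[1])) < key_out_degree)
      stop("infeasible degrees: target pool smaller than key_out_degree")
  }
  set.seed(seed)
  pathways <- sprintf("Synthetic pathway %d", seq_len(n_pathways))
  met_of <- setNames(paste0("MET_", enzyme_ids), enzyme_ids)

  rows <- vector("list", 0L)
  add <- function(id, rev, pw, enz, sub, prod) {
    rows[[length(rows) + 1L]] <<- data.frame(
      reaction_id = id, reversible = rev, pathway = pw,
      enzymes = I(list(enz)), substrates = I(list(sub)),
      products = I(list(prod)), stringsAsFactors = FALSE)
  }
  for (g in enzyme_ids)
    add(paste0("Rprod_", g), FALSE, sample(pathways, 1L),
        g, paste0("SRC_", g), met_of[[g]])

  key_targets <- list()
  cn <- 0L
  for (g in enzyme_ids) {
    targets <- if (g %in% key_gene_ids) {
      sample(setdiff(key_target_pool, g), key_out_degree)
    } else {
      n_out <- 1L + rpois(1L, max(mean_out_degree - 1, 0))
      sample(setdiff(enzyme_ids, g), min(n_out, length(enzyme_ids) - 1L))
    }
    if (g %in% key_gene_ids) key_targets[[g]] <- targets
    for (t in targets) {
      cn <- cn + 1L
      add(sprintf("Rcons_%05d", cn),
          runif(1) < reversible_fraction, sample(pathways, 1L),
          t, met_of[[g]], sprintf("SNK_%05d", cn))
    }
  }
  reactions <- do.call(rbind, rows)

  currency <- character(0)
  if (currency_metabolite_count > 0L) {
    currency <- sprintf("CURRENCY_%d", seq_len(currency_metabolite_count))
    for (cm in currency) {
      hit <- sample(nrow(reactions), 18L)
      for (i in hit)
        reactions$products[[i]] <- c(reactions$products[[i]], cm)
    }
  }
  rownames(reactions) <- NULL
  list(reactions = reactions,
       truth = list(planted_key_genes = key_gene_ids,
                    key_targets = key_targets,
                    currency_metabolites = currency, seed = seed))
}

#' Write a source reaction table as the canonical reaction TSV
#' @param reactions source reaction data frame (e.g. from
#'   [gen_reactions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reactions_tsv <- function(reactions, path) {
  joincol <- function(col) vapply(col, paste, character(1), collapse = ";")
  tab <- data.frame(reaction_id = reactions$reaction_id,
                    reversible = as.integer(reactions$reversible),
                    pathway = reactions$pathway,
                    enzymes = joincol(reactions$enzymes),
                    substrates = joincol(reactions$substrates),
                    products = joincol(reactions$products),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a source reaction table as toy KGML
#'
#' Produces the KGML dialect read by [parse_reactions()]: one
#' `<pathway>` document with gene `<entry>` elements and `<reaction>`
#' elements. All reactions are emitted into one document whose title is
#' `pathway_title`; per-reaction pathway labels are preserved only by
#' the TSV writer, so KGML fixtures are written one file per pathway by
#' splitting beforehand if needed.
#'
#' @param reactions source reaction data frame.
#' @param path output path.
#' @param pathway_title pathway title attribute.
#' @return `path`, invisibly.
#' @export
write_kgml <- function(reactions, path, pathway_title = "synthetic pathway") {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(sprintf('<pathway name="path:syn00001" title="%s">', esc(pathway_title)))
  for (i in seq_len(nrow(reactions))) {
    rid <- reactions$reaction_id[i]
    for (g in reactions$enzymes[[i]])
      lines <- c(lines, sprintf(
        '  <entry id="e%d" name="%s" type="gene" reaction="rn:%s"/>',
        length(lines), esc(g), esc(rid)))
    lines <- c(lines, sprintf('  <reaction id="x%d" name="rn:%s" type="%s">',
                              i, esc(rid),
                              if (reactions$reversible[i]) "reversible"
                              else "irreversible"))
    for (s in reactions$substrates[[i]])
      lines <- c(lines, sprintf('    <substrate id="s%d" name="cpd:%s"/>',
                                length(lines), esc(s)))
    for (p in reactions$products[[i]])
      lines <- c(lines, sprintf('    <product id="p%d" name="cpd:%s"/>',
                                length(lines), esc(p)))
    lines <- c(lines, "  </reaction>")
  }
  writeLines(c(lines, "</pathway>"), path)
  invisible(path)
}

#' Generate a term-annotation map with optional planted enrichment
#'
#' Random terms draw their genes uniformly from the background; planted
#' terms contain their designated genes plus `planted_fill` random
#' extras.
#'
#' @param background background gene ids.
#' @param n_terms number of random terms (`T01`, ...).
#' @param term_size_range inclusive range of random term sizes.
#' @param planted named list: term id -> designated gene set (subsets
#'   of `background`).
#' @param planted_fill random extra genes added to each planted term.
#' @param seed integer seed.
#' @return list `terms` (named list usable with [fisher_enrichment()])
#'   and `truth` (list: `planted_terms`, `seed`).
#' @export
gen_term_map <- function(background, n_terms = 50L,
                         term_size_range = c(10L, 30L),
                         planted = list(), planted_fill = 0L, seed = 1L) {
  stopifnot(all(unlist(planted) %in% background))
  set.seed(seed)
  terms <- lapply(seq_len(n_terms), function(i) {
    size <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
    sample(background, min(size, length(background)))
  })
  names(terms) <- sprintf("T%02d", seq_len(n_terms))
  for (tid in names(planted)) {
    extra <- sample(setdiff(background, planted[[tid]]),
                    min(planted_fill, length(background) - length(planted[[tid]])))
    terms[[tid]] <- unique(c(planted[[tid]], extra))
  }
  list(terms = terms,
       truth = list(planted_terms = names(planted), seed = seed))
}

#' Generate a functional-association network with planted proximity
#'
#' A connected backbone (a ring over a random permutation of the nodes)
#' plus uniform random edges up to `edge_density`. Disease genes are
#' drawn from the non-planted nodes (or given explicitly). Each planted
#' close gene is wired within `planted_hops` of every disease gene:
#' directly adjacent at `planted_hops = 1`, otherwise through a chain
#' of bridge nodes ending at a hub adjacent to all disease genes.
#' Optionally `n_isolated` extra nodes are left without edges to
#' exercise the unreachable-gene rules.
#'
#' @param n_nodes nodes in the connected part (ids `N001`, ... unless
#'   `node_ids` given).
#' @param edge_density target density of the random edges.
#' @param node_ids optional node names of length `n_nodes`.
#' @param disease_gene_ids optional explicit disease genes.
#' @param disease_gene_count disease genes to sample when
#'   `disease_gene_ids` is NULL.
#' @param planted_close_genes nodes planted close to the disease genes.
#' @param planted_hops maximum distance of planted genes to every
#'   disease gene (>= 1).
#' @param n_isolated isolated extra nodes (ids `ISO_1`, ...).
#' @param seed integer seed.
#' @return list `edges` (data frame `gene_a`, `gene_b`, `weight`),
#'   `graph` (igraph), `disease_genes`, `truth`.
#' @export
gen_association_network <- function(n_nodes = 300L, edge_density = 0.008,
                                    node_ids = NULL, disease_gene_ids = NULL,
                                    disease_gene_count = 10L,
                                    planted_close_genes = character(0),
                                    planted_hops = 1L, n_isolated = 0L,
                                    seed = 1L) {
  if (planted_hops < 1L) stop("planted_hops must be >= 1")
  set.seed(seed)
  nodes <- node_ids %||% sprintf("N%03d", seq_len(n_nodes))
  stopifnot(length(nodes) == n_nodes,
            all(planted_close_genes %in% nodes))
  perm <- sample(nodes)
  edges <- cbind(perm, c(perm[-1], perm[1]))  # connected ring backbone
  n_extra <- max(0L, round(edge_density * n_nodes * (n_nodes - 1) / 2) - n_nodes)
  if (n_extra > 0L) {
    a <- sample(nodes, n_extra, replace = TRUE)
    b <- sample(nodes, n_extra, replace = TRUE)
    keep <- a != b
    edges <- rbind(edges, cbind(a[keep], b[keep]))
  }
  disease <- disease_gene_ids %||%
    sample(setdiff(nodes, planted_close_genes), disease_gene_count)
  if (length(planted_close_genes)) {
    if (planted_hops == 1L) {
      for (g in planted_close_genes)
        edges <- rbind(edges, cbind(g, disease))
    } else {
      hub <- setdiff(nodes, c(planted_close_genes, disease))[1]
      edges <- rbind(edges, cbind(hub, disease))
      for (g in planted_close_genes) {
        chain <- c(g, sample(setdiff(nodes, c(planted_close_genes, disease, hub)),
                             planted_hops - 2L), hub)
        edges <- rbind(edges, cbind(chain[-length(chain)], chain[-1]))
      }
    }
  }
  edge_df <- data.frame(gene_a = edges[, 1], gene_b = edges[, 2],
                        weight = round(runif(nrow(edges), 0.5, 1), 3),
                        stringsAsFactors = FALSE)
  if (n_isolated > 0L) {
    iso <- sprintf("ISO_%d", seq_len(n_isolated))
    g <- association_network(edge_df)
    g <- igraph::add_vertices(g, n_isolated, name = iso)
  } else {
    g <- association_network(edge_df)
  }
  list(edges = edge_df, graph = g, disease_genes = disease,
       truth = list(disease_genes = disease,
                    planted_close_genes = planted_close_genes,
                    planted_hops = planted_hops, seed = seed))
}

#' Write an association edge list as TSV
#' @param edges data frame `gene_a`, `gene_b` \[, `weight`\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list_tsv <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a complete multi-dataset synthetic study
#'
#' Bundles the four generators into one internally consistent study:
#' a shared gene universe with one planted disease module containing
#' the planted key genes; `n_datasets` expression datasets re-drawing
#' the noise (and sample labels' expression) per dataset while keeping
#' the planted structure fixed; one reaction set whose key genes feed
#' `key_out_degree` module-mates; a term map whose planted term is the
#' planted module; and an association network over the gene universe
#' plus extra non-enzyme nodes, with the key genes planted adjacent to
#' the disease genes.
#'
#' @param seed master seed; per-component seeds are derived from it.
#' @param n_datasets expression datasets to generate.
#' @param n_genes,n_modules,module_size,effect_size,within_module_corr,
#'   missing_rate,n_samples_per_class passed to [gen_expression()].
#' @param n_key_genes planted key genes (first genes of module 1).
#' @param key_out_degree,mean_out_degree,reversible_fraction,
#'   currency_metabolite_count passed to [gen_reactions()].
#' @param n_terms random terms in the term map.
#' @param n_assoc_extra non-enzyme nodes added to the association
#'   network.
#' @param assoc_edge_density association-network density.
#' @return list with `datasets` (list of [expression_dataset()]),
#'   `reactions`, `term_map`, `assoc` (edges, graph, disease_genes) and
#'   `truth`.
#' @export
gen_study <- function(seed = 1L, n_datasets = 3L, n_genes = 200L,
                      n_modules = 5L, module_size = 20L, effect_size = 2,
                      within_module_corr = 0.8, missing_rate = 0.02,
                      n_samples_per_class = 20L, n_key_genes = 5L,
                      key_out_degree = 8L, mean_out_degree = 1.5,
                      reversible_fraction = 0.2,
                      currency_metabolite_count = 2L, n_terms = 30L,
                      n_assoc_extra = 100L, assoc_edge_density = 0.008) {
  wid <- nchar(as.character(n_genes))
  gene_ids <- sprintf("G%0*d", wid, seq_len(n_genes))
  module1 <- gene_ids[seq_len(module_size)]
  key_genes <- module1[seq_len(n_key_genes)]

  datasets <- lapply(seq_len(n_datasets), function(i) {
    gen_expression(n_genes = n_genes,
                   n_samples_per_class = n_samples_per_class,
                   n_modules = n_modules, module_size = module_size,
                   effect_size = effect_size,
                   within_module_corr = within_module_corr,
                   missing_rate = missing_rate,
                   seed = derive_seed(seed, i),
                   dataset_id = sprintf("synthetic_%d", i))$dataset
  })
  rx <- gen_reactions(gene_ids, key_gene_ids = key_genes,
                      key_target_pool = module1,
                      key_out_degree = key_out_degree,
                      mean_out_degree = mean_out_degree,
                      reversible_fraction = reversible_fraction,
                      currency_metabolite_count = currency_metabolite_count,
                      seed = derive_seed(seed, 101L))
  tm <- gen_term_map(gene_ids, n_terms = n_terms,
                     planted = list(PLANTED_MODULE = module1),
                     seed = derive_seed(seed, 102L))
  extra <- sprintf("X%03d", seq_len(n_assoc_extra))
  an <- gen_association_network(
    n_nodes = n_genes + n_assoc_extra,
    edge_density = assoc_edge_density,
    node_ids = c(gene_ids, extra),
    disease_gene_ids = NULL, disease_gene_count = 10L,
    planted_close_genes = key_genes, planted_hops = 1L,
    seed = derive_seed(seed, 103L))
  list(datasets = datasets,
       reactions = rx$reactions,
       term_map = tm$terms,
       assoc = an,
       truth = list(gene_ids = gene_ids,
                    planted_module_genes = module1,
                    planted_key_genes = key_genes,
                    planted_enriched_terms = tm$truth$planted_terms,
                    planted_close_genes = an$truth$planted_close_genes,
                    disease_genes = an$disease_genes,
                    effect_size = effect_size, seed = seed))
}
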
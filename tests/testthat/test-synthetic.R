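test_that("generators are pure functions of their parameters and seed", {
  a <- gen_expression(n_genes = 50, n_samples_per_class = 8, n_modules = 2,
                      module_size = 10, seed = 42)
  b <- gen_expression(n_genes = 50, n_samples_per_class = 8, n_modules = 2,
                      module_size = 10, seed = 42)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth, b$truth)
  c <- gen_expression(n_genes = 50, n_samples_per_class = 8, n_modules = 2,
                      module_size = 10, seed = 43)
  expect_false(identical(a$dataset$values, c$dataset$values))

  r1 <- gen_reactions(sprintf("E%02d", 1:15), seed = 7)
  r2 <- gen_reactions(sprintf("E%02d", 1:15), seed = 7)
  expect_identical(r1, r2)

  n1 <- gen_association_network(n_nodes = 40, seed = 9)
  n2 <- gen_association_network(n_nodes = 40, seed = 9)
  expect_identical(n1$edges, n2$edges)

  t1 <- gen_term_map(letters, n_terms = 5, seed = 13)
  expect_identical(t1, gen_term_map(letters, n_terms = 5, seed = 13))

  # byte-identical files on repeated writes
  st <- gen_study(seed = 17, n_datasets = 1, n_samples_per_class = 6)
  f1 <- tempfile(); f2 <- tempfile()
  write_reactions_tsv(st$reactions, f1)
  write_reactions_tsv(gen_study(seed = 17, n_datasets = 1,
                                n_samples_per_class = 6)$reactions, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truth manifests validate against the generated data", {
  st <- gen_study(seed = 23, n_samples_per_class = 8)
  for (ds in st$datasets) {
    expect_true(all(st$truth$planted_module_genes %in% genes(ds)))
    expect_true(all(st$truth$planted_key_genes %in%
                      st$truth$planted_module_genes))
  }
  enzymes <- unique(unlist(st$reactions$enzymes))
  expect_true(all(st$truth$planted_key_genes %in% enzymes))
  expect_true(all(st$truth$planted_enriched_terms %in% names(st$term_map)))
  nodes <- igraph::V(st$assoc$graph)$name
  expect_true(all(st$truth$planted_close_genes %in% nodes))
  expect_true(all(st$truth$disease_genes %in% nodes))
})

test_that("expression generator plants correlation structure and disease signal", {
  set.seed(41)
  within <- numeric(10); between <- numeric(10); spec <- numeric(10)
  null_spec <- numeric(10)
  for (rep in 1:10) {
    sim <- gen_expression(n_genes = 60, n_samples_per_class = 15,
                          n_modules = 2, module_size = 15,
                          within_module_corr = 0.9, effect_size = 2,
                          missing_rate = 0, seed = 600 + rep)
    corr <- pearson_matrix(sim$dataset)
    m1 <- sim$truth$planted_module_genes
    inside <- abs(corr[m1, m1][upper.tri(diag(length(m1)))])
    noise <- genes(sim$dataset)[41:60]
    outside <- abs(corr[m1, noise])
    within[rep] <- mean(inside); between[rep] <- mean(outside)
    spec[rep] <- module_specificity(m1, sim$dataset)$specificity
    # no effect: specificity near chance
    sim0 <- gen_expression(n_genes = 60, n_samples_per_class = 15,
                           n_modules = 2, module_size = 15, effect_size = 0,
                           missing_rate = 0, seed = 700 + rep)
    null_spec[rep] <- module_specificity(sim0$truth$planted_module_genes,
                                         sim0$dataset)$specificity
  }
  expect_gte(mean(within), 0.6)
  expect_gt(mean(within), mean(between))
  expect_gte(mean(spec), 0.85)
  expect_lte(mean(null_spec), 0.7)  # max(AUC, 1-AUC) of chance AUC
  # heavy missingness wipes out the gene set at the 0.8 cutoff
  sim_na <- gen_expression(n_genes = 100, n_samples_per_class = 10,
                           n_modules = 1, module_size = 10,
                           missing_rate = 0.95, seed = 3)
  expect_error(filter_missing(sim_na$dataset, 0.8), "empty dataset")
})

test_that("reaction generator plants currency metabolites and key out-links", {
  ids <- sprintf("G%03d", 1:60)
  module <- ids[1:20]
  keys <- ids[1:4]
  sim <- gen_reactions(ids, key_gene_ids = keys, key_target_pool = module,
                       key_out_degree = 8, currency_metabolite_count = 2,
                       seed = 31)
  dir_rx <- split_reactions(sim$reactions)
  retained <- filter_metabolites(dir_rx)
  expect_setequal(sim$truth$currency_metabolites,
                  setdiff(unique(unlist(c(dir_rx$substrates, dir_rx$products))),
                          retained))
  net <- build_enzyme_graph(dir_rx, retained)
  expect_true(all(keys %in% outward_genes(net)))
  for (g in keys) {
    nb <- out_neighbors(net, g)
    expect_gte(length(intersect(nb, module)), 8)
  }
  # the planted counts (k = n = 8 of K = 19 module-mates in a background
  # of 200) imply an enrichment p far below 0.01
  expect_lt(phyper(8 - 1, 19, 180, 8, lower.tail = FALSE), 0.01)
})

test_that("association generator plants proximity and isolated nodes", {
  sim <- gen_association_network(n_nodes = 50, disease_gene_count = 5,
                                 planted_close_genes = c("N005", "N006"),
                                 planted_hops = 1, n_isolated = 2, seed = 11)
  res <- mean_set_distance(sim$truth$planted_close_genes, sim$disease_genes,
                           sim$graph)
  expect_equal(res$observed_mean, 1)
  # two-hop planting bounds the distance by 2
  sim2 <- gen_association_network(n_nodes = 50, disease_gene_count = 5,
                                  planted_close_genes = c("N005", "N006"),
                                  planted_hops = 2, seed = 11)
  res2 <- mean_set_distance(sim2$truth$planted_close_genes,
                            sim2$disease_genes, sim2$graph)
  expect_lte(res2$observed_mean, 2)
  # isolated nodes are reported as excluded by the distance machinery
  iso <- mean_set_distance(c("ISO_1", "N005"), sim$disease_genes, sim$graph)
  expect_true("ISO_1" %in% iso$excluded)
})

test_that("a single synthetic study replicate recovers the planted key genes end to end", {
  st <- gen_study(seed = 47)
  dir_rx <- split_reactions(st$reactions)
  net <- build_enzyme_graph(dir_rx, filter_metabolites(dir_rx))
  bg <- outward_genes(net)
  selections <- lapply(st$datasets, function(ds0) {
    ds <- normalize_expression(filter_missing(ds0))
    mods <- detect_modules(ds, seed = 1)
    sc <- score_genes(ds, mods, net, bg)
    sc$gene_id[sc$selected]
  })
  comb <- combine_datasets(selections, 2)
  expect_true(all(st$truth$planted_key_genes %in% comb$gene_id))
  # planted term enriched for the combined predictions
  enr <- fisher_enrichment(comb$gene_id, st$term_map, bg)
  expect_equal(enr$term_id[1], "PLANTED_MODULE")
  expect_lt(enr$q[1], 0.05)
})
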
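test_that("Pearson matrix matches hand-computed correlations and handles missingness", {
  vals <- rbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = c(8, 6, 4, 2))
  colnames(vals) <- paste0("s", 1:4)
  corr <- pearson_matrix(make_ds(vals, c(1L, 1L, 0L, 0L)), min_shared = 2)
  expect_equal(corr["x", "y"], 0.8)       # hand-applied PCC formula
  expect_equal(corr["x", "z"], -1)
  expect_equal(corr, t(corr))
  expect_equal(unname(diag(corr)), rep(1, 3))
  # pairs sharing fewer than min_shared samples get 0 (undefined)
  vals2 <- rbind(a = c(1, 2, NA, NA), b = c(NA, NA, 1, 2), c = c(1, 2, 3, 4))
  colnames(vals2) <- paste0("s", 1:4)
  corr2 <- pearson_matrix(make_ds(vals2, c(1L, 1L, 0L, 0L)), min_shared = 2)
  expect_equal(corr2["a", "b"], 0)
  expect_equal(corr2["a", "c"], 1)
})

test_that("edge rules produce the expected graphs", {
  corr <- matrix(0.9, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(corr) <- 1
  g <- build_coexpression_graph(corr, "abs_threshold", threshold = 0.8)
  expect_equal(igraph::ecount(g), 3)      # triangle
  g2 <- build_coexpression_graph(corr, "abs_threshold", threshold = 0.95)
  expect_equal(igraph::ecount(g2), 0)
  expect_error(build_coexpression_graph(corr, "abs_threshold", threshold = 1.2),
               "threshold")
  # top-k rule: union of per-gene strongest partners, checked by enumeration
  set.seed(7)
  for (rep in 1:10) {
    n <- 6
    m <- matrix(runif(n * n, -1, 1), n, n,
                dimnames = list(letters[1:n], letters[1:n]))
    m <- (m + t(m)) / 2; diag(m) <- 1
    gk <- build_coexpression_graph(m, "top_k_per_gene", k = 1)
    a <- abs(m); diag(a) <- 0
    want <- unique(t(apply(cbind(1:n, apply(a, 1, which.max)), 1, sort)))
    got <- igraph::as_edgelist(gk)
    got_idx <- unique(t(apply(matrix(match(got, letters[1:n]), ncol = 2), 1, sort)))
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got_idx[, 1], got_idx[, 2]),
                    paste(want[, 1], want[, 2]))
  }
})

test_that("modularity partition separates planted cliques and filters small communities", {
  g1 <- igraph::make_full_graph(15)
  g2 <- igraph::make_full_graph(15)
  g <- igraph::add_edges(igraph::disjoint_union(g1, g2), c(1, 16))
  igraph::V(g)$name <- sprintf("n%02d", 1:30)
  part <- partition_modules(g, min_size = 11, seed = 1)
  expect_equal(lengths(part$modules), c(15L, 15L))
  expect_setequal(part$modules[[1]], sprintf("n%02d", 1:15))

  # one clique: no cut improves Q
  gc <- igraph::make_full_graph(30)
  igraph::V(gc)$name <- sprintf("c%02d", 1:30)
  expect_equal(lengths(partition_modules(gc)$modules), 30L)

  # communities below min_size go to the unassigned pool
  g8 <- igraph::disjoint_union(igraph::make_full_graph(8),
                               igraph::make_full_graph(8))
  igraph::V(g8)$name <- sprintf("e%02d", 1:16)
  p8 <- partition_modules(g8, min_size = 11)
  expect_length(p8$modules, 0)
  expect_length(p8$unassigned, 16)

  # edgeless graph: zero modules, not an error
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  expect_length(partition_modules(g0)$modules, 0)
})

test_that("partition plus unassigned pool is an exact cover of the graph nodes", {
  set.seed(3)
  for (rep in 1:5) {
    sim <- gen_expression(n_genes = 80, n_samples_per_class = 15,
                          n_modules = 3, module_size = 15, seed = rep)
    ds <- normalize_expression(sim$dataset)
    mods <- detect_modules(ds, min_size = 5, seed = rep)
    assigned <- unlist(mods$modules)
    expect_false(any(duplicated(assigned)))
    expect_setequal(c(assigned, mods$unassigned), genes(ds))
    # membership agrees with the module lists
    for (i in seq_along(mods$modules))
      expect_setequal(names(mods$membership)[mods$membership == i],
                      mods$modules[[i]])
  }
})

test_that("module specificity reproduces the concordant-pair AUC and direction rules", {
  vals <- rbind(g1 = c(5, 6, 7, 1, 2, 3), g2 = c(5, 6, 7, 1, 2, 3))
  colnames(vals) <- paste0("s", 1:6)
  ds <- make_ds(vals, c(1L, 1L, 1L, 0L, 0L, 0L))
  up <- module_specificity(c("g1", "g2"), ds)
  expect_equal(up$auc, 1)
  expect_equal(up$specificity, 1)
  expect_equal(up$direction, "up")

  ds_dn <- make_ds(vals, c(0L, 0L, 0L, 1L, 1L, 1L))
  dn <- module_specificity(c("g1", "g2"), ds_dn)
  expect_equal(dn$auc, 0)
  expect_equal(dn$specificity, 1)
  expect_equal(dn$direction, "down")

  # disease (3,1) vs normal (2,4): 1 concordant of 4 pairs
  vals2 <- rbind(g1 = c(3, 1, 2, 4)); colnames(vals2) <- paste0("s", 1:4)
  ds2 <- make_ds(vals2, c(1L, 1L, 0L, 0L))
  m2 <- module_specificity("g1", ds2)
  expect_equal(m2$auc, 0.25)
  expect_equal(m2$specificity, 0.75)

  expect_error(module_specificity(c("g1", "nope"), ds), "absent from dataset")
})

test_that("rank AUC equals brute-force pair counting and is monotone-invariant", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(4:16, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    score <- sample(seq(0, 3, by = 0.5), n, replace = TRUE)  # with ties
    expect_equal(roc_auc(score, labels), auc_brute(score, labels))
    # strictly monotone transform leaves the AUC unchanged
    expect_equal(roc_auc(exp(2 * score) + 1, labels), roc_auc(score, labels))
  }
})

test_that("planted disease modules are recovered with high overlap and specificity", {
  hits <- 0L
  n_rep <- 50L
  for (rep in seq_len(n_rep)) {
    sim <- gen_expression(n_genes = 100, n_samples_per_class = 25,
                          n_modules = 3, module_size = 20, effect_size = 2.5,
                          within_module_corr = 0.8, missing_rate = 0.02,
                          seed = 1000 + rep)
    ds <- normalize_expression(filter_missing(sim$dataset))
    mods <- detect_modules(ds, threshold = 0.7, seed = rep)
    truth <- sim$truth$planted_module_genes
    jac <- vapply(mods$modules, function(m)
      length(intersect(m, truth)) / length(union(m, truth)), numeric(1))
    if (!length(jac)) next
    best <- which.max(jac)
    if (jac[best] >= 0.8 && mods$table$specificity[best] >= 0.9)
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
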
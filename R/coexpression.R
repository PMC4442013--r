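#' Pairwise Pearson correlation matrix
#'
#' Correlations are computed over pairwise-complete observations of the
#' missing mask. Gene pairs with fewer than `min_shared` shared
#' non-missing samples (default 4) have an undefined correlation and are
#' set to 0, as are pairs where a gene is constant. The diagonal is 1.
#'
#' @param ds a [expression_dataset()] object.
#' @param min_shared minimum shared non-missing samples for a defined
#'   correlation.
#' @return symmetric genes x genes correlation matrix.
#' @export
pearson_matrix <- function(ds, min_shared = 4L) {
  stopifnot(inherits(ds, "metx_expression"))
  if (nrow(ds$values) < 2L) stop("need at least 2 genes")
  corr <- suppressWarnings(cor(t(ds$values), use = "pairwise.complete.obs"))
  shared <- tcrossprod(!is.na(ds$values) * 1)
  corr[shared < min_shared] <- 0
  corr[is.na(corr)] <- 0
  diag(corr) <- 1
  corr
}

#' Build the coexpression graph from a correlation matrix
#'
#' `abs_threshold` keeps an edge iff `|PCC| >= threshold`;
#' `top_k_per_gene` keeps the union over genes of each gene's `k`
#' strongest-|PCC| partners. The graph is undirected and simple; the
#' signed correlation is kept as edge attribute `pcc`, the weight is
#' `|pcc|`.
#'
#' @param corr symmetric correlation matrix with gene dimnames.
#' @param edge_rule `"abs_threshold"` or `"top_k_per_gene"`.
#' @param threshold absolute-correlation cutoff in \[0, 1\].
#' @param k neighbours per gene for the top-k rule.
#' @return an undirected igraph graph over all genes in `corr`.
#' @export
build_coexpression_graph <- function(corr,
                                     edge_rule = c("abs_threshold", "top_k_per_gene"),
                                     threshold = 0.7, k = 5L) {
  edge_rule <- match.arg(edge_rule)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            !is.null(rownames(corr)))
  n <- nrow(corr)
  a <- abs(corr)
  diag(a) <- 0
  if (edge_rule == "abs_threshold") {
    if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
    keep <- a >= threshold
  } else {
    if (k < 1L) stop("k must be >= 1")
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      ord <- order(a[i, ], decreasing = TRUE)
      top <- ord[seq_len(min(k, n - 1L))]
      top <- top[a[i, top] > 0]
      keep[i, top] <- TRUE
    }
    keep <- keep | t(keep)
  }
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(corr))
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(rownames(corr)[idx[, 1]],
                                    rownames(corr)[idx[, 2]]))
    pcc <- corr[idx]
    g <- igraph::set_edge_attr(g, "pcc", value = pcc)
    g <- igraph::set_edge_attr(g, "weight", value = abs(pcc))
  }
  g
}

# ---- Qcut-style modularity partition -------------------------------------
# Recursive spectral bisection on the generalized modularity matrix
# (Newman leading-eigenvector), with a Kernighan-Lin-style single-vertex
# refinement of every split and a final greedy pairwise merge step.

# refine a +/-1 split by greedy single-vertex flips; each vertex moves at
# most once per pass, the best configuration seen is kept
.kl_refine <- function(Bg, s, max_passes = 8L) {
  f <- as.numeric(t(s) %*% Bg %*% s)
  for (pass in seq_len(max_passes)) {
    moved <- rep(FALSE, length(s))
    best_f <- f; best_s <- s
    cur_s <- s; cur_f <- f
    for (step in seq_along(s)) {
      gains <- -4 * cur_s * as.numeric(Bg %*% cur_s) + 4 * diag(Bg)
      gains[moved] <- -Inf
      v <- which.max(gains)
      cur_f <- cur_f + gains[v]
      cur_s[v] <- -cur_s[v]
      moved[v] <- TRUE
      if (cur_f > best_f) { best_f <- cur_f; best_s <- cur_s }
    }
    if (best_f > f + 1e-12) { f <- best_f; s <- best_s } else break
  }
  list(s = s, f = f)
}

# attempt to split one community (vertex index set idx); NULL = indivisible
.spectral_split <- function(A, deg, m2, idx) {
  ng <- length(idx)
  if (ng < 2L) return(NULL)
  B <- A[idx, idx, drop = FALSE] - outer(deg[idx], deg[idx]) / m2
  Bg <- B
  diag(Bg) <- diag(B) - rowSums(B)
  es <- eigen(Bg, symmetric = TRUE)
  if (es$values[1] <= 1e-9) return(NULL)
  s <- ifelse(es$vectors[, 1] >= 0, 1, -1)
  if (all(s == s[1])) s[which.min(es$vectors[, 1] * s[1])] <- -s[1]
  ref <- .kl_refine(Bg, s)
  if (ref$f <= 1e-9 || all(ref$s == ref$s[1])) return(NULL)
  ref$s
}

# greedy pairwise merging while any merge increases Q
.merge_communities <- function(A, deg, m2, comm) {
  repeat {
    ids <- sort(unique(comm))
    if (length(ids) < 2L) break
    a <- vapply(ids, function(cid) sum(deg[comm == cid]) / m2, numeric(1))
    best <- c(NA, NA); best_gain <- 1e-10
    for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1L)) {
      vi <- comm == ids[i]; vj <- comm == ids[j]
      e_ij <- sum(A[vi, vj])
      if (e_ij == 0) next
      gain <- 2 * (e_ij / m2 - a[i] * a[j])
      if (gain > best_gain) { best_gain <- gain; best <- c(ids[i], ids[j]) }
    }
    if (is.na(best[1])) break
    comm[comm == best[1]] <- best[2]
  }
  comm
}

#' Partition a coexpression graph into modules
#'
#' Modularity (Q) optimization in the style of Qcut: starting from the
#' connected components, each community is recursively bisected with the
#' leading eigenvector of its generalized modularity matrix, every split
#' is refined by greedy single-vertex moves, recursion stops when no
#' split increases Q, and a final greedy merge step joins community
#' pairs whenever merging increases Q. Communities with at least
#' `min_size` genes become modules; the rest form the unassigned pool.
#' The procedure is deterministic given `seed`.
#'
#' @param graph undirected igraph graph with named vertices.
#' @param min_size smallest community reported as a module. The default
#'   11 keeps modules with strictly more than 10 genes.
#' @param seed integer seed (the algorithm is deterministic; the seed
#'   fixes tie-breaking order).
#' @return list with elements `modules` (list of gene-id vectors, by
#'   decreasing size), `unassigned` (gene ids), `membership` (named
#'   integer vector over all vertices; 0 = unassigned), and `Q` (Newman
#'   modularity of the full community structure before size filtering).
#' @export
partition_modules <- function(graph, min_size = 11L, seed = 1L) {
  stopifnot(igraph::is_igraph(graph))
  set.seed(seed)
  ids <- igraph::V(graph)$name
  n <- length(ids)
  if (igraph::ecount(graph) == 0L)
    return(list(modules = list(), unassigned = ids,
                membership = setNames(integer(n), ids), Q = NA_real_))
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  A <- (A > 0) * 1
  diag(A) <- 0
  deg <- rowSums(A)
  m2 <- sum(deg)

  comm <- igraph::components(graph)$membership
  queue <- unique(comm)
  next_id <- max(comm)
  while (length(queue)) {
    cid <- queue[1]; queue <- queue[-1]
    idx <- which(comm == cid)
    s <- .spectral_split(A, deg, m2, idx)
    if (is.null(s)) next
    next_id <- next_id + 1L
    comm[idx[s < 0]] <- next_id
    queue <- c(queue, cid, next_id)
  }
  comm <- .merge_communities(A, deg, m2, comm)
  Q <- igraph::modularity(graph, as.integer(factor(comm)))

  groups <- split(ids, comm)
  sizes <- lengths(groups)
  big <- groups[sizes >= min_size]
  ord <- order(-lengths(big), vapply(big, min, character(1)))
  modules <- unname(big[ord])
  membership <- setNames(integer(n), ids)
  for (i in seq_along(modules)) membership[modules[[i]]] <- i
  list(modules = modules,
       unassigned = ids[membership[ids] == 0L],
       membership = membership, Q = Q)
}

#' ROC-AUC of a score vector against binary labels
#'
#' Mann-Whitney rank form: ties contribute 1/2. The positive class is
#' label 1 (disease).
#'
#' @param score numeric scores, one per sample.
#' @param labels binary 0/1 labels aligned with `score`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(score, labels) {
  ok <- !is.na(score) & !is.na(labels)
  score <- score[ok]; labels <- as.integer(labels[ok])
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both label classes required")
  r <- rank(score)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Disease specificity of a coexpression module
#'
#' The module's per-sample profile is the median over its genes of the
#' (non-missing) expression values. The AUC of that profile against the
#' disease/normal labels is made orientation-invariant:
#' `specificity = max(AUC, 1 - AUC)`, with the direction (up for
#' AUC > 0.5 in disease, down for < 0.5, flat at 0.5) kept separately.
#'
#' @param module_genes gene ids, all present in `ds`.
#' @param ds a [expression_dataset()] object.
#' @return list with `specificity`, `direction`, `auc`, `median_profile`.
#' @export
module_specificity <- function(module_genes, ds) {
  stopifnot(inherits(ds, "metx_expression"), length(module_genes) > 0L)
  missing_genes <- setdiff(module_genes, genes(ds))
  if (length(missing_genes))
    stop("module gene absent from dataset: ", paste(missing_genes, collapse = ", "))
  sub <- ds$values[module_genes, , drop = FALSE]
  profile <- apply(sub, 2, function(col) {
    v <- col[!is.na(col)]
    if (!length(v)) NA_real_ else median(v)
  })
  auc <- roc_auc(profile, ds$labels)
  direction <- if (auc > 0.5) "up" else if (auc < 0.5) "down" else "flat"
  list(specificity = max(auc, 1 - auc), direction = direction,
       auc = auc, median_profile = profile)
}

#' Detect and score coexpression modules in one dataset
#'
#' Convenience wrapper running [pearson_matrix()],
#' [build_coexpression_graph()], [partition_modules()] and
#' [module_specificity()] in sequence.
#'
#' @inheritParams build_coexpression_graph
#' @inheritParams partition_modules
#' @param ds a [expression_dataset()] object (filtered and normalized).
#' @return object of class `metx_modules`: list with `modules` (gene-id
#'   lists), `table` (data frame: module_id, n_genes, specificity, auc,
#'   direction), `membership`, `unassigned`, `Q`, `dataset_id`.
#' @export
detect_modules <- function(ds, edge_rule = c("abs_threshold", "top_k_per_gene"),
                           threshold = 0.7, k = 5L, min_size = 11L, seed = 1L) {
  edge_rule <- match.arg(edge_rule)
  corr <- pearson_matrix(ds)
  graph <- build_coexpression_graph(corr, edge_rule, threshold = threshold, k = k)
  part <- partition_modules(graph, min_size = min_size, seed = seed)
  spec <- lapply(part$modules, module_specificity, ds = ds)
  tab <- data.frame(
    module_id = seq_along(part$modules),
    n_genes = lengths(part$modules),
    specificity = vapply(spec, `[[`, numeric(1), "specificity"),
    auc = vapply(spec, `[[`, numeric(1), "auc"),
    direction = vapply(spec, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE)
  structure(list(modules = part$modules, table = tab,
                 membership = part$membership,
                 unassigned = part$unassigned, Q = part$Q,
                 dataset_id = ds$dataset_id),
            class = "metx_modules")
}

#' @export
print.metx_modules <- function(x, ...) {
  cat(sprintf("<metx_modules '%s'> %d modules (Q = %.3f), %d unassigned genes\n",
              x$dataset_id, length(x$modules),
              if (is.na(x$Q)) NA else x$Q, length(x$unassigned)))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a module table as TSV
#'
#' One row per module: module_id, n_genes, specificity, direction and
#' the comma-joined gene list.
#'
#' @param mods a `metx_modules` object from [detect_modules()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modules_tsv <- function(mods, path) {
  tab <- mods$table
  tab$genes <- vapply(mods$modules, paste, character(1), collapse = ",")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
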
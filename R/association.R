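#' Build or read a functional-association network
#'
#' The network is an undirected simple graph over gene ids, optionally
#' carrying positive confidence weights (FunCoup-style). Input is a
#' data frame or 2-/3-column TSV edge list (`gene_a`, `gene_b`
#' \[, `weight`\]); duplicate edges are collapsed (maximum confidence
#' kept).
#'
#' @param edges data frame with two id columns and an optional numeric
#'   `weight` column.
#' @return an undirected igraph graph.
#' @export
association_network <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  has_w <- ncol(edges) >= 3L
  if (has_w) {
    names(edges)[1:3] <- c("from", "to", "weight")
    if (any(edges$weight <= 0)) stop("confidence weights must be > 0")
  } else names(edges)[1:2] <- c("from", "to")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(weight = "max", "ignore"))
}

#' @rdname association_network
#' @param path TSV edge list with a header row.
#' @export
read_association_network <- function(path) {
  association_network(read.delim(path, stringsAsFactors = FALSE))
}

.edge_costs <- function(net, mode) {
  if (mode == "hops") return(NA)  # igraph: NA = ignore weights
  w <- igraph::E(net)$weight
  if (is.null(w)) stop("weighted mode requires a weight edge attribute")
  1 / w  # higher confidence = shorter
}

#' Shortest-path distances from one gene
#'
#' Dijkstra distances (via igraph) from `source` to every node.
#' `hops` uses unit edge cost; `weighted` uses cost `1/confidence`.
#' Unreachable nodes get `Inf`.
#'
#' @param source a gene id present in the network.
#' @param net an [association_network()] graph.
#' @param mode `"hops"` or `"weighted"`.
#' @return named numeric distance vector over all nodes.
#' @export
shortest_paths_from <- function(source, net, mode = c("hops", "weighted")) {
  mode <- match.arg(mode)
  if (!source %in% igraph::V(net)$name)
    stop("source absent from network: ", source)
  igraph::distances(net, v = source, mode = "all",
                    weights = .edge_costs(net, mode))[1, ]
}

# per-gene mean distances to the disease set for a block of query nodes
# (all present in the network); self-distances optionally excluded
.per_gene_means <- function(query_in, disease_in, net, mode, include_self) {
  D <- igraph::distances(net, v = query_in, to = disease_in,
                         weights = .edge_costs(net, mode))
  if (!include_self) {
    both <- intersect(query_in, disease_in)
    D[cbind(both, both)] <- NA_real_
  }
  D[!is.finite(D)] <- NA_real_
  rowMeans(D, na.rm = TRUE)  # NaN when no disease gene is reachable
}

#' Mean shortest-path distance between a gene set and disease genes
#'
#' For every query gene, the mean shortest-path distance to all
#' reachable known disease genes; the observed statistic is the mean of
#' those per-gene means. Query genes absent from the network or
#' reaching no disease gene are excluded (and reported). A query gene
#' that is itself a disease gene has its zero self-distance excluded by
#' default.
#'
#' @param query_set predicted gene ids.
#' @param disease_genes known disease gene ids.
#' @param net an [association_network()] graph.
#' @param mode `"hops"` or `"weighted"` (see [shortest_paths_from()]).
#' @param include_self include the 0 self-distance for query genes that
#'   are also disease genes.
#' @return list `observed_mean`, `per_gene_means` (named), `excluded`.
#' @export
mean_set_distance <- function(query_set, disease_genes, net,
                              mode = c("hops", "weighted"),
                              include_self = FALSE) {
  mode <- match.arg(mode)
  nodes <- igraph::V(net)$name
  query_in <- intersect(unique(query_set), nodes)
  disease_in <- intersect(unique(disease_genes), nodes)
  if (!length(query_in) || !length(disease_in))
    stop("query and disease sets must intersect the network")
  pg <- .per_gene_means(query_in, disease_in, net, mode, include_self)
  unreachable <- names(pg)[is.nan(pg)]
  pg <- pg[!is.nan(pg)]
  if (!length(pg)) stop("no query gene reaches any disease gene")
  list(observed_mean = mean(pg),
       per_gene_means = pg,
       excluded = sort(c(setdiff(unique(query_set), nodes), unreachable)))
}

#' Permutation test of network proximity to known disease genes
#'
#' Compares the observed mean shortest-path statistic of the query set
#' (see [mean_set_distance()]) with a null built by drawing the same
#' number of genes uniformly without replacement from the pool,
#' `n_perm` times, applying identical exclusion rules. The empirical
#' p-value is the fraction of null means less than or equal to the
#' observed mean (no smoothing, so p = 0 is possible; the
#' `p_smoothed` field reports `(1 + count) / (1 + n_perm)`).
#'
#' @inheritParams mean_set_distance
#' @param n_perm number of null draws (default 1000).
#' @param pool `"network"` (all network nodes, default) or a character
#'   vector of gene ids to sample from (e.g. the enzyme background).
#' @param seed integer seed; the test is fully reproducible.
#' @return object of class `metx_assoc`: `observed_mean`, `null_means`,
#'   `p_empirical`, `p_smoothed`, `per_gene_mean_distance`, `excluded`,
#'   `null_summary` (mean, sd, 2.5/97.5 percentiles), `n_perm`, `seed`.
#' @export
permutation_test <- function(query_set, disease_genes, net, n_perm = 1000L,
                             pool = "network", seed = 1L,
                             mode = c("hops", "weighted"),
                             include_self = FALSE) {
  mode <- match.arg(mode)
  nodes <- igraph::V(net)$name
  pool_genes <- if (identical(pool, "network")) nodes
                else intersect(unique(pool), nodes)
  query_in <- intersect(unique(query_set), nodes)
  disease_in <- intersect(unique(disease_genes), nodes)
  if (!length(query_in) || !length(disease_in))
    stop("query and disease sets must intersect the network")
  if (length(pool_genes) < length(query_in))
    stop("pool smaller than query set")
  # one distance computation covers the query and every possible draw
  all_v <- union(pool_genes, query_in)
  pg <- .per_gene_means(all_v, disease_in, net, mode, include_self)
  obs_pg <- pg[query_in]
  unreachable <- names(obs_pg)[is.nan(obs_pg)]
  obs_pg <- obs_pg[!is.nan(obs_pg)]
  if (!length(obs_pg)) stop("no query gene reaches any disease gene")
  observed <- mean(obs_pg)
  set.seed(seed)
  q_size <- length(query_in)
  null_means <- vapply(seq_len(n_perm), function(i) {
    draw <- pg[sample(pool_genes, q_size)]
    draw <- draw[!is.nan(draw)]
    if (!length(draw)) NA_real_ else mean(draw)
  }, numeric(1))
  hits <- sum(null_means <= observed, na.rm = TRUE)
  structure(list(
    observed_mean = observed,
    null_means = null_means,
    p_empirical = hits / n_perm,
    p_smoothed = (1 + hits) / (1 + n_perm),
    per_gene_mean_distance = obs_pg,
    excluded = sort(c(setdiff(unique(query_set), nodes), unreachable)),
    null_summary = c(mean = mean(null_means, na.rm = TRUE),
                     sd = sd(null_means, na.rm = TRUE),
                     quantile(null_means, c(0.025, 0.975), na.rm = TRUE)),
    n_perm = n_perm, seed = seed), class = "metx_assoc")
}

#' @export
print.metx_assoc <- function(x, ...) {
  cat(sprintf(
    "<metx_assoc> observed mean shortest path = %.3f; null %.3f +/- %.3f; empirical p = %.4g (n_perm = %d)\n",
    x$observed_mean, x$null_summary["mean"], x$null_summary["sd"],
    x$p_empirical, x$n_perm))
  invisible(x)
}

#' Rank genes by proximity to the disease genes
#'
#' Ascending by mean shortest-path distance; ties broken
#' lexicographically by gene id.
#'
#' @param per_gene_means named numeric vector (e.g.
#'   `per_gene_mean_distance` from [permutation_test()]).
#' @param n optionally return only the closest `n` genes.
#' @return data frame `gene_id`, `mean_distance`, in rank order.
#' @export
rank_closest <- function(per_gene_means, n = NULL) {
  if (!length(per_gene_means)) stop("non-empty distance map required")
  ord <- order(per_gene_means, names(per_gene_means))
  out <- data.frame(gene_id = names(per_gene_means)[ord],
                    mean_distance = unname(per_gene_means[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(n)) out <- head(out, n)
  rownames(out) <- NULL
  out
}
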
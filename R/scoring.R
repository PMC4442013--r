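#' Hypergeometric enrichment of a gene's metabolic links in its module
#'
#' Tests whether the gene's outward metabolic links (its out-neighbors
#' in the enzyme network, restricted to the scoring background) fall
#' inside its own coexpression module more often than expected by
#' chance. With `N = |background| - 1` genes (the gene itself removed),
#' `K` of them module-mates, and `n` out-neighbors drawn, the p-value is
#' the upper hypergeometric tail `P(X >= k)` of the `k` within-module
#' neighbors. `k = 0` gives p = 1; a gene without outward links is
#' flagged.
#'
#' @param gene gene id; must be in `background`.
#' @param module_genes the gene's coexpression-module members.
#' @param net a `metx_metnet` object.
#' @param background the scoring background (outward genes intersected
#'   with the expression genes).
#' @return list `k`, `n`, `K`, `N`, `p`, `no_outward`.
#' @export
link_enrichment <- function(gene, module_genes, net, background) {
  if (!gene %in% background) stop("gene not in background: ", gene)
  nb <- intersect(out_neighbors(net, gene), background)
  mod_bg <- setdiff(intersect(module_genes, background), gene)
  n <- length(nb)
  K <- length(mod_bg)
  N <- length(background) - 1L
  k <- length(intersect(nb, mod_bg))
  p <- if (k == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, p = min(p, 1), no_outward = n == 0L)
}

#' Combine module specificity and link enrichment into one score
#'
#' `product_neglog` (default): `specificity * (-log10 p)` — zero when
#' p = 1, increasing in specificity and decreasing in p. `rank_sum`:
#' the average of the two within-dataset ranks (higher specificity and
#' lower p rank better); used when the two scales should not be fused
#' directly. Vectorized over genes; `rank_sum` requires the full
#' per-dataset vectors.
#'
#' @param specificity module specificities in \[0.5, 1\].
#' @param p enrichment p-values in (0, 1\]; exact zeros are clamped to
#'   the smallest positive double with a warning.
#' @param combiner `"product_neglog"` or `"rank_sum"`.
#' @return numeric importance scores (>= 0).
#' @export
importance_score <- function(specificity, p,
                             combiner = c("product_neglog", "rank_sum")) {
  combiner <- match.arg(combiner)
  if (any(p < 0 | p > 1)) stop("p-values must be in (0, 1]")
  if (any(p == 0)) {
    warning("p = 0 clamped to machine minimum")
    p[p == 0] <- .Machine$double.xmin
  }
  if (combiner == "product_neglog") {
    specificity * (-log10(p))
  } else {
    (rank(specificity) + rank(-p)) / 2
  }
}

#' Score all background genes of one dataset
#'
#' Builds one importance record per background gene present in the
#' expression dataset: its module id (NA for genes in no retained
#' module), the module's disease specificity (0.5 for unassigned genes,
#' whose enrichment p is 1 and importance 0), the link-enrichment
#' counts and p-value, the combined importance, and the
#' median-cutoff selection flag.
#'
#' @param ds a [expression_dataset()] object (the one `mods` was
#'   detected on).
#' @param mods a `metx_modules` object from [detect_modules()].
#' @param net a `metx_metnet` object.
#' @param background outward genes of `net`; intersected with the
#'   dataset's genes before scoring.
#' @param combiner passed to [importance_score()].
#' @param median_rule passed to [select_candidates()].
#' @return data frame of class `metx_scores` with columns `gene_id`,
#'   `dataset_id`, `module_id`, `specificity`, `out_neighbors_total`,
#'   `out_neighbors_in_module`, `enrichment_p`, `importance`,
#'   `selected`.
#' @export
score_genes <- function(ds, mods, net, background,
                        combiner = c("product_neglog", "rank_sum"),
                        median_rule = c("strict", "gte")) {
  combiner <- match.arg(combiner)
  median_rule <- match.arg(median_rule)
  bg <- intersect(background, genes(ds))
  if (length(bg) < 2L) stop("need at least 2 background genes in the dataset")
  member <- mods$membership[bg]
  member[is.na(member)] <- 0L
  spec_by_module <- c(0.5, mods$table$specificity)[member + 1L]
  enr <- lapply(seq_along(bg), function(i) {
    module_genes <- if (member[i] > 0L) mods$modules[[member[i]]] else character(0)
    link_enrichment(bg[i], module_genes, net, bg)
  })
  p <- vapply(enr, `[[`, numeric(1), "p")
  rec <- data.frame(
    gene_id = bg,
    dataset_id = ds$dataset_id,
    module_id = ifelse(member > 0L, member, NA_integer_),
    specificity = spec_by_module,
    out_neighbors_total = vapply(enr, `[[`, integer(1), "n"),
    out_neighbors_in_module = vapply(enr, `[[`, integer(1), "k"),
    enrichment_p = p,
    importance = importance_score(spec_by_module, p, combiner),
    stringsAsFactors = FALSE)
  rec$selected <- rec$gene_id %in% select_candidates(rec, median_rule)
  rownames(rec) <- NULL
  class(rec) <- c("metx_scores", "data.frame")
  rec
}

#' Select per-dataset candidate genes at the median importance cutoff
#'
#' Returns the genes whose importance exceeds the median importance over
#' all scored background genes of the dataset (strictly, by default; the
#' `"gte"` rule includes ties at the median). If all scores are
#' identical nothing exceeds the median and an empty selection is
#' returned with a warning.
#'
#' @param records a `metx_scores` data frame (one dataset).
#' @param median_rule `"strict"` (>) or `"gte"` (>=).
#' @return character vector of selected gene ids.
#' @export
select_candidates <- function(records, median_rule = c("strict", "gte")) {
  median_rule <- match.arg(median_rule)
  if (nrow(records) < 2L) stop("need at least 2 scored genes")
  med <- median(records$importance)
  keep <- if (median_rule == "strict") records$importance > med
          else records$importance >= med
  if (median_rule == "strict" && !any(keep))
    warning("all importance scores identical; empty selection")
  records$gene_id[keep]
}

#' Combine per-dataset selections into the key gene set
#'
#' A gene becomes a key enzyme-coding gene when it is selected in at
#' least `min_datasets` datasets (default 2). The genes selected in
#' every dataset (the all-datasets core) are reported in the `core`
#' attribute and flagged in the `in_all` column.
#'
#' @param selections named list of per-dataset gene-id vectors.
#' @param min_datasets minimum number of datasets a key gene must be
#'   selected in.
#' @return data frame (class `metx_combined`) with columns `gene_id`,
#'   `n_datasets_predicted`, `dataset_ids`, `in_all`; attribute `core`.
#' @export
combine_datasets <- function(selections, min_datasets = 2L) {
  if (length(selections) < min_datasets)
    stop("fewer input sets (", length(selections), ") than min_datasets")
  if (is.null(names(selections)))
    names(selections) <- paste0("dataset", seq_along(selections))
  all_genes <- sort(unique(unlist(selections)))
  if (!length(all_genes)) {
    out <- data.frame(gene_id = character(0),
                      n_datasets_predicted = integer(0),
                      dataset_ids = character(0), in_all = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "core") <- character(0)
    class(out) <- c("metx_combined", "data.frame")
    return(out)
  }
  hits <- vapply(selections, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1L) hits <- matrix(hits, nrow = 1L)
  n_pred <- rowSums(hits)
  out <- data.frame(
    gene_id = all_genes,
    n_datasets_predicted = as.integer(n_pred),
    dataset_ids = apply(hits, 1, function(h)
      paste(names(selections)[h], collapse = ",")),
    in_all = n_pred == length(selections),
    stringsAsFactors = FALSE)
  out <- out[out$n_datasets_predicted >= min_datasets, , drop = FALSE]
  out <- out[order(-out$n_datasets_predicted, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "core") <- out$gene_id[out$in_all]
  class(out) <- c("metx_combined", "data.frame")
  out
}

#' Hypergeometric significance of the overlap between two gene sets
#'
#' Approximate test of whether two prediction sets drawn from a common
#' background share more genes than chance: upper hypergeometric tail
#' `P(X >= |A` \eqn{\cap}` B|)` for `|B|` draws from `|background|` with
#' `|A|` successes. The expected overlap under independence is
#' `|A||B|/|background|`.
#'
#' @param set_a,set_b gene sets, both subsets of `background`.
#' @param background the common background gene set.
#' @return list `overlap`, `expected`, `p`.
#' @export
overlap_significance <- function(set_a, set_b, background) {
  if (!length(background)) stop("empty background")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% background) || !all(set_b %in% background))
    stop("sets must be subsets of the background")
  N <- length(background)
  ov <- length(intersect(set_a, set_b))
  p <- if (ov == 0L) 1 else
    phyper(ov - 1L, length(set_a), N - length(set_a), length(set_b),
           lower.tail = FALSE)
  list(overlap = ov,
       expected = length(set_a) * length(set_b) / N,
       p = min(p, 1))
}

#' Write a per-dataset score table as TSV
#' @param records a `metx_scores` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
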
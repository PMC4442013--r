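#' Fisher exact term enrichment against the enzyme background
#'
#' One-sided (greater) Fisher exact test per term on the 2x2 table of
#' in-set/in-term membership. Term gene sets are intersected with the
#' background before testing, so `N` is always the background size;
#' genes of the query set outside the background are dropped too.
#' Terms with no overlap report p = 1. P-values are FDR-adjusted with
#' [bh_adjust()].
#'
#' @param gene_set query genes (e.g. the combined key genes).
#' @param term_map named list: term id -> gene-id vector. An optional
#'   `descriptions` attribute (named character) supplies term names.
#' @param background background gene set (the enzyme-coding genes of
#'   the metabolic network).
#' @param fdr_method `"BH"` (Benjamini-Hochberg, default) or `"BY"`.
#' @return data frame sorted by `q` then `p` with columns `term_id`,
#'   `term_name`, `k_in_set`, `n_set`, `K_in_background`,
#'   `N_background`, `p`, `q`.
#' @export
fisher_enrichment <- function(gene_set, term_map, background,
                              fdr_method = c("BH", "BY")) {
  fdr_method <- match.arg(fdr_method)
  if (!length(background)) stop("empty background")
  gene_set <- intersect(unique(gene_set), background)
  if (!length(gene_set)) stop("empty gene set (after background intersection)")
  N <- length(background)
  n <- length(gene_set)
  res <- lapply(names(term_map), function(tid) {
    tg <- intersect(unique(term_map[[tid]]), background)
    K <- length(tg)
    k <- length(intersect(tg, gene_set))
    p <- if (k == 0L) 1 else
      fisher.test(matrix(c(k, n - k, K - k, N - K - n + k), nrow = 2),
                  alternative = "greater")$p.value
    data.frame(term_id = tid, k_in_set = k, n_set = n, K_in_background = K,
               N_background = N, p = min(p, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  descr <- attr(term_map, "descriptions")
  out$term_name <- if (is.null(descr)) out$term_id else
    ifelse(is.na(descr[out$term_id]), out$term_id, descr[out$term_id])
  out$q <- bh_adjust(out$p, method = fdr_method)
  out <- out[order(out$q, out$p, out$term_id),
             c("term_id", "term_name", "k_in_set", "n_set",
               "K_in_background", "N_background", "p", "q")]
  rownames(out) <- NULL
  out
}

#' FDR adjustment of p-values
#'
#' Benjamini-Hochberg step-up (default) or Benjamini-Yekutieli, in the
#' input order. Idempotent: adjusting adjusted values changes nothing.
#'
#' @param pvals p-values in (0, 1].
#' @param method `"BH"` or `"BY"`.
#' @return adjusted q-values, capped at 1.
#' @export
bh_adjust <- function(pvals, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0, 1]")
  p.adjust(pvals, method = method)
}

#' Read a term-annotation map
#'
#' GMT: one term per line, `term_id TAB description TAB gene TAB gene
#' ...`. Two-column TSV: header `term_id`, `gene_id`, one pair per
#' line.
#'
#' @param path input file.
#' @param format `"gmt"` or `"tsv"`.
#' @return named list term id -> gene ids, with a `descriptions`
#'   attribute for GMT input.
#' @export
read_term_map <- function(path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "gmt") {
    fields <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
    fields <- fields[lengths(fields) >= 3L]
    terms <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(terms) <- vapply(fields, `[[`, character(1), 1L)
    attr(terms, "descriptions") <-
      setNames(vapply(fields, `[[`, character(1), 2L), names(terms))
    terms
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("term_id", "gene_id") %in% names(tab)))
      stop("term TSV needs columns term_id and gene_id")
    lapply(split(tab$gene_id, tab$term_id), unique)
  }
}

#' Write a term map in GMT format
#' @param term_map named list term id -> gene ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_gmt <- function(term_map, path) {
  descr <- attr(term_map, "descriptions")
  lines <- vapply(names(term_map), function(tid) {
    d <- if (is.null(descr) || is.na(descr[tid])) tid else descr[tid]
    paste(c(tid, d, term_map[[tid]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
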
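#' Construct an expression dataset
#'
#' Bundles a genes x samples value matrix with binary sample labels
#' (disease = 1, normal = 0). Missing measurements are stored as `NA` in
#' the matrix; the missing mask is `is.na(values)`. Both label classes
#' must be present.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing.
#' @param labels per-sample labels, aligned with `colnames(values)`.
#'   Either integer 0/1 or character `"disease"`/`"normal"` (case
#'   insensitive); a named vector is reordered to the sample order.
#' @param dataset_id identifier carried through score tables.
#' @return an object of class `metx_expression` with elements
#'   `dataset_id`, `values`, `labels`.
#' @export
expression_dataset <- function(values, labels, dataset_id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids; collapse them first (see load_expression)")
  if (!is.null(names(labels))) {
    if (!all(colnames(values) %in% names(labels)))
      stop("labels missing for some samples")
    labels <- labels[colnames(values)]
  }
  if (length(labels) != ncol(values))
    stop("one label per sample required")
  if (is.character(labels) || is.factor(labels)) {
    lab <- tolower(as.character(labels))
    known <- lab %in% c("disease", "normal", "control", "healthy")
    if (!all(known)) stop("unrecognized label value: ", lab[!known][1])
    labels <- as.integer(lab == "disease")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("a label class empty: need at least one disease and one normal sample")
  structure(
    list(dataset_id = dataset_id,
         values = values,
         labels = setNames(labels, colnames(values))),
    class = "metx_expression")
}

#' @export
print.metx_expression <- function(x, ...) {
  cat(sprintf(
    "<metx_expression '%s'> %d genes x %d samples (%d disease / %d normal), %.1f%% missing\n",
    x$dataset_id, nrow(x$values), ncol(x$values),
    sum(x$labels == 1L), sum(x$labels == 0L),
    100 * mean(is.na(x$values))))
  invisible(x)
}

#' Gene and sample accessors
#' @param ds a `metx_expression` object
#' @return character vector of ids
#' @export
genes <- function(ds) rownames(ds$values)

#' @rdname genes
#' @export
samples <- function(ds) colnames(ds$values)

.collapse_duplicates <- function(mat, rule) {
  ids <- rownames(mat)
  if (!anyDuplicated(ids)) return(mat)
  groups <- split(seq_len(nrow(mat)), ids)
  rows <- lapply(groups, function(idx) {
    if (length(idx) == 1L) return(mat[idx, ])
    sub <- mat[idx, , drop = FALSE]
    switch(rule,
      median = apply(sub, 2, median, na.rm = TRUE),
      first = sub[1L, ],
      max_variance = sub[which.max(apply(sub, 1, function(r) {
        v <- var(r, na.rm = TRUE); if (is.na(v)) -Inf else v
      })), ])
  })
  out <- do.call(rbind, rows)
  out[is.nan(out)] <- NA_real_
  # keep first-appearance order of the ids
  out[unique(ids), , drop = FALSE]
}

.read_labels_tsv <- function(path, sample_ids) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(tab)))
    stop("labels file needs columns sample_id and label")
  miss <- setdiff(sample_ids, tab$sample_id)
  if (length(miss)) stop("no label for sample(s): ", paste(miss, collapse = ", "))
  setNames(tab$label, tab$sample_id)[sample_ids]
}

.parse_soft <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tb <- grep("^!dataset_table_begin", lines)
  te <- grep("^!dataset_table_end", lines)
  if (length(tb) != 1L || length(te) != 1L || te <= tb + 1L)
    stop("unreadable SOFT file: no dataset table found")
  tab <- read.delim(text = paste(lines[(tb + 1L):(te - 1L)], collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("null", "NA", ""))
  if (!"ID_REF" %in% names(tab)) stop("unreadable SOFT file: no ID_REF column")
  id_col <- if ("IDENTIFIER" %in% names(tab)) "IDENTIFIER" else "ID_REF"
  value_cols <- setdiff(names(tab), c("ID_REF", "IDENTIFIER"))
  mat <- as.matrix(tab[, value_cols, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- as.character(tab[[id_col]])

  # subset blocks carry the group labels
  starts <- grep("^\\^SUBSET", lines)
  if (!length(starts)) stop("no label information: SOFT file has no subset blocks")
  bounds <- c(starts, length(lines) + 1L)
  labels <- character(0)
  dataset_id <- sub("^\\^DATASET\\s*=\\s*", "",
                    grep("^\\^DATASET", lines, value = TRUE)[1])
  for (i in seq_along(starts)) {
    blk <- lines[starts[i]:(bounds[i + 1L] - 1L)]
    field <- function(key) {
      hit <- grep(paste0("^!", key, "\\s*="), blk, value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub("^[^=]*=\\s*", "", hit[1]))
    }
    type <- field("subset_type")
    if (!is.na(type) && !grepl("disease", type, ignore.case = TRUE)) next
    ids <- strsplit(field("subset_sample_id"), "\\s*,\\s*")[[1]]
    desc <- field("subset_description")
    lab <- if (grepl("control|normal|healthy", desc, ignore.case = TRUE))
      "normal" else "disease"
    labels[ids] <- lab
  }
  unlabeled <- setdiff(colnames(mat), names(labels))
  if (length(unlabeled))
    stop("no label for sample(s): ", paste(unlabeled, collapse = ", "))
  list(values = mat, labels = labels[colnames(mat)],
       dataset_id = if (is.na(dataset_id)) basename(path) else dataset_id)
}

#' Read an expression matrix with sample labels
#'
#' Supports a plain TSV (first column gene id, one column per sample, a
#' sidecar two-column labels file) and a minimal GDS/SOFT dialect in
#' which `^SUBSET` blocks define the sample groups (subset descriptions
#' matching control/normal/healthy become the normal class) and the
#' `ID_REF` table holds the values, with `null` marking missing entries.
#'
#' Duplicate gene ids (multiple probes for one gene) are collapsed by
#' the per-sample median across duplicate rows by default; `"first"`
#' and `"max_variance"` are available.
#'
#' @param path input file.
#' @param format `"tsv"` or `"soft"`.
#' @param labels for `format = "tsv"`, path to a TSV with columns
#'   `sample_id` and `label` (disease/normal), or a vector of labels.
#' @param duplicate_rule how to collapse duplicated gene ids.
#' @param dataset_id identifier; defaults to the file name (TSV) or the
#'   `^DATASET` accession (SOFT).
#' @return a [expression_dataset()] object.
#' @export
load_expression <- function(path, format = c("tsv", "soft"), labels = NULL,
                            duplicate_rule = c("median", "first", "max_variance"),
                            dataset_id = NULL) {
  format <- match.arg(format)
  duplicate_rule <- match.arg(duplicate_rule)
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("null", "NA", ""))
    if (ncol(tab) < 2L) stop("unreadable file: expected gene id + sample columns")
    mat <- as.matrix(tab[, -1, drop = FALSE])
    mode(mat) <- "numeric"
    rownames(mat) <- as.character(tab[[1]])
    if (is.null(labels)) stop("no label column: TSV input needs a labels file")
    if (is.character(labels) && length(labels) == 1L && file.exists(labels))
      labels <- .read_labels_tsv(labels, colnames(mat))
    dataset_id <- dataset_id %||% sub("\\.[^.]*$", "", basename(path))
  } else {
    parsed <- .parse_soft(path)
    mat <- parsed$values
    labels <- parsed$labels
    dataset_id <- dataset_id %||% parsed$dataset_id
  }
  mat <- .collapse_duplicates(mat, duplicate_rule)
  expression_dataset(mat, labels, dataset_id)
}

#' Remove genes with excessive missingness
#'
#' Retains exactly the genes whose fraction of missing entries is
#' strictly below `max_null_fraction`; the sample set is unchanged.
#' Applying the filter twice is a no-op.
#'
#' @param ds a [expression_dataset()] object.
#' @param max_null_fraction genes with missing fraction `>=` this value
#'   are dropped. Default 0.8.
#' @return the filtered dataset.
#' @export
filter_missing <- function(ds, max_null_fraction = 0.8) {
  stopifnot(inherits(ds, "metx_expression"),
            max_null_fraction >= 0, max_null_fraction <= 1)
  frac <- rowMeans(is.na(ds$values))
  keep <- frac < max_null_fraction
  if (!any(keep)) stop("empty dataset after filtering")
  expression_dataset(ds$values[keep, , drop = FALSE], ds$labels, ds$dataset_id)
}

#' Normalize expression values
#'
#' `per_gene_zscore` centers and scales every gene row over its
#' non-missing entries (constant rows become all-zero); `quantile`
#' applies quantile normalization across sample columns (via limma);
#' `none` is the identity.
#'
#' @param ds a [expression_dataset()] object.
#' @param method one of `"per_gene_zscore"`, `"quantile"`, `"none"`.
#' @return the normalized dataset.
#' @export
normalize_expression <- function(ds,
                                 method = c("per_gene_zscore", "quantile", "none")) {
  stopifnot(inherits(ds, "metx_expression"))
  method <- match.arg(method)
  vals <- ds$values
  if (method == "per_gene_zscore") {
    mu <- rowMeans(vals, na.rm = TRUE)
    sdv <- apply(vals, 1, sd, na.rm = TRUE)
    centered <- vals - mu
    flat <- is.na(sdv) | sdv == 0
    sdv[flat] <- 1
    vals <- centered / sdv
    vals[flat, ] <- 0
    vals[is.na(ds$values)] <- NA_real_
  } else if (method == "quantile") {
    vals <- limma::normalizeQuantiles(vals)
    dimnames(vals) <- dimnames(ds$values)
  }
  expression_dataset(vals, ds$labels, ds$dataset_id)
}

#' Write an expression dataset as TSV (+ labels sidecar)
#'
#' Inverse of the TSV branch of [load_expression()].
#'
#' @param ds a [expression_dataset()] object.
#' @param path output TSV for the matrix.
#' @param labels_path optional output TSV (`sample_id`, `label`).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(ds, path, labels_path = NULL) {
  tab <- data.frame(gene_id = genes(ds), ds$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    lab <- data.frame(sample_id = samples(ds),
                      label = ifelse(ds$labels == 1L, "disease", "normal"))
    write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
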
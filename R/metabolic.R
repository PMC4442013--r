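#' Parse reaction files into directed reaction records
#'
#' Reads KGML-style XML or a flat reaction TSV and returns one record
#' per *directed* reaction: an irreversible source reaction yields one
#' record, a reversible one yields two records with substrates and
#' products swapped (suffixes `_fwd` / `_rev`). Each record keeps its
#' `source_id` so that metabolite participation can be counted on the
#' pre-split reactions. Reactions without any enzyme mapping are skipped
#' with a warning; the skipped count is attached as attribute
#' `n_skipped`.
#'
#' The KGML dialect read here: `<reaction>` elements with a
#' `type` of `reversible`/`irreversible` and `<substrate>`/`<product>`
#' children whose `name` attributes are compound ids; `<entry>` elements
#' of type `gene` whose `reaction` attribute names the reaction(s) they
#' catalyze. Namespace-like prefixes (`rn:`, `cpd:`, `hsa:`, ...) are
#' stripped. The pathway name is the `title` attribute of the
#' `<pathway>` root.
#'
#' The reaction TSV has columns `reaction_id`, `reversible` (0/1 or
#' true/false), `pathway`, and `;`-joined `enzymes`, `substrates`,
#' `products`.
#'
#' @param paths one or more input files.
#' @param format `"reaction_tsv"` or `"kgml"`.
#' @return data frame of directed reactions with columns `reaction_id`,
#'   `source_id`, `reversible`, `pathway` and list-columns `enzymes`,
#'   `substrates`, `products`.
#' @export
parse_reactions <- function(paths, format = c("reaction_tsv", "kgml")) {
  format <- match.arg(format)
  src <- do.call(rbind, lapply(paths, function(p) {
    if (!file.exists(p)) stop("unreadable file: ", p)
    if (format == "kgml") .parse_kgml(p) else .parse_reaction_tsv(p)
  }))
  split_reactions(src)
}

.strip_prefix <- function(x) sub("^[a-zA-Z]+:", "", x)

.parse_reaction_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "reversible", "pathway", "enzymes",
            "substrates", "products")
  if (!all(need %in% names(tab)))
    stop("reaction TSV needs columns: ", paste(need, collapse = ", "))
  splitcol <- function(x) lapply(strsplit(as.character(x), ";", fixed = TRUE),
                                 function(v) v[nzchar(v)])
  data.frame(
    reaction_id = as.character(tab$reaction_id),
    reversible = as.logical(tab$reversible) |
      tab$reversible %in% c(1, "1", "true", "TRUE"),
    pathway = as.character(tab$pathway),
    enzymes = I(splitcol(tab$enzymes)),
    substrates = I(splitcol(tab$substrates)),
    products = I(splitcol(tab$products)),
    stringsAsFactors = FALSE)
}

.parse_kgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e)))
  pathway <- xml2::xml_attr(doc, "title")
  if (is.na(pathway)) pathway <- .strip_prefix(xml2::xml_attr(doc, "name"))
  # reaction -> gene map from gene entries
  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene'][@reaction]")
  rx_genes <- list()
  for (e in entries) {
    rxs <- .strip_prefix(strsplit(xml2::xml_attr(e, "reaction"), "\\s+")[[1]])
    gs <- .strip_prefix(strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1]])
    for (r in rxs) rx_genes[[r]] <- union(rx_genes[[r]], gs)
  }
  rx <- xml2::xml_find_all(doc, ".//reaction")
  rows <- lapply(rx, function(node) {
    rid <- .strip_prefix(xml2::xml_attr(node, "name"))
    if (is.na(rid)) rid <- xml2::xml_attr(node, "id")
    data.frame(
      reaction_id = rid,
      reversible = identical(xml2::xml_attr(node, "type"), "reversible"),
      pathway = pathway,
      enzymes = I(list(rx_genes[[rid]] %||% character(0))),
      substrates = I(list(.strip_prefix(
        xml2::xml_attr(xml2::xml_find_all(node, "./substrate"), "name")))),
      products = I(list(.strip_prefix(
        xml2::xml_attr(xml2::xml_find_all(node, "./product"), "name")))),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split reversible reactions into directed records
#'
#' @param reactions data frame of source reactions (columns
#'   `reaction_id`, `reversible`, `pathway` and list-columns `enzymes`,
#'   `substrates`, `products`), e.g. from [gen_reactions()].
#' @return directed reaction data frame (see [parse_reactions()]).
#' @export
split_reactions <- function(reactions) {
  no_enzyme <- lengths(reactions$enzymes) == 0L
  if (any(no_enzyme)) {
    warning(sum(no_enzyme), " reaction(s) without enzyme mapping skipped")
    reactions <- reactions[!no_enzyme, , drop = FALSE]
  }
  fwd <- data.frame(
    reaction_id = ifelse(reactions$reversible,
                         paste0(reactions$reaction_id, "_fwd"),
                         reactions$reaction_id),
    source_id = reactions$reaction_id,
    reversible = reactions$reversible,
    pathway = reactions$pathway,
    enzymes = I(reactions$enzymes),
    substrates = I(reactions$substrates),
    products = I(reactions$products),
    stringsAsFactors = FALSE)
  rev_src <- reactions[reactions$reversible, , drop = FALSE]
  if (nrow(rev_src)) {
    bwd <- data.frame(
      reaction_id = paste0(rev_src$reaction_id, "_rev"),
      source_id = rev_src$reaction_id,
      reversible = TRUE,
      pathway = rev_src$pathway,
      enzymes = I(rev_src$enzymes),
      substrates = I(rev_src$products),
      products = I(rev_src$substrates),
      stringsAsFactors = FALSE)
    fwd <- rbind(fwd, bwd)
  }
  attr(fwd, "n_skipped") <- sum(no_enzyme)
  rownames(fwd) <- NULL
  fwd
}

#' Currency-metabolite and pathway filter
#'
#' A metabolite is retained iff it participates in fewer than
#' `max_reaction_count` distinct *source* (pre-split) reactions and
#' never appears in a reaction whose pathway is excluded. Metabolites
#' failing the count test are "currency" metabolites (ATP-like hubs)
#' whose links would connect unrelated enzymes.
#'
#' @param reactions directed reaction data frame from
#'   [parse_reactions()] / [split_reactions()].
#' @param max_reaction_count first excluded participation count;
#'   default 18 retains metabolites in fewer than 18 reactions.
#' @param excluded_pathways pathway names whose metabolites are removed
#'   globally.
#' @return character vector of retained metabolite ids.
#' @export
filter_metabolites <- function(reactions, max_reaction_count = 18L,
                               excluded_pathways =
                                 "Xenobiotics Biodegradation and Metabolism") {
  if (!nrow(reactions)) stop("non-empty reaction list required")
  per_rx <- mapply(function(s, p) unique(c(s, p)),
                   reactions$substrates, reactions$products, SIMPLIFY = FALSE)
  # count each metabolite once per source reaction, not per directed half
  src_pairs <- unique(data.frame(
    source_id = rep(reactions$source_id, lengths(per_rx)),
    metabolite = unlist(per_rx), stringsAsFactors = FALSE))
  counts <- table(src_pairs$metabolite)
  in_excluded <- unique(unlist(
    per_rx[reactions$pathway %in% excluded_pathways]))
  mets <- names(counts)
  mets[counts < max_reaction_count & !(mets %in% in_excluded)]
}

#' Build the directed enzyme-enzyme network
#'
#' For every retained metabolite, every enzyme of a reaction producing
#' it gets a directed edge to every enzyme of a reaction consuming it —
#' the edge runs from the metabolite's generator to its consumer.
#' Parallel edges through different metabolites are merged into one edge
#' carrying the metabolite list. Self-edges are kept only when the
#' producing and consuming records descend from distinct source
#' reactions (the two halves of one split reversible reaction do not
#' count); they are flagged in the `self_loop` column.
#'
#' @param reactions directed reaction data frame from
#'   [parse_reactions()].
#' @param retained retained metabolite ids from [filter_metabolites()].
#' @return object of class `metx_metnet`: list with `nodes` (all enzyme
#'   ids seen in any reaction) and `edges` (data frame `from`, `to`,
#'   `metabolites` (`;`-joined), `self_loop`).
#' @export
build_enzyme_graph <- function(reactions, retained) {
  nodes <- sort(unique(unlist(reactions$enzymes)))
  # index reactions by produced / consumed metabolite up front
  prod_map <- split(rep(seq_len(nrow(reactions)), lengths(reactions$products)),
                    unlist(reactions$products))
  cons_map <- split(rep(seq_len(nrow(reactions)), lengths(reactions$substrates)),
                    unlist(reactions$substrates))
  links <- list()
  for (m in retained) {
    prod_idx <- unique(prod_map[[m]])
    cons_idx <- unique(cons_map[[m]])
    if (!length(prod_idx) || !length(cons_idx)) next
    for (pi in prod_idx) for (ci in cons_idx) {
      same_source <- reactions$source_id[pi] == reactions$source_id[ci]
      for (u in reactions$enzymes[[pi]]) for (v in reactions$enzymes[[ci]]) {
        if (u == v && same_source) next
        links[[length(links) + 1L]] <- c(u, v, m)
      }
    }
  }
  if (length(links)) {
    raw <- unique(do.call(rbind, links))
    key <- paste(raw[, 1], raw[, 2], sep = "\r")
    mets <- vapply(split(raw[, 3], key),
                   function(m) paste(sort(unique(m)), collapse = ";"),
                   character(1))
    uk <- unique(key)
    parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
    edges <- data.frame(from = parts[, 1], to = parts[, 2],
                        metabolites = mets[uk],
                        self_loop = parts[, 1] == parts[, 2],
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        metabolites = character(0), self_loop = logical(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "metx_metnet")
}

#' @export
print.metx_metnet <- function(x, ...) {
  cat(sprintf("<metx_metnet> %d enzyme genes, %d directed edges, %d with outward edges\n",
              length(x$nodes), nrow(x$edges), length(outward_genes(x))))
  invisible(x)
}

#' Enzyme genes with outward edges
#'
#' Nodes with out-degree >= 1: the enzymes that generate a retained
#' metabolite consumed by some enzyme, i.e. those with the largest
#' potential impact on the metabolic network. This set is the scoring
#' background for all downstream enrichment statistics.
#'
#' @param net a `metx_metnet` object from [build_enzyme_graph()].
#' @return character vector of gene ids.
#' @export
outward_genes <- function(net) {
  stopifnot(inherits(net, "metx_metnet"))
  sort(unique(net$edges$from))
}

#' Out-neighbors of an enzyme in the metabolic network
#' @param net a `metx_metnet` object.
#' @param gene a node id.
#' @return character vector of target gene ids (excluding the gene itself).
#' @export
out_neighbors <- function(net, gene) {
  setdiff(unique(net$edges$to[net$edges$from == gene]), gene)
}

#' Write the metabolic network as TSV edge list + background gene list
#' @param net a `metx_metnet` object.
#' @param edges_path output TSV (source_gene, target_gene, metabolites).
#' @param background_path optional output, one outward gene per line.
#' @return `edges_path`, invisibly.
#' @export
write_metnet_tsv <- function(net, edges_path, background_path = NULL) {
  out <- net$edges[, c("from", "to", "metabolites")]
  names(out) <- c("source_gene", "target_gene", "metabolites")
  write.table(out, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(background_path))
    writeLines(outward_genes(net), background_path)
  invisible(edges_path)
}
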
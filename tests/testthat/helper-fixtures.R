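# In-code fixtures shared across test files.

make_ds <- function(values, labels, id = "toy") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_dataset(values, labels, id)
}

# a metabolic network built directly from an edge list (for scoring
# tests that do not exercise the reaction machinery)
toy_metnet <- function(from, to, nodes = NULL) {
  nodes <- sort(unique(c(nodes, from, to)))
  structure(list(
    nodes = nodes,
    edges = data.frame(from = from, to = to,
                       metabolites = "m", self_loop = from == to,
                       stringsAsFactors = FALSE)),
    class = "metx_metnet")
}

# source reaction table from compact per-reaction strings ("A|S|P")
toy_reactions <- function(ids, reversible, pathway, enzymes, substrates, products) {
  data.frame(reaction_id = ids, reversible = reversible, pathway = pathway,
             enzymes = I(lapply(strsplit(enzymes, ","), trimws)),
             substrates = I(lapply(strsplit(substrates, ","), trimws)),
             products = I(lapply(strsplit(products, ","), trimws)),
             stringsAsFactors = FALSE)
}

soft_fixture <- function(path) {
  writeLines(c(
    "^DATASET = GDS_TOY",
    "!dataset_title = toy neuro dataset",
    "^SUBSET = GDS_TOY_1",
    "!subset_sample_id = GSM1,GSM2,GSM3",
    "!subset_description = control",
    "!subset_type = disease state",
    "^SUBSET = GDS_TOY_2",
    "!subset_sample_id = GSM4,GSM5,GSM6",
    "!subset_description = Parkinson's disease",
    "!subset_type = disease state",
    "!dataset_table_begin",
    paste("ID_REF", "IDENTIFIER", "GSM1", "GSM2", "GSM3", "GSM4", "GSM5", "GSM6", sep = "\t"),
    paste("p1", "GA", "1", "2", "3", "4", "5", "6", sep = "\t"),
    paste("p2", "GB", "2", "1", "null", "3", "2", "4", sep = "\t"),
    paste("p3", "GA", "3", "3", "3", "3", "3", "3", sep = "\t"),
    "!dataset_table_end"), path)
  path
}

kgml_fixture <- function(path) {
  writeLines(c(
    '<pathway name="path:toy00001" title="Toy glycolysis">',
    '  <entry id="1" name="hsa:A" type="gene" reaction="rn:R1"/>',
    '  <entry id="2" name="hsa:B" type="gene" reaction="rn:R2"/>',
    '  <reaction id="10" name="rn:R1" type="irreversible">',
    '    <substrate id="20" name="cpd:S"/>',
    '    <product id="21" name="cpd:P"/>',
    '  </reaction>',
    '  <reaction id="11" name="rn:R2" type="reversible">',
    '    <substrate id="22" name="cpd:P"/>',
    '    <product id="23" name="cpd:Q"/>',
    '  </reaction>',
    '</pathway>'), path)
  path
}

# minimal explicit study config for run_pipeline tests
study_config <- function(dir, st, n_perm = 200, seed = 11, min_datasets = 2) {
  for (i in seq_along(st$datasets))
    write_expression_tsv(st$datasets[[i]],
                         file.path(dir, sprintf("expr%d.tsv", i)),
                         file.path(dir, sprintf("lab%d.tsv", i)))
  write_reactions_tsv(st$reactions, file.path(dir, "reactions.tsv"))
  write_term_gmt(st$term_map, file.path(dir, "terms.gmt"))
  write_edge_list_tsv(st$assoc$edges, file.path(dir, "funcoup.tsv"))
  writeLines(st$assoc$disease_genes, file.path(dir, "disease.txt"))
  list(
    datasets = lapply(seq_along(st$datasets), function(i)
      list(id = sprintf("d%d", i),
           expression = file.path(dir, sprintf("expr%d.tsv", i)),
           labels = file.path(dir, sprintf("lab%d.tsv", i)),
           format = "tsv")),
    reactions = list(path = file.path(dir, "reactions.tsv"),
                     format = "reaction_tsv"),
    terms = list(path = file.path(dir, "terms.gmt"), format = "gmt"),
    association_network = file.path(dir, "funcoup.tsv"),
    disease_genes = file.path(dir, "disease.txt"),
    parameters = list(
      max_null_fraction = 0.8, normalize = "per_gene_zscore",
      edge_threshold = 0.7, min_module_size = 11,
      max_metabolite_reactions = 18,
      excluded_pathways = list("Xenobiotics Biodegradation and Metabolism"),
      combiner = "product_neglog", median_rule = "strict",
      min_datasets = min_datasets, n_perm = n_perm, pool = "network",
      distance_mode = "hops", seed = seed))
}
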
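test_that("reversible reactions split into two directed records with swapped sides", {
  rx <- toy_reactions(c("R1", "R2"), c(FALSE, TRUE), "p",
                      c("A", "B"), c("S1", "S2"), c("P1", "P2"))
  dir_rx <- split_reactions(rx)
  expect_equal(nrow(dir_rx), 3L)  # 1 irreversible + 2 halves
  rev_half <- dir_rx[dir_rx$reaction_id == "R2_rev", ]
  expect_equal(rev_half$substrates[[1]], "P2")
  expect_equal(rev_half$products[[1]], "S2")
  expect_equal(rev_half$enzymes[[1]],
               dir_rx$enzymes[[which(dir_rx$reaction_id == "R2_fwd")]])
  # without reversible reactions the record count equals the reaction count
  rx0 <- toy_reactions(c("R1", "R2"), c(FALSE, FALSE), "p",
                       c("A", "B"), c("S1", "S2"), c("P1", "P2"))
  expect_equal(nrow(split_reactions(rx0)), 2L)
  # enzyme-less reactions are skipped with a warning
  rx_bad <- toy_reactions(c("R1", "R2"), c(FALSE, FALSE), "p",
                          c("A", ""), c("S1", "S2"), c("P1", "P2"))
  expect_warning(out <- split_reactions(rx_bad), "without enzyme mapping")
  expect_equal(nrow(out), 1L)
})

test_that("KGML parsing extracts reactions, genes, reversibility and pathway", {
  dir_rx <- parse_reactions(kgml_fixture(tempfile(fileext = ".xml")), "kgml")
  expect_equal(nrow(dir_rx), 3L)  # R1 + R2 split in two
  expect_setequal(dir_rx$source_id, c("R1", "R2"))
  r1 <- dir_rx[dir_rx$reaction_id == "R1", ]
  expect_equal(r1$enzymes[[1]], "A")    # hsa: prefix stripped
  expect_equal(r1$substrates[[1]], "S")
  expect_equal(r1$products[[1]], "P")
  expect_true(all(dir_rx$pathway == "Toy glycolysis"))
  expect_error(parse_reactions(soft_fixture(tempfile()), "kgml"), "XML")
})

test_that("round-trip through the KGML writer preserves the reaction structure", {
  sim <- gen_reactions(sprintf("E%02d", 1:10), mean_out_degree = 1.2,
                       currency_metabolite_count = 0, seed = 4)
  path <- write_kgml(sim$reactions, tempfile(fileext = ".xml"))
  got <- parse_reactions(path, "kgml")
  want <- split_reactions(sim$reactions)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(got$reaction_id, want$reaction_id)
  for (rid in got$reaction_id) {
    i <- which(got$reaction_id == rid); j <- which(want$reaction_id == rid)
    expect_setequal(got$enzymes[[i]], want$enzymes[[j]])
    expect_setequal(got$substrates[[i]], want$substrates[[j]])
    expect_setequal(got$products[[i]], want$products[[j]])
  }
})

test_that("metabolite filter applies the reaction-count cutoff on source reactions", {
  # metabolite "hub" participates in 18 source reactions, "ok" in 17
  n <- 18
  rx <- toy_reactions(sprintf("R%02d", 1:n), rep(FALSE, n), "core",
                      sprintf("E%02d", 1:n),
                      c(rep("hub,ok", 17), "hub"),
                      sprintf("X%02d", 1:n))
  dir_rx <- split_reactions(rx)
  kept <- filter_metabolites(dir_rx, max_reaction_count = 18)
  expect_false("hub" %in% kept)   # 18 reactions: first excluded count
  expect_true("ok" %in% kept)     # 17 < 18
  # counting is per source reaction: splitting a reversible reaction
  # must not double its metabolites' participation
  rx$reversible[1] <- TRUE
  kept_rev <- filter_metabolites(split_reactions(rx), max_reaction_count = 18)
  expect_true("ok" %in% kept_rev)
  # excluded pathway removes its metabolites globally
  rx2 <- toy_reactions(c("R1", "R2"), c(FALSE, FALSE),
                       c("core", "Xenobiotics Biodegradation and Metabolism"),
                       c("A", "B"), c("m", "m"), c("p", "q"))
  expect_false("m" %in% filter_metabolites(split_reactions(rx2)))
  # raising the cutoff never removes metabolites
  for (cutoff in c(2, 5, 18, 40)) {
    low <- filter_metabolites(dir_rx, cutoff)
    high <- filter_metabolites(dir_rx, cutoff + 1)
    expect_true(all(low %in% high))
  }
})

test_that("enzyme edges run from metabolite producer to consumer", {
  rx <- toy_reactions(c("R1", "R2"), c(FALSE, FALSE), "p",
                      c("A", "B"), c("S", "m"), c("m", "P"))
  dir_rx <- split_reactions(rx)
  net <- build_enzyme_graph(dir_rx, retained = c("S", "m", "P"))
  expect_equal(net$edges$from, "A")
  expect_equal(net$edges$to, "B")
  expect_equal(net$edges$metabolites, "m")
  # filtered-out metabolite produces no edge
  net0 <- build_enzyme_graph(dir_rx, retained = c("S", "P"))
  expect_equal(nrow(net0$edges), 0L)
  expect_setequal(net0$nodes, c("A", "B"))  # nodes = all enzymes regardless
})

test_that("reversible splitting yields exactly the hand-enumerated edge set", {
  # A catalyzes the reversible S <-> P; B consumes P; C produces S
  rx <- toy_reactions(c("RA", "RB", "RC"), c(TRUE, FALSE, FALSE), "p",
                      c("A", "B", "C"), c("S", "P", "Q"), c("P", "T", "S"))
  dir_rx <- split_reactions(rx)
  net <- build_enzyme_graph(dir_rx, retained = c("S", "P", "Q", "T"))
  got <- sort(paste(net$edges$from, net$edges$to, sep = "->"))
  # P: produced by RA_fwd (A), consumed by RB (B) and RA_rev (A);
  # S: produced by RA_rev (A) and RC (C), consumed by RA_fwd (A).
  # The two A->A candidates pair the halves of the same source reaction
  # RA, so no self-loop survives:
  expect_equal(got, sort(c("A->B", "C->A")))
  # a genuine self-loop across distinct source reactions is kept and flagged
  rx2 <- toy_reactions(c("R1", "R2"), c(FALSE, FALSE), "p",
                       c("A", "A"), c("S", "m"), c("m", "T"))
  net2 <- build_enzyme_graph(split_reactions(rx2), c("S", "m", "T"))
  expect_true(any(net2$edges$from == "A" & net2$edges$to == "A" &
                    net2$edges$self_loop))
})

test_that("outward gene set equals a brute-force scan of the edge list", {
  rx <- toy_reactions(c("R1", "R2", "R3"), rep(FALSE, 3), "p",
                      c("A", "B", "C"), c("S", "mA", "mB"),
                      c("mA", "mB", "T"))
  net <- build_enzyme_graph(split_reactions(rx), c("S", "mA", "mB", "T"))
  expect_setequal(outward_genes(net), c("A", "B"))  # chain A->B->C
  # empty network
  empty <- build_enzyme_graph(split_reactions(rx), character(0))
  expect_length(outward_genes(empty), 0)
  # random toy networks vs direct scan
  set.seed(5)
  for (rep in 1:10) {
    sim <- gen_reactions(sprintf("E%02d", 1:20), mean_out_degree = 1.5,
                         currency_metabolite_count = 1, seed = rep)
    dir_rx <- split_reactions(sim$reactions)
    net <- build_enzyme_graph(dir_rx, filter_metabolites(dir_rx))
    expect_setequal(outward_genes(net), unique(net$edges$from))
    expect_true(all(outward_genes(net) %in% net$nodes))
  }
})

test_that("every edge metabolite is retained and edges grow with the cutoff", {
  sim <- gen_reactions(sprintf("E%02d", 1:25), reversible_fraction = 0.3,
                       currency_metabolite_count = 2, seed = 8)
  dir_rx <- split_reactions(sim$reactions)
  retained <- filter_metabolites(dir_rx)
  expect_false(any(sim$truth$currency_metabolites %in% retained))
  net <- build_enzyme_graph(dir_rx, retained)
  mets <- unlist(strsplit(net$edges$metabolites, ";", fixed = TRUE))
  expect_true(all(mets %in% retained))
  bigger <- build_enzyme_graph(dir_rx, filter_metabolites(dir_rx, 1000))
  expect_true(all(paste(net$edges$from, net$edges$to) %in%
                    paste(bigger$edges$from, bigger$edges$to)))
})
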
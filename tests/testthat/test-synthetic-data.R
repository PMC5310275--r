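test_that("identical seeds reproduce byte-identical datasets", {
  cfg <- sim_config(seed = 13, background_genes_per_chromosome = 120L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_family(cfg), d1)
  p2 <- write_simulation(simulate_family(cfg), d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = sprintf("file %s", nm))
  }
  # a different seed changes the dataset
  p3 <- write_simulation(simulate_family(sim_config(
    seed = 14, background_genes_per_chromosome = 120L)), withr::local_tempdir())
  expect_false(identical(readLines(p1[["genes"]]), readLines(p3[["genes"]])))
})

test_that("simulated truth carries the configured depth counts", {
  sim <- simulate_family(sim_config(seed = 2))
  expect_equal(unname(sim$truth$depth_counts), c(7L, 11L, 18L))
  expect_equal(length(unique(sim$leaves$ancient_id)), 7L)
  expect_equal(length(unique(stats::na.omit(sim$leaves$seed_id))), 11L)
  expect_equal(length(unique(stats::na.omit(sim$leaves$angiosperm_id))), 18L)
})

test_that("with no events and no loss every species carries its depth's genes", {
  cfg <- sim_config(events = c(wgd = 0, tandem = 0, proximal = 0, dispersed = 0),
                    isoform_probability = 0, seed = 5,
                    background_genes_per_chromosome = 120L)
  sim <- simulate_family(cfg)
  counts <- table(sim$leaves$species)
  panel <- cfg$species
  for (i in seq_len(nrow(panel))) {
    expected <- switch(panel$group[i],
                       bryophyte = , lycophyte = 7L,
                       gymnosperm = 11L, 18L)
    expect_equal(unname(counts[[panel$code[i]]]), expected,
                 label = panel$code[i])
  }
})

test_that("truth labels are consistent with the emitted evidence", {
  sim <- simulate_family(sim_config(seed = 21))
  truth <- sim$truth$genes
  anchored <- unique(c(sim$blocks$gene_a, sim$blocks$gene_b))
  # every truth-wgd gene appears in a block anchor
  expect_true(all(truth$gene_id[truth$duplication == "wgd"] %in% anchored))
  # every family gene model passes the detection gates
  det <- detect_family(sim$domain_hits, sim$genes)
  expect_setequal(det$gene_id, sim$leaves$gene_id)
  # tree leaves, classes and proteins agree on the family roster
  expect_setequal(sim$tree$tip.label, sim$leaves$gene_id)
  expect_setequal(names(sim$proteins), sim$leaves$gene_id)
})

test_that("inferred counts never exceed truth when genes are lost", {
  for (s in 1:3) {
    sim <- simulate_family(sim_config(loss_probability = 0.2, seed = 30 + s,
                                      background_genes_per_chromosome = 120L))
    res <- analyze_dataset(sim$genes, sim$domain_hits, sim$pairs, sim$blocks,
                           sim$tree, sim$classes, sim$config$species)
    expect_true(all(res$report$depth_counts <= sim$truth$depth_counts))
  }
})

test_that("leaf-order shuffling leaves the inference invariant", {
  sim <- simulate_family(sim_config(seed = 8, background_genes_per_chromosome = 120L))
  shuffled <- perturb_simulation(sim, "shuffle_leaf_order", seed = 99)
  expect_false(identical(ape::write.tree(sim$tree),
                         ape::write.tree(shuffled$tree)))
  res1 <- analyze_dataset(sim$genes, sim$domain_hits, sim$pairs, sim$blocks,
                          sim$tree, sim$classes, sim$config$species)
  res2 <- analyze_dataset(shuffled$genes, shuffled$domain_hits, shuffled$pairs,
                          shuffled$blocks, shuffled$tree, shuffled$classes,
                          shuffled$config$species)
  expect_equal(res1$report$depth_counts, res2$report$depth_counts)
  expect_equal(cluster_signatures(res1$clusters$angiosperm),
               cluster_signatures(res2$clusters$angiosperm))
})

test_that("dropping one redundant paralog preserves satisfiable depth counts", {
  cfg <- sim_config(seed = 17, background_genes_per_chromosome = 120L)
  sim <- simulate_family(cfg)
  # find a seed whose victim is a within-species duplicate copy: every clause
  # stays satisfiable, so counts must not move
  for (s in 1:50) {
    set.seed(s)
    victim <- sample(sim$leaves$gene_id, 1L)
    if (grepl("[wtpd]$", victim)) break
  }
  expect_true(grepl("[wtpd]$", victim))
  dropped <- perturb_simulation(sim, "drop_gene", seed = s)
  expect_false(victim %in% dropped$tree$tip.label)
  res <- analyze_dataset(dropped$genes, dropped$domain_hits, dropped$pairs,
                         dropped$blocks, dropped$tree, dropped$classes,
                         dropped$config$species)
  expect_equal(unname(res$report$depth_counts), c(7L, 11L, 18L))
})

test_that("support downgrade interacts with gating as documented", {
  sim <- simulate_family(sim_config(seed = 23, background_genes_per_chromosome = 120L))
  down <- perturb_simulation(sim, "downgrade_support", seed = 4)
  expect_equal(sum(down$tree$support < 1), 1L)
  atree_full <- annotated_gene_tree(sim$tree,
                                    setNames(sim$leaves$species, sim$leaves$gene_id),
                                    sim$config$species, sim$classes)
  atree_down <- annotated_gene_tree(down$tree,
                                    setNames(down$leaves$species, down$leaves$gene_id),
                                    down$config$species, down$classes)
  expect_lte(nrow(find_angiosperm_ancestors(atree_down, min_support = 0.5)),
             nrow(find_angiosperm_ancestors(atree_full, min_support = 0.5)))
  expect_error(perturb_simulation(sim, "explode"), "unknown perturbation")
})
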
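dm_config <- data.frame(code = c("d1", "d2", "m1", "m2"),
                        group = c("dicot", "dicot", "monocot", "monocot"))

atree_from_text <- function(newick, species, config = dm_config,
                            classes = NULL) {
  tree <- ape::read.tree(text = newick)
  tree$support <- normalize_support(tree$node.label %||%
                                      rep(NA_character_, tree$Nnode))
  annotated_gene_tree(tree, species = species, species_config = config,
                      classes = classes)
}

test_that("rooting by outgroup and midpoint behaves, and rejects scattered outgroups", {
  un <- ape::read.tree(text = "(a:1,b:1,(c:1,d:1):1);")
  r <- root_tree(un, outgroup = "a")
  expect_true(ape::is.rooted(r))
  sets <- lapply(phangorn::Descendants(r, ape::Ntip(r) + 1L + seq_len(r$Nnode - 1L), "tips"),
                 function(i) sort(r$tip.label[i]))
  expect_true(ape::is.monophyletic(r, c("b", "c", "d")))
  # idempotence: an already-rooted tree with a matching outgroup is unchanged
  expect_identical(root_tree(r, outgroup = "a"), r)
  # scattered outgroup
  un2 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,a2:1):1,e:1);")
  expect_error(root_tree(un2, outgroup = c("a", "c")), "not monophyletic")
  # midpoint rooting of a chain puts the root in the middle
  chain <- ape::read.tree(text = "(a:1,(b:1,(c:1,d:4):1):1);")
  expect_true(ape::is.rooted(root_tree(ape::unroot(chain), "midpoint")))
})

test_that("minimal taxon-complete clades: forced examples", {
  sp <- c(da = "d1", ma = "m1", db = "d2", mb = "m2")
  req <- taxon_requirement(taxon_clause(c("d1", "d2"), 1, "genes"),
                           taxon_clause(c("m1", "m2"), 1, "genes"))
  two <- minimal_complete_clades(
    atree_from_text("((da,ma),(db,mb));", sp), req)
  expect_length(two, 2L)
  one <- minimal_complete_clades(
    atree_from_text("((da,db),(ma,mb));", sp), req)
  expect_length(one, 1L)
  expect_setequal(one[[1L]]$members, c("da", "db", "ma", "mb"))
  expect_error(
    minimal_complete_clades(atree_from_text("((da,ma),(db,mb));", sp),
                            taxon_requirement(taxon_clause("zz", 1, "genes"))),
    "unknown species")
})

test_that("minimal clades equal the exhaustive-enumeration oracle", {
  panel <- species_panel()
  dic <- panel$code[panel$group == "dicot"]
  mon <- panel$code[panel$group == "monocot"]
  clauses <- list(list(species = dic, min = 2, unit = "species"),
                  list(species = mon, min = 1, unit = "genes"))
  req <- taxon_requirement(taxon_clause(dic, 2, "species"),
                           taxon_clause(mon, 1, "genes"))
  for (s in 1:20) {
    atree <- random_atree(sample(10:40, 1), seed = 500 + s)
    for (ms in list(NULL, 0.5)) {
      got <- minimal_complete_clades(atree, req, min_support = ms)
      expect_equal(cluster_signatures(got),
                   oracle_minimal_clades(atree, clauses, min_support = ms))
    }
  }
})

test_that("the reference tree yields the published depth structure", {
  atree <- reference_family_tree()
  anc <- find_ancient_lineages(atree)
  expect_equal(nrow(anc), 7L)
  expect_equal(sum(anc$class == "IA"), 2L)
  sd <- find_seed_ancestors(atree)
  expect_equal(nrow(sd), 11L)
  expect_equal(as.vector(table(sd$class)[c("IC1/ID", "IA", "IB", "II", "IC2", "IE")]),
               c(3L, 2L, 2L, 2L, 1L, 1L))
  ang <- find_angiosperm_ancestors(atree)
  expect_equal(nrow(ang), 18L)
  rep <- ancestry_report(anc, sd, ang)
  expect_equal(unname(rep$depth_counts), c(7L, 11L, 18L))
  # nesting: every angiosperm cluster resolves to one seed and one ancient line
  expect_true(all(rep$paths$seed_cluster != "unassigned"))
  expect_true(all(rep$paths$ancient_lineage != "unassigned"))
})

test_that("a basal clade without full seed-plant sister coverage does not attest", {
  panel <- species_panel()
  # drop the single Picea gene of lineage S09 -> the IE basal clade's sister
  # no longer covers all seed plants
  atree <- reference_family_tree()
  keep <- setdiff(atree$tree$tip.label, "Pab_S09")
  tr <- ape::keep.tip(atree$tree, keep)
  tr$support <- rep(1, tr$Nnode)
  pruned <- annotated_gene_tree(tr, species = atree$species,
                                species_config = panel,
                                classes = atree$classes)
  anc <- find_ancient_lineages(pruned)
  expect_equal(nrow(anc), 6L)
  # relaxing the sister clause to >=1 gymnosperm and >=1 angiosperm recovers it
  relaxed <- taxon_requirement(
    taxon_clause(panel$code[panel$group == "gymnosperm"], 1, "genes"),
    taxon_clause(panel$code[panel$group %in% c("dicot", "monocot")], 1, "genes"))
  expect_gte(nrow(find_ancient_lineages(pruned, sister_requirement = relaxed)),
             nrow(anc))
  # and the missing gymnosperm also removes exactly one seed cluster
  expect_equal(nrow(find_seed_ancestors(pruned)), 10L)
})

test_that("duplicating a qualifying seed cluster adds exactly one cluster", {
  base <- reference_family_tree()
  grafted <- grafted_reference_tree()
  expect_equal(nrow(find_seed_ancestors(grafted)),
               nrow(find_seed_ancestors(base)) + 1L)
  expect_equal(nrow(find_angiosperm_ancestors(grafted)),
               nrow(find_angiosperm_ancestors(base)) + 1L)
})

test_that("clause minima are monotone: relaxing never decreases the count", {
  for (s in 1:8) {
    atree <- random_atree(30, seed = 700 + s, support_na_frac = 0)
    full <- nrow(find_angiosperm_ancestors(atree))
    relaxed <- nrow(find_angiosperm_ancestors(atree, dicot_min = 1,
                                              monocot_min = 1))
    expect_gte(relaxed, full)
  }
})

test_that("support gating removes clusters whose defining node is weak", {
  atree <- reference_family_tree()
  ang <- find_angiosperm_ancestors(atree)
  # locate the defining node of the cluster holding Ath_L02 (seed S02 has two
  # angiosperm lineages, so pruning one still leaves its sibling qualifying)
  target <- which(vapply(ang$members, function(m) "Ath_L02" %in% m, logical(1)))
  tree <- atree$tree
  ntip <- ape::Ntip(tree)
  nodes <- ntip + seq_len(tree$Nnode)
  tips_of <- phangorn::Descendants(tree, nodes, "tips")
  node <- nodes[vapply(seq_along(nodes), function(i) {
    setequal(tree$tip.label[tips_of[[i]]], ang$members[[target]])
  }, logical(1))]
  atree$support[node - ntip] <- 0.1
  gated <- find_angiosperm_ancestors(atree, min_support = 0.5)
  expect_equal(nrow(gated), 17L)
  expect_false(any(vapply(gated$members, function(m) "Ath_L02" %in% m,
                          logical(1))))
})

test_that("collinearity support requires a single group per clade side", {
  cfg <- data.frame(code = c("d1", "d2", "m1"),
                    group = c("dicot", "dicot", "monocot"))
  sp <- setNames(rep(c("d1", "d2", "m1"), 3),
                 paste0(rep(c("da", "db", "ma"), 3), "_", rep(1:3, each = 3)))
  nwk <- "(((da_1,db_1),ma_1),(((da_2,db_2),ma_2),((da_3,db_3),ma_3)));"
  atree <- atree_from_text(nwk, sp, config = cfg)
  ang <- find_angiosperm_ancestors(atree)
  expect_equal(nrow(ang), 3L)
  dg <- data.frame(group_id = c("G1", "G1", "G1", "G2"),
                   gene_id = c("da_1", "db_1", "da_2", "db_2"))
  mg <- data.frame(group_id = "H3", gene_id = "ma_1")
  out <- collinearity_support(ang, dg, mg, species_map = sp,
                              species_config = cfg)
  sup <- setNames(out$collinearity_supported,
                  vapply(out$members, function(m) sort(m)[1], character(1)))
  expect_true(sup[["da_1"]])    # dicots in one group, monocot in one group
  expect_false(sup[["da_2"]])   # dicot members span two groups
  expect_false(sup[["da_3"]])   # no member in any group
})

test_that("clusters at every depth are pairwise disjoint and reports can be empty", {
  atree <- reference_family_tree()
  for (cl in list(find_ancient_lineages(atree), find_seed_ancestors(atree),
                  find_angiosperm_ancestors(atree))) {
    expect_equal(anyDuplicated(unlist(cl$members)), 0L)
  }
  empty <- ancestry_report(find_ancient_lineages(atree)[0, ],
                           find_seed_ancestors(atree)[0, ],
                           find_angiosperm_ancestors(atree)[0, ])
  expect_equal(unname(empty$depth_counts), c(0L, 0L, 0L))
  expect_equal(nrow(empty$paths), 0L)
})
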
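mini_genes <- function(starts, chrom = "c1", species = "sp1",
                       ids = sprintf("g%d", seq_along(starts))) {
  data.frame(species = species, gene_id = ids, chromosome = chrom,
             start = starts, end = starts + 100, strand = "+",
             locus_id = ids, protein_length = 100L, stringsAsFactors = FALSE)
}

pair <- function(a, b) data.frame(query_id = a, subject_id = b, evalue = 1e-10,
                                  stringsAsFactors = FALSE)

anchor <- function(a, b) data.frame(block_id = "1", species_a = NA, species_b = NA,
                                    gene_a = a, gene_b = b, evalue = NA,
                                    score = NA, stringsAsFactors = FALSE)

no_blocks <- anchor("x", "y")[0, ]

test_that("ranks order genes by start within species and chromosome", {
  r <- assign_ranks(mini_genes(c(100, 50, 900)))
  expect_equal(r$rank[match(c("g1", "g2", "g3"), r$gene_id)], c(1L, 0L, 2L))
  # chromosomes rank independently
  g2 <- rbind(mini_genes(c(100, 200), ids = c("a1", "a2")),
              mini_genes(c(50, 60), chrom = "c2", ids = c("b1", "b2")))
  r2 <- assign_ranks(g2)
  expect_equal(r2$rank[match(c("a1", "b1"), r2$gene_id)], c(0L, 0L))
  # a lone gene gets rank 0
  expect_equal(assign_ranks(mini_genes(500, ids = "solo"))$rank, 0L)
})

test_that("the priority cascade assigns wgd > tandem > proximal > dispersed", {
  # 30 genes in a row; ranks = order along the chromosome
  genes <- mini_genes(seq(100, by = 1000, length.out = 30))
  ranks <- assign_ranks(genes)
  # anchored gene that is also adjacent to a homolog stays wgd
  lab <- classify_duplications(c("g5", "g6"), pair("g5", "g6"),
                               anchor("g5", "g20"), ranks)
  expect_equal(lab$label[lab$gene_id == "g5"], "wgd")
  expect_equal(lab$label[lab$gene_id == "g6"], "tandem")
  # consecutive homologs (ranks 5 and 6) are both tandem
  lab2 <- classify_duplications(c("g6", "g7"), pair("g6", "g7"), no_blocks, ranks)
  expect_true(all(lab2$label == "tandem"))
  # rank difference 15 is proximal, 25 is dispersed (window 20 exclusive)
  lab3 <- classify_duplications(c("g5", "g20"), pair("g5", "g20"), no_blocks, ranks)
  expect_true(all(lab3$label == "proximal"))
  lab4 <- classify_duplications(c("g5", "g30"), pair("g5", "g30"), no_blocks, ranks)
  expect_true(all(lab4$label == "dispersed"))
  # boundary: difference 19 proximal, 20 dispersed
  lab5 <- classify_duplications(c("g1", "g20"), pair("g1", "g20"), no_blocks, ranks)
  expect_true(all(lab5$label == "proximal"))
  lab6 <- classify_duplications(c("g1", "g21"), pair("g1", "g21"), no_blocks, ranks)
  expect_true(all(lab6$label == "dispersed"))
  # no evidence at all: singleton
  expect_equal(classify_duplications("g9", pair("a", "b")[0, ], no_blocks,
                                     ranks)$label, "singleton")
  expect_error(classify_duplications("nope", pair("a", "b")[0, ], no_blocks,
                                     ranks), "without rank")
})

test_that("homology is symmetric: one-sided top-hit lists still classify both ends", {
  genes <- mini_genes(seq(100, by = 1000, length.out = 5))
  ranks <- assign_ranks(genes)
  lab <- classify_duplications(c("g1", "g2"), pair("g1", "g2"), no_blocks, ranks)
  expect_equal(sort(unique(lab$label)), "tandem")
})

test_that("labels partition the gene set and respect block priority", {
  for (s in 1:10) {
    inst <- random_genome(150L, seed = 1000 + s)
    lab <- classify_duplications(inst$genes$gene_id, inst$pairs, inst$blocks,
                                 inst$ranks)
    expect_setequal(lab$gene_id, inst$genes$gene_id)
    expect_equal(anyDuplicated(lab$gene_id), 0L)
    expect_true(all(lab$label %in% c("wgd", "tandem", "proximal", "dispersed",
                                     "singleton")))
    anchored <- unique(c(inst$blocks$gene_a, inst$blocks$gene_b))
    expect_true(all(lab$label[lab$gene_id %in% anchored] == "wgd"))
  }
})

test_that("classifier agrees with the per-gene rule-cascade oracle", {
  for (s in 1:15) {
    inst <- random_genome(sample(50:200, 1), seed = 2000 + s)
    lab <- classify_duplications(inst$genes$gene_id, inst$pairs, inst$blocks,
                                 inst$ranks)
    expected <- oracle_classify(inst$genes$gene_id, inst$pairs, inst$blocks,
                                inst$ranks)
    expect_equal(setNames(lab$label, lab$gene_id), expected)
  }
})

test_that("per-species proportions sum to one and match counts", {
  genes <- mini_genes(seq(100, by = 1000, length.out = 10))
  labels <- data.frame(
    gene_id = genes$gene_id,
    label = rep(c("wgd", "dispersed", "tandem", "proximal"), c(4, 3, 2, 1)))
  s <- duplication_summary(labels, genes$gene_id, genes)
  expect_equal(sum(s$proportion), 1)
  expect_equal(s$proportion[s$label == "wgd"], 0.4)
  expect_equal(s$proportion[s$label == "dispersed"], 0.3)
  expect_equal(s$proportion[s$label == "tandem"], 0.2)
  expect_equal(s$proportion[s$label == "proximal"], 0.1)
  # all-singleton family: wgd and dispersed shares are zero
  lab2 <- data.frame(gene_id = genes$gene_id, label = "singleton")
  s2 <- duplication_summary(lab2, genes$gene_id, genes)
  expect_equal(sum(s2$proportion[s2$label %in% c("wgd", "dispersed")]), 0)
  expect_warning(duplication_summary(labels, genes$gene_id, genes,
                                     species = c("sp1", "ghost")), "ghost")
})

test_that("classifier proportions equal simulator truth without loss", {
  sim <- simulate_family(sim_config(seed = 11))
  res <- analyze_dataset(sim$genes, sim$domain_hits, sim$pairs, sim$blocks,
                         sim$tree, sim$classes, sim$config$species)
  truth <- sim$truth$genes
  got <- unname(setNames(res$labels$label, res$labels$gene_id)[truth$gene_id])
  p_got <- prop.table(table(got))
  p_truth <- prop.table(table(truth$duplication))
  expect_equal(as.numeric(p_got[sort(names(p_got))]),
               as.numeric(p_truth[sort(names(p_truth))]), tolerance = 1e-12)
  expect_setequal(names(p_got), names(p_truth))
})
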
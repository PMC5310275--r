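make_gene_file <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(paste(c("species", "gene_id", "chromosome", "start", "end",
                       "strand", "locus_id", "protein_length"),
                     collapse = "\t"), rows), path)
  path
}

test_that("gene table rows map to validated loci", {
  p <- make_gene_file("ath\tAT1G01010.1\tChr1\t100\t900\t+\tAT1G01010\t300")
  g <- read_gene_table(p)
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 100)
  expect_equal(g$end, 900)
  expect_equal(g$locus_id, "AT1G01010")
})

test_that("gene table invariant violations are rejected with line numbers", {
  p <- make_gene_file("ath\tA.1\tChr1\t900\t100\t+\tA\t300")
  expect_error(read_gene_table(p), "start > end.*line 2")
  p2 <- make_gene_file(c("ath\tA.1\tChr1\t100\t900\t+\tA\t300",
                         "ath\tA.1\tChr1\t200\t800\t+\tA\t250"))
  expect_error(read_gene_table(p2), "duplicated gene_id")
  p3 <- make_gene_file("ath\tA.1\tChr1\t100\t900\t?\tA\t300")
  expect_error(read_gene_table(p3), "strand")
})

test_that("domain table parses hit coordinates and rejects invalid hits", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("protein_id", "profile_name", "profile_length", "hmm_from",
                 "hmm_to", "evalue", "score"), collapse = "\t")
  writeLines(c(hdr, "P1\tDUF260\t100\t10\t95\t1e-20\t80.1"), path)
  h <- read_domain_table(path)
  expect_equal(h$hmm_from, 10)
  expect_equal(h$hmm_to, 95)

  writeLines(hdr, path)
  expect_equal(nrow(read_domain_table(path)), 0L)

  writeLines(c(hdr, "P1\tDUF260\t100\t10\t95\t-1e-20\t80.1"), path)
  expect_error(read_domain_table(path), "negative E-value")
  writeLines(c(hdr, "P1\tDUF260\t100\t10\t120\t1e-20\t80.1"), path)
  expect_error(read_domain_table(path), "profile coordinates")
})

test_that("collinearity dialect parses blocks, anchors and edge cases", {
  path <- withr::local_tempfile(fileext = ".collinearity")
  writeLines(c(
    "############### Parameters ###############",
    "## Alignment 0: score=500 N=3 ath&vvi plus",
    "0-  0:\tg1\tg2\t1e-50",
    "0-  1:\tg3\tg4\t1e-40",
    "0-  2:\tg5\tg6\t1e-30",
    "## Alignment 1: score=200 N=2 osa&zma plus",
    "1-  0:\tg7\tg8\t1e-20",
    "1-  1:\tg9\tg10\t1e-10"), path)
  b <- read_collinearity(path)
  expect_equal(length(unique(b$block_id)), 2L)
  expect_equal(as.vector(table(b$block_id)[c("0", "1")]), c(3L, 2L))
  expect_equal(b$gene_a[b$block_id == "0"], c("g1", "g3", "g5"))
  expect_equal(b$species_a[1], "ath")
  expect_equal(b$species_b[4], "zma")

  writeLines("############### Parameters ###############", path)
  expect_equal(nrow(read_collinearity(path)), 0L)

  writeLines(c("0-  0:\tg1\tg2\t1e-50"), path)
  expect_error(read_collinearity(path), "outside any")
})

test_that("collinearity anchors are cross-checked against a gene table", {
  path <- withr::local_tempfile(fileext = ".collinearity")
  writeLines(c("## Alignment 0: score=1 N=1 a&b plus", "0- 0:\tg1\tzz\t0"),
             path)
  genes <- data.frame(species = c("a", "b"), gene_id = c("g1", "g2"),
                      chromosome = "c", start = 1, end = 2, strand = "+",
                      locus_id = c("g1", "g2"), protein_length = 10)
  expect_error(read_collinearity(path, genes = genes), "absent from the gene table")
})

test_that("gene table and collinearity files round-trip", {
  sim <- simulate_family(sim_config(seed = 7, background_genes_per_chromosome = 120L))
  gp <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(sim$genes, gp)
  expect_equal(read_gene_table(gp), sim$genes, ignore_attr = TRUE)
  bp <- withr::local_tempfile(fileext = ".collinearity")
  write_collinearity(sim$blocks, bp)
  back <- read_collinearity(bp)
  expect_equal(back[c("block_id", "gene_a", "gene_b")],
               sim$blocks[c("block_id", "gene_a", "gene_b")],
               ignore_attr = TRUE)
})

test_that("newick supports are normalized from percentages and fractions", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1)95:1,c:1);", path)
  tr <- read_newick_tree(path)
  expect_true(0.95 %in% tr$support)

  writeLines("((a,b)0.95,c);", path)
  expect_true(0.95 %in% read_newick_tree(path)$support)

  writeLines("((a,b),c);", path)
  tr3 <- read_newick_tree(path)
  expect_true(anyNA(tr3$support))

  writeLines("((a,b)120,c);", path)
  expect_error(read_newick_tree(path), "outside")
  writeLines("((a,b,c);", path)
  expect_error(read_newick_tree(path), "parse")
})

test_that("support normalization is idempotent and preserves NA", {
  x <- c(95, 0.5, 1, 0, 100, NA)
  once <- normalize_support(x)
  expect_equal(normalize_support(once), once)
  expect_true(is.na(once[6]))
  expect_equal(once[1], 0.95)
  expect_equal(once[3], 1)     # 1 is a fraction, not a percentage
  expect_equal(once[5], 1)
})

test_that("trees round-trip with topology and supports intact", {
  atree <- reference_family_tree()
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick_tree(atree$tree, path)
  back <- read_newick_tree(path)
  expect_setequal(back$tip.label, atree$tree$tip.label)
  expect_equal(sort(back$support), sort(atree$tree$support), tolerance = 1e-6)
  expect_true(ape::all.equal.phylo(back, atree$tree, use.edge.length = FALSE))
})
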
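# Independent brute-force oracles and random-instance generators used by the
# property tests. These re-derive expected results from first principles and
# never call the code paths they check.

# --- minimal taxon-complete clades, by exhaustive clade enumeration ---------
# clauses: list of list(species=, min=, unit="genes"|"species")
oracle_minimal_clades <- function(atree, clauses, min_support = NULL) {
  tree <- atree$tree
  ntip <- ape::Ntip(tree)
  nodes <- seq_len(ntip + tree$Nnode)
  tips_of <- phangorn::Descendants(tree, nodes, "tips")
  leaf_sp <- atree$species[tree$tip.label]
  clause_ok <- function(spvec, cl) {
    hit <- spvec[spvec %in% cl$species]
    if (identical(cl$unit, "species")) length(unique(hit)) >= cl$min
    else length(hit) >= cl$min
  }
  support_ok <- function(nd) {
    if (is.null(min_support) || nd <= ntip) return(TRUE)
    s <- atree$support[nd - ntip]
    if (!is.na(s)) return(s >= min_support)
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    all(kids <= ntip)
  }
  qual <- vapply(nodes, function(nd) {
    all(vapply(clauses, clause_ok, logical(1), spvec = leaf_sp[tips_of[[nd]]])) &&
      support_ok(nd)
  }, logical(1))
  sets <- lapply(nodes[qual], function(nd) sort(tree$tip.label[tips_of[[nd]]]))
  if (length(sets) == 0L) return(character(0))
  minimal <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      j != i && length(sets[[j]]) < length(sets[[i]]) &&
        all(sets[[j]] %in% sets[[i]])
    }, logical(1)))
  }, logical(1))
  unname(sort(vapply(sets[minimal], paste, character(1), collapse = "|")))
}

cluster_signatures <- function(records) {
  if (is.data.frame(records)) records <- records$members
  else records <- lapply(records, `[[`, "members")
  unname(sort(vapply(records, function(m) paste(sort(m), collapse = "|"), character(1))))
}

# --- connected components via igraph ----------------------------------------
oracle_components <- function(pairs) {
  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  unname(sort(vapply(split(names(comp$membership), comp$membership),
                     function(v) paste(sort(v), collapse = "|"), character(1))))
}

group_signatures <- function(groups) {
  if (nrow(groups) == 0L) return(character(0))
  unname(sort(vapply(split(groups$gene_id, groups$group_id),
                     function(v) paste(sort(v), collapse = "|"), character(1))))
}

# --- duplication cascade, per-gene loop --------------------------------------
oracle_classify <- function(genes, pairs, blocks, ranks, window = 20L) {
  anchored <- unique(c(blocks$gene_a, blocks$gene_b))
  partners <- function(g) {
    unique(c(pairs$subject_id[pairs$query_id == g],
             pairs$query_id[pairs$subject_id == g]))
  }
  rk <- function(g) ranks[match(g, ranks$gene_id), ]
  vapply(genes, function(g) {
    if (g %in% anchored) return("wgd")
    ps <- partners(g)
    if (length(ps) == 0L) return("singleton")
    me <- rk(g)
    dd <- vapply(ps, function(p) {
      other <- rk(p)
      if (identical(other$species, me$species) &&
          identical(other$chromosome, me$chromosome)) {
        abs(other$rank - me$rank)
      } else NA_real_
    }, numeric(1))
    if (any(!is.na(dd) & dd == 1)) return("tandem")
    if (any(!is.na(dd) & dd > 1 & dd < window)) return("proximal")
    "dispersed"
  }, character(1))
}

# --- detection filter, row-by-row loop ---------------------------------------
oracle_filter <- function(hits, cfg) {
  keep <- character(0)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    cov <- (h$hmm_to - h$hmm_from + 1) / h$profile_length
    if (h$profile_name == cfg$profile_name && h$evalue <= cfg$max_evalue &&
        cov >= cfg$min_coverage) {
      keep <- c(keep, h$protein_id)
    }
  }
  sort(unique(keep))
}

# --- position-by-position motif comparator -----------------------------------
oracle_scan <- function(sequence, pattern) {
  s <- strsplit(toupper(sequence), "")[[1L]]
  p <- strsplit(toupper(pattern), "")[[1L]]
  n <- length(s); m <- length(p)
  if (m > n) return(integer(0))
  out <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    win <- s[i:(i + m - 1L)]
    if (all(p == "X" | p == win)) out <- c(out, i)
  }
  out
}

# --- random instances --------------------------------------------------------
random_atree <- function(n_leaves, seed, support_na_frac = 0.2) {
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = TRUE)
  tree$tip.label <- sprintf("g%03d", seq_len(n_leaves))
  panel <- species_panel()
  sp <- sample(panel$code, n_leaves, replace = TRUE)
  sup <- round(runif(tree$Nnode), 3)
  sup[runif(tree$Nnode) < support_na_frac] <- NA_real_
  tree$support <- sup
  annotated_gene_tree(tree, species = setNames(sp, tree$tip.label),
                      species_config = panel)
}

random_pairs <- function(n_vertices, n_edges, seed) {
  set.seed(seed)
  ids <- sprintf("v%03d", seq_len(n_vertices))
  a <- sample(ids, n_edges, replace = TRUE)
  b <- sample(ids, n_edges, replace = TRUE)
  keep <- a != b
  data.frame(gene_a = pmin(a[keep], b[keep]), gene_b = pmax(a[keep], b[keep]),
             stringsAsFactors = FALSE)
}

random_genome <- function(n_genes, seed, n_species = 2L, n_chrom = 3L,
                          n_pairs = NULL, n_anchors = NULL) {
  set.seed(seed)
  ids <- sprintf("x%03d", seq_len(n_genes))
  genes <- data.frame(
    species = sample(sprintf("sp%d", seq_len(n_species)), n_genes, TRUE),
    gene_id = ids,
    chromosome = sample(sprintf("c%d", seq_len(n_chrom)), n_genes, TRUE),
    start = sample.int(100000L, n_genes), end = NA_real_, strand = "+",
    locus_id = ids, protein_length = 100L, stringsAsFactors = FALSE)
  genes$end <- genes$start + 500
  n_pairs <- n_pairs %||% max(1L, n_genes %/% 2L)
  q <- sample(ids, n_pairs, TRUE); s <- sample(ids, n_pairs, TRUE)
  keep <- q != s
  pairs <- data.frame(query_id = q[keep], subject_id = s[keep],
                      evalue = 1e-10, stringsAsFactors = FALSE)
  n_anchors <- n_anchors %||% max(1L, n_genes %/% 10L)
  ba <- sample(ids, n_anchors, TRUE); bb <- sample(ids, n_anchors, TRUE)
  keep <- ba != bb
  blocks <- data.frame(block_id = "1", species_a = NA_character_,
                       species_b = NA_character_, gene_a = ba[keep],
                       gene_b = bb[keep], evalue = NA_real_, score = NA_real_,
                       stringsAsFactors = FALSE)
  list(genes = genes, pairs = pairs, blocks = blocks,
       ranks = assign_ranks(genes))
}

# reference tree with one extra seed-plant cluster grafted as a sister copy
grafted_reference_tree <- function() {
  atree <- reference_family_tree()
  base <- sub(";$", "", ape::write.tree(atree$tree))
  panel <- species_panel()
  angio <- panel$code[panel$group %in% c("dicot", "monocot")]
  dic <- panel$code[panel$group == "dicot"]
  mon <- panel$code[panel$group == "monocot"]
  nest <- function(v) Reduce(function(x, y) sprintf("(%s,%s)1:1", x, y), v)
  extra <- sprintf("(Pab_X:1,(%s,%s)1:1)1:1",
                   nest(sprintf("%s_X:1", dic)), nest(sprintf("%s_X:1", mon)))
  newick <- sprintf("(%s:1,%s);", base, extra)
  tree <- ape::read.tree(text = newick)
  tree$support <- normalize_support(tree$node.label)
  new_sp <- setNames(c(atree$species, setNames(c("Pab", dic, mon),
                                               paste0(c("Pab", dic, mon), "_X"))),
                     NULL)
  names(new_sp) <- c(names(atree$species), paste0(c("Pab", dic, mon), "_X"))
  annotated_gene_tree(tree, species = new_sp, species_config = panel,
                      classes = atree$classes)
}
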
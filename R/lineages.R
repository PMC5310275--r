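FAMILY_CLASSES <- c("IA", "IB", "IC1/ID", "IC2", "IE", "II")

#' Allocate ancestral lineages across depths and classes
#'
#' Builds the lineage bookkeeping used by the simulator and the packaged
#' reference tree: `n_ancient` root lineages, each expanding into one or
#' more seed-plant lineages via stem duplications, each of those expanding
#' into one or more angiosperm lineages. With the default counts (7, 11, 18)
#' the canonical class layout is used — two ancient lineages in class IA and
#' one in each remaining class; seed lineages distributed 2 (IA), 2 (IB),
#' 3 (IC1/ID), 1 (IC2), 1 (IE), 2 (II); angiosperm lineages 3/3/5/2/2/3 —
#' so that class IA-2 splits before angiosperm emergence. Other counts are
#' allocated round-robin.
#'
#' @param n_ancient,n_seed,n_angiosperm lineage counts per depth
#'   (`n_ancient <= n_seed <= n_angiosperm`).
#' @return list with data.frames `ancient` (`id`, `class`), `seed` (`id`,
#'   `ancient_id`, `class`) and `angiosperm` (`id`, `seed_id`, `class`).
#' @export
allocate_lineages <- function(n_ancient = 7L, n_seed = 11L,
                              n_angiosperm = 18L) {
  if (n_ancient < 1L || n_seed < n_ancient || n_angiosperm < n_seed) {
    stopf("lineage counts must satisfy 1 <= n_ancient <= n_seed <= n_angiosperm")
  }
  if (n_ancient == 7L && n_seed == 11L && n_angiosperm == 18L) {
    anc_class <- c("IA", "IA", "IB", "IC1/ID", "IC2", "IE", "II")
    seed_parent <- c(1L, 2L, 3L, 3L, 4L, 4L, 4L, 5L, 6L, 7L, 7L)
    angio_parent <- c(1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L, 6L, 6L, 7L,
                      8L, 8L, 9L, 9L, 10L, 11L, 11L)
  } else {
    anc_class <- rep_len(FAMILY_CLASSES, n_ancient)
    seed_parent <- sort(c(seq_len(n_ancient),
                          rep_len(seq_len(n_ancient), n_seed - n_ancient)))
    angio_parent <- sort(c(seq_len(n_seed),
                           rep_len(seq_len(n_seed), n_angiosperm - n_seed)))
  }
  ancient <- data.frame(id = sprintf("A%02d", seq_len(n_ancient)),
                        class = anc_class, stringsAsFactors = FALSE)
  seed <- data.frame(id = sprintf("S%02d", seq_len(n_seed)),
                     ancient_id = ancient$id[seed_parent],
                     class = ancient$class[seed_parent],
                     stringsAsFactors = FALSE)
  angiosperm <- data.frame(id = sprintf("L%02d", seq_len(n_angiosperm)),
                           seed_id = seed$id[angio_parent],
                           class = seed$class[angio_parent],
                           stringsAsFactors = FALSE)
  list(ancient = ancient, seed = seed, angiosperm = angiosperm)
}

# left-deep nesting of newick fragments with a support label on each join
nest_newick <- function(parts, support_label) {
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) return(NULL)
  out <- parts[[1L]]
  for (i in seq_along(parts)[-1L]) {
    out <- sprintf("(%s,%s)%s:1", out, parts[[i]], support_label)
  }
  out
}

leaf_nwk <- function(id) sprintf("%s:1", id)

# attach duplicate copies as successive sisters of their template leaf
leaf_with_copies <- function(id, copies, support_label) {
  frag <- leaf_nwk(id)
  for (cp in copies[[id]] %||% character(0)) {
    frag <- sprintf("(%s,%s)%s:1", frag, leaf_nwk(cp), support_label)
  }
  frag
}

#' Build the lineage gene tree and its leaf metadata
#'
#' Deterministically constructs the rooted gene tree implied by a lineage
#' allocation over a species panel: each ancient lineage is a clade of the
#' form (basal genes, seed-plant descendants); each seed lineage is
#' (gymnosperm genes, angiosperm descendants); each angiosperm lineage is a
#' (dicots, monocots) clade with one leaf per species. Gene ids are
#' `<species>_<lineage>` (e.g. `Ath_L07`, `Pab_S03`, `Ppa_A01`). Lost genes
#' are omitted; per-species duplicate copies are attached as sisters of
#' their template leaf. All internal nodes carry the given support label.
#'
#' @param alloc allocation from [allocate_lineages()].
#' @param species_config species configuration.
#' @param copies named list template gene id -> character vector of copy ids.
#' @param lost character vector of base gene ids to omit.
#' @param support_label label written on internal nodes (default `"1"`,
#'   i.e. certain).
#' @return list with `newick` (string), `tree` (`phylo` with normalized
#'   `support`) and `leaves` (data.frame `gene_id`, `species`, `class`,
#'   `ancient_id`, `seed_id`, `angiosperm_id`).
#' @export
build_lineage_tree <- function(alloc, species_config = species_panel(),
                               copies = list(), lost = character(0),
                               support_label = "1") {
  species_config <- validate_species_config(species_config)
  basal_sp <- species_in_groups(species_config, c("bryophyte", "lycophyte"))
  gym_sp <- species_in_groups(species_config, "gymnosperm")
  dic_sp <- species_in_groups(species_config, "dicot")
  mon_sp <- species_in_groups(species_config, "monocot")
  meta <- list()
  add_meta <- function(gene, sp, class, anc, seed, ang) {
    meta[[length(meta) + 1L]] <<- data.frame(
      gene_id = gene, species = sp, class = class, ancient_id = anc,
      seed_id = seed, angiosperm_id = ang, stringsAsFactors = FALSE)
  }
  base_leaf <- function(sp, lineage, class, anc, seed, ang) {
    id <- paste0(sp, "_", lineage)
    if (id %in% lost) return(NULL)
    add_meta(id, sp, class, anc, seed, ang)
    for (cp in copies[[id]] %||% character(0)) {
      add_meta(cp, sp, class, anc, seed, ang)
    }
    leaf_with_copies(id, copies, support_label)
  }
  angio_subtree <- function(ang_row) {
    seed_id <- ang_row$seed_id
    anc_id <- alloc$seed$ancient_id[match(seed_id, alloc$seed$id)]
    dic <- nest_newick(lapply(dic_sp, base_leaf, lineage = ang_row$id,
                              class = ang_row$class, anc = anc_id,
                              seed = seed_id, ang = ang_row$id), support_label)
    mon <- nest_newick(lapply(mon_sp, base_leaf, lineage = ang_row$id,
                              class = ang_row$class, anc = anc_id,
                              seed = seed_id, ang = ang_row$id), support_label)
    nest_newick(list(dic, mon), support_label)
  }
  seed_subtree <- function(seed_row) {
    gym <- nest_newick(lapply(gym_sp, base_leaf, lineage = seed_row$id,
                              class = seed_row$class,
                              anc = seed_row$ancient_id, seed = seed_row$id,
                              ang = NA_character_), support_label)
    angs <- alloc$angiosperm[alloc$angiosperm$seed_id == seed_row$id, ,
                             drop = FALSE]
    ang <- nest_newick(lapply(seq_len(nrow(angs)), function(i)
      angio_subtree(angs[i, , drop = FALSE])), support_label)
    nest_newick(list(gym, ang), support_label)
  }
  ancient_subtree <- function(anc_row) {
    basal <- nest_newick(lapply(basal_sp, base_leaf, lineage = anc_row$id,
                                class = anc_row$class, anc = anc_row$id,
                                seed = NA_character_, ang = NA_character_),
                         support_label)
    seeds <- alloc$seed[alloc$seed$ancient_id == anc_row$id, , drop = FALSE]
    sd <- nest_newick(lapply(seq_len(nrow(seeds)), function(i)
      seed_subtree(seeds[i, , drop = FALSE])), support_label)
    nest_newick(list(basal, sd), support_label)
  }
  root <- nest_newick(lapply(seq_len(nrow(alloc$ancient)), function(i)
    ancient_subtree(alloc$ancient[i, , drop = FALSE])), support_label)
  if (is.null(root)) stopf("the lineage tree has no surviving leaves")
  newick <- paste0(sub(":1$", "", root), ";")
  tree <- ape::read.tree(text = newick)
  tree$support <- normalize_support(tree$node.label %||%
                                      rep(NA_character_, tree$Nnode))
  list(newick = newick, tree = tree, leaves = do.call(rbind, meta))
}

#' Packaged reference gene tree
#'
#' Deterministically builds the reference land-plant family tree used in the
#' package's worked examples and acceptance checks: the default eleven
#' species panel with 7 ancient lineages (two in class IA, one in each of
#' IB, IC1/ID, IC2, IE, II), 11 seed-plant lineages (3 in IC1/ID, 2 in each
#' of IA, IB, II, 1 in each of IC2, IE) and 18 angiosperm lineages. Each
#' basal (bryophyte + lycophyte) clade is sister to the clade of all its
#' seed-plant descendants, and every angiosperm lineage carries one gene per
#' angiosperm species. All supports are 1.
#'
#' @return an [annotated_gene_tree()].
#' @export
reference_family_tree <- function() {
  alloc <- allocate_lineages(7L, 11L, 18L)
  built <- build_lineage_tree(alloc, species_panel())
  annotated_gene_tree(
    built$tree,
    species = stats::setNames(built$leaves$species, built$leaves$gene_id),
    species_config = species_panel(),
    classes = stats::setNames(built$leaves$class, built$leaves$gene_id))
}
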
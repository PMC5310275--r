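#' Species- and class-annotated gene trees
#'
#' Binds a rooted `phylo` gene tree to its leaf annotations: a gene -> species
#' map (mandatory; every leaf species must occur in the species config), an
#' optional gene -> class map, and normalized branch supports in `[0, 1]`
#' (taken from the tree's `support` component or its `node.label`, see
#' [read_newick_tree()]). Multifurcations are kept as-is.
#'
#' @param tree a `phylo` object (rooted; use [root_tree()] first otherwise).
#' @param species named character vector or data.frame (`gene_id`, `species`)
#'   mapping every leaf to a species code.
#' @param species_config species configuration (see [species_panel()]).
#' @param classes optional named character vector or data.frame (`gene_id`,
#'   `class`) mapping leaves to family classes.
#' @return object of class `annotated_gene_tree`: list with elements `tree`,
#'   `support`, `species`, `classes`, `species_config`.
#' @export
annotated_gene_tree <- function(tree, species, species_config = species_panel(),
                                classes = NULL) {
  if (!inherits(tree, "phylo")) stopf("tree must be a 'phylo' object")
  if (!ape::is.rooted(tree)) stopf("tree must be rooted; see root_tree()")
  species_config <- validate_species_config(species_config)
  if (is.data.frame(species)) {
    species <- stats::setNames(species$species, species$gene_id)
  }
  miss <- setdiff(tree$tip.label, names(species))
  if (length(miss) > 0L) {
    stopf("leaf gene(s) without species annotation: %s",
          paste(utils::head(miss, 5L), collapse = ", "))
  }
  leaf_sp <- unname(species[tree$tip.label])
  unknown <- setdiff(unique(leaf_sp), species_config$code)
  if (length(unknown) > 0L) {
    stopf("leaf species not in the species config: %s",
          paste(unknown, collapse = ", "))
  }
  if (is.data.frame(classes)) {
    classes <- stats::setNames(classes$class, classes$gene_id)
  }
  sup <- tree$support %||% normalize_support(tree$node.label %||%
                                               rep(NA_character_, tree$Nnode))
  if (length(sup) != tree$Nnode) sup <- rep(NA_real_, tree$Nnode)
  structure(list(tree = tree, support = as.numeric(sup),
                 species = species, classes = classes,
                 species_config = species_config),
            class = "annotated_gene_tree")
}

#' @export
print.annotated_gene_tree <- function(x, ...) {
  cat(sprintf("annotated gene tree: %d leaves, %d internal nodes, %d species\n",
              length(x$tree$tip.label), x$tree$Nnode,
              length(unique(x$species[x$tree$tip.label]))))
  invisible(x)
}

#' Root an unrooted gene tree
#'
#' Roots on the edge separating a monophyletic outgroup, or at the midpoint
#' of the longest leaf-to-leaf path when `outgroup = "midpoint"`. An
#' already-rooted tree whose root bipartition matches the requested outgroup
#' is returned unchanged.
#'
#' @param tree a `phylo` object.
#' @param outgroup character vector of outgroup leaf labels, or `"midpoint"`.
#' @return rooted `phylo` object.
#' @export
root_tree <- function(tree, outgroup = "midpoint") {
  if (identical(outgroup, "midpoint")) {
    if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
    return(phangorn::midpoint(tree))
  }
  miss <- setdiff(outgroup, tree$tip.label)
  if (length(miss) > 0L) {
    stopf("outgroup leaf/leaves not in the tree: %s",
          paste(miss, collapse = ", "))
  }
  if (ape::is.rooted(tree)) {
    root_children <- tree_children(tree)[[ape::Ntip(tree) + 1L]]
    sets <- clade_leafsets(tree)
    for (ch in root_children) {
      if (setequal(tree$tip.label[sets[[ch]]], outgroup)) return(tree)
    }
  }
  if (!ape::is.monophyletic(tree, tips = outgroup)) {
    ingroup <- setdiff(tree$tip.label, outgroup)
    if (!ape::is.monophyletic(tree, tips = ingroup)) {
      stopf("outgroup is not monophyletic; scattered leaves include: %s",
            paste(utils::head(outgroup, 5L), collapse = ", "))
    }
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# ---- internal phylo helpers -------------------------------------------------

# children of every node (index over 1..Ntip+Nnode); leaves get integer(0)
tree_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(n)) ch[[i]] <- integer(0)
  sp <- split(tree$edge[, 2L], tree$edge[, 1L])
  for (nm in names(sp)) ch[[as.integer(nm)]] <- as.integer(sp[[nm]])
  ch
}

# internal node ids in postorder (children before parents)
postorder_nodes <- function(tree) {
  unique(ape::reorder.phylo(tree, "postorder")$edge[, 1L])
}

# leaf-tip indices under every node
clade_leafsets <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  sets <- vector("list", n)
  for (i in seq_len(ntip)) sets[[i]] <- i
  ch <- tree_children(tree)
  for (nd in postorder_nodes(tree)) {
    sets[[nd]] <- sort(unlist(sets[ch[[nd]]], use.names = FALSE))
  }
  sets
}

# parent of every node (NA for the root)
tree_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- rep(NA_integer_, n)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

node_support <- function(atree, node) {
  ntip <- ape::Ntip(atree$tree)
  if (node <= ntip) return(NA_real_)
  atree$support[node - ntip]
}
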
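#' Taxon-coverage requirements on clades
#'
#' A requirement is a list of clauses that must all hold on a clade's leaf
#' multiset. Each clause names a species set and a minimum: with
#' `unit = "genes"` at least `min_count` leaves from the set must be present;
#' with `unit = "species"` at least `min_count` *distinct* species from the
#' set must be represented. Species outside every clause are transparent —
#' they neither satisfy nor block a clause.
#'
#' @param species character vector of species codes.
#' @param min_count minimum count (>= 1).
#' @param unit `"genes"` or `"species"`.
#' @return `taxon_clause()`: a clause; `taxon_requirement()`: a list of
#'   clauses with class `taxon_requirement`.
#' @export
taxon_clause <- function(species, min_count = 1L, unit = c("genes", "species")) {
  unit <- match.arg(unit)
  if (min_count < 1) stopf("clause minimum count must be >= 1")
  if (length(species) == 0L) stopf("clause species set must be nonempty")
  structure(list(species = unique(species), min_count = as.integer(min_count),
                 unit = unit), class = "taxon_clause")
}

#' @param ... taxon clauses.
#' @rdname taxon_clause
#' @export
taxon_requirement <- function(...) {
  cl <- list(...)
  if (length(cl) == 1L && is.list(cl[[1L]]) && !inherits(cl[[1L]], "taxon_clause")) {
    cl <- cl[[1L]]
  }
  if (!all(vapply(cl, inherits, logical(1), "taxon_clause"))) {
    stopf("all arguments must be taxon_clause objects")
  }
  structure(cl, class = "taxon_requirement")
}

# one clause per species code: ">= 1 gene from each of these species"
each_species_clauses <- function(codes) {
  lapply(codes, function(s) taxon_clause(s, 1L, "genes"))
}

clause_satisfied <- function(leaf_species, clause) {
  hit <- leaf_species[leaf_species %in% clause$species]
  if (clause$unit == "genes") {
    length(hit) >= clause$min_count
  } else {
    length(unique(hit)) >= clause$min_count
  }
}

requirement_satisfied <- function(leaf_species, req) {
  all(vapply(req, clause_satisfied, logical(1), leaf_species = leaf_species))
}

check_requirement_species <- function(req, species_config) {
  known <- species_config$code
  for (cl in req) {
    bad <- setdiff(cl$species, known)
    if (length(bad) > 0L) {
      stopf("requirement references unknown species: %s",
            paste(bad, collapse = ", "))
    }
  }
  invisible(req)
}

# support gate at a candidate node: pass when no threshold is set, when the
# node's support meets it, or when the node is a cherry parent (all children
# leaves) whose support is missing
support_passes <- function(atree, node, children, min_support) {
  if (is.null(min_support)) return(TRUE)
  s <- node_support(atree, node)
  if (!is.na(s)) return(s >= min_support)
  all(children[[node]] <= ape::Ntip(atree$tree))
}

#' Minimal taxon-complete clades
#'
#' Scans the rooted tree in postorder and returns the *minimal* clades whose
#' leaf multiset satisfies every clause of the requirement (no qualifying
#' strict descendant) and whose defining node passes the optional support
#' gate. Minimal qualifying clades are pairwise disjoint by construction.
#'
#' @param atree an [annotated_gene_tree()].
#' @param req a [taxon_requirement()].
#' @param min_support optional support threshold in `[0, 1]`; `NULL` (the
#'   default) disables support gating.
#' @return list of records, each with `node` (internal node id), `members`
#'   (leaf labels) and `support`.
#' @export
minimal_complete_clades <- function(atree, req, min_support = NULL) {
  check_requirement_species(req, atree$species_config)
  tree <- atree$tree
  ntip <- ape::Ntip(tree)
  nall <- ntip + tree$Nnode
  children <- tree_children(tree)
  sets <- clade_leafsets(tree)
  leaf_sp <- unname(atree$species[tree$tip.label])

  qualifies <- logical(nall)
  for (nd in seq_len(nall)) {
    qualifies[nd] <- requirement_satisfied(leaf_sp[sets[[nd]]], req) &&
      (nd <= ntip || support_passes(atree, nd, children, min_support))
  }
  # leaves can qualify only under single-species single-gene requirements
  has_qual <- logical(nall)
  minimal <- integer(0)
  for (nd in c(seq_len(ntip), postorder_nodes(tree))) {
    child_qual <- any(has_qual[children[[nd]]])
    if (qualifies[nd] && !child_qual) minimal <- c(minimal, nd)
    has_qual[nd] <- qualifies[nd] || child_qual
  }
  lapply(sort(minimal), function(nd) {
    list(node = nd, members = tree$tip.label[sets[[nd]]],
         support = node_support(atree, nd))
  })
}

majority_class <- function(members, classes) {
  if (is.null(classes)) return(NA_character_)
  cl <- classes[members]
  cl <- cl[!is.na(cl)]
  if (length(cl) == 0L) return(NA_character_)
  tab <- table(cl)
  names(tab)[order(-tab, names(tab))][1L]  # majority, ties lexicographic
}

make_clusters <- function(records, depth, atree, scope_members = NULL) {
  n <- length(records)
  members <- lapply(records, `[[`, "members")
  df <- data.frame(
    cluster_id = if (n > 0) sprintf("%s_%02d", toupper(substr(depth, 1, 3)), seq_len(n)) else character(0),
    depth = rep(depth, n),
    class = vapply(members, majority_class, character(1), classes = atree$classes),
    support = vapply(records, function(r) r$support %||% NA_real_, numeric(1)),
    n_members = vapply(members, length, integer(1)),
    collinearity_supported = rep(NA, n),
    stringsAsFactors = FALSE)
  df$members <- I(members)
  df$scope_members <- I(scope_members %||% members)
  class(df) <- c("lineage_clusters", class(df))
  assert_disjoint(df)
  df
}

assert_disjoint <- function(clusters) {
  all_members <- unlist(clusters$members, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stopf("internal error: clusters at depth '%s' are not pairwise disjoint",
          clusters$depth[1L])
  }
  invisible(clusters)
}

#' Ancient land-plant gene lineages
#'
#' Finds the maximal clades whose leaves are exclusively bryophyte/lycophyte
#' genes. Such a basal clade attests an ancient lineage iff its sister
#' clade's leaf set satisfies the sister requirement — by default at least
#' one gene from *every* configured seed-plant species (gymnosperms plus
#' angiosperms), the topology-checkable reading of basal genes "neighboring"
#' seed-plant genes. The optional support gate applies at the basal clade's
#' node. Zero attestations is a valid result.
#'
#' @inheritParams minimal_complete_clades
#' @param sister_requirement optional [taxon_requirement()] evaluated on the
#'   sister clade; default: every seed-plant species present.
#' @return a `lineage_clusters` data.frame (depth `"ancient"`); members are
#'   the basal-clade genes, `scope_members` the basal clade plus its sister
#'   (used for lineage-path containment).
#' @export
find_ancient_lineages <- function(atree, min_support = NULL,
                                  sister_requirement = NULL) {
  cfg <- atree$species_config
  basal_sp <- species_in_groups(cfg, c("bryophyte", "lycophyte"))
  if (length(basal_sp) == 0L) {
    stopf("no bryophyte/lycophyte species configured")
  }
  seed_sp <- species_in_groups(cfg, c("gymnosperm", "dicot", "monocot"))
  req <- sister_requirement %||% taxon_requirement(each_species_clauses(seed_sp))
  check_requirement_species(req, cfg)

  tree <- atree$tree
  ntip <- ape::Ntip(tree)
  children <- tree_children(tree)
  parents <- tree_parents(tree)
  sets <- clade_leafsets(tree)
  leaf_sp <- unname(atree$species[tree$tip.label])

  nall <- ntip + tree$Nnode
  all_basal <- logical(nall)
  for (nd in seq_len(ntip)) all_basal[nd] <- leaf_sp[nd] %in% basal_sp
  for (nd in postorder_nodes(tree)) {
    all_basal[nd] <- all(all_basal[children[[nd]]])
  }
  records <- list()
  for (nd in seq_len(nall)) {
    if (!all_basal[nd]) next
    par <- parents[nd]
    if (is.na(par) || all_basal[par]) next  # not maximal (or basal root)
    if (!support_passes(atree, nd, children, min_support)) next
    sister_leaves <- setdiff(sets[[par]], sets[[nd]])
    if (!requirement_satisfied(leaf_sp[sister_leaves], req)) next
    records[[length(records) + 1L]] <- list(
      node = nd, members = tree$tip.label[sets[[nd]]],
      support = node_support(atree, nd),
      scope = tree$tip.label[sets[[par]]])
  }
  make_clusters(records, "ancient", atree,
                scope_members = lapply(records, `[[`, "scope"))
}

#' Seed-plant ancestor clusters
#'
#' Minimal clades containing at least one gymnosperm gene plus at least one
#' gene from every configured angiosperm species — the stringent criterion
#' guarding against long-branch attraction when retracing ancestors that
#' predate seed-plant emergence.
#'
#' @inheritParams minimal_complete_clades
#' @return a `lineage_clusters` data.frame (depth `"seed"`).
#' @export
find_seed_ancestors <- function(atree, min_support = NULL) {
  cfg <- atree$species_config
  gym <- species_in_groups(cfg, "gymnosperm")
  if (length(gym) == 0L) stopf("no gymnosperm species configured")
  angio <- species_in_groups(cfg, c("dicot", "monocot"))
  if (length(angio) == 0L) stopf("no angiosperm species configured")
  req <- taxon_requirement(c(list(taxon_clause(gym, 1L, "genes")),
                             each_species_clauses(angio)))
  make_clusters(minimal_complete_clades(atree, req, min_support),
                "seed", atree)
}

#' Angiosperm ancestor clusters
#'
#' Minimal clades whose angiosperm leaves cover at least `dicot_min` dicot
#' species and `monocot_min` monocot species (defaults: all configured
#' dicots and all configured monocots). Non-angiosperm leaves are
#' transparent: they neither satisfy nor block the clauses, so gymnosperm
#' orthologs interleaved by stem duplications do not disqualify a clade.
#'
#' @inheritParams minimal_complete_clades
#' @param dicot_min,monocot_min minimum number of distinct dicot/monocot
#'   species a clade must cover; `NULL` means all configured.
#' @return a `lineage_clusters` data.frame (depth `"angiosperm"`).
#' @export
find_angiosperm_ancestors <- function(atree, min_support = NULL,
                                      dicot_min = NULL, monocot_min = NULL) {
  cfg <- atree$species_config
  dic <- species_in_groups(cfg, "dicot")
  mon <- species_in_groups(cfg, "monocot")
  if (length(dic) == 0L) stopf("no dicot species configured")
  if (length(mon) == 0L) stopf("no monocot species configured")
  dicot_min <- dicot_min %||% length(dic)
  monocot_min <- monocot_min %||% length(mon)
  if (dicot_min > length(dic) || monocot_min > length(mon)) {
    stopf("clause minima exceed the number of configured species")
  }
  req <- taxon_requirement(taxon_clause(dic, dicot_min, "species"),
                           taxon_clause(mon, monocot_min, "species"))
  make_clusters(minimal_complete_clades(atree, req, min_support),
                "angiosperm", atree)
}

#' Cross-support angiosperm clusters with collinear groups
#'
#' An angiosperm cluster is collinearity-supported iff (a) all of its dicot
#' members that occur in any dicot collinear group fall in one single group,
#' (b) likewise for monocot members and monocot groups, and (c) at least one
#' member occurs in some group. Clusters with no grouped member are flagged
#' unsupported (massive duplication can obscure syntenic blocks).
#'
#' @param clusters `lineage_clusters` at depth `"angiosperm"`.
#' @param dicot_groups,monocot_groups group tables from [merge_groups()].
#' @param species_map named character vector gene -> species code.
#' @param species_config species configuration.
#' @return `clusters` with `collinearity_supported` filled in.
#' @export
collinearity_support <- function(clusters, dicot_groups, monocot_groups,
                                 species_map, species_config = species_panel()) {
  if (nrow(clusters) > 0L && !all(clusters$depth == "angiosperm")) {
    stopf("collinearity support applies to angiosperm-depth clusters")
  }
  species_config <- validate_species_config(species_config)
  dic <- species_in_groups(species_config, "dicot")
  mon <- species_in_groups(species_config, "monocot")
  gmap_d <- stats::setNames(dicot_groups$group_id, dicot_groups$gene_id)
  gmap_m <- stats::setNames(monocot_groups$group_id, monocot_groups$gene_id)
  one_group <- function(members, scope_sp, gmap) {
    g <- gmap[members[species_map[members] %in% scope_sp]]
    g <- g[!is.na(g)]
    list(ok = length(unique(g)) <= 1L, any = length(g) > 0L)
  }
  clusters$collinearity_supported <- vapply(clusters$members, function(m) {
    d <- one_group(m, dic, gmap_d)
    mo <- one_group(m, mon, gmap_m)
    d$ok && mo$ok && (d$any || mo$any)
  }, logical(1))
  clusters
}

#' Ancestry report across the three depths
#'
#' Tabulates cluster counts per depth and class, and traces each gene's
#' lineage path gene -> angiosperm cluster -> seed cluster -> ancient
#' lineage by clade containment (a deeper cluster contains a shallower one
#' when the shallower member set is a subset of the deeper cluster's scope;
#' for ancient lineages the scope is the attesting basal clade plus its
#' sister). Containment failures are reported as `"unassigned"`, never
#' dropped; an angiosperm cluster contained in more than one seed cluster
#' would violate disjointness and raises an error.
#'
#' @param ancient,seed,angiosperm `lineage_clusters` data.frames.
#' @return list of class `ancestry_report` with elements `counts` (data.frame
#'   `depth`, `class`, `n`), `depth_counts` (named vector), `paths`
#'   (data.frame `gene_id`, `angiosperm_cluster`, `seed_cluster`,
#'   `ancient_lineage`) and `clusters` (all three tables combined).
#' @export
ancestry_report <- function(ancient, seed, angiosperm) {
  depth_counts <- c(ancient = nrow(ancient), seed = nrow(seed),
                    angiosperm = nrow(angiosperm))
  all_cl <- rbind(ancient, seed, angiosperm)
  counts <- if (nrow(all_cl) > 0L) {
    agg <- stats::aggregate(list(n = all_cl$cluster_id),
                            by = list(depth = all_cl$depth,
                                      class = ifelse(is.na(all_cl$class),
                                                     "unclassified", all_cl$class)),
                            FUN = length)
    agg[order(match(agg$depth, c("ancient", "seed", "angiosperm")), agg$class), ]
  } else {
    data.frame(depth = character(), class = character(), n = integer())
  }
  containing_cluster <- function(members, deeper) {
    hits <- which(vapply(deeper$scope_members, function(s) all(members %in% s),
                         logical(1)))
    if (length(hits) > 1L) {
      stopf("cluster containment is ambiguous (%d containing clusters)",
            length(hits))
    }
    if (length(hits) == 1L) deeper$cluster_id[hits] else "unassigned"
  }
  paths <- if (nrow(angiosperm) > 0L) {
    do.call(rbind, lapply(seq_len(nrow(angiosperm)), function(i) {
      mem <- angiosperm$members[[i]]
      seed_id <- containing_cluster(mem, seed)
      anc_id <- if (seed_id == "unassigned") "unassigned" else {
        containing_cluster(seed$members[[match(seed_id, seed$cluster_id)]],
                           ancient)
      }
      data.frame(gene_id = mem,
                 angiosperm_cluster = angiosperm$cluster_id[i],
                 seed_cluster = seed_id, ancient_lineage = anc_id,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(), angiosperm_cluster = character(),
               seed_cluster = character(), ancient_lineage = character())
  }
  structure(list(counts = counts, depth_counts = depth_counts, paths = paths,
                 clusters = all_cl),
            class = "ancestry_report")
}

#' @export
print.ancestry_report <- function(x, ...) {
  cat(sprintf("ancestral lineages: %d ancient, %d seed-plant, %d angiosperm\n",
              x$depth_counts[["ancient"]], x$depth_counts[["seed"]],
              x$depth_counts[["angiosperm"]]))
  if (nrow(x$counts) > 0L) {
    print(x$counts, row.names = FALSE)
  }
  invisible(x)
}

#' Flatten lineage clusters to a plain table
#'
#' @param clusters a `lineage_clusters` data.frame.
#' @return data.frame with one row per member gene.
#' @export
clusters_table <- function(clusters) {
  if (nrow(clusters) == 0L) {
    return(data.frame(cluster_id = character(), depth = character(),
                      class = character(), support = numeric(),
                      collinearity_supported = logical(),
                      gene_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
    data.frame(cluster_id = clusters$cluster_id[i], depth = clusters$depth[i],
               class = clusters$class[i], support = clusters$support[i],
               collinearity_supported = clusters$collinearity_supported[i],
               gene_id = clusters$members[[i]], stringsAsFactors = FALSE)
  }))
}
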
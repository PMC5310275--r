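#' Configuration for the gene-family evolution simulator
#'
#' The simulator evolves a gene family along a species panel: `n_ancient`
#' root lineages established in early land plants, stem duplications
#' expanding them to `n_seed` lineages before seed-plant emergence and to
#' `n_angiosperm` lineages before angiosperm emergence, then per-species
#' duplication events (WGD / tandem / proximal / dispersed) inside each
#' angiosperm genome, with optional gene loss. Defaults encode a typical
#' land-plant family history: depth counts (7, 11, 18) on the eleven-species
#' panel, and per-angiosperm-species event counts dominated by WGD and
#' dispersed duplications.
#'
#' @param species species configuration (see [species_panel()]).
#' @param n_ancient_lineages,n_seed_lineages,n_angiosperm_lineages lineage
#'   counts per depth (see [allocate_lineages()]).
#' @param events named integer vector of per-angiosperm-species duplication
#'   event counts with names `wgd`, `tandem`, `proximal`, `dispersed`; each
#'   event targets one distinct family gene and creates one copy.
#' @param wgd_retention fraction of background genes retained in a
#'   duplicated block (the family gene itself is always retained).
#' @param background_genes_per_chromosome,n_chromosomes genome size knobs.
#' @param loss_probability per-gene probability that a base family gene is
#'   lost (applied before events).
#' @param isoform_probability probability that a family gene model gets a
#'   second, shorter isoform sharing its locus.
#' @param seed RNG seed; the whole dataset is deterministic given the seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(species = species_panel(),
                       n_ancient_lineages = 7L, n_seed_lineages = 11L,
                       n_angiosperm_lineages = 18L,
                       events = c(wgd = 5L, tandem = 2L, proximal = 1L,
                                  dispersed = 4L),
                       wgd_retention = 0.5,
                       background_genes_per_chromosome = 200L,
                       n_chromosomes = 5L,
                       loss_probability = 0,
                       isoform_probability = 0.2,
                       seed = 1L) {
  species <- validate_species_config(species)
  ev <- c(wgd = 0L, tandem = 0L, proximal = 0L, dispersed = 0L)
  ev[names(events)] <- as.integer(events)
  bad <- setdiff(names(events), names(ev))
  if (length(bad) > 0L) stopf("unknown event type(s): %s", paste(bad, collapse = ", "))
  if (any(ev < 0L)) stopf("event counts must be >= 0")
  if (sum(ev) > n_angiosperm_lineages) {
    stopf("per-species event total (%d) exceeds the number of angiosperm lineages (%d)",
          sum(ev), n_angiosperm_lineages)
  }
  if (wgd_retention < 0 || wgd_retention > 1) stopf("wgd_retention must be in [0, 1]")
  if (loss_probability < 0 || loss_probability >= 1) {
    stopf("loss_probability must be in [0, 1)")
  }
  n_slots <- ceiling(n_angiosperm_lineages / n_chromosomes)
  if (20L + 30L * (n_slots - 1L) > background_genes_per_chromosome) {
    stopf("chromosomes too short for %d lineages: increase background_genes_per_chromosome",
          n_angiosperm_lineages)
  }
  structure(list(species = species,
                 n_ancient_lineages = as.integer(n_ancient_lineages),
                 n_seed_lineages = as.integer(n_seed_lineages),
                 n_angiosperm_lineages = as.integer(n_angiosperm_lineages),
                 events = ev, wgd_retention = wgd_retention,
                 background_genes_per_chromosome = as.integer(background_genes_per_chromosome),
                 n_chromosomes = as.integer(n_chromosomes),
                 loss_probability = loss_probability,
                 isoform_probability = isoform_probability,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# lineage slot layout: lineage j of a depth sits on chromosome
# ((j-1) %% n_chrom) + 1 at gene-order slot 20 + 30 * ((j-1) %/% n_chrom),
# identical in every species carrying it (the syntenic position)
lineage_slot <- function(j, n_chrom) {
  list(chrom = ((j - 1L) %% n_chrom) + 1L,
       slot = 20L + 30L * ((j - 1L) %/% n_chrom))
}

bg_id <- function(sp, chrom, slot) sprintf("%s_bg%d_%03d", sp, chrom, slot)

#' Simulate a gene-family evolution dataset with ground truth
#'
#' Emits every pipeline input — gene table, domain hits, homology pairs,
#' collinearity blocks, species-annotated gene tree, class map and protein
#' sequences — plus the ground truth the generator knows: per-gene lineage
#' ids at each depth, duplication labels, true collinear groups and depth
#' counts. Background genes fill each chromosome; family genes occupy fixed
#' syntenic slots so inter-species collinear blocks (within dicots and
#' within monocots, as block detection is run per clade) carry the true
#' ortholog anchors. WGD events duplicate a window of the template's
#' chromosome onto another chromosome and emit the intra-species block;
#' tandem copies insert at gene-order offset 1, proximal at an offset drawn
#' uniformly from 2..19, dispersed copies land on a different chromosome.
#' Tree supports are emitted as 1 (the simulated history is certain); noise
#' is injected only via [perturb_simulation()]. Homology pairs connect genes
#' of the same ancient lineage and are truncated to the top 5 partners per
#' query by simulated similarity (same-species copies closest, then
#' phylogenetically near species). Class-diagnostic motifs are implanted in
#' the simulated proteins: `SKYQ` in class IA, `LxLxL` in class II.
#'
#' @param cfg a [sim_config()].
#' @return list of class `family_simulation` with elements `config`, `genes`,
#'   `domain_hits`, `pairs`, `blocks`, `tree`, `leaves`, `classes`,
#'   `proteins`, `truth`.
#' @export
simulate_family <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  species <- cfg$species
  n_chrom <- cfg$n_chromosomes
  bg_n <- cfg$background_genes_per_chromosome
  alloc <- allocate_lineages(cfg$n_ancient_lineages, cfg$n_seed_lineages,
                             cfg$n_angiosperm_lineages)
  angio_sp <- species_in_groups(species, c("dicot", "monocot"))
  gym_sp <- species_in_groups(species, "gymnosperm")
  basal_sp <- species_in_groups(species, c("bryophyte", "lycophyte"))

  # lineages carried per species group
  carried <- function(sp) {
    grp <- species$group[species$code == sp]
    switch(grp,
           bryophyte = , lycophyte = alloc$ancient$id,
           gymnosperm = alloc$seed$id,
           alloc$angiosperm$id)
  }
  base_ids <- unlist(lapply(species$code, function(sp)
    paste0(sp, "_", carried(sp))), use.names = FALSE)

  # gene loss on base genes
  lost <- base_ids[stats::runif(length(base_ids)) < cfg$loss_probability]

  # per-angiosperm-species duplication events over surviving base genes
  ev_counts <- cfg$events
  ev_types <- rep(names(ev_counts), ev_counts)
  events <- list()
  for (sp in angio_sp) {
    surv <- setdiff(paste0(sp, "_", alloc$angiosperm$id), lost)
    n_ev <- min(length(ev_types), length(surv))
    targets <- sample(surv, n_ev)
    if (n_ev > 0L) {
      events[[sp]] <- data.frame(species = sp, template = targets,
                                 type = ev_types[seq_len(n_ev)],
                                 stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(species = character(), template = character(),
               type = character(), stringsAsFactors = FALSE)
  suffix <- c(wgd = "w", tandem = "t", proximal = "p", dispersed = "d")
  events$copy <- paste0(events$template, suffix[events$type])

  # ---- genome assembly ------------------------------------------------------
  chrom_genes <- list()   # [[sp]][[chrom]] ordered gene ids
  for (sp in species$code) {
    chrom_genes[[sp]] <- lapply(seq_len(n_chrom), function(cc)
      bg_id(sp, cc, seq_len(bg_n)))
    lin <- carried(sp)
    for (j in seq_along(lin)) {
      id <- paste0(sp, "_", lin[j])
      if (id %in% lost) next
      pos <- lineage_slot(j, n_chrom)
      chrom_genes[[sp]][[pos$chrom]][pos$slot] <- id
    }
  }

  intra_blocks <- list()
  ev_order <- order(events$template)
  for (k in ev_order) {
    sp <- events$species[k]
    tmpl <- events$template[k]
    cp <- events$copy[k]
    cc <- which(vapply(chrom_genes[[sp]], function(v) tmpl %in% v, logical(1)))
    idx <- match(tmpl, chrom_genes[[sp]][[cc]])
    other <- (cc %% n_chrom) + 1L
    if (events$type[k] == "tandem") {
      chrom_genes[[sp]][[cc]] <- append(chrom_genes[[sp]][[cc]], cp, after = idx)
    } else if (events$type[k] == "proximal") {
      off <- sample(2:19, 1L)
      chrom_genes[[sp]][[cc]] <- append(chrom_genes[[sp]][[cc]], cp,
                                        after = idx + off - 1L)
    } else if (events$type[k] == "dispersed") {
      chrom_genes[[sp]][[other]] <- c(chrom_genes[[sp]][[other]], cp)
    } else {  # wgd: duplicate a window of the template's chromosome
      win <- max(1L, idx - 5L):min(length(chrom_genes[[sp]][[cc]]), idx + 5L)
      orig <- chrom_genes[[sp]][[cc]][win]
      keep <- orig == tmpl | stats::runif(length(orig)) < cfg$wgd_retention
      orig <- orig[keep]
      dup <- ifelse(orig == tmpl, cp, paste0(orig, "w"))
      chrom_genes[[sp]][[other]] <- c(chrom_genes[[sp]][[other]], dup)
      intra_blocks[[length(intra_blocks) + 1L]] <- data.frame(
        species_a = sp, species_b = sp, gene_a = orig, gene_b = dup,
        stringsAsFactors = FALSE)
    }
  }

  # ---- gene table -----------------------------------------------------------
  gene_rows <- list()
  for (sp in species$code) {
    for (cc in seq_len(n_chrom)) {
      ids <- chrom_genes[[sp]][[cc]]
      n <- length(ids)
      is_fam <- !grepl("_bg", ids)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        species = sp, gene_id = ids, chromosome = paste0("Chr", cc),
        start = (seq_len(n) - 1L) * 1000 + 1, end = (seq_len(n) - 1L) * 1000 + 900,
        strand = rep_len(c("+", "-"), n), locus_id = ids,
        protein_length = ifelse(is_fam, 240L, 300L), stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)
  fam_genes <- genes$gene_id[!grepl("_bg", genes$gene_id)]
  # alternative isoforms of family loci
  iso_of <- fam_genes[stats::runif(length(fam_genes)) < cfg$isoform_probability]
  if (length(iso_of) > 0L) {
    iso <- genes[match(iso_of, genes$gene_id), , drop = FALSE]
    iso$gene_id <- paste0(iso$gene_id, ".2")
    iso$protein_length <- 180L
    genes <- rbind(genes, iso)
  }
  genes <- genes[order(genes$species, genes$chromosome, genes$start,
                       genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  # ---- domain hits ----------------------------------------------------------
  fam_models <- genes$gene_id[!grepl("_bg", genes$gene_id)]
  hits <- data.frame(protein_id = fam_models, profile_name = "DUF260",
                     profile_length = 100L, hmm_from = 3L, hmm_to = 98L,
                     evalue = 1e-40, score = 150.0, stringsAsFactors = FALSE)
  decoys <- do.call(rbind, lapply(species$code, function(sp) data.frame(
    protein_id = bg_id(sp, 1L, 1:3),
    profile_name = c("DUF260", "DUF260", "ANK"),
    profile_length = c(100L, 100L, 80L),
    hmm_from = c(10L, 5L, 1L), hmm_to = c(49L, 95L, 80L),
    evalue = c(1e-30, 1e-3, 1e-30), score = c(40, 20, 90),
    stringsAsFactors = FALSE)))
  domain_hits <- rbind(hits, decoys)
  rownames(domain_hits) <- NULL

  # ---- lineage tree, leaf metadata, classes ---------------------------------
  copies <- split(events$copy, events$template)
  built <- build_lineage_tree(alloc, species, copies = copies, lost = lost)
  leaves <- built$leaves

  # ---- homology pairs (top-5 by simulated similarity within ancient lineage)
  sp_order <- stats::setNames(seq_len(nrow(species)), species$code)
  leaf_sp <- stats::setNames(leaves$species, leaves$gene_id)
  pair_rows <- list()
  for (anc in unique(leaves$ancient_id)) {
    grp <- leaves[leaves$ancient_id == anc, , drop = FALSE]
    if (nrow(grp) < 2L) next
    ang <- ifelse(is.na(grp$angiosperm_id), "-", grp$angiosperm_id)
    sdd <- ifelse(is.na(grp$seed_id), "-", grp$seed_id)
    same_ang <- outer(ang, ang, "==") & ang != "-"
    same_seed <- outer(sdd, sdd, "==") & sdd != "-"
    depth_div <- ifelse(same_ang, 0L, ifelse(same_seed, 1L, 2L))
    spd <- abs(outer(sp_order[grp$species], sp_order[grp$species], "-"))
    dist <- 200 * depth_div + spd
    diag(dist) <- Inf
    for (i in seq_len(nrow(grp))) {
      ord <- order(dist[i, ], grp$gene_id)
      top <- ord[is.finite(dist[i, ord])][seq_len(min(5L, nrow(grp) - 1L))]
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        query_id = grp$gene_id[i], subject_id = grp$gene_id[top],
        evalue = 1e-120 * (1 + dist[i, top]), stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows) > 0L) do.call(rbind, pair_rows) else
    data.frame(query_id = character(), subject_id = character(),
               evalue = numeric(), stringsAsFactors = FALSE)

  # ---- collinearity blocks --------------------------------------------------
  block_rows <- list()
  bi <- 0L
  add_block <- function(df) {
    bi <<- bi + 1L
    df$block_id <- as.character(bi)
    block_rows[[length(block_rows) + 1L]] <<- df
  }
  for (scope in c("dicot", "monocot")) {
    sps <- species_in_groups(species, scope)
    if (length(sps) < 2L) next
    cmb <- utils::combn(sps, 2L)
    for (p in seq_len(ncol(cmb))) {
      spa <- cmb[1L, p]; spb <- cmb[2L, p]
      for (j in seq_len(nrow(alloc$angiosperm))) {
        pos <- lineage_slot(j, n_chrom)
        offs <- setdiff(-5:5, 0L)
        ga <- bg_id(spa, pos$chrom, pos$slot + offs)
        gb <- bg_id(spb, pos$chrom, pos$slot + offs)
        fa <- paste0(spa, "_", alloc$angiosperm$id[j])
        fb <- paste0(spb, "_", alloc$angiosperm$id[j])
        if (!(fa %in% lost) && !(fb %in% lost)) {
          ins <- sum(offs < 0L)
          ga <- append(ga, fa, after = ins)
          gb <- append(gb, fb, after = ins)
        }
        add_block(data.frame(species_a = spa, species_b = spb,
                             gene_a = ga, gene_b = gb, stringsAsFactors = FALSE))
      }
    }
  }
  for (b in intra_blocks) add_block(b)
  blocks <- do.call(rbind, block_rows)
  blocks$evalue <- 1e-50
  blocks$score <- 100
  blocks <- blocks[c("block_id", "species_a", "species_b", "gene_a", "gene_b",
                     "evalue", "score")]
  rownames(blocks) <- NULL

  # ---- proteins with class-diagnostic motifs --------------------------------
  prot_len <- 120L
  consensus <- lapply(stats::setNames(FAMILY_CLASSES, FAMILY_CLASSES),
                      function(cl) sample(AA_ALPHABET, prot_len, replace = TRUE))
  proteins <- character(0)
  for (i in seq_len(nrow(leaves))) {
    base <- consensus[[leaves$class[i]]]
    mut <- stats::runif(prot_len) < 0.05
    base[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
    if (leaves$class[i] == "IA") base[61:64] <- c("S", "K", "Y", "Q")
    if (leaves$class[i] == "II") base[c(101L, 103L, 105L)] <- "L"
    proteins[leaves$gene_id[i]] <- paste(base, collapse = "")
  }

  # ---- ground truth ---------------------------------------------------------
  truth_genes <- leaves
  truth_genes$duplication <- "singleton"
  truth_genes$duplication[match(events$copy, truth_genes$gene_id)] <- events$type
  truth_genes$duplication[match(events$template, truth_genes$gene_id)] <- events$type
  truth_groups <- list()
  for (scope in c("dicot", "monocot")) {
    sps <- species_in_groups(species, scope)
    rows <- list()
    for (j in seq_len(nrow(alloc$angiosperm))) {
      lid <- alloc$angiosperm$id[j]
      base <- setdiff(paste0(sps, "_", lid), lost)
      wcop <- events$copy[events$type == "wgd" & events$template %in% base]
      members <- sort(c(base, wcop))
      if (length(members) >= 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          lineage = lid, gene_id = members, stringsAsFactors = FALSE)
      }
    }
    truth_groups[[scope]] <- if (length(rows) > 0L) do.call(rbind, rows) else
      data.frame(lineage = character(), gene_id = character(),
                 stringsAsFactors = FALSE)
  }

  structure(list(
    config = cfg, genes = genes, domain_hits = domain_hits, pairs = pairs,
    blocks = blocks, tree = built$tree, leaves = leaves,
    classes = data.frame(gene_id = leaves$gene_id, class = leaves$class,
                         stringsAsFactors = FALSE),
    proteins = proteins,
    truth = list(genes = truth_genes, groups = truth_groups,
                 depth_counts = c(ancient = cfg$n_ancient_lineages,
                                  seed = cfg$n_seed_lineages,
                                  angiosperm = cfg$n_angiosperm_lineages),
                 lost = lost, events = events)),
    class = "family_simulation")
}

#' @export
print.family_simulation <- function(x, ...) {
  cat(sprintf("simulated family dataset: %d gene models (%d family), %d species, seed %d\n",
              nrow(x$genes), nrow(x$leaves), nrow(x$config$species),
              x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to pipeline input files
#'
#' Emits the exact dialects the readers consume: `genes.tsv`, `hits.tsv`,
#' `pairs.tsv`, `blocks.collinearity`, `tree.nwk`, `classes.tsv`,
#' `species.tsv`, `proteins.fasta`, plus `truth_genes.tsv` and
#' `truth_groups_<scope>.tsv`. Byte-identical for identical simulations.
#'
#' @param sim a [simulate_family()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genes = file.path(dir, "genes.tsv"),
             hits = file.path(dir, "hits.tsv"),
             pairs = file.path(dir, "pairs.tsv"),
             blocks = file.path(dir, "blocks.collinearity"),
             tree = file.path(dir, "tree.nwk"),
             classes = file.path(dir, "classes.tsv"),
             species = file.path(dir, "species.tsv"),
             proteins = file.path(dir, "proteins.fasta"),
             truth_genes = file.path(dir, "truth_genes.tsv"))
  write_gene_table(sim$genes, paths[["genes"]])
  write_domain_table(sim$domain_hits, paths[["hits"]])
  write_pair_table(sim$pairs, paths[["pairs"]])
  write_collinearity(sim$blocks, paths[["blocks"]])
  write_newick_tree(sim$tree, paths[["tree"]])
  write_tsv(sim$classes, paths[["classes"]])
  write_tsv(sim$config$species[c("code", "group")], paths[["species"]])
  aa <- Biostrings::AAStringSet(sim$proteins)
  Biostrings::writeXStringSet(aa, paths[["proteins"]])
  write_tsv(sim$truth$genes, paths[["truth_genes"]])
  for (scope in names(sim$truth$groups)) {
    p <- file.path(dir, sprintf("truth_groups_%s.tsv", scope))
    write_tsv(sim$truth$groups[[scope]], p)
    paths[[paste0("truth_groups_", scope)]] <- p
  }
  paths
}

#' Apply one controlled perturbation to a simulated dataset
#'
#' Robustness harness for property tests. Exactly one perturbation is
#' applied: `drop_gene` removes one uniformly chosen family gene from every
#' table, the tree and the sequences; `shuffle_leaf_order` rewrites the tree
#' with randomly rotated children (same rooted topology, different
#' serialization); `downgrade_support` sets one uniformly chosen internal
#' node's support to 0.1.
#'
#' @param sim a [simulate_family()] result.
#' @param op one of `"drop_gene"`, `"shuffle_leaf_order"`,
#'   `"downgrade_support"`.
#' @param seed RNG seed for the perturbation's own randomness.
#' @return perturbed `family_simulation`.
#' @export
perturb_simulation <- function(sim, op, seed = 1L) {
  ops <- c("drop_gene", "shuffle_leaf_order", "downgrade_support")
  if (!op %in% ops) {
    stopf("unknown perturbation '%s' (expected one of %s)", op,
          paste(ops, collapse = ", "))
  }
  set.seed(seed)
  if (op == "drop_gene") {
    victim <- sample(sim$leaves$gene_id, 1L)
    sim$genes <- sim$genes[!(sim$genes$gene_id %in%
                               c(victim, paste0(victim, ".2"))), , drop = FALSE]
    sim$domain_hits <- sim$domain_hits[!(sim$domain_hits$protein_id %in%
                                           c(victim, paste0(victim, ".2"))), ,
                                       drop = FALSE]
    sim$pairs <- sim$pairs[sim$pairs$query_id != victim &
                             sim$pairs$subject_id != victim, , drop = FALSE]
    sim$blocks <- sim$blocks[sim$blocks$gene_a != victim &
                               sim$blocks$gene_b != victim, , drop = FALSE]
    tr <- sim$tree
    tr$node.label <- ifelse(is.na(tr$support), "",
                            formatC(tr$support, format = "g"))
    tr <- ape::drop.tip(tr, victim)
    tr$support <- normalize_support(tr$node.label)
    sim$tree <- tr
    sim$leaves <- sim$leaves[sim$leaves$gene_id != victim, , drop = FALSE]
    sim$classes <- sim$classes[sim$classes$gene_id != victim, , drop = FALSE]
    sim$proteins <- sim$proteins[names(sim$proteins) != victim]
    sim$truth$genes <- sim$truth$genes[sim$truth$genes$gene_id != victim, ,
                                       drop = FALSE]
  } else if (op == "shuffle_leaf_order") {
    tr <- sim$tree
    ntip <- ape::Ntip(tr)
    children <- tree_children(tr)
    sup <- sim$tree$support
    frag <- function(nd) {
      if (nd <= ntip) return(sprintf("%s:1", tr$tip.label[nd]))
      kids <- children[[nd]]
      kids <- kids[sample.int(length(kids))]
      lab <- sup[nd - ntip]
      sprintf("(%s)%s:1", paste(vapply(kids, frag, character(1)), collapse = ","),
              ifelse(is.na(lab), "", formatC(lab, format = "g")))
    }
    newick <- paste0(sub(":1$", "", frag(ntip + 1L)), ";")
    tr2 <- ape::read.tree(text = newick)
    tr2$support <- normalize_support(tr2$node.label %||%
                                       rep(NA_character_, tr2$Nnode))
    sim$tree <- tr2
  } else {  # downgrade_support
    nd <- sample.int(sim$tree$Nnode, 1L)
    sim$tree$support[nd] <- 0.1
  }
  sim
}
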
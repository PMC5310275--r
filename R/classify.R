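#' Settings for duplication-type classification
#'
#' @param proximal_window exclusive upper bound on the gene-order distance of
#'   a proximal pair: partners at rank difference `d` with `1 < d <
#'   proximal_window` are proximal. The default 20 encodes "spanning less
#'   than 20 genes in a nearby chromosomal region".
#' @param top_hits number of homology hits retained per query upstream
#'   (BLAST top-k); recorded for provenance, not re-applied here.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(proximal_window = 20L, top_hits = 5L) {
  if (proximal_window < 2) stopf("proximal_window must be >= 2")
  if (top_hits < 1) stopf("top_hits must be >= 1")
  structure(list(proximal_window = as.integer(proximal_window),
                 top_hits = as.integer(top_hits)),
            class = "classifier_config")
}

#' Gene-order ranks within chromosomes
#'
#' Within each (species, chromosome), genes sorted by `start`, then `end`,
#' then `gene_id` receive ranks `0 .. n-1`. Identical coordinates are
#' permitted; the `gene_id` sort makes ranks deterministic. The input should
#' be one representative per locus (see [locus_representatives()]).
#'
#' @param genes gene table.
#' @return data.frame with columns `gene_id`, `species`, `chromosome`, `rank`.
#' @export
assign_ranks <- function(genes) {
  ord <- order(genes$species, genes$chromosome, genes$start, genes$end,
               genes$gene_id)
  g <- genes[ord, , drop = FALSE]
  key <- paste(g$species, g$chromosome, sep = "\r")
  rank <- stats::ave(seq_len(nrow(g)), key, FUN = function(i) seq_along(i) - 1L)
  data.frame(gene_id = g$gene_id, species = g$species,
             chromosome = g$chromosome, rank = as.integer(rank),
             stringsAsFactors = FALSE)
}

#' Classify duplication types
#'
#' Assigns each input gene exactly one label by the strict priority cascade
#' `wgd > tandem > proximal > dispersed > singleton`:
#'
#' * `wgd` — the gene appears in any collinear-block anchor (collinear gene
#'   in a syntenic block);
#' * `tandem` — it has a homology partner on the same chromosome (same
#'   species) at rank difference exactly 1 (consecutive repeat);
#' * `proximal` — a partner on the same chromosome at rank difference
#'   strictly between 1 and `cfg$proximal_window`;
#' * `dispersed` — any homology partner at all;
#' * `singleton` — otherwise.
#'
#' Homology pairs are symmetrized first (top-k BLAST lists are asymmetric;
#' duplication is symmetric). Pass *intra-species* blocks and pairs when
#' reproducing a per-genome classification; the function uses whatever
#' evidence it is given. Labels form a partition of `genes`.
#'
#' @param genes character vector of gene ids to label.
#' @param pairs homology pairs (`query_id`, `subject_id`, ...).
#' @param blocks collinearity anchors in long format (see
#'   [read_collinearity()]).
#' @param ranks rank table from [assign_ranks()], covering every gene in
#'   `genes` and every gene referenced by `pairs`.
#' @param cfg a [classifier_config()].
#' @return data.frame with columns `gene_id`, `label`.
#' @export
classify_duplications <- function(genes, pairs, blocks, ranks,
                                  cfg = classifier_config()) {
  genes <- unique(genes)
  missing_rank <- setdiff(genes, ranks$gene_id)
  if (length(missing_rank) > 0L) {
    stopf("gene(s) without rank assignment: %s",
          paste(utils::head(missing_rank, 5L), collapse = ", "))
  }
  # symmetrize pairs
  pa <- c(pairs$query_id, pairs$subject_id)
  pb <- c(pairs$subject_id, pairs$query_id)
  keep <- !duplicated(paste(pa, pb, sep = "\r"))
  pa <- pa[keep]; pb <- pb[keep]
  pr_missing <- setdiff(unique(c(pa, pb)), ranks$gene_id)
  if (length(pr_missing) > 0L) {
    stopf("homology pair gene(s) absent from ranks: %s",
          paste(utils::head(pr_missing, 5L), collapse = ", "))
  }
  ia <- match(pa, ranks$gene_id)
  ib <- match(pb, ranks$gene_id)
  same_chr <- ranks$species[ia] == ranks$species[ib] &
    ranks$chromosome[ia] == ranks$chromosome[ib]
  dd <- abs(ranks$rank[ia] - ranks$rank[ib])

  anchored <- unique(c(blocks$gene_a, blocks$gene_b))
  has_tandem <- unique(pa[same_chr & dd == 1L])
  has_proximal <- unique(pa[same_chr & dd > 1L & dd < cfg$proximal_window])
  has_partner <- unique(pa)

  label <- rep("singleton", length(genes))
  label[genes %in% has_partner] <- "dispersed"
  label[genes %in% has_proximal] <- "proximal"
  label[genes %in% has_tandem] <- "tandem"
  label[genes %in% anchored] <- "wgd"
  data.frame(gene_id = genes, label = label, stringsAsFactors = FALSE)
}

DUPLICATION_LABELS <- c("wgd", "tandem", "proximal", "dispersed", "singleton")

#' Per-species duplication-type proportions of a gene family
#'
#' @param labels data.frame from [classify_duplications()].
#' @param family character vector of family gene ids (must be labeled).
#' @param genes gene table supplying species membership.
#' @param species optional character vector of species expected to have
#'   family genes; species with none are omitted with a warning.
#' @return data.frame with columns `species`, `label`, `n`, `proportion`;
#'   proportions sum to 1 within each species.
#' @export
duplication_summary <- function(labels, family, genes, species = NULL) {
  family <- unique(family)
  unl <- setdiff(family, labels$gene_id)
  if (length(unl) > 0L) {
    stopf("family gene(s) without labels: %s",
          paste(utils::head(unl, 5L), collapse = ", "))
  }
  sp <- genes$species[match(family, genes$gene_id)]
  lab <- labels$label[match(family, labels$gene_id)]
  if (!is.null(species)) {
    empty <- setdiff(species, sp)
    if (length(empty) > 0L) {
      warnf("species with no family genes omitted: %s",
            paste(empty, collapse = ", "))
    }
  }
  tab <- table(factor(sp), factor(lab, levels = DUPLICATION_LABELS))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("species", "label", "n")
  tot <- stats::ave(out$n, out$species, FUN = sum)
  out$proportion <- ifelse(tot > 0, out$n / tot, NA_real_)
  out <- out[tot > 0, , drop = FALSE]
  out[order(out$species, match(out$label, DUPLICATION_LABELS)), ,
      drop = FALSE]
}
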
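#' Detection settings for domain-based family membership
#'
#' The detection rule keeps a protein when at least one of its domain hits to
#' the family profile simultaneously passes the E-value gate and the
#' profile-coverage gate. Defaults encode the LOB-domain (PFAM DUF260) setup:
#' per-domain E-value at most 1e-5 (the operational reading of the profile's
#' gathering threshold) and at least 80% of the profile columns matched.
#' Coverage is measured in profile (HMM) coordinates because the 80% rule
#' refers to the domain model, not the target sequence.
#'
#' @param max_evalue maximum per-domain E-value (> 0).
#' @param min_coverage minimum fraction of profile columns covered, in (0, 1].
#' @param profile_name profile the family is defined by.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(max_evalue = 1e-5, min_coverage = 0.80,
                             profile_name = "DUF260") {
  if (!is.numeric(max_evalue) || max_evalue <= 0) {
    stopf("max_evalue must be > 0")
  }
  if (!is.numeric(min_coverage) || min_coverage <= 0 || min_coverage > 1) {
    stopf("min_coverage must be in (0, 1]")
  }
  structure(list(max_evalue = max_evalue, min_coverage = min_coverage,
                 profile_name = profile_name), class = "detection_config")
}

#' Fraction of the profile covered by a domain hit
#'
#' `(hmm_to - hmm_from + 1) / profile_length`, vectorized over a hit table.
#'
#' @param hits domain-hit data.frame (see [read_domain_table()]).
#' @return numeric vector of coverage fractions in (0, 1].
#' @export
domain_coverage <- function(hits) {
  (hits$hmm_to - hits$hmm_from + 1) / hits$profile_length
}

#' Filter domain hits to candidate family proteins
#'
#' A protein is retained iff it has at least one hit to `cfg$profile_name`
#' whose E-value is `<= cfg$max_evalue` AND whose profile coverage is
#' `>= cfg$min_coverage` — both gates on the same hit; boundary values pass.
#'
#' @param hits domain-hit data.frame; may carry several hits per protein and
#'   hits to unrelated profiles.
#' @param cfg a [detection_config()].
#' @return character vector of retained protein ids (sorted, unique).
#' @export
filter_candidates <- function(hits, cfg = detection_config()) {
  if (nrow(hits) == 0L) return(character(0))
  ok <- hits$profile_name == cfg$profile_name &
    hits$evalue <= cfg$max_evalue &
    domain_coverage(hits) >= cfg$min_coverage
  sort(unique(hits$protein_id[ok]))
}

#' Collapse alternatively spliced isoforms to one representative per locus
#'
#' Among member proteins, exactly one representative is kept per `locus_id`:
#' the longest protein, ties broken by the lexicographically smallest
#' `gene_id`. Protein ids are matched against `gene_id` in the gene table
#' (gene models are isoform-level).
#'
#' @param members character vector of member protein/gene ids.
#' @param genes gene table (see [read_gene_table()]).
#' @return character vector of representative gene ids (sorted).
#' @export
collapse_isoforms <- function(members, genes) {
  members <- unique(members)
  if (length(members) == 0L) return(character(0))
  idx <- match(members, genes$gene_id)
  if (anyNA(idx)) {
    stopf("member protein(s) without a gene-table entry: %s",
          paste(members[is.na(idx)], collapse = ", "))
  }
  g <- genes[idx, , drop = FALSE]
  ord <- order(g$locus_id, -g$protein_length, g$gene_id)
  g <- g[ord, , drop = FALSE]
  sort(g$gene_id[!duplicated(g$locus_id)])
}

#' Detect family members from domain hits
#'
#' Runs [filter_candidates()] then [collapse_isoforms()] and reports, per
#' representative gene, the species and the best passing hit (smallest
#' E-value among hits passing both gates; coverage from that hit).
#'
#' @inheritParams filter_candidates
#' @inheritParams collapse_isoforms
#' @return data.frame with columns `gene_id`, `species`, `coverage`, `evalue`.
#' @export
detect_family <- function(hits, genes, cfg = detection_config()) {
  cand <- filter_candidates(hits, cfg)
  reps <- collapse_isoforms(cand, genes)
  if (length(reps) == 0L) {
    return(data.frame(gene_id = character(), species = character(),
                      coverage = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  pass <- hits[hits$protein_id %in% reps &
                 hits$profile_name == cfg$profile_name &
                 hits$evalue <= cfg$max_evalue &
                 domain_coverage(hits) >= cfg$min_coverage, , drop = FALSE]
  pass <- pass[order(pass$protein_id, pass$evalue, -domain_coverage(pass)), ,
               drop = FALSE]
  best <- pass[!duplicated(pass$protein_id), , drop = FALSE]
  i <- match(reps, best$protein_id)
  data.frame(
    gene_id = reps,
    species = genes$species[match(reps, genes$gene_id)],
    coverage = domain_coverage(best)[i],
    evalue = best$evalue[i],
    stringsAsFactors = FALSE)
}

#' One representative gene model per locus
#'
#' Applies the isoform-collapse rule (longest protein, then smallest
#' `gene_id`) to a whole gene table, returning the rows of the chosen
#' representatives. Gene ranks for duplication classification are computed on
#' this reduced table.
#'
#' @param genes gene table.
#' @return gene table subset, one row per locus.
#' @export
locus_representatives <- function(genes) {
  ord <- order(genes$species, genes$locus_id, -genes$protein_length,
               genes$gene_id)
  g <- genes[ord, , drop = FALSE]
  keep <- !duplicated(paste(g$species, g$locus_id, sep = "\r"))
  out <- g[keep, , drop = FALSE]
  out[order(out$gene_id), , drop = FALSE]
}
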
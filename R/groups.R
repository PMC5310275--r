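#' Family-internal collinear pairs
#'
#' Extracts block anchors whose both genes belong to the family and
#' deduplicates them as unordered pairs (the same pair reported by several
#' blocks counts once). Self anchors are dropped.
#'
#' @param blocks collinearity anchors in long format.
#' @param family character vector of family gene ids.
#' @return data.frame with columns `gene_a`, `gene_b` (`gene_a < gene_b`).
#' @export
family_pairs <- function(blocks, family) {
  keep <- blocks$gene_a %in% family & blocks$gene_b %in% family
  p <- canonical_pairs(blocks$gene_a[keep], blocks$gene_b[keep])
  data.frame(gene_a = p$a, gene_b = p$b, stringsAsFactors = FALSE)
}

#' Recursively merge collinear pairs into collinear groups
#'
#' Family genes linked by collinear anchor pairs are merged transitively: the
#' groups are the connected components of the pair graph (the closure of
#' "iterative clustering" of collinear genes). Singleton vertices never
#' arise (every input gene sits in a pair), so every group has at least two
#' members. Group ids are assigned deterministically by sorting components on
#' their smallest member id. Dicot and monocot pair sets are merged in
#' separate calls; a pair spanning two scopes signals mis-scoped input and is
#' an error.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (order within a
#'   pair and order of pairs are irrelevant).
#' @param scope_map optional named character vector gene -> clade scope used
#'   to reject pairs spanning scopes.
#' @param species_map optional named character vector gene -> species code.
#' @return data.frame with columns `group_id`, `gene_id` and, when maps are
#'   given, `species` and `clade_scope`; zero pairs yield zero rows.
#' @export
merge_groups <- function(pairs, scope_map = NULL, species_map = NULL) {
  empty <- data.frame(group_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  if (!is.null(scope_map)) {
    sa <- unname(scope_map[pairs$gene_a])
    sb <- unname(scope_map[pairs$gene_b])
    bad <- which(!is.na(sa) & !is.na(sb) & sa != sb)
    if (length(bad) > 0L) {
      stopf("collinear pair spans clade scopes (%s [%s] - %s [%s])",
            pairs$gene_a[bad[1L]], sa[bad[1L]],
            pairs$gene_b[bad[1L]], sb[bad[1L]])
    }
  }
  ids <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  # union-find with path compression
  parent <- seq_along(ids)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  ia <- match(pairs$gene_a, ids)
  ib <- match(pairs$gene_b, ids)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  # deterministic ids: components ordered by smallest member id
  root_order <- sort(unique(comp))  # ids are sorted, so root index order = smallest-member order
  gid <- sprintf("G%03d", match(comp, root_order))
  out <- data.frame(group_id = gid, gene_id = ids, stringsAsFactors = FALSE)
  out <- out[order(out$group_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(species_map)) out$species <- unname(species_map[out$gene_id])
  if (!is.null(scope_map)) out$clade_scope <- unname(scope_map[out$gene_id])
  out
}

#' Build collinear groups for one clade scope
#'
#' Convenience wrapper: restricts the family to species of the requested
#' scope, extracts family-internal anchor pairs (inter- and intra-species
#' blocks both participate) and merges them.
#'
#' @param blocks collinearity anchors in long format.
#' @param family character vector of family gene ids.
#' @param genes gene table.
#' @param species_config species configuration (see [species_panel()]).
#' @param scope clade scope, e.g. `"dicot"` or `"monocot"`.
#' @return group table as from [merge_groups()].
#' @export
collinear_groups <- function(blocks, family, genes, species_config,
                             scope = c("dicot", "monocot", "other")) {
  scope <- match.arg(scope)
  species_config <- validate_species_config(species_config)
  in_scope <- species_config$code[species_config$clade_scope == scope]
  sp <- stats::setNames(genes$species, genes$gene_id)
  fam_scope <- family[sp[family] %in% in_scope]
  pairs <- family_pairs(blocks, fam_scope)
  scope_map <- stats::setNames(
    species_config$clade_scope[match(sp, species_config$code)], names(sp))
  merge_groups(pairs, scope_map = scope_map, species_map = sp)
}
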
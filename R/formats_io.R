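#' Read and validate a gene-position table
#'
#' The gene table is a tab-separated file with a header row and one row per
#' gene model (isoform-level), carrying the seven locus fields plus the
#' species code: `species`, `gene_id`, `chromosome`, `start`, `end`, `strand`,
#' `locus_id`, `protein_length`. Coordinates are 1-based inclusive base
#' positions (GFF convention); gene order ("rank") is derived from
#' coordinates, never stored. Alternative isoforms of one locus share
#' `locus_id` and `species`.
#'
#' @param path path to a TSV file.
#' @return data.frame with one validated row per gene model.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv(path)
  validate_gene_table(df, source = path)
}

GENE_TABLE_COLS <- c("species", "gene_id", "chromosome", "start", "end",
                     "strand", "locus_id", "protein_length")

#' @rdname read_gene_table
#' @param genes data.frame shaped like the gene table.
#' @param source label used in error messages.
#' @export
validate_gene_table <- function(genes, source = "gene table") {
  check_columns(genes, GENE_TABLE_COLS, source)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$protein_length <- as.numeric(genes$protein_length)
  line <- seq_len(nrow(genes)) + 1L  # header is line 1
  bad <- which(is.na(genes$start) | is.na(genes$end) |
                 is.na(genes$protein_length) | !nzchar(genes$gene_id))
  if (length(bad) > 0L) {
    stopf("%s: malformed row at line %d", source, line[bad[1L]])
  }
  bad <- which(genes$start > genes$end)
  if (length(bad) > 0L) {
    stopf("%s: start > end at line %d (gene %s)", source, line[bad[1L]],
          genes$gene_id[bad[1L]])
  }
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stopf("%s: invalid strand '%s' at line %d", source,
          genes$strand[bad[1L]], line[bad[1L]])
  }
  bad <- which(genes$protein_length <= 0)
  if (length(bad) > 0L) {
    stopf("%s: non-positive protein_length at line %d", source, line[bad[1L]])
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0L) {
    stopf("%s: duplicated gene_id(s): %s", source,
          paste(unique(dup), collapse = ", "))
  }
  genes
}

#' @rdname read_gene_table
#' @export
write_gene_table <- function(genes, path) {
  write_tsv(genes[GENE_TABLE_COLS], path)
}

#' Read a profile-HMM per-domain hit table
#'
#' A tab-separated projection of HMMER per-domain output with a header row and
#' the six hit fields: `protein_id`, `profile_name`, `profile_length`,
#' `hmm_from`, `hmm_to`, `evalue`, `score`. `hmm_from`/`hmm_to` are 1-based
#' inclusive profile-column coordinates; `evalue` is the per-domain
#' (independent) E-value. Native HMMER `--domtblout` files are not parsed
#' verbatim: project columns target name, query name, qlen, hmm from, hmm to,
#' i-Evalue and score into this layout first. Hits are returned unsorted and
#' unfiltered; see [filter_candidates()] for the detection gates.
#'
#' @param path path to a TSV file.
#' @return data.frame of validated hits (possibly zero rows).
#' @export
read_domain_table <- function(path) {
  df <- read_tsv(path)
  validate_domain_table(df, source = path)
}

DOMAIN_TABLE_COLS <- c("protein_id", "profile_name", "profile_length",
                       "hmm_from", "hmm_to", "evalue", "score")

#' @rdname read_domain_table
#' @param hits data.frame shaped like the domain table.
#' @param source label used in error messages.
#' @export
validate_domain_table <- function(hits, source = "domain table") {
  check_columns(hits, DOMAIN_TABLE_COLS, source)
  for (col in c("profile_length", "hmm_from", "hmm_to", "evalue", "score")) {
    hits[[col]] <- as.numeric(hits[[col]])
  }
  if (nrow(hits) == 0L) return(hits)
  line <- seq_len(nrow(hits)) + 1L
  bad <- which(is.na(hits$hmm_from) | is.na(hits$hmm_to) |
                 is.na(hits$profile_length) | is.na(hits$evalue))
  if (length(bad) > 0L) stopf("%s: malformed row at line %d", source, line[bad[1L]])
  bad <- which(hits$evalue < 0)
  if (length(bad) > 0L) {
    stopf("%s: negative E-value at line %d", source, line[bad[1L]])
  }
  bad <- which(hits$hmm_from < 1 | hits$hmm_from > hits$hmm_to |
                 hits$hmm_to > hits$profile_length)
  if (length(bad) > 0L) {
    stopf("%s: profile coordinates violate 1 <= hmm_from <= hmm_to <= profile_length at line %d",
          source, line[bad[1L]])
  }
  hits
}

#' @rdname read_domain_table
#' @export
write_domain_table <- function(hits, path) {
  write_tsv(hits[DOMAIN_TABLE_COLS], path)
}

#' Read a homology-pair table
#'
#' Tab-separated with header columns `query_id`, `subject_id`, `evalue`
#' (BLAST-style gene pairs, typically truncated to the top hits per query).
#' Self pairs are rejected.
#'
#' @param path path to a TSV file.
#' @return data.frame of pairs.
#' @export
read_pair_table <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("query_id", "subject_id", "evalue"), path)
  df$evalue <- as.numeric(df$evalue)
  if (nrow(df) > 0L && any(bad <- df$query_id == df$subject_id)) {
    stopf("%s: self pair at line %d", path, which(bad)[1L] + 1L)
  }
  if (nrow(df) > 0L && any(bad <- !is.na(df$evalue) & df$evalue < 0)) {
    stopf("%s: negative E-value at line %d", path, which(bad)[1L] + 1L)
  }
  df
}

#' @rdname read_pair_table
#' @param pairs data.frame of pairs.
#' @export
write_pair_table <- function(pairs, path) {
  write_tsv(pairs[c("query_id", "subject_id", "evalue")], path)
}

#' Read an MCScanX-style collinearity file
#'
#' Parses the ".collinearity" dialect: lines starting `## Alignment N:` open a
#' block; the header tail may carry `score=` and a `spA&spB` species token;
#' each following anchor line has the form `N-i: geneA geneB evalue`
#' (whitespace separated, the leading `N-i:` index is ignored). Other `#`
#' lines are comments. An anchor line before any block header is an error.
#'
#' @param path path to a collinearity file.
#' @param genes optional gene table; when supplied, every anchor gene must
#'   occur in it and block species are cross-checked against it.
#' @return data.frame in long "anchor" layout with columns `block_id`,
#'   `species_a`, `species_b`, `gene_a`, `gene_b`, `evalue`, `score`; one row
#'   per anchor, anchors in file order. Zero blocks yield zero rows.
#' @export
read_collinearity <- function(path, genes = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  out <- list()
  block_id <- NA_character_
  species_a <- species_b <- NA_character_
  score <- NA_real_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*$", ln)) next
    m <- regmatches(ln, regexec("^##\\s*Alignment\\s+(\\S+?):(.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      block_id <- m[2L]
      tail <- m[3L]
      score <- NA_real_
      sm <- regmatches(tail, regexec("score=([0-9.eE+-]+)", tail))[[1L]]
      if (length(sm) == 2L) score <- as.numeric(sm[2L])
      species_a <- species_b <- NA_character_
      pm <- regmatches(tail, regexec("(\\S+)&(\\S+)", tail))[[1L]]
      if (length(pm) == 3L) {
        species_a <- pm[2L]
        species_b <- pm[3L]
      }
      next
    }
    if (grepl("^#", ln)) next
    # anchor line
    body <- sub("^\\s*[0-9]+-\\s*[0-9]+:\\s*", "", ln)
    if (identical(body, ln)) {
      # tolerate plain "geneA geneB [evalue]" anchor lines
      body <- trimws(ln)
    }
    if (is.na(block_id)) {
      stopf("%s: anchor line outside any '## Alignment' block at line %d",
            path, i)
    }
    parts <- strsplit(trimws(body), "\\s+")[[1L]]
    if (length(parts) < 2L) stopf("%s: malformed anchor line %d", path, i)
    out[[length(out) + 1L]] <- data.frame(
      block_id = block_id, species_a = species_a, species_b = species_b,
      gene_a = parts[1L], gene_b = parts[2L],
      evalue = if (length(parts) >= 3L) suppressWarnings(as.numeric(parts[3L])) else NA_real_,
      score = score, stringsAsFactors = FALSE)
  }
  blocks <- if (length(out) == 0L) {
    data.frame(block_id = character(), species_a = character(),
               species_b = character(), gene_a = character(),
               gene_b = character(), evalue = numeric(), score = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  if (!is.null(genes)) {
    ids <- unique(c(blocks$gene_a, blocks$gene_b))
    unknown <- setdiff(ids, genes$gene_id)
    if (length(unknown) > 0L) {
      stopf("%s: anchor gene(s) absent from the gene table: %s", path,
            paste(utils::head(unknown, 5L), collapse = ", "))
    }
    sp <- stats::setNames(genes$species, genes$gene_id)
    blocks$species_a <- unname(sp[blocks$gene_a])
    blocks$species_b <- unname(sp[blocks$gene_b])
  }
  blocks
}

#' @rdname read_collinearity
#' @param blocks long-format anchor data.frame as returned by
#'   `read_collinearity()`.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("############### collinear blocks ###############", con)
  if (nrow(blocks) > 0L) {
    for (bid in unique(blocks$block_id)) {
      b <- blocks[blocks$block_id == bid, , drop = FALSE]
      sp <- if (!is.na(b$species_a[1L]) && !is.na(b$species_b[1L])) {
        sprintf(" %s&%s", b$species_a[1L], b$species_b[1L])
      } else ""
      sc <- if (!is.na(b$score[1L])) sprintf(" score=%g", b$score[1L]) else ""
      writeLines(sprintf("## Alignment %s:%s N=%d%s plus", bid, sc, nrow(b), sp), con)
      ev <- ifelse(is.na(b$evalue), "0", format(b$evalue, scientific = TRUE))
      writeLines(sprintf("%s-%3d:\t%s\t%s\t%s", bid, seq_len(nrow(b)) - 1L,
                         b$gene_a, b$gene_b, ev), con)
    }
  }
  invisible(path)
}

#' Normalize branch-support values
#'
#' Supports on gene trees occur both as fractions in `[0, 1]` and as
#' percentages in `(1, 100]` (e.g. SH-aLRT printed as "95"). Values in
#' `(1, 100]` are divided by 100; values already in `[0, 1]` are kept;
#' anything outside `[0, 100]` is an error. Missing supports stay `NA` (never
#' coerced to zero). The transformation is idempotent.
#'
#' @param x numeric or character vector of raw support labels.
#' @return numeric vector of supports in `[0, 1]`, `NA` where absent.
#' @export
normalize_support <- function(x) {
  if (is.null(x)) return(numeric(0))
  x <- as.character(x)
  x[!nzchar(trimws(x))] <- NA_character_
  v <- suppressWarnings(as.numeric(x))
  if (any(!is.na(x) & is.na(v))) {
    stopf("non-numeric support label(s): %s",
          paste(utils::head(x[!is.na(x) & is.na(v)], 3L), collapse = ", "))
  }
  if (any(v < 0 | v > 100, na.rm = TRUE)) {
    stopf("support value(s) outside [0, 100]: %s",
          paste(utils::head(v[!is.na(v) & (v < 0 | v > 100)], 3L), collapse = ", "))
  }
  ifelse(!is.na(v) & v > 1, v / 100, v)
}

#' Read a Newick gene tree with support labels
#'
#' Internal node labels, when present, are interpreted as numeric branch
#' supports and normalized to `[0, 1]` via [normalize_support()]. The tree is
#' returned as an [ape::read.tree()] `phylo` object with an extra `support`
#' component (numeric, one value per internal node in node order, `NA` where
#' the label is absent).
#'
#' @param path path to a Newick file.
#' @return a `phylo` object with a `support` component.
#' @export
read_newick_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stopf("failed to parse Newick in %s: %s",
                                           path, conditionMessage(e)))
  if (is.null(tr)) stopf("failed to parse Newick in %s", path)
  tr$support <- normalize_support(tr$node.label %||% rep(NA_character_, tr$Nnode))
  if (length(tr$support) == 0L) tr$support <- rep(NA_real_, tr$Nnode)
  tr
}

#' @rdname read_newick_tree
#' @param tree `phylo` object, optionally with a `support` component.
#' @param digits decimal places used when serializing supports.
#' @export
write_newick_tree <- function(tree, path, digits = 6L) {
  if (!is.null(tree$support)) {
    lab <- ifelse(is.na(tree$support), "",
                  formatC(tree$support, digits = digits, format = "g"))
    tree$node.label <- lab
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
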
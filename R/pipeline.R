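#' Assemble a pipeline run configuration
#'
#' A run configuration names the input files and every stage parameter.
#' `read_run_config()` loads one from a YAML file; `run_config()` builds one
#' in code. Missing parameters take the package defaults.
#'
#' @param genes,hits,pairs,blocks,tree,classes,species input file paths
#'   (dialects as documented in the respective readers).
#' @param out_dir directory for stage outputs and the run manifest.
#' @param max_evalue,min_coverage,profile_name detection gates
#'   (see [detection_config()]).
#' @param proximal_window,top_hits classifier settings
#'   (see [classifier_config()]).
#' @param min_support,dicot_min,monocot_min ancestry-inference settings
#'   (see [find_angiosperm_ancestors()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(genes, hits, pairs, blocks, tree, classes, species,
                       out_dir, max_evalue = 1e-5, min_coverage = 0.80,
                       profile_name = "DUF260", proximal_window = 20L,
                       top_hits = 5L, min_support = NULL, dicot_min = NULL,
                       monocot_min = NULL) {
  structure(list(genes = genes, hits = hits, pairs = pairs, blocks = blocks,
                 tree = tree, classes = classes, species = species,
                 out_dir = out_dir, max_evalue = max_evalue,
                 min_coverage = min_coverage, profile_name = profile_name,
                 proximal_window = proximal_window, top_hits = top_hits,
                 min_support = min_support, dicot_min = dicot_min,
                 monocot_min = monocot_min),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys mirror the `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("run config not found: %s", path)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full analysis on in-memory tables
#'
#' Executes detect -> classify -> groups (per clade scope) -> ancestry ->
#' report on already-loaded inputs. Classification is per-genome: only
#' intra-species homology pairs and intra-species blocks feed the
#' duplication cascade, while collinear-group merging uses all blocks.
#' An unrooted tree is midpoint-rooted first.
#'
#' @param genes gene table; @param hits domain-hit table;
#' @param pairs homology pairs; @param blocks collinearity anchors;
#' @param tree `phylo` gene tree; @param classes gene -> class data.frame;
#' @param species_config species configuration.
#' @param detection a [detection_config()].
#' @param classifier a [classifier_config()].
#' @param min_support,dicot_min,monocot_min ancestry settings.
#' @return list with `members`, `labels`, `summary`, `groups` (dicot and
#'   monocot tables), `clusters` (three `lineage_clusters`), `report`.
#' @export
analyze_dataset <- function(genes, hits, pairs, blocks, tree, classes,
                            species_config = species_panel(),
                            detection = detection_config(),
                            classifier = classifier_config(),
                            min_support = NULL, dicot_min = NULL,
                            monocot_min = NULL) {
  species_config <- validate_species_config(species_config)
  members <- with_stage("detect", detect_family(hits, genes, detection))
  reps <- locus_representatives(genes)
  ranks <- assign_ranks(reps)
  sp_map <- stats::setNames(genes$species, genes$gene_id)
  intra_pairs <- pairs[sp_map[pairs$query_id] == sp_map[pairs$subject_id], ,
                       drop = FALSE]
  bsa <- blocks$species_a
  bsb <- blocks$species_b
  if (nrow(blocks) > 0L && (anyNA(bsa) || anyNA(bsb))) {
    bsa <- sp_map[blocks$gene_a]
    bsb <- sp_map[blocks$gene_b]
  }
  intra_blocks <- blocks[!is.na(bsa) & !is.na(bsb) & bsa == bsb, ,
                         drop = FALSE]
  labels <- with_stage("classify",
    classify_duplications(reps$gene_id, intra_pairs, intra_blocks, ranks,
                          classifier))
  dup_summary <- duplication_summary(labels, members$gene_id, genes)
  groups <- with_stage("groups", list(
    dicot = collinear_groups(blocks, members$gene_id, genes, species_config,
                             "dicot"),
    monocot = collinear_groups(blocks, members$gene_id, genes, species_config,
                               "monocot")))
  res <- with_stage("ancestry", {
    if (!ape::is.rooted(tree)) tree <- root_tree(tree, "midpoint")
    atree <- annotated_gene_tree(tree, species = sp_map,
                                 species_config = species_config,
                                 classes = classes)
    ancient <- find_ancient_lineages(atree, min_support = min_support)
    seed <- find_seed_ancestors(atree, min_support = min_support)
    angio <- find_angiosperm_ancestors(atree, min_support = min_support,
                                       dicot_min = dicot_min,
                                       monocot_min = monocot_min)
    angio <- collinearity_support(angio, groups$dicot, groups$monocot,
                                  sp_map, species_config)
    list(ancient = ancient, seed = seed, angiosperm = angio)
  })
  report <- with_stage("report",
    ancestry_report(res$ancient, res$seed, res$angiosperm))
  list(members = members, labels = labels, summary = dup_summary,
       groups = groups, clusters = res, report = report)
}

#' Run the pipeline end to end from files
#'
#' Reads every input named in the configuration, runs [analyze_dataset()],
#' writes the stage outputs (`members.tsv`, `labels.tsv`,
#' `duplication_summary.tsv`, `groups_dicot.tsv`, `groups_monocot.tsv`,
#' `clusters.tsv`, `lineage_paths.tsv`, `summary_counts.tsv`) into
#' `out_dir`, and records a YAML run manifest (`manifest.yaml`) with the
#' package version, all parameters, input and output MD5 checksums and
#' per-stage record counts. A failing stage aborts with the stage named.
#' Identical configuration and inputs reproduce identical outputs byte for
#' byte.
#'
#' @param config a [run_config()] or the path to a YAML run config.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  read_in <- function(stage, field, reader) {
    with_stage(stage, {
      p <- config[[field]]
      if (is.null(p) || !file.exists(p)) {
        stopf("input '%s' not found at %s", field, p %||% "<unset>")
      }
      reader(p)
    })
  }
  species_config <- with_stage("config", {
    validate_species_config(read_tsv(config$species))
  })
  genes <- read_in("detect", "genes", read_gene_table)
  hits <- read_in("detect", "hits", read_domain_table)
  pairs <- read_in("classify", "pairs", read_pair_table)
  blocks <- read_in("classify", "blocks",
                    function(p) read_collinearity(p, genes = genes))
  tree <- read_in("ancestry", "tree", read_newick_tree)
  classes <- read_in("ancestry", "classes", read_tsv)

  res <- analyze_dataset(
    genes, hits, pairs, blocks, tree, classes, species_config,
    detection = detection_config(config$max_evalue, config$min_coverage,
                                 config$profile_name),
    classifier = classifier_config(config$proximal_window, config$top_hits),
    min_support = config$min_support, dicot_min = config$dicot_min,
    monocot_min = config$monocot_min)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- c(members = "members.tsv", labels = "labels.tsv",
               summary = "duplication_summary.tsv",
               groups_dicot = "groups_dicot.tsv",
               groups_monocot = "groups_monocot.tsv",
               clusters = "clusters.tsv", paths = "lineage_paths.tsv",
               counts = "summary_counts.tsv")
  outputs <- stats::setNames(file.path(out, outputs), names(outputs))
  write_tsv(res$members, outputs[["members"]])
  write_tsv(res$labels, outputs[["labels"]])
  write_tsv(res$summary, outputs[["summary"]])
  write_tsv(res$groups$dicot, outputs[["groups_dicot"]])
  write_tsv(res$groups$monocot, outputs[["groups_monocot"]])
  write_tsv(rbind(clusters_table(res$clusters$ancient),
                  clusters_table(res$clusters$seed),
                  clusters_table(res$clusters$angiosperm)),
            outputs[["clusters"]])
  write_tsv(res$report$paths, outputs[["paths"]])
  write_tsv(res$report$counts, outputs[["counts"]])

  manifest <- list(
    package = "lbdtrace",
    version = as.character(utils::packageVersion("lbdtrace")),
    parameters = config[setdiff(names(config), "out_dir")],
    inputs = lapply(config[c("genes", "hits", "pairs", "blocks", "tree",
                             "classes", "species")], function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stage_counts = list(
      detected_members = nrow(res$members),
      labels = as.list(table(factor(res$labels$label,
                                    levels = DUPLICATION_LABELS))),
      dicot_groups = length(unique(res$groups$dicot$group_id)),
      monocot_groups = length(unique(res$groups$monocot$group_id)),
      depth_counts = as.list(res$report$depth_counts)),
    outputs = lapply(as.list(outputs), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  message(sprintf(
    "pipeline complete: %d members; groups %d dicot / %d monocot; lineages %d/%d/%d",
    nrow(res$members), manifest$stage_counts$dicot_groups,
    manifest$stage_counts$monocot_groups,
    res$report$depth_counts[["ancient"]], res$report$depth_counts[["seed"]],
    res$report$depth_counts[["angiosperm"]]))
  invisible(manifest)
}
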
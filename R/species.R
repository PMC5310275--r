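#' Species configuration tables
#'
#' A species configuration maps each species code to a major land-plant group.
#' The groups drive every depth-specific inference: bryophytes and lycophytes
#' are the basal (pre-seed-plant) witnesses, gymnosperms plus angiosperms are
#' the seed plants, and dicots/monocots are the two angiosperm clades whose
#' collinear groups are built separately.
#'
#' `species_panel()` returns the default eleven-species panel spanning a
#' bryophyte (Ppa), a lycophyte (Smo), a gymnosperm (Pab), five dicots
#' (Aco, Ath, Egr, Ptr, Vvi) and three monocots (Osa, Sbi, Zma), mirroring a
#' typical land-plant comparative design.
#'
#' @param species data.frame with columns `code` and `group`.
#' @return `species_panel()`: a data.frame with columns `code`, `group` and
#'   `clade_scope` (`dicot`, `monocot` or `other`).
#' @export
species_panel <- function() {
  df <- data.frame(
    code = c("Ppa", "Smo", "Pab",
             "Aco", "Ath", "Egr", "Ptr", "Vvi",
             "Osa", "Sbi", "Zma"),
    group = c("bryophyte", "lycophyte", "gymnosperm",
              rep("dicot", 5L), rep("monocot", 3L)),
    stringsAsFactors = FALSE
  )
  validate_species_config(df)
}

SPECIES_GROUPS <- c("bryophyte", "lycophyte", "gymnosperm", "dicot", "monocot")

#' @rdname species_panel
#' @export
validate_species_config <- function(species) {
  check_columns(species, c("code", "group"), "species config")
  if (anyDuplicated(species$code)) {
    stopf("duplicated species code(s): %s",
          paste(unique(species$code[duplicated(species$code)]), collapse = ", "))
  }
  bad <- setdiff(unique(species$group), SPECIES_GROUPS)
  if (length(bad) > 0L) {
    stopf("unknown species group(s): %s (expected one of %s)",
          paste(bad, collapse = ", "), paste(SPECIES_GROUPS, collapse = ", "))
  }
  species$clade_scope <- ifelse(species$group %in% c("dicot", "monocot"),
                                species$group, "other")
  species
}

species_in_groups <- function(species, groups) {
  species$code[species$group %in% groups]
}
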
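## Packaged machine-readable transcription of a published survey table
## assigning each Tetrahymena Rab to its primary localization category.

.LOCALIZATION_CATEGORIES <- c(
  "Parasomal sacs", "Endocytic vesicles", "Posterior (recycling?) endosomes",
  "Lysosomes/phagosomes", "Oral apparatus", "All phagosomes",
  "Selected phagosomes", "Cytoproct-localized phagosomes", "Cytoproct region",
  "Contractile vacuole Rabs", "ER-to-Golgi", "Golgi",
  "Dense core granule docking", "Basal bodies", "Cortical cytoskeleton",
  "Plasma membrane vicinity", "Nuclear envelope", "Indeterminate structures",
  "Not cloned")

.LOCALIZATION_MD5 <- "9b0ceb592fcc9920e175c07a9d041763"

#' Load the packaged Rab localization table
#'
#' Returns the verbatim transcription of the published primary-localization
#' survey: one row per (Rab, category) listing, so a Rab appearing under
#' two categories (TtRabD17: oral apparatus and selected phagosomes) has
#' two rows. \code{conserved} marks sequence-conserved Rabs;
#' \code{cloned = FALSE} marks Rabs that were predicted but never cloned.
#' The fixture is checksum-pinned; a corrupt or edited copy raises an
#' error.
#'
#' @return data.frame with columns rab, category, conserved, cloned.
#' @examples
#' tab <- loadPaperTable()
#' subset(tab, category == "Contractile vacuole Rabs")$rab
#' @export
loadPaperTable <- function() {
  path <- system.file("extdata", "ttrab_localization.tsv", package = "RabKit",
                      mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), .LOCALIZATION_MD5))
    stop("localization fixture is corrupt (checksum mismatch)")
  tab <- read.delim(path, colClasses = c("character", "character",
                                         "logical", "logical"))
  bad <- setdiff(tab$category, .LOCALIZATION_CATEGORIES)
  if (length(bad)) stop("fixture category outside the closed set: ",
                        paste(bad, collapse = ", "))
  tab
}

#' The closed set of primary localization categories
#'
#' @return character(19) of category names.
#' @export
localizationCategories <- function() .LOCALIZATION_CATEGORIES

#' Standard pathway groupings of the localization categories
#'
#' Convenience groupings used for the published pathway-level counts:
#' endocytic (FM4-64-positive compartments), phagosomal, oral apparatus,
#' Golgi, and contractile vacuole.
#'
#' @return named list of category vectors.
#' @export
localizationCategoryGroups <- function() {
  list(
    endocytic = c("Parasomal sacs", "Endocytic vesicles",
                  "Posterior (recycling?) endosomes"),
    phagosomal = c("All phagosomes", "Selected phagosomes",
                   "Cytoproct-localized phagosomes", "Lysosomes/phagosomes"),
    oral_apparatus = "Oral apparatus",
    golgi = "Golgi",
    contractile_vacuole = "Contractile vacuole Rabs"
  )
}

#' Summarize localization records into family-level counts
#'
#' Counts are over distinct Rabs: a Rab listed under two member categories
#' of a group is counted once in that group. The conserved percentage is
#' rounded to the nearest integer.
#'
#' @param records data.frame as returned by \code{\link{loadPaperTable}}.
#' @param categoryGroups named list of category vectors (default
#'   \code{\link{localizationCategoryGroups}()}).
#' @return list with \code{total_distinct}, \code{per_category} (named
#'   integer, rows per category), \code{group_counts} (named integer,
#'   deduplicated within group), \code{conserved_count}, and
#'   \code{conserved_percent}.
#' @export
summarizeLocalization <- function(records,
                                  categoryGroups = localizationCategoryGroups()) {
  if (!nrow(records)) stop("empty records")
  for (g in names(categoryGroups)) {
    bad <- setdiff(categoryGroups[[g]], .LOCALIZATION_CATEGORIES)
    if (length(bad))
      stop("unknown category in group '", g, "': ", paste(bad, collapse = ", "))
  }
  distinct <- unique(records$rab)
  perCat <- table(factor(records$category, levels = .LOCALIZATION_CATEGORIES))
  groupCounts <- vapply(categoryGroups, function(cats)
    length(unique(records$rab[records$category %in% cats])), 0L)
  conservedIds <- unique(records$rab[records$conserved])
  list(
    total_distinct = length(distinct),
    per_category = setNames(as.integer(perCat), names(perCat)),
    group_counts = groupCounts,
    conserved_count = length(conservedIds),
    conserved_percent = round(100 * length(conservedIds) / length(distinct))
  )
}
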
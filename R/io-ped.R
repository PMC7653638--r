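#' Read a 6-column PED pedigree
#'
#' Standard whitespace-delimited PED: family id, sample id, father id,
#' mother id, sex (1 = male, 2 = female), phenotype (2 = affected,
#' 1 = unaffected). A parent id of `0` marks a missing parent (founder).
#'
#' @param path PED file.
#' @return A validated pedigree tibble with columns `family_id`,
#'   `sample_id`, `father_id`, `mother_id` (`NA` for founders), `sex`,
#'   `affected` (logical).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) abort(sprintf("PED file not found: %s", path))
  raw <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) abort(sprintf("cannot parse PED %s: %s", path,
                                      conditionMessage(e))))
  if (ncol(raw) != 6) {
    abort(sprintf("PED %s must have exactly 6 columns, found %d",
                  path, ncol(raw)))
  }
  names(raw) <- c("family_id", "sample_id", "father_id", "mother_id",
                  "sex", "phenotype")
  as_pedigree(tibble::tibble(
    family_id = raw$family_id,
    sample_id = raw$sample_id,
    father_id = ifelse(raw$father_id == "0", NA_character_, raw$father_id),
    mother_id = ifelse(raw$mother_id == "0", NA_character_, raw$mother_id),
    sex = as.integer(raw$sex),
    affected = raw$phenotype == "2"
  ))
}

#' Validate an in-memory pedigree
#'
#' Checks referential integrity (every parent id resolves to a member),
#' uniqueness of sample ids, and acyclicity (no individual is its own
#' ancestor). A pedigree without any affected member is accepted with a
#' warning, since segregation scans on it are vacuous.
#'
#' @param pedigree Data frame with columns `sample_id`, `father_id`,
#'   `mother_id`, `affected` (and optionally `family_id`, `sex`).
#' @return The pedigree as a tibble, invisibly classed for printing.
#' @export
as_pedigree <- function(pedigree) {
  assert_columns(pedigree, c("sample_id", "father_id", "mother_id",
                             "affected"), "pedigree")
  ped <- tibble::as_tibble(pedigree)
  if (anyDuplicated(ped$sample_id)) {
    abort(sprintf("duplicate sample id(s) in pedigree: %s",
                  paste(unique(ped$sample_id[duplicated(ped$sample_id)]),
                        collapse = ", ")))
  }
  parents <- c(ped$father_id, ped$mother_id)
  dangling <- setdiff(parents[!is.na(parents)], ped$sample_id)
  if (length(dangling) > 0) {
    abort(sprintf("pedigree references unknown parent id(s): %s",
                  paste(dangling, collapse = ", ")))
  }
  # Acyclicity: iteratively resolve members whose parents are all resolved;
  # anything left participates in a cycle (incl. self-parenting).
  resolved <- character(0)
  pending <- ped$sample_id
  repeat {
    ready <- pending[vapply(pending, function(id) {
      row <- ped[ped$sample_id == id, ]
      ok <- function(p) is.na(p) || p %in% resolved
      ok(row$father_id) && ok(row$mother_id)
    }, logical(1))]
    if (length(ready) == 0) break
    resolved <- c(resolved, ready)
    pending <- setdiff(pending, ready)
  }
  if (length(pending) > 0) {
    abort(sprintf("pedigree contains a cycle involving: %s",
                  paste(pending, collapse = ", ")))
  }
  if (!any(ped$affected)) {
    warn("pedigree has no affected member; segregation scans will be empty")
  }
  ped
}

#' Write a pedigree as a 6-column PED file
#'
#' @param pedigree Pedigree tibble (see [read_pedigree()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  assert_columns(pedigree, c("sample_id", "father_id", "mother_id",
                             "affected"), "pedigree")
  fam <- if ("family_id" %in% names(pedigree)) pedigree$family_id else "FAM1"
  sex <- if ("sex" %in% names(pedigree)) pedigree$sex else 0L
  lines <- paste(fam, pedigree$sample_id,
                 ifelse(is.na(pedigree$father_id), "0", pedigree$father_id),
                 ifelse(is.na(pedigree$mother_id), "0", pedigree$mother_id),
                 sex, ifelse(pedigree$affected, 2L, 1L), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Two-parent, two-affected-children quartet pedigree
#'
#' The nuclear family structure the pipeline is built around: two founder
#' parents (labelled unaffected — carrier parents of a digenic pair are
#' expected to be clinically unremarkable) and two affected children.
#'
#' @param family_id Family label.
#' @return Pedigree tibble with members `father`, `mother`, `proband`,
#'   `sibling`.
#' @export
#' @examples
#' quartet_pedigree()
quartet_pedigree <- function(family_id = "FAM1") {
  tibble::tibble(
    family_id = family_id,
    sample_id = c("father", "mother", "proband", "sibling"),
    father_id = c(NA, NA, "father", "father"),
    mother_id = c(NA, NA, "mother", "mother"),
    sex = c(1L, 2L, 2L, 2L),
    affected = c(FALSE, FALSE, TRUE, TRUE)
  )
}

affected_ids <- function(pedigree) {
  pedigree$sample_id[pedigree$affected]
}

founder_ids <- function(pedigree) {
  pedigree$sample_id[is.na(pedigree$father_id) & is.na(pedigree$mother_id)]
}
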
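#' Read a gene-set collection from a GMT file
#'
#' One set per line, tab-separated: set name, description, then one or more
#' gene symbols. Duplicate genes within a line are stored once (set
#' semantics); empty gene fields are dropped.
#'
#' @param path GMT file.
#' @return Tibble with one row per (set, gene): columns `set_name`,
#'   `description`, `gene`. An empty file yields an empty tibble.
#' @export
read_geneset <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf(
        "GMT parse error at line %d of %s: expected >= 3 tab-separated fields",
        i, path))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    j <- j + 1
    out[[j]] <- tibble::tibble(set_name = fields[1],
                               description = fields[2],
                               gene = genes)
  }
  sets <- dplyr::bind_rows(out)
  if (nrow(sets) == 0) {
    return(tibble::tibble(set_name = character(), description = character(),
                          gene = character()))
  }
  if (anyDuplicated(unique(sets[, c("set_name", "description")])$set_name)) {
    abort(sprintf("duplicate set name(s) in %s", path))
  }
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param genesets Tibble with columns `set_name`, `gene` and optionally
#'   `description`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_geneset <- function(genesets, path) {
  assert_columns(genesets, c("set_name", "gene"), "gene-set collection")
  desc <- if ("description" %in% names(genesets)) genesets$description
    else genesets$set_name
  split_genes <- split(genesets$gene, genesets$set_name)
  split_desc <- vapply(split(desc, genesets$set_name), `[`, character(1), 1)
  nm <- names(split_genes)
  writeLines(vapply(nm, function(s) {
    paste(c(s, split_desc[[s]], unique(split_genes[[s]])), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

# name -> character vector of genes
geneset_list <- function(genesets) {
  split(genesets$gene, genesets$set_name)
}
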
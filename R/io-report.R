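#' Write a ranked candidate-pair report
#'
#' Serializes candidate pairs with a fixed, documented column order:
#' `rank, gene_a, variant_a, origin_a, gene_b, variant_b, origin_b,
#' shared_affected_count, genesets, score`. The JSON form round-trips
#' losslessly through [read_report()].
#'
#' @param pairs Candidate-pair tibble (as produced by [rank_pairs()] or
#'   [scan_digenic()]); an empty tibble yields a header-only file.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(pairs, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  report <- report_table(pairs)
  if (format == "tsv") {
    readr::write_tsv(report, path, na = "")
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a candidate-pair report written by [write_report()]
#'
#' @param path Report file.
#' @param format `"tsv"` or `"json"`; inferred from the file extension by
#'   default.
#' @return Tibble with the documented report columns.
#' @export
read_report <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("report file not found: %s", path))
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv")
  if (format == "tsv") {
    out <- readr::read_tsv(path, col_types = readr::cols(
      rank = readr::col_integer(),
      gene_a = readr::col_character(), variant_a = readr::col_character(),
      origin_a = readr::col_character(),
      gene_b = readr::col_character(), variant_b = readr::col_character(),
      origin_b = readr::col_character(),
      shared_affected_count = readr::col_integer(),
      genesets = readr::col_character(),
      score = readr::col_double()
    ), na = "")
  } else {
    raw <- jsonlite::fromJSON(path)
    out <- if (length(raw) == 0) report_table(empty_pairs()) else
      tibble::as_tibble(raw)
    out$rank <- as.integer(out$rank)
    out$shared_affected_count <- as.integer(out$shared_affected_count)
    out$score <- as.double(out$score)
  }
  out[, REPORT_COLUMNS]
}

# Normalize an internal pair tibble to the external report schema.
report_table <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    p <- empty_pairs()
  } else {
    p <- pairs
  }
  if (!"rank" %in% names(p)) p$rank <- seq_len(nrow(p))
  if (!"score" %in% names(p)) p$score <- NA_real_
  if (!"genesets" %in% names(p)) p$genesets <- NA_character_
  if (!"shared_affected_count" %in% names(p)) {
    p$shared_affected_count <- vapply(p$shared_affected, length, integer(1))
  }
  tibble::tibble(
    rank = as.integer(p$rank),
    gene_a = p$gene_a, variant_a = p$variant_a, origin_a = p$origin_a,
    gene_b = p$gene_b, variant_b = p$variant_b, origin_b = p$origin_b,
    shared_affected_count = as.integer(p$shared_affected_count),
    genesets = p$genesets,
    score = p$score
  )
}

#' Read a per-variant annotation table
#'
#' Tab-separated with the exact columns `variant_id, gene, region_class,
#' af_global, af_popmax, cadd_phred, sift_score, polyphen2_score, lrt_pred,
#' mutationtaster_pred, gerp_rs, phylop_score`. Empty cells are missing
#' values. When both this table and VCF INFO keys provide a gene or region
#' class, the table is authoritative.
#'
#' @param path Annotation TSV.
#' @return Tibble with the columns above, typed (frequencies and numeric
#'   scores as doubles, categorical calls as character).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("annotation file not found: %s", path))
  }
  out <- readr::read_tsv(path, na = c("", "NA"), col_types = readr::cols(
    variant_id = readr::col_character(),
    gene = readr::col_character(),
    region_class = readr::col_character(),
    af_global = readr::col_double(),
    af_popmax = readr::col_double(),
    cadd_phred = readr::col_double(),
    sift_score = readr::col_double(),
    polyphen2_score = readr::col_double(),
    lrt_pred = readr::col_character(),
    mutationtaster_pred = readr::col_character(),
    gerp_rs = readr::col_double(),
    phylop_score = readr::col_double()
  ))
  assert_columns(out, ANNOTATION_COLUMNS, "annotation table")
  out[, ANNOTATION_COLUMNS]
}

#' Write a per-variant annotation table
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  assert_columns(annotations, ANNOTATION_COLUMNS, "annotation table")
  readr::write_tsv(annotations[, ANNOTATION_COLUMNS], path, na = "")
  invisible(path)
}
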
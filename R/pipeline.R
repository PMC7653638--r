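#' Run the digenic prioritization scan on in-memory tables
#'
#' Executes the fixed stage order of the pipeline and logs a funnel of
#' surviving counts: input variants -> autosomal -> coding region ->
#' rarity -> deleterious (majority vote) -> shared monoallelic ->
#' candidate pairs -> gene-set restricted -> ranked. The variant-level
#' counts are non-increasing by construction and this is asserted at run
#' time. Annotation-table gene symbols and region classes override any
#' carried on the variant records (the side table is authoritative).
#'
#' @param variants Variant table (see [read_vcf()]).
#' @param genotypes Long genotype table.
#' @param pedigree Pedigree tibble.
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param genesets Gene-set tibble, or `NULL` when
#'   `config$digenic$geneset_mode == "off"`.
#' @param config A [scan_config()].
#' @return An object of class `"digenic_scan"`: a list with `pairs` (the
#'   ranked CandidatePair tibble), `stage_counts` (funnel tibble with
#'   `stage`, `n`, `unit`), `candidates` (shared-monoallelic
#'   SegregationResult rows), `classified` (per-variant filter table),
#'   `config`, `pedigree`. Supports [tidy()], [glance()], [autoplot()] and
#'   `print()`.
#' @export
#' @examples
#' sim <- simulate_family_exome(sim_config(n_background = 200, seed = 3))
#' scan <- scan_digenic(sim$variants, sim$genotypes, sim$pedigree,
#'                      sim$annotations, sim$genesets)
#' glance(scan)
scan_digenic <- function(variants, genotypes, pedigree, annotations,
                         genesets = NULL, config = scan_config()) {
  assert_columns(variants, c("variant_id", "chrom"), "variant table")
  pedigree <- as_pedigree(pedigree)
  assert_columns(annotations, ANNOTATION_COLUMNS, "annotation table")

  # annotation table is authoritative for gene / region class
  ann <- annotations[match(variants$variant_id, annotations$variant_id), ]
  merged <- variants
  merged$gene <- dplyr::coalesce(ann$gene,
                                 variants$gene %||%
                                   rep(NA_character_, nrow(variants)))
  merged$region_class <- dplyr::coalesce(
    ann$region_class,
    variants$region_class %||% rep(NA_character_, nrow(variants)))
  ann$variant_id <- merged$variant_id
  ann$gene <- merged$gene
  ann$region_class <- merged$region_class

  counts <- list()
  counts[["input"]] <- nrow(merged)

  if (config$segregation$chromosomes == "autosomes") {
    keep <- is_autosome(merged$chrom)
    n_sex <- sum(!keep)
    if (n_sex > 0) {
      message(sprintf("excluding %d non-autosomal variant(s)", n_sex))
    }
    merged <- merged[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]
  }
  counts[["autosomal"]] <- nrow(merged)

  classified <- classify_variants(ann, config = config)

  keep <- classified$region_ok
  merged <- merged[keep, , drop = FALSE]
  classified_stage <- classified[keep, , drop = FALSE]
  counts[["region"]] <- nrow(merged)

  keep <- classified_stage$rare
  merged <- merged[keep, , drop = FALSE]
  classified_stage <- classified_stage[keep, , drop = FALSE]
  counts[["rarity"]] <- nrow(merged)

  keep <- classified_stage$deleterious
  merged <- merged[keep, , drop = FALSE]
  counts[["deleterious"]] <- nrow(merged)

  candidates <- shared_monoallelic_scan(
    merged, genotypes, pedigree,
    allow_other_parent_carrier =
      config$segregation$allow_other_parent_carrier)
  counts[["shared_monoallelic"]] <- nrow(candidates)

  maternal <- candidates[candidates$origin == "maternal", , drop = FALSE]
  paternal <- candidates[candidates$origin == "paternal", , drop = FALSE]
  pairs <- pair_trans(maternal, paternal, pedigree,
                      require_all_affected =
                        config$digenic$require_all_affected)
  counts[["pairs"]] <- nrow(pairs)

  if (config$digenic$geneset_mode != "off") {
    pairs <- geneset_restrict(pairs, genesets,
                              mode = config$digenic$geneset_mode)
  }
  counts[["geneset"]] <- nrow(pairs)

  pairs <- rank_pairs(pairs, classified, annotations)
  counts[["ranked"]] <- nrow(pairs)

  stage_counts <- tibble::tibble(
    stage = names(counts),
    n = as.integer(unlist(counts)),
    unit = c(rep("variants", 6), rep("pairs", 3))
  )
  variant_funnel <- stage_counts$n[stage_counts$unit == "variants"]
  stopifnot(all(diff(variant_funnel) <= 0))

  structure(list(
    pairs = pairs,
    stage_counts = stage_counts,
    candidates = candidates,
    classified = classified,
    config = config,
    pedigree = pedigree
  ), class = "digenic_scan")
}

#' Run the scan from files and write the report
#'
#' File-based front end of [scan_digenic()]: reads the VCF, PED, annotation
#' TSV, gene sets and optional YAML config, checks input consistency
#' (pedigree samples must match the VCF sample columns; the fraction of
#' variants lacking an annotation row must not exceed
#' `pipeline.max_missing_annotation`), runs the scan, and writes
#' `report.tsv`, `report.json`, `funnel.json` and the resolved
#' `config.yaml` into `out_dir`. Zero candidate pairs is a normal outcome,
#' not an error.
#'
#' @param vcf,ped,annotations Paths to the input files.
#' @param genesets Path to a GMT file, or `NULL` (requires gene-set mode
#'   `"off"`).
#' @param config A [scan_config()], a path to a YAML config, or `NULL` for
#'   defaults.
#' @param out_dir Output directory (created if needed).
#' @return The `"digenic_scan"` object, invisibly.
#' @export
run_scan <- function(vcf, ped, annotations, genesets = NULL,
                     config = NULL, out_dir = ".") {
  cfg <- if (is.null(config)) scan_config()
    else if (inherits(config, "scan_config")) config
    else read_scan_config(config)
  v <- read_vcf(vcf)
  pedigree <- read_pedigree(ped)
  ann <- read_annotations(annotations)
  gs <- if (!is.null(genesets)) read_geneset(genesets) else NULL

  vcf_samples <- unique(v$genotypes$sample_id)
  if (nrow(v$variants) > 0 &&
      !setequal(vcf_samples, pedigree$sample_id)) {
    abort(sprintf(
      "sample mismatch between VCF and PED: VCF has {%s}, PED has {%s}",
      paste(sort(vcf_samples), collapse = ", "),
      paste(sort(pedigree$sample_id), collapse = ", ")))
  }
  if (nrow(v$variants) > 0) {
    frac_missing <- mean(!(v$variants$variant_id %in% ann$variant_id))
    if (frac_missing > cfg$pipeline$max_missing_annotation) {
      abort(sprintf(
        "%.1f%% of variants have no annotation row (limit %.1f%%)",
        100 * frac_missing, 100 * cfg$pipeline$max_missing_annotation))
    }
  }

  scan <- scan_digenic(v$variants, v$genotypes, pedigree, ann,
                       genesets = gs, config = cfg)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(scan$pairs, file.path(out_dir, "report.tsv"), "tsv")
  write_report(scan$pairs, file.path(out_dir, "report.json"), "json")
  jsonlite::write_json(scan$stage_counts,
                       file.path(out_dir, "funnel.json"),
                       dataframe = "rows", pretty = TRUE)
  write_scan_config(cfg, file.path(out_dir, "config.yaml"))
  invisible(scan)
}

#' Score a written report against a written simulation truth
#'
#' @param truth Path to a `truth.json` written by [write_simulation()].
#' @param report Path to a report (TSV or JSON) from [write_report()].
#' @param out Optional path for a metrics JSON file.
#' @return Tibble with `recall`, `precision`, `n_candidates`.
#' @export
run_evaluate <- function(truth, report, out = NULL) {
  if (!file.exists(truth)) abort(sprintf("truth file not found: %s", truth))
  tr <- tryCatch(jsonlite::fromJSON(truth),
                 error = function(e) abort(sprintf(
                   "malformed truth file %s: %s", truth,
                   conditionMessage(e))))
  pairs <- read_report(report)
  metrics <- evaluate_recovery(tr, pairs)
  if (!is.null(out)) {
    jsonlite::write_json(as.list(metrics), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  metrics
}
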
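#' Rarity filter on population allele frequency
#'
#' A variant passes when the selected frequency field is missing — a novel
#' variant absent from the population database — or strictly below
#' `max_af`. The default field is the global database frequency rather
#' than the population-maximum: a digenic candidate may be common within
#' one ancestry subset (e.g. global MAF 0.002 with a subset MAF of 0.02)
#' and would be lost under a popmax rule; popmax mode remains available as
#' a stricter option.
#'
#' @param annotations Annotation tibble with `af_global` (and `af_popmax`
#'   when `use_popmax = TRUE`).
#' @param max_af Threshold frequency in (0, 1]. Default 0.01.
#' @param use_popmax Filter on `af_popmax` instead of `af_global`.
#' @return Logical vector, one element per annotation row.
#' @export
#' @examples
#' ann <- tibble::tibble(af_global = c(0.002, 0.00039, NA, 0.02))
#' rarity_pass(ann)
rarity_pass <- function(annotations, max_af = 0.01, use_popmax = FALSE) {
  if (!is.numeric(max_af) || length(max_af) != 1 ||
      max_af <= 0 || max_af > 1) {
    abort("max_af must be a single frequency in (0, 1]")
  }
  field <- if (isTRUE(use_popmax)) "af_popmax" else "af_global"
  assert_columns(annotations, field, "annotation table")
  af <- annotations[[field]]
  if (any(af < 0, na.rm = TRUE) || any(af > 1, na.rm = TRUE)) {
    abort(sprintf("%s contains frequencies outside [0, 1]", field))
  }
  is.na(af) | af < max_af
}

#' Tri-state call for one in-silico predictor
#'
#' Maps a predictor's raw score or categorical call to
#' `"damaging"` / `"benign"` / `"missing"` using the cutoff table (see
#' [predictor_thresholds()] for the rules and defaults). Absent values
#' (`NA` or empty string) are `"missing"` and never vote.
#'
#' @param name One of `"cadd"`, `"sift"`, `"polyphen2"`, `"lrt"`,
#'   `"mutationtaster"`, `"gerp"`, `"phylop"`.
#' @param values Numeric scores or character calls (vectorized).
#' @param thresholds Cutoff table from [predictor_thresholds()].
#' @return Character vector in `{"damaging", "benign", "missing"}`.
#' @export
#' @examples
#' predictor_call("cadd", c(25, 12, NA))
#' predictor_call("sift", 0.3)
predictor_call <- function(name, values,
                           thresholds = predictor_thresholds()) {
  if (length(name) != 1 || !name %in% PREDICTORS) {
    abort(sprintf("unknown predictor '%s'; expected one of: %s",
                  paste(name, collapse = ","),
                  paste(PREDICTORS, collapse = ", ")))
  }
  cut <- thresholds[[name]]
  if (name %in% c("lrt", "mutationtaster")) {
    v <- as.character(values)
    missing <- is.na(v) | !nzchar(v)
    damaging <- !missing & v %in% cut
  } else {
    v <- suppressWarnings(as.numeric(values))
    missing <- is.na(v)
    damaging <- !missing & (if (name == "sift") v <= cut else v >= cut)
  }
  as.character(ifelse(missing, "missing",
                      ifelse(damaging, "damaging", "benign")))
}

#' Majority vote over the predictor ensemble
#'
#' A variant's verdict is deleterious when strictly more than half of the
#' informative (non-missing) calls are damaging AND at least
#' `min_informative` calls are informative. Ties are not a majority.
#' Variants with too few informative predictors are conservatively not
#' deleterious and flagged `insufficient_evidence` rather than guessed.
#'
#' @param calls A character matrix / data frame with one column per
#'   predictor and values in `{"damaging", "benign", "missing"}` (`NA` is
#'   treated as missing), or a named character vector for a single variant.
#' @param min_informative Minimum informative calls for a verdict
#'   (default 4 of 7).
#' @return Tibble with columns `n_damaging`, `n_informative`,
#'   `insufficient_evidence`, `verdict`, one row per input row.
#' @export
#' @examples
#' majority_vote(c(cadd = "damaging", sift = "damaging",
#'                 polyphen2 = "damaging", lrt = "damaging",
#'                 mutationtaster = "benign", gerp = "benign",
#'                 phylop = "benign"))
majority_vote <- function(calls, min_informative = 4) {
  if (is.null(dim(calls))) calls <- t(as.matrix(calls))
  m <- as.matrix(calls)
  bad <- !(m %in% c("damaging", "benign", "missing") | is.na(m))
  if (any(bad)) {
    abort(sprintf("invalid call value(s): %s",
                  paste(unique(m[bad]), collapse = ", ")))
  }
  if (ncol(m) > length(PREDICTORS)) {
    abort("calls cover more than the seven-predictor ensemble")
  }
  n_damaging <- rowSums(m == "damaging", na.rm = TRUE)
  n_informative <- rowSums(m == "damaging" | m == "benign", na.rm = TRUE)
  insufficient <- n_informative < min_informative
  tibble::tibble(
    n_damaging = as.integer(n_damaging),
    n_informative = as.integer(n_informative),
    insufficient_evidence = insufficient,
    verdict = !insufficient & n_damaging > n_informative / 2
  )
}

#' Coding-region filter
#'
#' Keeps variants in coding regions or near exon-intron junctions:
#' `region_class` must be `"exonic"` or `"splicing"`. Any other known label
#' (`"other"`) fails; unknown labels are a validation error; a missing
#' region class fails without erroring.
#'
#' @param variants Tibble with a `region_class` column (a bare character
#'   vector is also accepted).
#' @return Logical vector.
#' @export
#' @examples
#' region_pass(c("exonic", "splicing", "other"))
region_pass <- function(variants) {
  region <- if (is.data.frame(variants)) {
    assert_columns(variants, "region_class", "variant table")
    variants$region_class
  } else {
    variants
  }
  unknown <- setdiff(unique(region[!is.na(region)]), REGION_LEVELS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown region_class label(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  !is.na(region) & region %in% c("exonic", "splicing")
}

#' Classify variants: rarity, region and majority-vote deleteriousness
#'
#' Applies the three per-variant filters to an annotation table in one
#' pass. `deleterious` is the majority-vote verdict alone; the pipeline
#' combines it with `region_ok` and `rare` when building its funnel.
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param config A [scan_config()].
#' @return Tibble with `variant_id`, `gene`, `region_class`, `region_ok`,
#'   `rare`, one `call_<predictor>` column per predictor, `n_damaging`,
#'   `n_informative`, `insufficient_evidence`, `deleterious`.
#' @export
#' @examples
#' sim <- simulate_family_exome(sim_config(n_background = 50, seed = 1))
#' classify_variants(sim$annotations)
classify_variants <- function(annotations, config = scan_config()) {
  assert_columns(annotations, ANNOTATION_COLUMNS, "annotation table")
  calls <- vapply(PREDICTORS, function(p) {
    predictor_call(p, annotations[[PREDICTOR_COLUMNS[[p]]]],
                   thresholds = config$vote$thresholds)
  }, character(nrow(annotations)))
  if (nrow(annotations) == 1) calls <- t(as.matrix(calls))
  vote <- majority_vote(calls,
                        min_informative = config$vote$min_informative)
  call_cols <- tibble::as_tibble(as.data.frame(calls,
                                               stringsAsFactors = FALSE))
  names(call_cols) <- paste0("call_", PREDICTORS)
  dplyr::bind_cols(
    tibble::tibble(
      variant_id = annotations$variant_id,
      gene = annotations$gene,
      region_class = annotations$region_class,
      region_ok = region_pass(annotations$region_class),
      rare = rarity_pass(annotations, max_af = config$rarity$max_af,
                         use_popmax = config$rarity$use_popmax)
    ),
    call_cols,
    tibble::tibble(
      n_damaging = vote$n_damaging,
      n_informative = vote$n_informative,
      insufficient_evidence = vote$insufficient_evidence,
      deleterious = vote$verdict
    )
  )
}
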
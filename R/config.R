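#' Per-predictor damaging cutoffs
#'
#' Operating points at which each of the seven in-silico predictors is read
#' as a "damaging" call. The values are the tools' conventional published
#' thresholds; the underlying study lists the programs but no cutoffs, so
#' every one is overridable here or through the `vote.thresholds.*` config
#' keys.
#'
#' * CADD: PHRED-scaled score >= 20 (top 1\% of possible substitutions).
#' * SIFT: tolerance score <= 0.05 (lower = more damaging).
#' * PolyPhen-2: probability >= 0.446 ("possibly damaging" boundary).
#' * LRT: categorical call `"D"` (deleterious).
#' * MutationTaster: call in `{"A", "D"}` (disease causing).
#' * GERP++: rejected-substitutions score >= 2.0.
#' * PhyloP: conservation score >= 1.5.
#'
#' @param cadd,sift,polyphen2,gerp,phylop Numeric cutoffs.
#' @param lrt,mutationtaster Character vectors of calls read as damaging.
#' @return Named list of thresholds, one entry per predictor.
#' @export
predictor_thresholds <- function(cadd = 20, sift = 0.05, polyphen2 = 0.446,
                                 gerp = 2.0, phylop = 1.5,
                                 lrt = "D", mutationtaster = c("A", "D")) {
  stopifnot(is.numeric(cadd), is.numeric(sift), is.numeric(polyphen2),
            is.numeric(gerp), is.numeric(phylop),
            is.character(lrt), is.character(mutationtaster))
  list(cadd = cadd, sift = sift, polyphen2 = polyphen2, gerp = gerp,
       phylop = phylop, lrt = lrt, mutationtaster = mutationtaster)
}

#' Scan configuration
#'
#' Bundles every tunable of the prioritization pipeline. Defaults encode the
#' study design the package implements: variants are retained when novel or
#' rarer than 1\% in the population database, called deleterious when a
#' strict majority of informative predictors votes damaging (with at least
#' `min_informative` votes cast), segregation requires the non-transmitting
#' parent to be homozygous reference, and candidate gene pairs must co-occur
#' in at least one supplied gene set.
#'
#' @param max_af Rarity threshold on the population allele frequency,
#'   in (0, 1]. A variant passes when its frequency is missing (novel) or
#'   strictly below this value. Default 0.01.
#' @param use_popmax Use the population-maximum frequency instead of the
#'   global frequency (stricter). Default `FALSE`: the global frequency is
#'   the field the rarity rule is applied to.
#' @param min_informative Minimum number of non-missing predictor calls
#'   required before a majority verdict is issued; variants with fewer are
#'   conservatively classified non-deleterious. Default 4 of 7.
#' @param thresholds Per-predictor cutoffs, see [predictor_thresholds()].
#' @param allow_other_parent_carrier Permissive shared-monoallelic mode: the
#'   non-carrier parent's genotype is ignored rather than required to be
#'   observed homozygous reference. Default `FALSE` (strict), which is the
#'   mode under which parental origin, and hence a trans configuration, is
#'   unambiguous.
#' @param chromosomes `"autosomes"` (default; X/Y/MT are excluded with a
#'   logged count) or `"all"`.
#' @param require_all_affected Candidate pairs must be carried by every
#'   affected member (default `TRUE`).
#' @param geneset_mode `"both_in_same_set"` (default), `"either"`, or
#'   `"off"`; see [geneset_restrict()].
#' @param max_missing_annotation Abort a file-based scan when more than this
#'   fraction of variants has no annotation row. Default 0.2.
#' @return A list of class `"scan_config"` with components `rarity`,
#'   `vote`, `segregation`, `digenic`, `pipeline`.
#' @export
#' @examples
#' cfg <- scan_config(max_af = 0.005, use_popmax = TRUE)
#' cfg$rarity$max_af
scan_config <- function(max_af = 0.01,
                        use_popmax = FALSE,
                        min_informative = 4,
                        thresholds = predictor_thresholds(),
                        allow_other_parent_carrier = FALSE,
                        chromosomes = c("autosomes", "all"),
                        require_all_affected = TRUE,
                        geneset_mode = c("both_in_same_set", "either", "off"),
                        max_missing_annotation = 0.2) {
  chromosomes <- match.arg(chromosomes)
  geneset_mode <- match.arg(geneset_mode)
  if (!is.numeric(max_af) || length(max_af) != 1 ||
      max_af <= 0 || max_af > 1) {
    abort("rarity.max_af must be a single frequency in (0, 1]")
  }
  if (!is.numeric(min_informative) || min_informative < 0 ||
      min_informative > length(PREDICTORS)) {
    abort("vote.min_informative must be between 0 and 7")
  }
  unknown <- setdiff(names(thresholds), PREDICTORS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown predictor(s) in thresholds: %s",
                  paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      rarity = list(max_af = max_af, use_popmax = isTRUE(use_popmax)),
      vote = list(min_informative = as.integer(min_informative),
                  thresholds = modifyList(predictor_thresholds(), thresholds)),
      segregation = list(
        allow_other_parent_carrier = isTRUE(allow_other_parent_carrier),
        chromosomes = chromosomes
      ),
      digenic = list(require_all_affected = isTRUE(require_all_affected),
                     geneset_mode = geneset_mode),
      pipeline = list(max_missing_annotation = max_missing_annotation)
    ),
    class = "scan_config"
  )
}

#' Read a scan configuration from a YAML file
#'
#' Keys are grouped as in [scan_config()] (`rarity:`, `vote:`,
#' `segregation:`, `digenic:`, `pipeline:`); any key left out falls back to
#' the package default. `vote.thresholds` entries override individual
#' predictor cutoffs.
#'
#' @param path YAML file.
#' @return A `"scan_config"` object.
#' @export
read_scan_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  get <- function(group, key, default) {
    val <- raw[[group]][[key]]
    if (is.null(val)) default else val
  }
  thresholds <- modifyList(predictor_thresholds(),
                           raw[["vote"]][["thresholds"]] %||% list())
  scan_config(
    max_af = get("rarity", "max_af", 0.01),
    use_popmax = get("rarity", "use_popmax", FALSE),
    min_informative = get("vote", "min_informative", 4),
    thresholds = thresholds,
    allow_other_parent_carrier =
      get("segregation", "allow_other_parent_carrier", FALSE),
    chromosomes = get("segregation", "chromosomes", "autosomes"),
    require_all_affected = get("digenic", "require_all_affected", TRUE),
    geneset_mode = get("digenic", "geneset_mode", "both_in_same_set"),
    max_missing_annotation = get("pipeline", "max_missing_annotation", 0.2)
  )
}

#' Write a resolved scan configuration to YAML
#'
#' @param config A `"scan_config"` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan_config <- function(config, path) {
  stopifnot(inherits(config, "scan_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
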
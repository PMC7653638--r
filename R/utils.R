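# Canonical predictor order used throughout: the seven-member in-silico
# ensemble voted on by the deleteriousness classifier.
PREDICTORS <- c("cadd", "sift", "polyphen2", "lrt", "mutationtaster",
                "gerp", "phylop")

# Annotation-table column housing each predictor's raw score or call.
PREDICTOR_COLUMNS <- c(
  cadd = "cadd_phred",
  sift = "sift_score",
  polyphen2 = "polyphen2_score",
  lrt = "lrt_pred",
  mutationtaster = "mutationtaster_pred",
  gerp = "gerp_rs",
  phylop = "phylop_score"
)

REGION_LEVELS <- c("exonic", "splicing", "other")

ANNOTATION_COLUMNS <- c("variant_id", "gene", "region_class",
                        "af_global", "af_popmax", unname(PREDICTOR_COLUMNS))

REPORT_COLUMNS <- c("rank", "gene_a", "variant_a", "origin_a",
                    "gene_b", "variant_b", "origin_b",
                    "shared_affected_count", "genesets", "score")

assert_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    abort(paste0(what, " must be a data frame"))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Canonical variant key
#'
#' Builds the canonical `"chrom:pos:ref:alt"` identifier used as the key for
#' every per-variant table in the package. Coordinates are 1-based (VCF
#' convention) and the key refers to a single alternate allele, so
#' multiallelic sites must be split before keys are assigned.
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based positions.
#' @param ref Reference alleles.
#' @param alt Single alternate alleles.
#' @return Character vector of variant identifiers.
#' @export
#' @examples
#' variant_key("chr8", 38285540, "G", "A")
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

autosome_labels <- function() {
  c(as.character(1:22), paste0("chr", 1:22))
}

is_autosome <- function(chrom) {
  chrom %in% autosome_labels()
}

# Long genotype tibble (variant_id, sample_id, gt) -> integer matrix with
# variants as rows and samples as columns. Pairs absent from the long table
# come back as NA (missing genotype).
gt_matrix <- function(genotypes, variant_ids = NULL, sample_ids = NULL) {
  assert_columns(genotypes, c("variant_id", "sample_id", "gt"),
                 "genotype table")
  variant_ids <- variant_ids %||% unique(genotypes$variant_id)
  sample_ids <- sample_ids %||% unique(genotypes$sample_id)
  m <- matrix(NA_integer_, nrow = length(variant_ids),
              ncol = length(sample_ids),
              dimnames = list(variant_ids, sample_ids))
  keep <- genotypes$variant_id %in% variant_ids &
    genotypes$sample_id %in% sample_ids
  g <- genotypes[keep, , drop = FALSE]
  m[cbind(match(g$variant_id, variant_ids),
          match(g$sample_id, sample_ids))] <- as.integer(g$gt)
  m
}

# Matrix -> long tibble, inverse of gt_matrix (row-major over variants so
# record order is preserved).
gt_long <- function(m) {
  tibble::tibble(
    variant_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    gt = as.integer(m)
  )
}

empty_segregation <- function() {
  tibble::tibble(
    variant_id = character(),
    gene = character(),
    pattern = character(),
    origin = character(),
    affected_carriers = list(),
    partner_variant = character()
  )
}

empty_pairs <- function() {
  tibble::tibble(
    gene_a = character(), variant_a = character(), origin_a = character(),
    gene_b = character(), variant_b = character(), origin_b = character(),
    shared_affected = list(), shared_affected_count = integer(),
    genesets = character(), score = double(), rank = integer()
  )
}
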